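#' Read beat annotations from CSV
#'
#' The CSV dialect has a mandatory header `sample_index,beat_class`; classes
#' are serialized as `"N"`, `"PVC"`, `"PAC"`.
#'
#' @param path CSV file path.
#' @return beat-annotation data.frame sorted by `sample_index`.
#' @export
read_csv_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  header <- strsplit(trimws(lines[1L]), ",")[[1L]]
  if (length(header) < 2L || header[1L] != "sample_index" || header[2L] != "beat_class") {
    stop("bad annotation header in ", path,
         ": expected 'sample_index,beat_class', got '", lines[1L], "'")
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(beat_annotations())
  parts <- strsplit(body, ",")
  idx <- integer(length(body))
  cls <- character(length(body))
  for (i in seq_along(body)) {
    p <- trimws(parts[[i]])
    if (length(p) < 2L) stop("malformed annotation row at line ", i + 1L, ": '", body[i], "'")
    v <- suppressWarnings(as.integer(p[1L]))
    if (is.na(v)) stop("bad sample_index '", p[1L], "' at line ", i + 1L)
    if (!(p[2L] %in% ANNOTATION_CLASSES)) {
      stop("unknown beat class token '", p[2L], "' at line ", i + 1L)
    }
    idx[i] <- v
    cls[i] <- p[2L]
  }
  beat_annotations(idx, cls)
}

#' Write beat annotations to CSV
#'
#' Inverse of [read_csv_annotations()]: write-then-read is the identity on
#' valid annotation tables.
#'
#' @param annotations beat-annotation data.frame.
#' @param path output CSV file path.
#' @export
write_csv_annotations <- function(annotations, path) {
  annotations <- beat_annotations(annotations$sample_index, annotations$beat_class)
  lines <- c("sample_index,beat_class",
             sprintf("%d,%s", annotations$sample_index, annotations$beat_class))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a JSON record container
#'
#' The JSON container holds a full annotated record:
#' `{record_id, fs, lead_name, samples, annotations: [{sample_index, beat_class}, ...]}`.
#' Used for synthetic fixtures and the `simulate` CLI output.
#'
#' @param path JSON file path.
#' @return an [annotated_record()].
#' @export
read_json_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("record_id", "fs", "samples")) {
    if (is.null(x[[key]])) stop("JSON record missing field '", key, "': ", path)
  }
  rec <- ecg_record(x$samples, x$fs,
                    lead_name = if (is.null(x$lead_name)) "I" else x$lead_name,
                    record_id = x$record_id)
  ann <- x$annotations
  if (is.null(ann) || length(ann) == 0L) {
    ann <- beat_annotations()
  } else {
    ann <- beat_annotations(ann$sample_index, ann$beat_class)
  }
  annotated_record(rec, ann)
}

#' @param arec an [annotated_record()] to serialize.
#' @rdname read_json_record
#' @export
write_json_record <- function(arec, path) {
  stopifnot(inherits(arec, "annotated_record"))
  obj <- list(
    record_id = arec$record$record_id,
    fs = arec$record$fs,
    lead_name = arec$record$lead_name,
    samples = arec$record$samples,
    annotations = arec$annotations
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
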