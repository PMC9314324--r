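#' Beat class levels
#'
#' Fixed four-class channel order used everywhere in the package:
#' channel 0 = `NOQRS` (no beat), 1 = `N` (normal sinus QRS),
#' 2 = `PVC` (premature ventricular contraction),
#' 3 = `PAC` (premature atrial contraction).
#'
#' Annotations only ever carry the three beat classes (`N`, `PVC`, `PAC`);
#' `NOQRS` exists as the background channel of segmentation masks.
#'
#' @format Character vector of length 4, in channel order.
#' @export
BEAT_CLASSES <- c("NOQRS", "N", "PVC", "PAC")

#' @rdname BEAT_CLASSES
#' @export
ANNOTATION_CLASSES <- c("N", "PVC", "PAC")

#' Channel index (0-based) of a beat class
#'
#' @param class character vector of class names.
#' @return integer vector of 0-based channel indices.
#' @export
beat_class_index <- function(class) {
  idx <- match(class, BEAT_CLASSES)
  if (anyNA(idx)) {
    stop("unknown beat class: ", paste(unique(class[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Construct a single-lead ECG record
#'
#' Sample indices are 0-based throughout the package; time in seconds is
#' `sample_index / fs`.
#'
#' @param samples numeric vector of amplitudes (arbitrary units, typically mV).
#' @param fs sampling frequency in Hz (> 0).
#' @param lead_name lead label, e.g. `"I"`.
#' @param record_id record identifier.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead_name = "I", record_id = "record") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("record must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive finite number")
  }
  if (any(!is.finite(samples))) {
    stop("record '", record_id, "' contains non-finite sample values")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         lead_name = as.character(lead_name), record_id = as.character(record_id)),
    class = "ecg_record"
  )
}

#' Construct a beat annotation table
#'
#' @param sample_index integer vector of 0-based beat fiducial positions.
#' @param beat_class character vector of classes in `c("N","PVC","PAC")`.
#' @return data.frame with columns `sample_index`, `beat_class`, sorted by
#'   `sample_index`.
#' @export
beat_annotations <- function(sample_index = integer(0), beat_class = character(0)) {
  if (length(sample_index) != length(beat_class)) {
    stop("sample_index and beat_class must have equal length")
  }
  sample_index <- as.integer(round(sample_index))
  beat_class <- as.character(beat_class)
  bad <- !(beat_class %in% ANNOTATION_CLASSES)
  if (any(bad)) {
    stop("unknown beat class: ", paste(unique(beat_class[bad]), collapse = ", "))
  }
  ord <- order(sample_index)
  ann <- data.frame(sample_index = sample_index[ord],
                    beat_class = beat_class[ord],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$sample_index)) {
    stop("duplicate annotation sample_index: ",
         paste(unique(ann$sample_index[duplicated(ann$sample_index)]), collapse = ", "))
  }
  ann
}

#' Construct an annotated ECG record
#'
#' @param record an [ecg_record()].
#' @param annotations a beat-annotation data.frame (see [beat_annotations()]).
#' @return object of class `annotated_record` with fields `record` and
#'   `annotations`.
#' @export
annotated_record <- function(record, annotations = beat_annotations()) {
  stopifnot(inherits(record, "ecg_record"))
  annotations <- beat_annotations(annotations$sample_index, annotations$beat_class)
  n <- length(record$samples)
  out_of_bounds <- annotations$sample_index < 0L | annotations$sample_index >= n
  if (any(out_of_bounds)) {
    stop("annotation sample_index out of bounds [0, ", n, ") for record '",
         record$record_id, "': ",
         paste(annotations$sample_index[out_of_bounds], collapse = ", "))
  }
  structure(list(record = record, annotations = annotations),
            class = "annotated_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> lead %s, %d samples @ %g Hz (%.1f s)\n",
              x$record_id, x$lead_name, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
print.annotated_record <- function(x, ...) {
  print(x$record)
  counts <- table(factor(x$annotations$beat_class, levels = ANNOTATION_CLASSES))
  cat(sprintf("  %d beats (N: %d, PVC: %d, PAC: %d)\n",
              nrow(x$annotations), counts[["N"]], counts[["PVC"]], counts[["PAC"]]))
  invisible(x)
}

#' Select the analysis lead from a multi-lead signal matrix
#'
#' Lead "I" is used when present (case-insensitive exact match); otherwise the
#' first lead is used.
#'
#' @param signals numeric matrix, one column per lead (vectors are treated as
#'   a single lead).
#' @param lead_names character vector parallel to the columns.
#' @return list with `samples` (numeric vector) and `lead_name`.
#' @export
select_lead <- function(signals, lead_names) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1L)
  if (ncol(signals) == 0L || length(lead_names) == 0L) {
    stop("no leads to select from")
  }
  if (length(lead_names) != ncol(signals)) {
    stop("lead_names must be parallel to signal columns")
  }
  hit <- which(toupper(trimws(lead_names)) == "I")
  idx <- if (length(hit) > 0L) hit[1L] else 1L
  list(samples = as.numeric(signals[, idx]), lead_name = as.character(lead_names[idx]))
}
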