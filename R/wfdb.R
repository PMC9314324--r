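# Minimal WFDB support: header (.hea) parsing, signal formats 8/16/80/212,
# MIT annotation files. Reading only; the package never writes WFDB files.

# MIT annotation code -> symbol (index = code). Codes with no symbol are NA.
WFDB_ANN_CODES <- local({
  s <- rep(NA_character_, 49)
  s[c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14)] <-
    c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q", "~")
  s[c(16, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31)] <-
    c("|", "s", "T", "*", "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?", "!")
  s[c(32, 33, 34, 35, 36, 37, 38, 39, 40, 41)] <-
    c("[", "]", "e", "n", "@", "x", "f", "(", ")", "r")
  s
})

#' Beat symbol to class mapping
#'
#' Frozen mapping from WFDB beat annotation symbols to the three supported
#' classes. Beats annotated in more detail than N/PAC/PVC are mapped to the
#' closest supported option: bundle-branch-block, escape, paced and fusion-
#' with-paced beats to `N`; atrial/nodal/supraventricular premature beats to
#' `PAC`; ventricular ectopy including R-on-T and ventricular fusion to
#' `PVC`. Non-beat symbols (rhythm changes, noise marks, waveform boundaries)
#' are dropped. Beat-like symbols absent from the table map to `N` with a
#' warning.
#'
#' @format Named character vector: names are WFDB symbols, values classes.
#' @export
WFDB_BEAT_CLASS_MAP <- c(
  "N" = "N", "L" = "N", "R" = "N", "B" = "N", "e" = "N", "j" = "N",
  "n" = "N", "f" = "N", "/" = "N", "Q" = "N", "?" = "N",
  "A" = "PAC", "a" = "PAC", "J" = "PAC", "S" = "PAC",
  "V" = "PVC", "r" = "PVC", "E" = "PVC", "F" = "PVC"
)

WFDB_NONBEAT_SYMBOLS <- c("~", "|", "s", "T", "*", "D", "\"", "=", "p", "^",
                          "t", "+", "u", "!", "[", "]", "@", "x", "(", ")")

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("corrupt WFDB header (no record line): ", hea_path)
  rec_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec_tok) < 2L) stop("corrupt WFDB header record line: ", hea_path)
  record_name <- sub("/.*$", "", rec_tok[1L])
  nsig <- suppressWarnings(as.integer(rec_tok[2L]))
  if (is.na(nsig) || nsig < 0L) stop("corrupt WFDB header (bad signal count): ", hea_path)
  fs <- 250
  if (length(rec_tok) >= 3L) {
    fs_tok <- sub("/.*$", "", rec_tok[3L])   # strip counter frequency
    fs <- suppressWarnings(as.numeric(fs_tok))
    if (is.na(fs) || fs <= 0) stop("corrupt WFDB header (bad fs): ", hea_path)
  }
  nsamp <- if (length(rec_tok) >= 4L) suppressWarnings(as.integer(rec_tok[4L])) else NA_integer_
  if (length(lines) < 1L + nsig) stop("corrupt WFDB header (missing signal lines): ", hea_path)
  signals <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    tok <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    if (length(tok) < 2L) stop("corrupt WFDB signal line ", i, ": ", hea_path)
    fmt <- as.integer(sub("[x:+].*$", "", tok[2L]))
    gain <- 200; baseline <- NA_real_; adc_zero <- 0
    if (length(tok) >= 3L) {
      g <- tok[3L]
      m <- regmatches(g, regexec("^(-?[0-9.]+)(\\(([-0-9]+)\\))?(/.*)?$", g))[[1L]]
      if (length(m) > 0L) {
        gain <- as.numeric(m[2L])
        if (nzchar(m[4L])) baseline <- as.numeric(m[4L])
      }
    }
    if (length(tok) >= 5L) adc_zero <- suppressWarnings(as.numeric(tok[5L]))
    if (is.na(adc_zero)) adc_zero <- 0
    if (is.na(gain) || gain == 0) gain <- 200
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else ""
    signals[[i]] <- list(file = tok[1L], format = fmt, gain = gain,
                         baseline = baseline, description = desc)
  }
  list(record_name = record_name, nsig = nsig, fs = fs, nsamp = nsamp,
       signals = signals)
}

read_wfdb_signals <- function(hdr, dat_path) {
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.info(dat_path)$size)
  fmt <- hdr$signals[[1L]]$format
  nsig <- hdr$nsig
  if (fmt == 16L) {
    vals <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                    signed = TRUE, endian = "little")
  } else if (fmt == 80L) {
    vals <- as.integer(raw) - 128L
  } else if (fmt == 212L) {
    n3 <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(n3)])
    b0 <- b[seq(1L, n3, by = 3L)]
    b1 <- b[seq(2L, n3, by = 3L)]
    b2 <- b[seq(3L, n3, by = 3L)]
    s0 <- bitwOr(bitwShiftL(bitwAnd(b1, 0x0FL), 8L), b0)
    s1 <- bitwOr(bitwShiftL(bitwAnd(b1, 0xF0L), 4L), b2)
    s0 <- ifelse(s0 >= 2048L, s0 - 4096L, s0)
    s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
    vals <- as.vector(rbind(s0, s1))
  } else if (fmt == 8L) {
    # first differences, 8-bit signed
    d <- as.integer(raw)
    d <- ifelse(d >= 128L, d - 256L, d)
    vals <- d   # per-channel cumsum applied after demultiplexing
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  nframes <- length(vals) %/% nsig
  if (!is.na(hdr$nsamp) && hdr$nsamp > 0L) nframes <- min(nframes, hdr$nsamp)
  m <- matrix(vals[seq_len(nframes * nsig)], ncol = nsig, byrow = TRUE)
  if (fmt == 8L) m <- apply(m, 2L, cumsum)
  # adc units -> physical units
  for (i in seq_len(nsig)) {
    m[, i] <- (m[, i] - hdr$signals[[i]]$baseline) / hdr$signals[[i]]$gain
  }
  m
}

read_wfdb_annotations <- function(ann_path) {
  raw <- readBin(ann_path, "raw", n = file.info(ann_path)$size)
  n <- length(raw)
  pos <- 1L
  time <- 0
  pending <- 0
  samples <- numeric(0)
  symbols <- character(0)
  while (pos + 1L <= n) {
    b0 <- as.integer(raw[pos]); b1 <- as.integer(raw[pos + 1L])
    pos <- pos + 2L
    word <- bitwOr(b0, bitwShiftL(b1, 8L))
    code <- bitwShiftR(word, 10L)
    interval <- bitwAnd(word, 0x3FFL)
    if (code == 0L && interval == 0L) break
    if (code == 59L) {           # SKIP: 4-byte long interval, high word first
      if (pos + 3L > n) break
      w1 <- bitwOr(as.integer(raw[pos]), bitwShiftL(as.integer(raw[pos + 1L]), 8L))
      w2 <- bitwOr(as.integer(raw[pos + 2L]), bitwShiftL(as.integer(raw[pos + 3L]), 8L))
      pos <- pos + 4L
      pending <- pending + w1 * 65536 + w2
    } else if (code %in% c(60L, 61L, 62L)) {   # NUM / SUB / CHN modifiers
      next
    } else if (code == 63L) {    # AUX: interval = byte count, padded to even
      skip <- interval + (interval %% 2L)
      pos <- pos + skip
    } else {
      time <- time + pending + interval
      pending <- 0
      sym <- if (code >= 1L && code <= length(WFDB_ANN_CODES)) WFDB_ANN_CODES[code] else NA_character_
      samples <- c(samples, time)
      symbols <- c(symbols, if (is.na(sym)) sprintf("<%d>", code) else sym)
    }
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

map_beat_symbols <- function(symbols) {
  keep <- !(symbols %in% WFDB_NONBEAT_SYMBOLS)
  symbols <- symbols[keep]
  cls <- WFDB_BEAT_CLASS_MAP[symbols]
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unknown beat symbol(s) mapped to N: ",
            paste(unique(symbols[unknown]), collapse = " "), call. = FALSE)
    cls[unknown] <- "N"
  }
  list(keep = keep, class = unname(cls))
}

#' Read a WFDB record with optional beat annotations
#'
#' Parses the WFDB header/signal pair at `path` (with or without the `.hea`
#' extension), reduces multi-lead recordings to a single lead (lead "I" when
#' present, otherwise the first lead), and attaches beat annotations from the
#' companion annotation file when one exists. Beat symbols outside
#' \{N, PAC, PVC\} are mapped to the closest supported class via
#' [WFDB_BEAT_CLASS_MAP]; non-beat symbols are dropped.
#'
#' @param path record path (header file, with or without `.hea`).
#' @param annotation_extension extension of the annotation file (default
#'   `"atr"`); set `NULL` to skip annotations.
#' @return an [annotated_record()].
#' @export
read_wfdb_record <- function(path, annotation_extension = "atr") {
  base <- sub("\\.hea$", "", path)
  hdr <- parse_wfdb_header(paste0(base, ".hea"))
  if (hdr$nsig < 1L) stop("record has no signals: ", path)
  dat_path <- file.path(dirname(base), hdr$signals[[1L]]$file)
  m <- read_wfdb_signals(hdr, dat_path)
  lead_names <- vapply(hdr$signals, function(s) {
    if (nzchar(s$description)) s$description else s$file
  }, character(1))
  sel <- select_lead(m, lead_names)
  rec <- ecg_record(sel$samples, hdr$fs, lead_name = sel$lead_name,
                    record_id = hdr$record_name)
  ann <- beat_annotations()
  if (!is.null(annotation_extension)) {
    ann_path <- paste0(base, ".", annotation_extension)
    if (file.exists(ann_path)) {
      tab <- read_wfdb_annotations(ann_path)
      mp <- map_beat_symbols(tab$symbol)
      idx <- tab$sample[mp$keep]
      beyond <- idx >= length(rec$samples)
      if (any(beyond)) {
        stop("annotation sample index beyond signal end in ", ann_path, ": ",
             paste(idx[beyond], collapse = ", "))
      }
      if (anyDuplicated(idx)) {
        first <- !duplicated(idx)
        idx <- idx[first]; mp$class <- mp$class[first]
      }
      ann <- beat_annotations(idx, mp$class)
    }
  }
  annotated_record(rec, ann)
}
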