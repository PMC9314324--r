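# Deterministic post-processing: per-sample argmax -> maximal same-class
# segments -> segment centers as candidate peaks -> iterative suppression
# of the weaker of any two peaks closer than 0.15 s.

MIN_PEAK_GAP_S <- 0.15
MIN_SEGMENT_LEN <- 2L

#' Per-sample argmax labels of a probability mask
#'
#' Ties break toward the lower channel index (NOQRS first).
#'
#' @param mask `4 x L` probability matrix (rows NOQRS, N, PVC, PAC).
#' @return integer vector of length `L` with 0-based class indices.
#' @export
argmax_labels <- function(mask) {
  stopifnot(is.matrix(mask), nrow(mask) == 4L)
  max.col(t(mask), ties.method = "first") - 1L
}

#' Maximal runs of identical non-background labels
#'
#' Runs shorter than `min_len` samples are discarded as argmax flicker.
#'
#' @param labels integer vector of 0-based class indices.
#' @param min_len minimum run length in samples (default 2).
#' @return data.frame with 0-based `start` (inclusive), `end` (exclusive)
#'   and `class_index` columns.
#' @export
labels_to_segments <- function(labels, min_len = MIN_SEGMENT_LEN) {
  if (length(labels) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      class_index = integer(0)))
  }
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0L & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             class_index = r$values[keep])
}

#' Candidate peaks from segments
#'
#' The candidate position is the segment center, `floor((start + end - 1) /
#' 2)` (even-length segments round down); its strength is the mean
#' probability of the segment's class over the segment span.
#'
#' @param segments data.frame from [labels_to_segments()].
#' @param mask the `4 x L` probability matrix the labels came from.
#' @param strength_by how "stronger" is measured in suppression: mean
#'   assigned-class probability over the segment (default; robust to
#'   single-sample spikes), its maximum, or the segment length.
#' @return data.frame of candidate peaks: `center_index`, `class_index`,
#'   `beat_class`, `strength`, `start`, `end`.
#' @export
segments_to_peaks <- function(segments, mask,
                              strength_by = c("mean", "max", "length")) {
  strength_by <- match.arg(strength_by)
  n <- nrow(segments)
  center <- integer(n)
  strength <- numeric(n)
  for (i in seq_len(n)) {
    s <- segments$start[i]; e <- segments$end[i]
    center[i] <- (s + e - 1L) %/% 2L
    p <- mask[segments$class_index[i] + 1L, (s + 1L):e]
    strength[i] <- switch(strength_by, mean = mean(p), max = max(p),
                          length = e - s)
  }
  data.frame(center_index = center, class_index = segments$class_index,
             beat_class = BEAT_CLASSES[segments$class_index + 1L],
             strength = strength, start = segments$start,
             end = segments$end, stringsAsFactors = FALSE)
}

#' Suppress close candidate peaks
#'
#' While any two peaks are strictly closer than `min_gap_s`, the weaker
#' peak of the closest offending pair is removed (ties on distance: the
#' earlier pair; ties on strength: the later peak is removed). The result
#' is a fixed point: all surviving pairs are at least `min_gap_s` apart,
#' and a pair at exactly `min_gap_s` survives.
#'
#' @param peaks data.frame from [segments_to_peaks()] sorted by
#'   `center_index`.
#' @param min_gap_s minimum allowed inter-peak distance in seconds.
#' @param fs sampling rate of `center_index` (Hz).
#' @return the surviving subset of `peaks`.
#' @export
suppress_close_peaks <- function(peaks, min_gap_s = MIN_PEAK_GAP_S, fs = MODEL_FS) {
  if (nrow(peaks) <= 1L) return(peaks)
  if (is.unsorted(peaks$center_index)) stop("peaks must be sorted by center_index")
  centers <- peaks$center_index
  strength <- peaks$strength
  alive <- rep(TRUE, length(centers))
  # gaps compare in exact integer sample units; the small guard keeps a gap
  # of exactly min_gap_s on the surviving side of the strict inequality
  thr <- min_gap_s * fs - 1e-9
  repeat {
    ai <- which(alive)
    if (length(ai) <= 1L) break
    gaps <- diff(centers[ai])
    off <- which(gaps < thr)
    if (length(off) == 0L) break
    k <- off[gaps[off] == min(gaps[off])][1L]   # distance tie: earliest pair
    a <- ai[k]; b <- ai[k + 1L]
    drop <- if (strength[a] < strength[b]) a else b   # strength tie: the later
    alive[drop] <- FALSE
  }
  peaks[alive, , drop = FALSE]
}

#' Probability mask to detection peaks
#'
#' Composition argmax -> segments -> centers -> close-peak suppression.
#'
#' @param probs `4 x L` probability matrix at 100 Hz.
#' @param min_gap_s suppression distance in seconds.
#' @param fs sampling rate of the mask.
#' @param strength_by strength strategy, see [segments_to_peaks()].
#' @return data.frame of surviving peaks (see [segments_to_peaks()]).
#' @export
probs_to_peaks <- function(probs, min_gap_s = MIN_PEAK_GAP_S, fs = MODEL_FS,
                           strength_by = "mean") {
  labels <- argmax_labels(probs)
  segs <- labels_to_segments(labels)
  peaks <- segments_to_peaks(segs, probs, strength_by)
  suppress_close_peaks(peaks, min_gap_s, fs)
}

#' Detect and classify QRS complexes in an ECG record
#'
#' Full pipeline: resample to 100 Hz, split into 30 s windows (sliding with
#' 50% overlap for longer records; zero-padded for shorter ones),
#' standardize each window, run model inference, post-process the
#' probability masks, merge window peaks (each peak is kept from the window
#' whose center is nearest), and map centers back to the record's native
#' sampling rate.
#'
#' @param model a trained `qrs_model`.
#' @param record an [ecg_record()] or [annotated_record()] of any sampling
#'   rate >= 100 Hz and duration >= 1 s.
#' @return object of class `detection_result`: list with `record_id`,
#'   `fs` (native rate) and `peaks` (data.frame with `center_index` at
#'   100 Hz, `native_index` at the native rate, `time_s`, `beat_class`,
#'   `strength`).
#' @export
detect <- function(model, record) {
  if (inherits(record, "annotated_record")) record <- record$record
  stopifnot(inherits(record, "ecg_record"))
  native_fs <- record$fs
  if (length(record$samples) / native_fs < 1) {
    stop("record shorter than 1 s: ", record$record_id)
  }
  arec <- resample_to_100hz(annotated_record(record))
  x <- arec$record$samples
  L <- WINDOW_SAMPLES
  n <- length(x)
  starts <- if (n <= L) 0L else {
    st <- seq(0L, n - L, by = L %/% 2L)
    if (st[length(st)] != n - L) st <- c(st, n - L)
    st
  }
  all_peaks <- NULL
  centers <- starts + L / 2
  for (wi in seq_along(starts)) {
    s0 <- starts[wi]
    xw <- if (n < L) c(x, rep(0, L - n)) else x[(s0 + 1L):(s0 + L)]
    probs <- infer(model, standardize(xw))
    labels <- argmax_labels(probs)
    segs <- labels_to_segments(labels)
    peaks <- segments_to_peaks(segs, probs)
    if (nrow(peaks) == 0L) next
    peaks$center_index <- peaks$center_index + s0
    # keep peaks owned by this window (nearest window center)
    d_this <- abs(peaks$center_index - centers[wi])
    owned <- rep(TRUE, nrow(peaks))
    for (wj in seq_along(starts)) {
      if (wj == wi) next
      owned <- owned & d_this <= abs(peaks$center_index - centers[wj])
    }
    peaks <- peaks[owned & peaks$center_index < n, , drop = FALSE]
    all_peaks <- rbind(all_peaks, peaks[, c("center_index", "class_index",
                                            "beat_class", "strength")])
  }
  if (is.null(all_peaks)) {
    all_peaks <- data.frame(center_index = integer(0), class_index = integer(0),
                            beat_class = character(0), strength = numeric(0),
                            stringsAsFactors = FALSE)
  }
  all_peaks <- all_peaks[order(all_peaks$center_index), , drop = FALSE]
  all_peaks <- all_peaks[!duplicated(all_peaks$center_index), , drop = FALSE]
  all_peaks <- suppress_close_peaks(all_peaks)
  rownames(all_peaks) <- NULL
  all_peaks$time_s <- all_peaks$center_index / MODEL_FS
  all_peaks$native_index <- pmin(round(all_peaks$center_index * native_fs / MODEL_FS),
                                 length(record$samples) - 1L)
  structure(list(record_id = record$record_id, fs = native_fs,
                 model_fs = MODEL_FS, peaks = all_peaks),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  counts <- table(factor(x$peaks$beat_class, levels = ANNOTATION_CLASSES))
  cat(sprintf("<detection_result '%s'> %d beats (N: %d, PVC: %d, PAC: %d)\n",
              x$record_id, nrow(x$peaks), counts[["N"]], counts[["PVC"]],
              counts[["PAC"]]))
  invisible(x)
}

#' Convert a detection result to a beat-annotation table
#'
#' @param det a `detection_result`.
#' @param at `"native"` (indices at the record's sampling rate) or
#'   `"model"` (100 Hz indices).
#' @return beat-annotation data.frame usable with
#'   [write_csv_annotations()].
#' @export
detection_to_annotations <- function(det, at = c("native", "model")) {
  at <- match.arg(at)
  idx <- if (at == "native") det$peaks$native_index else det$peaks$center_index
  keep <- !duplicated(idx)
  beat_annotations(idx[keep], det$peaks$beat_class[keep])
}
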