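# Signal conditioning and segmentation-target construction: resample to
# 100 Hz, standardize to zero mean / unit variance, training-time crops and
# polarity inversion, 10-sample-widened 4-channel target masks, and
# weighted-oversampling record weights.

MODEL_FS <- 100          # model sampling rate, Hz
WINDOW_SAMPLES <- 3000L  # 30 s at 100 Hz
WIDEN_SAMPLES <- 10L     # samples per beat in the target mask

# Fourier-domain resampling of x (length n) to length m: keep the lowest
# frequencies, scale by m/n. Exact for band-limited periodic content and
# fiducial-free (annotations are rescaled by index arithmetic, never
# re-detected).
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- min(n, m) %/% 2L
  Y[1L] <- X[1L]
  if (half >= 1L) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  }
  if (m < n && m %% 2L == 0L) {
    # fold the split Nyquist bin to keep the output real
    Y[m %/% 2L + 1L] <- Re(X[m %/% 2L + 1L]) + Re(X[n - m %/% 2L + 1L])
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Resample an annotated record to 100 Hz
#'
#' The signal is resampled in the Fourier domain; annotation indices are
#' rescaled by `100 / fs` and rounded to the nearest integer (duplicates
#' after rounding collapse to the first). A 45 s record at 200 Hz (9000
#' samples) becomes 4500 samples, and a beat at index 400 moves to 200.
#'
#' @param arec an [annotated_record()] (or [ecg_record()]).
#' @return resampled [annotated_record()] at 100 Hz.
#' @export
resample_to_100hz <- function(arec) {
  if (inherits(arec, "ecg_record")) arec <- annotated_record(arec)
  stopifnot(inherits(arec, "annotated_record"))
  rec <- arec$record
  if (rec$fs <= 0) stop("invalid sampling rate: ", rec$fs)
  if (rec$fs == MODEL_FS) return(arec)
  if (rec$fs < MODEL_FS) {
    message("upsampling record '", rec$record_id, "' from ", rec$fs, " Hz to 100 Hz")
  }
  n_in <- length(rec$samples)
  n_out <- round(n_in * MODEL_FS / rec$fs)
  y <- fft_resample(rec$samples, n_out)
  idx <- round(arec$annotations$sample_index * MODEL_FS / rec$fs)
  idx <- pmin(pmax(idx, 0L), n_out - 1L)
  keep <- !duplicated(idx)
  new_rec <- ecg_record(y, MODEL_FS, rec$lead_name, rec$record_id)
  annotated_record(new_rec,
                   beat_annotations(idx[keep], arec$annotations$beat_class[keep]))
}

#' Standardize a signal to zero mean and unit variance
#'
#' Uses the population variance; a constant signal maps to all zeros
#' (guarded divide). Idempotent and invariant under affine transforms
#' `a * x + b` with `a > 0`.
#'
#' @param x numeric vector.
#' @return standardized numeric vector.
#' @export
standardize <- function(x) {
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) return(rep(0, length(x)))
  (x - mu) / sd_pop
}

#' Random 30 s training crop
#'
#' Crops a 100 Hz record to exactly 3000 samples at a uniformly random
#' feasible offset; annotations outside the crop are dropped, those inside
#' are re-indexed relative to the crop start. Records shorter than 3000
#' samples are right-padded with zeros (logged via `message`). Uses the
#' current RNG state.
#'
#' @param arec an [annotated_record()] at 100 Hz.
#' @param len crop length in samples (default 3000).
#' @return cropped [annotated_record()]; the chosen offset is attached as
#'   attribute `"crop_offset"`.
#' @export
random_crop_30s <- function(arec, len = WINDOW_SAMPLES) {
  stopifnot(inherits(arec, "annotated_record"))
  rec <- arec$record
  n <- length(rec$samples)
  if (n < len) {
    message("padding record '", rec$record_id, "' from ", n, " to ", len, " samples")
    x <- c(rec$samples, rep(0, len - n))
    out <- annotated_record(ecg_record(x, rec$fs, rec$lead_name, rec$record_id),
                            arec$annotations)
    attr(out, "crop_offset") <- 0L
    return(out)
  }
  offset <- sample.int(n - len + 1L, 1L) - 1L
  crop_record(arec, offset, len)
}

# Deterministic crop at a given offset (also used for evaluation windows).
crop_record <- function(arec, offset, len = WINDOW_SAMPLES) {
  rec <- arec$record
  x <- rec$samples[(offset + 1L):(offset + len)]
  ann <- arec$annotations
  keep <- ann$sample_index >= offset & ann$sample_index < offset + len
  out <- annotated_record(
    ecg_record(x, rec$fs, rec$lead_name, rec$record_id),
    beat_annotations(ann$sample_index[keep] - offset, ann$beat_class[keep]))
  attr(out, "crop_offset") <- as.integer(offset)
  out
}

#' Random polarity inversion
#'
#' Returns `-x` with probability `p`, else `x` (annotations are unaffected
#' by polarity). Uses the current RNG state.
#'
#' @param x numeric vector.
#' @param p inversion probability.
#' @return possibly negated `x`.
#' @export
random_invert <- function(x, p = 0.5) {
  if (p > 0 && stats::runif(1) < p) -x else x
}

#' Encode beat annotations as a per-sample target mask
#'
#' Each beat at index `i` contributes a run of exactly 10 samples of its
#' class, centered on the fiducial (`i - 5 ... i + 4`), clipped at the
#' window edges; all other samples are `NOQRS`. Overlapping runs of
#' different classes resolve later-beat-wins.
#'
#' @param annotations beat-annotation data.frame with indices in `[0, L)`.
#' @param L mask length in samples.
#' @param widen run length per beat (default 10 samples).
#' @return integer vector of length `L` with 0-based class channel indices
#'   (0 = NOQRS, 1 = N, 2 = PVC, 3 = PAC).
#' @export
encode_targets <- function(annotations, L = WINDOW_SAMPLES,
                           widen = WIDEN_SAMPLES) {
  mask <- integer(L)
  if (nrow(annotations) == 0L) return(mask)
  stopifnot(all(annotations$sample_index >= 0L),
            all(annotations$sample_index < L))
  half <- widen %/% 2L
  ord <- order(annotations$sample_index)
  overlaps <- 0L
  for (k in ord) {
    i <- annotations$sample_index[k]
    lo <- max(0L, i - half)
    hi <- min(L - 1L, i + widen - half - 1L)
    cls <- beat_class_index(annotations$beat_class[k])
    run <- (lo + 1L):(hi + 1L)
    if (any(mask[run] != 0L & mask[run] != cls)) overlaps <- overlaps + 1L
    mask[run] <- cls
  }
  if (overlaps > 0L) {
    message(overlaps, " widened run(s) overlapped a different class; later beat wins")
  }
  mask
}

#' One-hot expansion of a class-index mask
#'
#' @param mask integer vector of 0-based class indices.
#' @param n_classes number of channels (default 4).
#' @return `n_classes x L` matrix of 0/1 values, rows in channel order.
#' @export
mask_to_onehot <- function(mask, n_classes = 4L) {
  m <- matrix(0, nrow = n_classes, ncol = length(mask))
  m[cbind(mask + 1L, seq_along(mask))] <- 1
  m
}

#' Weighted-oversampling record weights
#'
#' Balances the expected per-epoch exposure of the beat classes: record `r`
#' gets weight `sum_c count[r,c] / total[c]` over the classes present in the
#' dataset, normalized to sum to one. A class absent from the whole dataset
#' is excluded (with a warning).
#'
#' @param manifest data.frame with columns `n_N`, `n_PVC`, `n_PAC` (as
#'   produced by [make_dataset()]).
#' @return numeric vector of per-record sampling weights summing to 1.
#' @export
oversampling_weights <- function(manifest) {
  counts <- as.matrix(manifest[, c("n_N", "n_PVC", "n_PAC"), drop = FALSE])
  totals <- colSums(counts)
  absent <- totals == 0
  if (any(absent)) {
    warning("class(es) absent from dataset, excluded from balancing: ",
            paste(sub("^n_", "", colnames(counts)[absent]), collapse = ", "),
            call. = FALSE)
  }
  use <- !absent
  if (!any(use)) stop("no beats in dataset; cannot compute weights")
  w <- counts[, use, drop = FALSE] %*% (1 / totals[use])
  w <- as.numeric(w)
  if (sum(w) == 0) stop("all records have zero beats of the balanced classes")
  w / sum(w)
}
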