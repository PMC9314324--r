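# Synthetic single-lead Holter ECG generator. Emulates the structure of
# 45 s / 200 Hz ambulatory recordings with N / PAC / PVC beats and heavy
# movement-noise episodes, so the whole pipeline can be trained and
# evaluated without any external data.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthesis configuration
#'
#' Defaults mirror the structure of ambulatory Holter screening recordings:
#' 45 s single-lead records sampled at 200 Hz, mean heart rate 70 bpm with
#' a few percent premature beats, and moderate movement noise with roughly
#' one artifact burst per record.
#'
#' @param duration_s record duration in seconds.
#' @param fs sampling rate in Hz (>= 100).
#' @param heart_rate_bpm mean heart rate.
#' @param rhythm `"sinus"` (Gaussian RR jitter, ~5% CV) or `"irregular"`
#'   (AF-like uniform RR jitter, ~30% CV).
#' @param pac_fraction,pvc_fraction per-beat probability of a premature
#'   atrial / ventricular beat.
#' @param noise_level nonnegative scalar scaling baseline wander and
#'   broadband noise (0 = clean).
#' @param artifact_burst_rate expected number of high-amplitude movement
#'   artifact bursts per record (Poisson).
#' @param invert flip signal polarity.
#' @param seed integer seed or `NULL` to use the current RNG state.
#' @return a `synthesis_config` list.
#' @export
synthesis_config <- function(duration_s = 45, fs = 200, heart_rate_bpm = 70,
                             rhythm = c("sinus", "irregular"),
                             pac_fraction = 0.05, pvc_fraction = 0.05,
                             noise_level = 0.3, artifact_burst_rate = 1,
                             invert = FALSE, seed = NULL) {
  rhythm <- match.arg(rhythm)
  stopifnot(duration_s > 0, fs >= 100, heart_rate_bpm > 0,
            pac_fraction >= 0, pvc_fraction >= 0,
            pac_fraction + pvc_fraction <= 1,
            noise_level >= 0, artifact_burst_rate >= 0)
  structure(list(duration_s = duration_s, fs = fs,
                 heart_rate_bpm = heart_rate_bpm, rhythm = rhythm,
                 pac_fraction = pac_fraction, pvc_fraction = pvc_fraction,
                 noise_level = noise_level,
                 artifact_burst_rate = artifact_burst_rate,
                 invert = invert, seed = seed),
            class = "synthesis_config")
}

gauss_wave <- function(t, a, mu, sigma) a * exp(-((t - mu)^2) / (2 * sigma^2))

# Analytic Gaussian-mixture beat templates (P, QRS, T components), sampled
# at fs. Time 0 is the R-peak fiducial. PVC: wide large QRS, no P wave,
# discordant T. PAC: narrow QRS with inverted ectopic P.
TEMPLATE_COMPONENTS <- list(
  N = rbind(c(0.15, -0.18, 0.022),    # P
            c(-0.12, -0.028, 0.009),  # Q
            c(1.00, 0.000, 0.010),    # R
            c(-0.22, 0.028, 0.011),   # S
            c(0.30, 0.240, 0.055)),   # T
  PAC = rbind(c(-0.08, -0.14, 0.018), # inverted ectopic P
              c(-0.12, -0.028, 0.009),
              c(1.00, 0.000, 0.010),
              c(-0.22, 0.028, 0.011),
              c(0.30, 0.240, 0.055)),
  PVC = rbind(c(-0.25, -0.060, 0.022),
              c(1.35, 0.000, 0.032),
              c(-0.60, 0.070, 0.030),
              c(-0.40, 0.330, 0.080))
)

#' Beat waveform template
#'
#' @param class `"N"`, `"PVC"` or `"PAC"`.
#' @param fs sampling rate in Hz.
#' @return list with `waveform` (numeric kernel), `qrs_offset` (0-based
#'   index of the R-peak fiducial inside the kernel) and `class`.
#' @export
beat_template <- function(class = c("N", "PVC", "PAC"), fs = 200) {
  class <- match.arg(class)
  comp <- TEMPLATE_COMPONENTS[[class]]
  t <- seq(-0.30, 0.45, by = 1 / fs)
  w <- numeric(length(t))
  for (i in seq_len(nrow(comp))) {
    w <- w + gauss_wave(t, comp[i, 1], comp[i, 2], comp[i, 3])
  }
  list(waveform = w, qrs_offset = which.min(abs(t))[1L] - 1L, class = class)
}

#' QRS width of a template
#'
#' Total duration (seconds) where the absolute amplitude exceeds 10% of the
#' kernel's absolute peak, restricted to +-0.2 s around the fiducial. PVC
#' templates are strictly wider than N templates by this measure.
#'
#' @param template a [beat_template()].
#' @param fs sampling rate the template was built at.
#' @return width in seconds.
#' @export
template_qrs_width <- function(template, fs = 200) {
  w <- template$waveform
  i0 <- template$qrs_offset
  lo <- max(0L, i0 - round(0.2 * fs)) + 1L
  hi <- min(length(w), i0 + round(0.2 * fs) + 1L)
  seg <- w[lo:hi]
  sum(abs(seg) >= 0.1 * max(abs(w))) / fs
}

draw_rr <- function(base_rr, rhythm) {
  if (rhythm == "sinus") {
    jit <- max(0.8, min(1.2, stats::rnorm(1, 1, 0.05)))
  } else {
    # AF-like irregularity: uniform jitter with ~30% coefficient of variation
    a <- 0.3 * sqrt(3)
    jit <- stats::runif(1, 1 - a, 1 + a)
  }
  base_rr * jit
}

#' Simulate a single annotated Holter ECG record
#'
#' Beats are placed by an RR-interval model (see [synthesis_config()]);
#' premature beats (PAC/PVC) shorten the preceding RR interval by a factor
#' 0.7 and a PVC is followed by a compensatory pause (factor 1.3).
#' Consecutive fiducials are kept >= 0.25 s apart. Movement noise is added
#' via [add_movement_noise()]. Identical seeds give bit-identical output.
#'
#' @param config a [synthesis_config()].
#' @return an [annotated_record()] whose annotations are the ground-truth
#'   fiducial positions and classes.
#' @export
simulate_record <- function(config = synthesis_config()) {
  stopifnot(inherits(config, "synthesis_config"))
  if (config$duration_s * config$heart_rate_bpm / 60 < 1) {
    stop("infeasible config: fewer than one beat per record")
  }
  with_local_seed(config$seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    base_rr <- 60 / config$heart_rate_bpm
    templates <- list(N = beat_template("N", fs),
                      PVC = beat_template("PVC", fs),
                      PAC = beat_template("PAC", fs))
    x <- numeric(n)
    idx <- integer(0)
    cls <- character(0)
    t <- 0.3 + stats::runif(1, 0, base_rr / 2)
    current <- "N"
    repeat {
      i <- round(t * fs)
      if (i >= n) break
      idx <- c(idx, i)
      cls <- c(cls, current)
      tpl <- templates[[current]]
      amp <- 1 + stats::rnorm(1, 0, 0.05)
      k0 <- i - tpl$qrs_offset
      ks <- seq_along(tpl$waveform) - 1L + k0
      ok <- ks >= 0L & ks < n
      x[ks[ok] + 1L] <- x[ks[ok] + 1L] + amp * tpl$waveform[ok]
      nxt <- sample(c("PAC", "PVC", "N"), 1L,
                    prob = c(config$pac_fraction, config$pvc_fraction,
                             1 - config$pac_fraction - config$pvc_fraction))
      rr <- draw_rr(base_rr, config$rhythm)
      if (nxt %in% c("PAC", "PVC")) rr <- rr * 0.7
      if (current == "PVC") rr <- rr * 1.3   # compensatory pause
      rr <- max(rr, 0.25)
      t <- t + rr
      current <- nxt
    }
    if (length(idx) < 1L) stop("infeasible config: no beat fits in the record")
    if (config$invert) x <- -x
    rec <- ecg_record(x, fs, lead_name = "I", record_id = "synthetic")
    rec <- add_movement_noise(rec, config$noise_level,
                              config$artifact_burst_rate, seed = NULL)
    annotated_record(rec, beat_annotations(idx, cls))
  })
}

# Poisson-placed artifact bursts; exposed internally so the placement model
# can be Monte-Carlo checked in isolation.
place_artifact_bursts <- function(n_samples, fs, rate) {
  k <- stats::rpois(1, rate)
  if (k == 0L) return(data.frame(start = integer(0), len = integer(0),
                                 amp = numeric(0)))
  start <- sort(sample.int(n_samples, k, replace = TRUE) - 1L)
  len <- round(stats::runif(k, 0.5, 2.5) * fs)
  amp <- stats::runif(k, 1.0, 2.5)
  data.frame(start = start, len = len, amp = amp)
}

#' Add movement noise to an ECG record
#'
#' Adds (a) sub-1 Hz sinusoidal baseline wander, (b) broadband Gaussian
#' noise, both scaled by `noise_level`, and (c) Poisson-placed
#' high-amplitude artifact bursts emulating electrode/movement artifacts.
#' With `noise_level = 0` and `artifact_burst_rate = 0` the record is
#' returned unchanged (exact identity).
#'
#' @param record an [ecg_record()].
#' @param noise_level nonnegative noise scale.
#' @param artifact_burst_rate expected bursts per record.
#' @param seed optional integer seed.
#' @return a new [ecg_record()].
#' @export
add_movement_noise <- function(record, noise_level = 0.3,
                               artifact_burst_rate = 1, seed = NULL) {
  stopifnot(inherits(record, "ecg_record"), noise_level >= 0,
            artifact_burst_rate >= 0)
  if (noise_level == 0 && artifact_burst_rate == 0) return(record)
  with_local_seed(seed, {
    n <- length(record$samples)
    fs <- record$fs
    tt <- (seq_len(n) - 1L) / fs
    x <- record$samples
    if (noise_level > 0) {
      for (j in 1:3) {     # baseline wander: slow drift below 1 Hz
        f <- stats::runif(1, 0.05, 0.8)
        a <- noise_level * stats::runif(1, 0.2, 0.5)
        x <- x + a * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      }
      x <- x + stats::rnorm(n, 0, 0.2 * noise_level)
    }
    bursts <- place_artifact_bursts(n, fs, artifact_burst_rate)
    if (nrow(bursts) > 0) {
      for (i in seq_len(nrow(bursts))) {
        j0 <- bursts$start[i]
        len <- min(bursts$len[i], n - j0)
        if (len < 2L) next
        env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))  # Hann
        x[(j0 + 1L):(j0 + len)] <- x[(j0 + 1L):(j0 + len)] +
          bursts$amp[i] * env * stats::rnorm(len)
      }
    }
    ecg_record(x, fs, record$lead_name, record$record_id)
  })
}

#' Generate a synthetic dataset with a manifest
#'
#' Per-record seeds are derived deterministically from the master seed, and
#' each record's mean heart rate is drawn uniformly within +-15% of the
#' configured rate, so records differ while the whole dataset is exactly
#' reproducible.
#'
#' @param n_records number of records (>= 1).
#' @param config base [synthesis_config()] shared by all records.
#' @param seed master integer seed.
#' @param id_prefix prefix for the generated record ids.
#' @return list with `records` (list of [annotated_record()]) and `manifest`
#'   (data.frame: one row per record with its config and class counts).
#' @export
make_dataset <- function(n_records, config = synthesis_config(), seed = 1L,
                         id_prefix = "syn") {
  stopifnot(n_records >= 1)
  with_local_seed(seed, {
    hr_mult <- stats::runif(n_records, 0.85, 1.15)
    seeds <- (as.numeric(seed) * 7919 + 104729 * seq_len(n_records)) %%
      .Machine$integer.max
    records <- vector("list", n_records)
    rows <- vector("list", n_records)
    for (i in seq_len(n_records)) {
      cfg <- config
      cfg$heart_rate_bpm <- config$heart_rate_bpm * hr_mult[i]
      cfg$seed <- as.integer(seeds[i])
      arec <- simulate_record(cfg)
      rid <- sprintf("%s%04d", id_prefix, i)
      arec$record$record_id <- rid
      counts <- table(factor(arec$annotations$beat_class,
                             levels = ANNOTATION_CLASSES))
      records[[i]] <- arec
      rows[[i]] <- data.frame(
        record_id = rid, seed = cfg$seed, duration_s = cfg$duration_s,
        fs = cfg$fs, heart_rate_bpm = cfg$heart_rate_bpm,
        rhythm = cfg$rhythm, pac_fraction = cfg$pac_fraction,
        pvc_fraction = cfg$pvc_fraction, noise_level = cfg$noise_level,
        artifact_burst_rate = cfg$artifact_burst_rate,
        n_N = as.integer(counts[["N"]]), n_PVC = as.integer(counts[["PVC"]]),
        n_PAC = as.integer(counts[["PAC"]]),
        n_beats = nrow(arec$annotations), stringsAsFactors = FALSE)
    }
    list(records = records, manifest = do.call(rbind, rows))
  })
}
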