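# Shared fixtures and independent oracles. Everything is generated in code;
# no binary files ship with the package.

# ---- WFDB fixture writer (format 16 + MIT annotations) -------------------
# The package deliberately has no WFDB write support; tests create fixtures
# with this minimal independent writer and read them back with the package.

wfdb_symbol_code <- function(symbol) {
  code <- match(symbol, qrseg:::WFDB_ANN_CODES)
  stopifnot(!anyNA(code))
  code
}

write_wfdb_fixture <- function(dir, name, signals, fs, lead_names,
                               gain = 200, baseline = 0, ann = NULL) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  nsig <- ncol(signals)
  nsamp <- nrow(signals)
  hea <- c(sprintf("%s %d %g %d", name, nsig, fs, nsamp),
           sprintf("%s.dat 16 %g(%g)/mV 16 %g 0 0 0 %s",
                   name, gain, baseline, baseline, lead_names))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  adc <- round(t(signals) * gain + baseline)   # interleaved frame-major
  writeBin(as.integer(adc), file.path(dir, paste0(name, ".dat")),
           size = 2, endian = "little")
  if (!is.null(ann)) {
    con <- file(file.path(dir, paste0(name, ".atr")), "wb")
    prev <- 0
    for (i in seq_len(nrow(ann))) {
      interval <- ann$sample[i] - prev
      prev <- ann$sample[i]
      code <- wfdb_symbol_code(ann$symbol[i])
      if (interval >= 1024) {
        # SKIP pseudo-annotation: code 59, then 4-byte interval, high word first
        writeBin(as.integer(bitwShiftL(59L, 10L)), con, size = 2, endian = "little")
        writeBin(as.integer(interval %/% 65536), con, size = 2, endian = "little")
        writeBin(as.integer(interval %% 65536), con, size = 2, endian = "little")
        interval <- 0
      }
      writeBin(as.integer(bitwOr(bitwShiftL(code, 10L), interval)), con,
               size = 2, endian = "little")
    }
    writeBin(0L, con, size = 2, endian = "little")
    close(con)
  }
  file.path(dir, name)
}

# ---- small model helpers -------------------------------------------------

tiny_model_config <- function(...) {
  model_config(channels = c(3, 4), kernel_size = 3, gru_hidden = 4, ...)
}

# ---- random instance generators -----------------------------------------

random_annotations <- function(L = 3000, fs = 100, min_gap_s = 0.15,
                               max_gap_s = 1.2) {
  gaps <- stats::runif(ceiling(L / fs / min_gap_s), min_gap_s + 1 / fs, max_gap_s)
  times <- cumsum(gaps) + 0.05
  times <- times[times < (L - 6) / fs]
  idx <- round(times * fs)
  keep <- !duplicated(idx) & idx >= 5
  idx <- idx[keep]
  beat_annotations(idx, sample(ANNOTATION_CLASSES, length(idx), replace = TRUE))
}

# ---- independent oracles -------------------------------------------------

# Maximum bipartite matching cardinality by bitmask dynamic programming
# over reference subsets (exact for <= ~12 references).
bf_max_matching <- function(pred, ref, tol = 0.1) {
  np <- length(pred)
  nr <- length(ref)
  if (np == 0 || nr == 0) return(0L)
  masks <- 0:(2^nr - 1)
  dp <- rep(-1L, 2^nr)
  dp[1] <- 0L
  for (p in seq_len(np)) {
    compat <- which(abs(ref - pred[p]) <= tol + 1e-9)
    dp2 <- dp
    for (r in compat) {
      bit <- 2^(r - 1)
      free <- which(dp >= 0L & bitwAnd(masks, bit) == 0L)
      tgt <- free + bit
      dp2[tgt] <- pmax(dp2[tgt], dp[free] + 1L)
    }
    dp <- dp2
  }
  max(dp)
}

# Close-peak suppression oracle: independent O(n^3) implementation over
# integer sample positions that recomputes the full pairwise distance matrix
# at every iteration and removes the weaker peak of the closest offending
# pair (distance tie: earliest pair; strength tie: the later peak).
bf_suppress <- function(centers, strengths, min_gap_samples = 15L) {
  alive <- rep(TRUE, length(centers))
  repeat {
    ai <- which(alive)
    if (length(ai) <= 1) break
    best <- NULL
    best_d <- Inf
    for (i in seq_along(ai)) {
      for (j in seq_along(ai)) {
        if (i < j) {
          d <- abs(centers[ai[j]] - centers[ai[i]])
          if (d < min_gap_samples && d < best_d) {
            best_d <- d
            best <- c(ai[i], ai[j])
          }
        }
      }
    }
    if (is.null(best)) break
    drop <- if (strengths[best[1]] < strengths[best[2]]) best[1] else best[2]
    alive[drop] <- FALSE
  }
  which(alive)
}
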