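test_that("match_beats: inclusive 0.1 s tolerance boundary", {
  m <- match_beats(10.00, 10.10)
  expect_equal(m$tp, 1L)
  m2 <- match_beats(10.00, 10.11)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))
  expect_error(match_beats(c(2, 1), c(1, 2)), "sorted")
})

test_that("match_beats equals the exhaustive maximum-matching oracle", {
  set.seed(41)
  for (k in 1:300) {
    np <- sample(0:10, 1); nr <- sample(0:10, 1)
    pred <- sort(runif(np, 0, 3))
    ref <- sort(runif(nr, 0, 3))
    m <- match_beats(pred, ref)
    expect_equal(m$tp, bf_max_matching(pred, ref))
    expect_equal(m$tp + m$fp, np)
    expect_equal(m$tp + m$fn, nr)
    # one-to-one with all offsets within tolerance
    if (m$tp > 0) {
      expect_false(anyDuplicated(m$pairs$pred_idx) > 0)
      expect_false(anyDuplicated(m$pairs$ref_idx) > 0)
      expect_true(all(abs(m$pairs$offset) <= 0.1 + 1e-9))
    }
  }
})

test_that("matching symmetry and tolerance monotonicity", {
  set.seed(43)
  for (k in 1:50) {
    pred <- sort(runif(sample(1:8, 1), 0, 2))
    ref <- sort(runif(sample(1:8, 1), 0, 2))
    m <- match_beats(pred, ref)
    ms <- match_beats(ref, pred)
    expect_equal(m$tp, ms$tp)
    expect_equal(m$fp, ms$fn)
    expect_equal(m$fn, ms$fp)
    tps <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.5),
                  function(tol) match_beats(pred, ref, tol)$tp, numeric(1))
    expect_true(all(diff(tps) >= 0))
  }
})

test_that("detection_f1 closed forms", {
  expect_equal(detection_f1(list(tp = 9, fp = 1, fn = 1)), 0.9)
  expect_equal(detection_f1(list(tp = 0, fp = 0, fn = 0)), 1.0)
  expect_equal(detection_f1(list(tp = 0, fp = 5, fn = 5)), 0.0)
})

test_that("classification_f1: perfect case, misclassification bookkeeping", {
  pred_t <- c(1, 2, 3); ref_t <- c(1, 2, 3)
  m <- match_beats(pred_t, ref_t)
  cls <- c("N", "PVC", "PAC")
  rep1 <- classification_f1(m, cls, cls)
  expect_equal(unname(rep1$per_class_f1), c(1, 1, 1))
  expect_equal(rep1$micro_f1, 1)
  expect_equal(rep1$macro_f1, 1)

  rep2 <- classification_f1(m, c("PVC", "PVC", "PAC"), cls)
  # pair 1: predicted PVC, reference N -> N FN, PVC FP, confusion[N,PVC]
  expect_equal(unname(rep2$class_counts$fn[["N"]]), 1)
  expect_equal(unname(rep2$class_counts$fp[["PVC"]]), 1)
  expect_equal(rep2$confusion["N", "PVC"], 1L)
  # macro is the unweighted mean of per-class F1
  expect_equal(rep2$macro_f1, mean(rep2$per_class_f1))
})

test_that("macro F1 equals the arithmetic-mean oracle on constructed counts", {
  # construct counts giving per-class F1 of 0.99, 0.17, 0.80
  f1 <- function(tp, fp, fn) 2 * tp / (2 * tp + fp + fn)
  stopifnot(abs(f1(99, 1, 1) - 0.99) < 1e-9)
  # directly check mean arithmetic as the report computes it
  per <- c(N = 0.99, PVC = 0.80, PAC = 0.17)
  expect_equal(round(mean(per), 2), 0.65)
})

test_that("unmatched beats count as class FP/FN by default, not in matched_only", {
  pred_t <- c(1.0, 5.0)   # 5.0 unmatched
  ref_t <- c(1.0, 9.0)    # 9.0 undetected PVC
  m <- match_beats(pred_t, ref_t)
  r <- classification_f1(m, c("N", "PAC"), c("N", "PVC"))
  expect_equal(unname(r$class_counts$fn[["PVC"]]), 1)
  expect_equal(unname(r$class_counts$fp[["PAC"]]), 1)
  r2 <- classification_f1(m, c("N", "PAC"), c("N", "PVC"), matched_only = TRUE)
  expect_equal(unname(r2$class_counts$fn[["PVC"]]), 0)
  expect_equal(unname(r2$class_counts$fp[["PAC"]]), 0)
  expect_equal(r2$micro_f1, 1)
})

test_that("evaluate_dataset: pooling invariance and mean +- population sd", {
  set.seed(47)
  mkrec <- function(id, n) {
    idx <- sort(sample(seq(50, 2950, by = 30), n))
    annotated_record(ecg_record(rnorm(3000), 100, record_id = id),
                     beat_annotations(idx, sample(ANNOTATION_CLASSES, n, TRUE)))
  }
  refs <- list(a = mkrec("a", 20), b = mkrec("b", 25))
  # detections: reference beats with some noise and one dropped beat each
  dets <- lapply(refs, function(r) {
    ann <- r$annotations[-1, ]
    data.frame(time_s = ann$sample_index / 100, beat_class = ann$beat_class)
  })
  ev <- evaluate_dataset(dets, refs)
  expect_equal(ev$report$detection$fn, 2)
  expect_equal(ev$report$detection$fp, 0)
  # pooling invariance: two identical records = one record's counts doubled
  ev_a <- evaluate_dataset(dets["a"], refs["a"])
  both <- evaluate_dataset(list(a = dets$a, a2 = dets$a),
                           list(a = refs$a, a2 = refs$a))
  expect_equal(both$report$detection$f1, ev_a$report$detection$f1)

  # dataset aggregation: F1s 1.0 and 0.9 -> mean 0.95, population sd 0.05
  refs2 <- list(r1 = mkrec("r1", 10), r2 = mkrec("r2", 9))
  d1 <- data.frame(time_s = refs2$r1$annotations$sample_index / 100,
                   beat_class = refs2$r1$annotations$beat_class)
  ann2 <- refs2$r2$annotations
  d2 <- data.frame(time_s = c(ann2$sample_index / 100, 29.9),
                   beat_class = c(ann2$beat_class, "N"))   # 1 FP + 1 FN
  d2 <- d2[-1, ]
  ev2 <- evaluate_dataset(list(r1 = d1, r2 = d2), refs2,
                          dataset = c("ds1", "ds2"))
  expect_equal(unname(ev2$per_dataset$f1[["ds1"]]), 1.0)
  f1_2 <- unname(ev2$per_dataset$f1[["ds2"]])
  expect_equal(ev2$per_dataset$mean_f1, mean(c(1, f1_2)))
  expect_equal(ev2$per_dataset$sd_f1, abs(1 - f1_2) / 2)

  expect_error(evaluate_dataset(dets["a"], refs), "ids do not align")
})
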