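# Tolerance-matched evaluation: a predicted beat is a true positive when it
# lies within 0.1 s (inclusive) of a reference annotation, under a
# maximum-cardinality one-to-one matching. Detection F1 plus per-class /
# micro / macro classification F1.

MATCH_TOLERANCE_S <- 0.1
.TOL_EPS <- 1e-9

#' Match predicted beats to reference annotations
#'
#' Computes a maximum-cardinality one-to-one matching between predicted and
#' reference beat times under `|dt| <= tolerance_s` (inclusive: an offset of
#' exactly 0.1 s counts as a true positive). A greedy nearest-pair pass is
#' followed by augmenting-path repair, so the matched count always equals
#' the true maximum.
#'
#' @param predicted,reference sorted numeric vectors of beat times in
#'   seconds.
#' @param tolerance_s matching tolerance (default 0.1 s).
#' @return object of class `match_result`: list with `pairs` (data.frame
#'   `pred_idx`, `ref_idx`, `offset`), `fp_idx`, `fn_idx`, and counts `tp`,
#'   `fp`, `fn`.
#' @export
match_beats <- function(predicted, reference, tolerance_s = MATCH_TOLERANCE_S) {
  if (is.unsorted(predicted)) stop("predicted beat times must be sorted")
  if (is.unsorted(reference)) stop("reference beat times must be sorted")
  np <- length(predicted)
  nr <- length(reference)
  tol <- tolerance_s + .TOL_EPS
  adj <- vector("list", np)
  for (p in seq_len(np)) {
    adj[[p]] <- which(abs(reference - predicted[p]) <= tol)
  }
  # greedy nearest-pair seed (canonical), then augmenting-path repair
  cand <- NULL
  for (p in seq_len(np)) {
    if (length(adj[[p]]) > 0L) {
      cand <- rbind(cand, data.frame(p = p, r = adj[[p]],
                                     d = abs(reference[adj[[p]]] - predicted[p])))
    }
  }
  pred_match <- rep(NA_integer_, np)
  ref_match <- rep(NA_integer_, nr)
  if (!is.null(cand)) {
    cand <- cand[order(cand$d, cand$p, cand$r), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      p <- cand$p[i]; r <- cand$r[i]
      if (is.na(pred_match[p]) && is.na(ref_match[r])) {
        pred_match[p] <- r
        ref_match[r] <- p
      }
    }
    # repair to maximum cardinality on the unmatched predictions
    adj_rest <- lapply(seq_len(np), function(p) {
      if (is.na(pred_match[p])) adj[[p]] else integer(0)
    })
    aug <- local({
      ref_m <- ref_match
      pred_m <- pred_match
      try_aug <- function(p, visited) {
        for (r in adj[[p]]) {
          if (!visited[r]) {
            visited[r] <- TRUE
            if (is.na(ref_m[r])) {
              ref_m[r] <<- p; pred_m[p] <<- r
              return(TRUE)
            }
            if (try_aug(ref_m[r], visited)) {
              ref_m[r] <<- p; pred_m[p] <<- r
              return(TRUE)
            }
          }
        }
        FALSE
      }
      for (p in which(is.na(pred_match))) {
        if (length(adj_rest[[p]]) > 0L) try_aug(p, rep(FALSE, nr))
      }
      list(pred_match = pred_m, ref_match = ref_m)
    })
    pred_match <- aug$pred_match
    ref_match <- aug$ref_match
  }
  matched_p <- which(!is.na(pred_match))
  pairs <- data.frame(pred_idx = matched_p, ref_idx = pred_match[matched_p],
                      offset = predicted[matched_p] - reference[pred_match[matched_p]])
  structure(list(pairs = pairs,
                 fp_idx = which(is.na(pred_match)),
                 fn_idx = which(is.na(ref_match)),
                 tp = nrow(pairs),
                 fp = np - nrow(pairs),
                 fn = nr - nrow(pairs)),
            class = "match_result")
}

#' Detection F1 score
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`; defined as 1.0 when both beat lists are
#' empty and 0.0 when TP is zero with non-empty lists.
#'
#' @param match a `match_result` (or list with `tp`, `fp`, `fn`).
#' @return F1 in `[0, 1]`.
#' @export
detection_f1 <- function(match) {
  d <- 2 * match$tp + match$fp + match$fn
  if (d == 0) 1.0 else 2 * match$tp / d
}

f1_from_counts <- function(tp, fp, fn) {
  d <- 2 * tp + fp + fn
  if (d == 0) 1.0 else 2 * tp / d
}

#' Classification F1 report
#'
#' Per-class, micro and macro F1 over {N, PAC, PVC}. By default detection
#' errors count against classification (an undetected PVC is a PVC false
#' negative, a spurious prediction is a false positive of its predicted
#' class); `matched_only = TRUE` restricts all counts to matched pairs.
#' Macro F1 is the unweighted mean of the three per-class F1 scores; micro
#' F1 pools TP/FP/FN across classes. The confusion matrix is restricted to
#' matched pairs.
#'
#' @param match a `match_result` from [match_beats()].
#' @param predicted_classes,reference_classes character vectors of classes
#'   parallel to the matched time vectors.
#' @param matched_only condition the report on successful detection.
#' @return object of class `metrics_report`.
#' @export
classification_f1 <- function(match, predicted_classes, reference_classes,
                              matched_only = FALSE) {
  cls <- ANNOTATION_CLASSES
  tp <- stats::setNames(numeric(3), cls)
  fp <- stats::setNames(numeric(3), cls)
  fn <- stats::setNames(numeric(3), cls)
  confusion <- matrix(0L, 3, 3, dimnames = list(reference = cls, predicted = cls))
  if (nrow(match$pairs) > 0) {
    pc <- predicted_classes[match$pairs$pred_idx]
    rc <- reference_classes[match$pairs$ref_idx]
    for (i in seq_along(pc)) {
      confusion[rc[i], pc[i]] <- confusion[rc[i], pc[i]] + 1L
      if (pc[i] == rc[i]) {
        tp[pc[i]] <- tp[pc[i]] + 1
      } else {
        fp[pc[i]] <- fp[pc[i]] + 1
        fn[rc[i]] <- fn[rc[i]] + 1
      }
    }
  }
  if (!matched_only) {
    for (i in match$fp_idx) fp[predicted_classes[i]] <- fp[predicted_classes[i]] + 1
    for (i in match$fn_idx) fn[reference_classes[i]] <- fn[reference_classes[i]] + 1
  }
  per_class <- vapply(cls, function(c) f1_from_counts(tp[c], fp[c], fn[c]),
                      numeric(1))
  micro <- f1_from_counts(sum(tp), sum(fp), sum(fn))
  macro <- mean(per_class)
  structure(list(detection = list(tp = match$tp, fp = match$fp, fn = match$fn,
                                  f1 = detection_f1(match)),
                 class_counts = list(tp = tp, fp = fp, fn = fn),
                 per_class_f1 = per_class, micro_f1 = micro,
                 macro_f1 = macro, confusion = confusion),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Detection: TP %d  FP %d  FN %d  F1 %.4f\n",
              x$detection$tp, x$detection$fp, x$detection$fn, x$detection$f1))
  cat(sprintf("Classification F1: N %.4f  PVC %.4f  PAC %.4f  micro %.4f  macro %.4f\n",
              x$per_class_f1[["N"]], x$per_class_f1[["PVC"]],
              x$per_class_f1[["PAC"]], x$micro_f1, x$macro_f1))
  invisible(x)
}

#' Evaluate detections against references over a dataset
#'
#' Pools TP/FP/FN counts across records for the dataset-level report and
#' also returns a per-record table. When a `dataset` grouping is supplied,
#' per-dataset F1 scores and their mean +- population standard deviation
#' are reported as well.
#'
#' @param detections named list (by record id) of `detection_result`s or
#'   data.frames with `time_s` and `beat_class`.
#' @param references named list (by record id) of [annotated_record()]s or
#'   beat-annotation data.frames (indices interpreted with `ref_fs`).
#' @param ref_fs sampling rate of plain reference annotation indices.
#' @param dataset optional character vector (parallel to `detections`)
#'   assigning each record to a dataset.
#' @param tolerance_s matching tolerance in seconds.
#' @return list with `report` (pooled `metrics_report`), `per_record`
#'   (data.frame), and optionally `per_dataset` with `mean_f1` and `sd_f1`.
#' @export
evaluate_dataset <- function(detections, references, ref_fs = MODEL_FS,
                             dataset = NULL, tolerance_s = MATCH_TOLERANCE_S) {
  ids_d <- names(detections)
  ids_r <- names(references)
  if (is.null(ids_d) || is.null(ids_r)) stop("detections and references must be named by record id")
  missing_ids <- union(setdiff(ids_d, ids_r), setdiff(ids_r, ids_d))
  if (length(missing_ids) > 0) {
    stop("record ids do not align; missing: ", paste(missing_ids, collapse = ", "))
  }
  agg <- list(tp = 0, fp = 0, fn = 0)
  cls_counts <- list(tp = stats::setNames(numeric(3), ANNOTATION_CLASSES),
                     fp = stats::setNames(numeric(3), ANNOTATION_CLASSES),
                     fn = stats::setNames(numeric(3), ANNOTATION_CLASSES))
  confusion <- matrix(0L, 3, 3, dimnames = list(reference = ANNOTATION_CLASSES,
                                                predicted = ANNOTATION_CLASSES))
  per_record <- NULL
  rec_f1 <- stats::setNames(numeric(length(ids_d)), ids_d)
  for (id in ids_d) {
    det <- detections[[id]]
    if (inherits(det, "detection_result")) {
      pt <- det$peaks$time_s
      pc <- det$peaks$beat_class
    } else {
      pt <- det$time_s
      pc <- det$beat_class
    }
    ref <- references[[id]]
    if (inherits(ref, "annotated_record")) {
      rt <- ref$annotations$sample_index / ref$record$fs
      rc <- ref$annotations$beat_class
    } else {
      rt <- ref$sample_index / ref_fs
      rc <- ref$beat_class
    }
    m <- match_beats(pt, rt, tolerance_s)
    rep_i <- classification_f1(m, pc, rc)
    agg$tp <- agg$tp + m$tp; agg$fp <- agg$fp + m$fp; agg$fn <- agg$fn + m$fn
    for (f in c("tp", "fp", "fn")) {
      cls_counts[[f]] <- cls_counts[[f]] + rep_i$class_counts[[f]]
    }
    confusion <- confusion + rep_i$confusion
    rec_f1[id] <- detection_f1(m)
    per_record <- rbind(per_record,
                        data.frame(record_id = id, n_ref = length(rt),
                                   n_pred = length(pt), tp = m$tp, fp = m$fp,
                                   fn = m$fn, detection_f1 = rec_f1[id],
                                   stringsAsFactors = FALSE))
  }
  per_class <- vapply(ANNOTATION_CLASSES, function(c) {
    f1_from_counts(cls_counts$tp[c], cls_counts$fp[c], cls_counts$fn[c])
  }, numeric(1))
  report <- structure(
    list(detection = list(tp = agg$tp, fp = agg$fp, fn = agg$fn,
                          f1 = f1_from_counts(agg$tp, agg$fp, agg$fn)),
         class_counts = cls_counts, per_class_f1 = per_class,
         micro_f1 = f1_from_counts(sum(cls_counts$tp), sum(cls_counts$fp),
                                   sum(cls_counts$fn)),
         macro_f1 = mean(per_class), confusion = confusion),
    class = "metrics_report")
  out <- list(report = report, per_record = per_record)
  if (!is.null(dataset)) {
    stopifnot(length(dataset) == length(ids_d))
    # pooled per-dataset F1
    ds_names <- unique(dataset)
    ds_f1 <- stats::setNames(numeric(length(ds_names)), ds_names)
    for (d in ds_names) {
      sub <- per_record[dataset == d, , drop = FALSE]
      ds_f1[d] <- f1_from_counts(sum(sub$tp), sum(sub$fp), sum(sub$fn))
    }
    out$per_dataset <- list(
      f1 = ds_f1,
      mean_f1 = mean(ds_f1),
      sd_f1 = sqrt(mean((ds_f1 - mean(ds_f1))^2)))   # population sd
  }
  out
}
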