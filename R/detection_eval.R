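#' Pairwise intersection-over-union between two instance masks
#'
#' For every pair of overlapping objects (one from the predicted mask, one
#' from the ground truth), `IoU = |intersection| / |union|` in pixels.
#' Non-overlapping pairs are omitted (their IoU is 0).
#'
#' @param pred,truth [label_mask()]s of equal shape.
#' @return an object of class `iou_table`: list with `pairs` (data.frame
#'   `pred`, `truth`, `iou`, sorted by decreasing IoU), `pred_ids`,
#'   `truth_ids`.
#' @export
pairwise_iou <- function(pred, truth) {
  stopifnot(inherits(pred, "label_mask"), inherits(truth, "label_mask"))
  if (!identical(dim(pred$labels), dim(truth$labels))) {
    stop("mask shape mismatch", call. = FALSE)
  }
  p <- as.vector(pred$labels); t <- as.vector(truth$labels)
  pred_ids <- sort(setdiff(unique(p), 0L))
  truth_ids <- sort(setdiff(unique(t), 0L))
  both <- p > 0L & t > 0L
  if (any(both)) {
    key <- paste(p[both], t[both])
    inter <- table(key)
    parts <- do.call(rbind, strsplit(names(inter), " ", fixed = TRUE))
    pi <- as.integer(parts[, 1]); ti <- as.integer(parts[, 2])
    area_p <- tabulate(p[p > 0L])
    area_t <- tabulate(t[t > 0L])
    inter_n <- as.integer(inter)
    iou <- inter_n / (area_p[pi] + area_t[ti] - inter_n)
    ord <- order(-iou, ti, pi)
    pairs <- data.frame(pred = pi[ord], truth = ti[ord], iou = iou[ord])
  } else {
    pairs <- data.frame(pred = integer(0), truth = integer(0),
                        iou = numeric(0))
  }
  structure(list(pairs = pairs, pred_ids = pred_ids, truth_ids = truth_ids),
            class = "iou_table")
}

#' Match predicted to ground-truth objects at an IoU threshold
#'
#' One-to-one matching among pairs with IoU at or above the threshold.
#' Default is greedy matching in descending-IoU order (ties broken by
#' smaller truth id, then smaller pred id); `method = "optimal"` solves the
#' maximum-cardinality, maximum-total-IoU assignment exactly by branch
#' enumeration (intended for small object counts). The two coincide
#' whenever overlaps are one-to-one.
#'
#' @param iou an `iou_table` from [pairwise_iou()].
#' @param iou_threshold matching threshold in `(0, 1]`, default 0.5.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return an object of class `match_result`: list with `pairs` (data.frame
#'   `pred`, `truth`, `iou`), counts `tp`, `fp`, `fn`, and `iou_threshold`.
#' @export
match_objects <- function(iou, iou_threshold = 0.5,
                          method = c("greedy", "optimal")) {
  stopifnot(inherits(iou, "iou_table"))
  method <- match.arg(method)
  if (iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must be in (0, 1]", call. = FALSE)
  }
  cand <- iou$pairs[iou$pairs$iou >= iou_threshold, , drop = FALSE]
  if (method == "greedy") {
    used_p <- integer(0); used_t <- integer(0); keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!(cand$pred[i] %in% used_p) && !(cand$truth[i] %in% used_t)) {
        keep <- c(keep, i)
        used_p <- c(used_p, cand$pred[i])
        used_t <- c(used_t, cand$truth[i])
      }
    }
    matched <- cand[keep, , drop = FALSE]
  } else {
    matched <- optimal_matching(cand)
  }
  tp <- nrow(matched)
  structure(list(pairs = matched, tp = tp,
                 fp = length(iou$pred_ids) - tp,
                 fn = length(iou$truth_ids) - tp,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

# Exact assignment by depth-first enumeration over candidate pairs:
# maximize (cardinality, total IoU) lexicographically. Exponential in the
# number of contested pairs; intended for small scenes and test oracles.
optimal_matching <- function(cand) {
  n <- nrow(cand)
  if (!n) return(cand)
  best <- list(card = -1L, total = -Inf, keep = integer(0))
  recurse <- function(i, used_p, used_t, keep, total) {
    if (i > n) {
      if (length(keep) > best$card ||
          (length(keep) == best$card && total > best$total + 1e-12)) {
        best <<- list(card = length(keep), total = total, keep = keep)
      }
      return(invisible())
    }
    # upper bound pruning on cardinality
    if (length(keep) + (n - i + 1L) < best$card) return(invisible())
    p <- cand$pred[i]; t <- cand$truth[i]
    if (!(p %in% used_p) && !(t %in% used_t)) {
      recurse(i + 1L, c(used_p, p), c(used_t, t), c(keep, i),
              total + cand$iou[i])
    }
    recurse(i + 1L, used_p, used_t, keep, total)
  }
  recurse(1L, integer(0), integer(0), integer(0), 0)
  cand[best$keep, , drop = FALSE]
}

#' Detection scores from a match result
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2 * precision * recall / (precision + recall)`. In a detection
#' setting there are no true negatives, so accuracy is defined as
#' `tp / (tp + fp + fn)` (the standard detection convention). Undefined
#' ratios (zero denominators) are reported as `NA`.
#'
#' @param match a `match_result` from [match_objects()].
#' @return data.frame with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `accuracy`, `f1`.
#' @export
detection_scores <- function(match) {
  stopifnot(inherits(match, "match_result"))
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (tp + fp + fn == 0) {
    stop("no objects in prediction or truth: scores undefined", call. = FALSE)
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             recall = recall, accuracy = tp / (tp + fp + fn), f1 = f1)
}

#' Evaluate a predicted mask against ground truth
#'
#' Convenience wrapper: [pairwise_iou()] then [match_objects()] then
#' [detection_scores()].
#'
#' @param pred,truth [label_mask()]s of equal shape.
#' @param iou_threshold matching threshold, default 0.5.
#' @param method matching method, see [match_objects()].
#' @return data.frame of detection scores.
#' @export
evaluate_detection <- function(pred, truth, iou_threshold = 0.5,
                               method = "greedy") {
  detection_scores(match_objects(pairwise_iou(pred, truth),
                                 iou_threshold = iou_threshold,
                                 method = method))
}
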