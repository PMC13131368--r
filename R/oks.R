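#' Object keypoint similarity between a predicted and a true frame
#'
#' OKS scores the agreement of predicted and true keypoints while
#' accounting for object scale and keypoint visibility:
#' \deqn{OKS = \frac{\sum_i \exp(-d_i^2 / (2 s^2 k_i^2)) \, [v_i > 0]}
#'                  {\sum_i [v_i > 0]}}
#' where \eqn{d_i} is the Euclidean pixel displacement of keypoint
#' \eqn{i}, \eqn{s^2} the object area in squared pixels, \eqn{k_i} a
#' per-keypoint falloff constant, and the indicator runs over keypoints
#' visible in the ground truth. Keypoints absent in the truth
#' (visibility 0) are excluded from both sums.
#'
#' @param pred,truth [kp_frame()] objects sharing one schema.
#' @param kappas Per-keypoint constants: a single value recycled to all
#'   labels or a named vector. Default 0.05 for every label.
#' @param area Object area in squared pixels, or `NULL` to use the truth
#'   bbox area (falling back to the bounding box of the visible truth
#'   keypoints).
#' @return A list of class `oks_record`: `oks`, `per_keypoint_terms`
#'   (named, NA for excluded labels), `area`, `n_visible`.
#' @export
#' @examples
#' tr <- simulate_trajectory(head_model_params(n_frames = 1, seed = 1))$trajectory
#' compute_oks(tr$frames[[1]], tr$frames[[1]])$oks # identical frames -> 1
compute_oks <- function(pred, truth, kappas = 0.05, area = NULL) {
  labels <- truth$schema$names
  if (!identical(labels, pred$schema$names)) {
    stop("pred and truth frames use different schemas", call. = FALSE)
  }
  if (length(kappas) == 1L && is.null(names(kappas))) {
    kappas <- stats::setNames(rep(kappas, length(labels)), labels)
  }
  if (anyNA(kappas[labels])) {
    stop("kappas missing for some schema labels", call. = FALSE)
  }
  kappas <- kappas[labels]
  if (is.null(area)) area <- frame_area(truth)
  if (!is.finite(area) || area <= 0) {
    stop("object area must be positive", call. = FALSE)
  }
  vis <- truth$visibility > 0L
  n_visible <- sum(vis)
  if (n_visible < 1L) {
    stop("OKS undefined: no visible ground-truth keypoints", call. = FALSE)
  }
  d2 <- rowSums((pred$points - truth$points)^2)
  terms <- exp(-d2 / (2 * area * kappas^2))
  terms[!vis] <- NA_real_
  structure(
    list(
      oks = mean(terms[vis]),
      per_keypoint_terms = terms,
      area = area,
      n_visible = n_visible
    ),
    class = "oks_record"
  )
}

# object area: bbox w*h when present, else bounding box of visible keypoints
frame_area <- function(frame) {
  if (!is.null(frame$bbox)) {
    return(frame$bbox[3] * frame$bbox[4])
  }
  vis <- frame$visibility > 0L
  if (!any(vis)) {
    return(NA_real_)
  }
  xs <- frame$points[vis, 1]
  ys <- frame$points[vis, 2]
  (max(xs) - min(xs)) * (max(ys) - min(ys))
}

#' Classify OKS scores at one threshold
#'
#' A prediction whose OKS is within the threshold (score >= tau) counts
#' as a true positive; below it, a false positive. With exactly one
#' scored prediction per ground-truth instance, recall per threshold is
#' tp over the number of truth instances; missed truth instances
#' (`n_truth` larger than the number of scores) count as false
#' negatives.
#'
#' @param scores Numeric OKS scores or a list of `oks_record`s.
#' @param threshold Threshold tau in `[0, 1]`.
#' @param n_truth Number of ground-truth instances; defaults to the
#'   number of scores (one prediction per truth).
#' @return A one-row data.frame: threshold, tp, fp, precision, recall.
#' @export
classify_at_threshold <- function(scores, threshold, n_truth = NULL) {
  scores <- as_oks_values(scores)
  if (!length(scores)) stop("no OKS scores to classify", call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  if (is.null(n_truth)) n_truth <- length(scores)
  tp <- sum(scores >= threshold)
  fp <- length(scores) - tp
  data.frame(
    threshold = threshold, tp = tp, fp = fp,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = tp / n_truth
  )
}

as_oks_values <- function(scores) {
  if (is.list(scores)) {
    vapply(scores, function(s) if (inherits(s, "oks_record")) s$oks else as.numeric(s), numeric(1))
  } else {
    as.numeric(scores)
  }
}

#' Evaluate predicted keypoints against truth across an OKS threshold sweep
#'
#' Scores every (pred, truth) pair with [compute_oks()], classifies the
#' scores at each threshold of the sweep (default 0.50 to 0.95 in steps
#' of 0.05), and reports average precision and average recall as the
#' arithmetic means over the sweep plus the named 0.75 and 0.95 cuts and
#' the F1 score of the means.
#'
#' @param pairs List of `list(pred = , truth = )` pairs, or two parallel
#'   lists via `preds` and `truths`.
#' @param kappas,area Passed to [compute_oks()].
#' @param thresholds Numeric sweep, default `seq(0.5, 0.95, by = 0.05)`.
#' @param n_truth Total ground-truth instances (>= number of pairs);
#'   defaults to the number of pairs.
#' @return A list of class `oks_eval`: `per_threshold` (data.frame),
#'   `ap_mean`, `ar_mean`, `ap_at`, `ar_at`, `f1`, `oks` (scores).
#' @export
evaluate_keypoints <- function(pairs, kappas = 0.05, area = NULL,
                               thresholds = seq(0.5, 0.95, by = 0.05),
                               n_truth = NULL) {
  if (!length(pairs)) stop("need at least one (pred, truth) pair", call. = FALSE)
  schemas <- vapply(
    pairs,
    function(p) paste(p$truth$schema$names, collapse = ","), character(1)
  )
  if (length(unique(schemas)) != 1L) {
    stop("all pairs must share one keypoint schema", call. = FALSE)
  }
  scores <- vapply(pairs, function(p) {
    compute_oks(p$pred, p$truth, kappas = kappas, area = area)$oks
  }, numeric(1))
  if (is.null(n_truth)) n_truth <- length(scores)
  per <- do.call(rbind, lapply(thresholds, function(tau) {
    classify_at_threshold(scores, tau, n_truth = n_truth)
  }))
  ap_mean <- mean(per$precision)
  ar_mean <- mean(per$recall)
  at <- function(col, tau) {
    i <- which(abs(per$threshold - tau) < 1e-9)
    if (length(i)) per[[col]][i[1]] else NA_real_
  }
  structure(
    list(
      per_threshold = per,
      ap_mean = ap_mean, ar_mean = ar_mean,
      ap_at = c("0.75" = at("precision", 0.75), "0.95" = at("precision", 0.95)),
      ar_at = c("0.75" = at("recall", 0.75), "0.95" = at("recall", 0.95)),
      f1 = f1_score(ap_mean, ar_mean),
      oks = scores
    ),
    class = "oks_eval"
  )
}

#' @export
print.oks_eval <- function(x, ...) {
  cat(
    "<oks_eval> ", length(x$oks), " instances | AP ", round(x$ap_mean, 3),
    " AR ", round(x$ar_mean, 3), " F1 ", round(x$f1, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' F1 score: harmonic mean of precision and recall
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return `2 P R / (P + R)`, or 0 when both are 0.
#' @export
#' @examples
#' f1_score(0.958, 0.958) # harmonic mean of equal values is that value
f1_score <- function(precision, recall) {
  stopifnot(
    precision >= 0, precision <= 1,
    recall >= 0, recall <= 1
  )
  if (precision + recall == 0) {
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Write an evaluation report as CSV
#'
#' One row per threshold plus a summary row holding the sweep means,
#' the named cuts and F1.
#'
#' @param eval An `oks_eval` from [evaluate_keypoints()].
#' @param path Output CSV path.
#' @export
write_eval_report <- function(eval, path) {
  per <- eval$per_threshold
  per$row <- sprintf("tau=%.2f", per$threshold)
  summary_row <- data.frame(
    row = "summary", threshold = NA_real_, tp = NA_integer_, fp = NA_integer_,
    precision = eval$ap_mean, recall = eval$ar_mean
  )
  out <- rbind(per[, c("row", "threshold", "tp", "fp", "precision", "recall")], summary_row)
  out$ap_075 <- c(rep(NA_real_, nrow(per)), eval$ap_at[["0.75"]])
  out$ap_095 <- c(rep(NA_real_, nrow(per)), eval$ap_at[["0.95"]])
  out$ar_075 <- c(rep(NA_real_, nrow(per)), eval$ar_at[["0.75"]])
  out$ar_095 <- c(rep(NA_real_, nrow(per)), eval$ar_at[["0.95"]])
  out$f1 <- c(rep(NA_real_, nrow(per)), eval$f1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
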