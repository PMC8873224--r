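# Screening evaluation machinery: feature-conditioned confusion
# outcomes, sensitivity/specificity with confidence intervals, quadratic
# weighted kappa, ROC/AUC with dual operating points, prevalence
# subsampling and the workload-reduction statistic.

#' Binary screening tasks
#'
#' The four binary tasks evaluated on a graded cohort. Each task's
#' positive set is an upward-closed set of severity levels (the DMO task
#' is driven by the maculopathy flag instead).
#'
#' @param name one of `"DR_VS_NONDR"`, `"REFERABLE"`, `"PDR_VS_NONPDR"`,
#'   `"DMO"`.
#' @param table the [grading_table()] whose ladder the task partitions.
#' @return a list of class `binary_task` with the positive level set.
#' @export
binary_task <- function(name = c("DR_VS_NONDR", "REFERABLE",
                                 "PDR_VS_NONPDR", "DMO"),
                        table = grading_table("icdrs")) {
  name <- match.arg(name)
  k <- length(table$levels)
  positive <- switch(name,
    DR_VS_NONDR = table$levels[-1L],
    REFERABLE = table$levels[seq(match(table$referable$min_level,
                                       table$levels), k)],
    PDR_VS_NONPDR = table$levels[k],
    DMO = character(0))
  structure(list(name = name, scheme = table$scheme,
                 levels = table$levels, positive_levels = positive),
            class = "binary_task")
}

#' Feature-conditioned confusion outcome of one graded image
#'
#' Implements the lesion-conditioned outcome definitions used for
#' screening evaluation, which differ from plain grade-confusion
#' counting:
#' * **FP** whenever the detected lesions imply a strictly higher
#'   severity level than the ground truth (severity over-call), even if
#'   both grades fall on the same side of the task threshold;
#' * otherwise **TP** when ground truth is task-positive and the
#'   prediction is also task-positive;
#' * **FN** when ground truth is task-positive but only lower-severity
#'   (task-negative) findings were made;
#' * **TN** when nothing, or only task-negative findings, are reported
#'   on a task-negative image (e.g. under the referable task an ICDRS
#'   mild image with only MAs detected is a TN).
#'
#' Set `conventional = TRUE` for plain threshold confusion counting
#' (prediction positive vs ground truth positive) instead.
#'
#' @param predicted a `grade_result` (or a bare level label).
#' @param gt_level ground-truth level label on the same ladder.
#' @param task a [binary_task()].
#' @param gt_dmo ground-truth maculopathy flag (DMO task only).
#' @param predicted_dmo predicted maculopathy flag, used when
#'   `predicted` is a bare label.
#' @param conventional logical; use plain confusion counting.
#' @return one of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
classify_outcome <- function(predicted, gt_level, task,
                             gt_dmo = FALSE, predicted_dmo = FALSE,
                             conventional = FALSE) {
  stopifnot(inherits(task, "binary_task"))
  if (inherits(predicted, "grade_result")) {
    predicted_dmo <- isTRUE(predicted$dmo)
    predicted <- predicted$level
  }
  if (task$name == "DMO") {
    p_pos <- isTRUE(predicted_dmo)
    g_pos <- isTRUE(gt_dmo)
    return(if (p_pos && g_pos) "TP" else if (p_pos) "FP"
           else if (g_pos) "FN" else "TN")
  }
  p <- match(as.character(predicted), task$levels)
  g <- match(as.character(gt_level), task$levels)
  if (is.na(p) || is.na(g)) {
    stop("level label not on the ", task$scheme, " ladder", call. = FALSE)
  }
  p_pos <- task$levels[p] %in% task$positive_levels
  g_pos <- task$levels[g] %in% task$positive_levels
  if (conventional) {
    return(if (p_pos && g_pos) "TP" else if (p_pos) "FP"
           else if (g_pos) "FN" else "TN")
  }
  if (p > g) "FP"
  else if (g_pos) { if (p_pos) "TP" else "FN" }
  else "TN"
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param conf confidence level (default 0.95).
#' @return numeric c(low, high).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' @inheritParams wilson_ci
#' @return numeric c(low, high).
#' @export
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(low, high)
}

#' Summarise a list of confusion outcomes
#'
#' Counts TP/TN/FP/FN and derives sensitivity, specificity, PPV, NPV and
#' accuracy with 95% confidence intervals. Metrics whose denominator is
#' zero are reported as `NA` (absent), never as 0.
#'
#' @param outcomes character vector of `"TP"/"TN"/"FP"/"FN"` labels.
#' @param ci_method `"wilson"` (default) or `"clopper"`.
#' @param conf confidence level (default 0.95).
#' @return an object of class `eval_summary`: counts plus a metric table
#'   with point estimates and interval bounds.
#' @export
summarise_eval <- function(outcomes, ci_method = c("wilson", "clopper"),
                           conf = 0.95) {
  ci_method <- match.arg(ci_method)
  outcomes <- as.character(outcomes)
  bad <- setdiff(unique(outcomes), c("TP", "TN", "FP", "FN"))
  if (length(bad) || !length(outcomes)) {
    stop("outcomes must be a non-empty vector of TP/TN/FP/FN labels",
         call. = FALSE)
  }
  n <- length(outcomes)
  tp <- sum(outcomes == "TP")
  tn <- sum(outcomes == "TN")
  fp <- sum(outcomes == "FP")
  fn <- sum(outcomes == "FN")
  ci_fun <- if (ci_method == "wilson") wilson_ci else clopper_pearson_ci
  one <- function(x, d) {
    if (d == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(x / d, ci_fun(x, d, conf))
  }
  metrics <- rbind(sensitivity = one(tp, tp + fn),
                   specificity = one(tn, tn + fp),
                   ppv = one(tp, tp + fp),
                   npv = one(tn, tn + fn),
                   accuracy = one(tp + tn, n))
  colnames(metrics) <- c("estimate", "ci_low", "ci_high")
  structure(list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn), n = n,
                 metrics = as.data.frame(metrics),
                 ci_method = ci_method, conf = conf),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> n=%d TP=%d TN=%d FP=%d FN=%d (%s %g%% CI)\n",
              x$n, x$counts[["TP"]], x$counts[["TN"]], x$counts[["FP"]],
              x$counts[["FN"]], x$ci_method, 100 * x$conf))
  m <- x$metrics
  for (nm in rownames(m)) {
    if (is.na(m[nm, "estimate"])) next
    cat(sprintf("  %-11s %6.2f%% (%.2f-%.2f%%)\n", nm,
                100 * m[nm, "estimate"], 100 * m[nm, "ci_low"],
                100 * m[nm, "ci_high"]))
  }
  invisible(x)
}

#' Quadratic weighted kappa
#'
#' Chance-corrected ordinal agreement with squared-distance weights:
#' kappa = 1 - sum(w * O) / sum(w * E), with w_ij = (i - j)^2 /
#' (k - 1)^2, O the observed contingency table and E the outer product
#' of the marginals scaled to n.
#'
#' @param rater_a,rater_b equal-length vectors of ordinal labels coded
#'   0 .. k-1.
#' @param k number of ordinal categories.
#' @return kappa in \[-1, 1\]. Errors when the chance-agreement
#'   denominator is zero (both raters constant and identical), rather
#'   than silently returning 1.
#' @export
quadratic_weighted_kappa <- function(rater_a, rater_b, k) {
  a <- as.integer(rater_a)
  b <- as.integer(rater_b)
  if (length(a) != length(b) || length(a) < 2L) {
    stop("raters must have equal length >= 2", call. = FALSE)
  }
  if (any(a < 0L | a >= k) || any(b < 0L | b >= k)) {
    stop("labels must lie in [0, k)", call. = FALSE)
  }
  n <- length(a)
  O <- table(factor(a, levels = 0:(k - 1)), factor(b, levels = 0:(k - 1)))
  E <- outer(rowSums(O), colSums(O)) / n
  w <- outer(0:(k - 1), 0:(k - 1), function(i, j) (i - j)^2 / (k - 1)^2)
  denom <- sum(w * E)
  if (denom == 0) {
    stop("quadratic weighted kappa is undefined: no chance disagreement (both raters constant)",
         call. = FALSE)
  }
  1 - sum(w * O) / denom
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores in descending
#' order (prediction positive when score >= threshold) and returns the
#' full operating characteristic, anchored at (0, 0) and ending at
#' (1, 1). `auc()` integrates it with the trapezoidal rule.
#'
#' @param scores numeric scores, larger meaning more disease-positive.
#' @param labels logical (or 0/1) ground-truth labels; both classes must
#'   be present.
#' @return for `roc_curve()`: a data.frame of class `roc_curve` with
#'   columns `threshold`, `tp`, `fp`, `tn`, `fn`, `fpr`, `tpr`; for
#'   `auc()`: a single number in \[0, 1\].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must be equal-length and free of NA",
         call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), 0)
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), 0)
  out <- data.frame(threshold = c(Inf, thr),
                    tp = c(0, tp), fp = c(0, fp),
                    tn = n_neg - c(0, fp), fn = n_pos - c(0, tp))
  out$fpr <- out$fp / n_neg
  out$tpr <- out$tp / n_pos
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @rdname roc_curve
#' @param curve a `roc_curve` result.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                         utils::tail(curve$tpr, -1)) / 2)
}

#' Select a screening operating point on a ROC curve
#'
#' `HIGH_SENSITIVITY`: among thresholds with sensitivity >= `floor`,
#' the one maximising specificity. `HIGH_SPECIFICITY`: among thresholds
#' with specificity >= `floor`, the one maximising sensitivity. When the
#' floor is infeasible the nearest feasible point (smallest shortfall in
#' the floored metric) is returned with `feasible = FALSE`.
#'
#' @param curve a [roc_curve()] result.
#' @param mode `"HIGH_SENSITIVITY"` or `"HIGH_SPECIFICITY"`.
#' @param floor required minimum for the floored metric, in (0, 1).
#' @return a list: `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `feasible`.
#' @export
select_operating_point <- function(curve,
                                   mode = c("HIGH_SENSITIVITY",
                                            "HIGH_SPECIFICITY"),
                                   floor = 0.9) {
  stopifnot(inherits(curve, "roc_curve"))
  mode <- match.arg(mode)
  assert_scalar_number(floor, "floor", 1e-12, 1 - 1e-12)
  sens <- curve$tpr
  spec <- 1 - curve$fpr
  target <- if (mode == "HIGH_SENSITIVITY") sens else spec
  other <- if (mode == "HIGH_SENSITIVITY") spec else sens
  ok <- target >= floor
  if (any(ok)) {
    # maximise the free metric subject to the floor; ties -> higher floored
    # metric, then the more conservative (earlier) threshold
    idx <- which(ok)[order(-other[ok], -target[ok])][1L]
    feasible <- TRUE
  } else {
    idx <- which(target == max(target))[1L]
    feasible <- FALSE
  }
  row <- curve[idx, ]
  list(threshold = row$threshold,
       sensitivity = row$tpr,
       specificity = 1 - row$fpr,
       ppv = if (row$tp + row$fp > 0) row$tp / (row$tp + row$fp) else NA_real_,
       npv = if (row$tn + row$fn > 0) row$tn / (row$tn + row$fn) else NA_real_,
       feasible = feasible)
}

#' Subsample a labelled cohort to a target positive prevalence
#'
#' Keeps every negative and downsamples the positives uniformly at
#' random (seeded) so the realised positive fraction is within one
#' record of the target; deterministic given the seed.
#'
#' @param positive logical vector labelling the cohort.
#' @param target_prevalence desired positive fraction, in (0, 1).
#' @param seed integer seed.
#' @return integer vector of retained indices (sorted).
#' @export
subsample_prevalence <- function(positive, target_prevalence, seed = 1L) {
  positive <- as.logical(positive)
  assert_scalar_number(target_prevalence, "target_prevalence",
                       1e-12, 1 - 1e-12)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("cohort must contain both positives and negatives", call. = FALSE)
  }
  keep_pos <- round(target_prevalence / (1 - target_prevalence) * n_neg)
  if (keep_pos > n_pos) {
    stop(sprintf("target prevalence %.3f unreachable by downsampling positives (have %d, need %d)",
                 target_prevalence, n_pos, keep_pos), call. = FALSE)
  }
  if (keep_pos < 1) {
    stop("target prevalence too low: would retain no positives",
         call. = FALSE)
  }
  pos_idx <- which(positive)
  chosen <- with_seed(seed, sample(pos_idx, keep_pos))
  sort(c(which(!positive), chosen))
}

#' Workload reduction of an automated pre-screening filter
#'
#' Fraction of images the automated filter clears without human review,
#' assuming only positive returns are seen again by a human:
#' (TN + FN) / n.
#'
#' @param outcomes character vector of TP/TN/FP/FN labels.
#' @return a number in \[0, 1\].
#' @export
workload_reduction <- function(outcomes) {
  outcomes <- as.character(outcomes)
  if (!length(outcomes)) stop("outcomes must be non-empty", call. = FALSE)
  mean(outcomes %in% c("TN", "FN"))
}
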