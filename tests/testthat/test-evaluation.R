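icdrs <- grading_table("icdrs")

test_that("feature-conditioned outcomes follow the four definitions", {
  referable <- binary_task("REFERABLE", icdrs)
  # normal image, nothing detected
  expect_identical(classify_outcome("0", "0", referable), "TN")
  # mild image, only MAs detected (prediction mild)
  expect_identical(classify_outcome("1", "1", referable), "TN")
  # moderate ground truth but PDR-level lesions detected: over-call
  expect_identical(classify_outcome("4", "2", referable), "FP")
  # severe ground truth, only mild findings
  expect_identical(classify_outcome("1", "3", referable), "FN")
  # over-call within the negatives is still FP
  expect_identical(classify_outcome("1", "0", referable), "FP")
  # under-call within the positives is TP for the binary task
  expect_identical(classify_outcome("2", "3", referable), "TP")

  # conventional mode: plain threshold confusion
  expect_identical(classify_outcome("1", "0", referable,
                                    conventional = TRUE), "TN")
  expect_identical(classify_outcome("4", "2", referable,
                                    conventional = TRUE), "TP")

  dmo <- binary_task("DMO", icdrs)
  expect_identical(classify_outcome("0", "0", dmo, gt_dmo = TRUE,
                                    predicted_dmo = TRUE), "TP")
  expect_identical(classify_outcome("0", "0", dmo, gt_dmo = FALSE,
                                    predicted_dmo = TRUE), "FP")
})

test_that("classify_outcome is total over every level pair and task", {
  for (scheme in c("icdrs", "nsc")) {
    tab <- grading_table(scheme)
    for (task_name in c("DR_VS_NONDR", "REFERABLE", "PDR_VS_NONPDR")) {
      task <- binary_task(task_name, tab)
      for (p in tab$levels) for (g in tab$levels) {
        out <- classify_outcome(p, g, task)
        expect_true(out %in% c("TP", "TN", "FP", "FN"))
      }
    }
  }
})

test_that("summarise_eval computes metrics, CIs, and absent denominators", {
  outcomes <- c(rep("TP", 45), rep("FN", 5), rep("TN", 90), rep("FP", 10))
  s <- summarise_eval(outcomes)
  expect_identical(sum(s$counts), 150L)
  expect_equal(s$metrics["sensitivity", "estimate"], 0.90)
  expect_equal(s$metrics["specificity", "estimate"], 0.90)
  expect_equal(s$metrics["accuracy", "estimate"], 135 / 150)
  expect_true(all(s$metrics$ci_low <= s$metrics$estimate &
                  s$metrics$estimate <= s$metrics$ci_high))

  # Wilson CI against the independent closed form
  expect_equal(as.numeric(s$metrics["sensitivity", c("ci_low", "ci_high")]),
               brute_wilson(45, 50), tolerance = 1e-12)
  expect_equal(wilson_ci(90, 100), brute_wilson(90, 100), tolerance = 1e-12)

  # all positive: specificity is absent, not zero
  s2 <- summarise_eval(rep("TP", 20))
  expect_identical(s2$metrics["sensitivity", "estimate"], 1)
  expect_true(is.na(s2$metrics["specificity", "estimate"]))

  # Clopper-Pearson option against qbeta directly
  s3 <- summarise_eval(outcomes, ci_method = "clopper")
  expect_equal(s3$metrics["sensitivity", "ci_low"],
               qbeta(0.025, 45, 6), tolerance = 1e-12)
  expect_error(summarise_eval(character()), "non-empty")
})

test_that("quadratic weighted kappa matches the brute-force tabulation", {
  expect_equal(quadratic_weighted_kappa(c(0, 1, 2, 3, 4),
                                        c(0, 1, 2, 3, 4), 5), 1)
  a <- c(0, 1, 2, 3, 4)
  b <- c(0, 1, 2, 3, 3)
  expect_equal(quadratic_weighted_kappa(a, b, 5), brute_qwk(a, b, 5),
               tolerance = 1e-12)
  # negative agreement, 2x2
  expect_equal(quadratic_weighted_kappa(c(0, 0, 1, 1), c(1, 1, 0, 0), 2),
               brute_qwk(c(0, 0, 1, 1), c(1, 1, 0, 0), 2),
               tolerance = 1e-12)
  for (seed in 1:25) {
    ab <- withr::with_seed(seed, list(a = sample(0:4, 300, TRUE),
                                      b = sample(0:4, 300, TRUE)))
    expect_lt(abs(quadratic_weighted_kappa(ab$a, ab$b, 5) -
                  brute_qwk(ab$a, ab$b, 5)), 1e-12)
    # invariances: permuting pairs; reversing the category order
    perm <- withr::with_seed(seed + 1, sample(300))
    expect_equal(quadratic_weighted_kappa(ab$a[perm], ab$b[perm], 5),
                 quadratic_weighted_kappa(ab$a, ab$b, 5), tolerance = 1e-12)
    expect_equal(quadratic_weighted_kappa(4 - ab$a, 4 - ab$b, 5),
                 quadratic_weighted_kappa(ab$a, ab$b, 5), tolerance = 1e-12)
  }
  expect_error(quadratic_weighted_kappa(c(2, 2, 2), c(2, 2, 2), 5),
               "undefined")
})

test_that("ROC curve and AUC match the rank-statistic oracle", {
  # perfect separation
  curve <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc(curve), 1)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)

  for (seed in 1:20) {
    sl <- withr::with_seed(seed, {
      labels <- runif(200) < 0.4
      list(scores = round(runif(200), 2), labels = labels)  # with ties
    })
    curve <- roc_curve(sl$scores, sl$labels)
    expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
    expect_equal(auc(curve), brute_auc(sl$scores, sl$labels),
                 tolerance = 1e-12)
  }
  # labels independent of scores: AUC near 1/2
  big <- withr::with_seed(99, list(s = runif(2000), l = runif(2000) < 0.5))
  expect_lt(abs(auc(roc_curve(big$s, big$l)) - 0.5), 0.05)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("operating points match exhaustive search and flag infeasibility", {
  sl <- withr::with_seed(3, {
    labels <- runif(500) < 0.3
    scores <- rnorm(500, mean = ifelse(labels, 1, 0))
    list(scores = scores, labels = labels)
  })
  curve <- roc_curve(sl$scores, sl$labels)
  for (mode in c("HIGH_SENSITIVITY", "HIGH_SPECIFICITY")) {
    got <- select_operating_point(curve, mode, floor = 0.85)
    want <- brute_operating_point(curve, mode, 0.85)
    expect_true(got$feasible)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
  infeasible <- select_operating_point(curve, "HIGH_SENSITIVITY",
                                       floor = 1 - 1e-9)
  # sensitivity 1 is always reachable at the lowest threshold
  expect_equal(infeasible$sensitivity, 1)
  perfect <- roc_curve(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  pt <- select_operating_point(perfect, "HIGH_SPECIFICITY", 0.99)
  expect_equal(pt$sensitivity, 1)
  expect_equal(pt$specificity, 1)
})

test_that("prevalence subsampling hits the target and is deterministic", {
  positive <- rep(c(TRUE, FALSE), c(3050, 6950))
  idx5 <- subsample_prevalence(positive, 0.05, seed = 4)
  expect_lt(abs(mean(positive[idx5]) - 0.05), 0.001)
  idx15 <- subsample_prevalence(positive, 0.15, seed = 4)
  expect_lt(abs(mean(positive[idx15]) - 0.15), 0.001)
  expect_identical(idx5, subsample_prevalence(positive, 0.05, seed = 4))
  expect_false(identical(idx5, subsample_prevalence(positive, 0.05,
                                                    seed = 5)))
  expect_true(all(which(!positive) %in% idx5))  # negatives all kept
  # target at the current prevalence keeps everything
  expect_identical(subsample_prevalence(positive, 0.305, seed = 1),
                   seq_along(positive))
  expect_error(subsample_prevalence(positive, 0.9, seed = 1),
               "unreachable")
})

test_that("workload reduction counts images cleared without human review", {
  expect_identical(workload_reduction(rep("TN", 10)), 1)
  expect_identical(workload_reduction(rep("TP", 10)), 0)
  expect_equal(workload_reduction(c(rep("TN", 70), rep("TP", 20),
                                    rep("FP", 5), rep("FN", 5))), 0.75)
})
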