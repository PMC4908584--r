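toy_cohort <- function(ref, pred, flag = NULL) {
  co <- data.frame(subject_id = sprintf("S%02d", seq_along(ref)),
                   reference_pmol_L = ref, predicted_pmol_L = pred)
  if (!is.null(flag)) co$flag <- flag
  co
}

test_that("median bias is the median relative error, flags excluded", {
  ref <- c(100, 200, 300, 400)
  expect_equal(median_bias(toy_cohort(ref, ref)), 0)
  expect_equal(median_bias(toy_cohort(ref, 1.1 * ref)), 10)

  co <- toy_cohort(c(ref, 500), c(1.05 * ref, Inf),
                   flag = c(rep("ok", 4), "above_range"))
  expect_message(b <- median_bias(co), "excluded 1")
  expect_equal(b, 5)
  expect_error(median_bias(toy_cohort(100, Inf, flag = "above_range")),
               class = "lfa_input_error")
})

test_that("correlation matches the product-moment formula", {
  ref <- c(100, 200, 300, 400)
  expect_equal(cohort_correlation(toy_cohort(ref, 2 * ref + 5))$estimate, 1)
  expect_equal(cohort_correlation(toy_cohort(ref, -ref))$estimate, -1)

  pred <- c(110, 190, 310, 390)
  r_hand <- sum((ref - mean(ref)) * (pred - mean(pred))) /
    sqrt(sum((ref - mean(ref))^2) * sum((pred - mean(pred))^2))
  got <- cohort_correlation(toy_cohort(ref, pred))
  expect_equal(got$estimate, r_hand)
  # hand computation: covariance sum 48000, variance sums 50000 and 46400
  expect_equal(got$estimate, 48000 / sqrt(50000 * 46400), tolerance = 1e-12)
  expect_lt(got$p_value, 0.01)

  expect_error(cohort_correlation(toy_cohort(ref, rep(7, 4))),
               class = "lfa_input_error")
  expect_error(cohort_correlation(toy_cohort(ref[1:2], pred[1:2])),
               class = "lfa_input_error")
})

test_that("deficiency classification is strict-below with flag overrides", {
  expect_equal(classify_deficiency(186.7, 221), "deficient")
  expect_equal(classify_deficiency(221, 221), "not_deficient")  # equality
  expect_equal(classify_deficiency(400, 332), "not_deficient")
  # an above-range ">top calibrator" result is sufficient at any cut-off
  expect_equal(classify_deficiency(Inf, 332, flag = "above_range"),
               "not_deficient")
  expect_equal(classify_deficiency(0, 150, flag = "below_range"),
               "deficient")
})

test_that("sensitivity and specificity come from the confusion counts", {
  co <- toy_cohort(rep(100, 4), rep(100, 4))
  co$reference_pmol_L <- c(100, 100, 400, 400)
  co$predicted_pmol_L <- c(90, 110, 410, 390)
  ss <- sens_spec(co, 332)
  expect_equal(ss$sensitivity, 1); expect_equal(ss$specificity, 1)

  # 8 reference-deficient of which 7 called, 4 sufficient all called
  ref <- c(rep(200, 8), rep(500, 4))
  pred <- c(rep(150, 7), 400, rep(450, 4))
  ss2 <- sens_spec(toy_cohort(ref, pred), 332)
  expect_equal(ss2$sensitivity, 7 / 8)
  expect_equal(ss2$specificity, 1)
  expect_equal(unlist(ss2[c("tp", "fp", "tn", "fn")]),
               c(tp = 7, fp = 0, tn = 4, fn = 1))

  # all-negative cohort: sensitivity undefined
  ss3 <- sens_spec(toy_cohort(rep(500, 5), rep(480, 5)), 332)
  expect_true(is.na(ss3$sensitivity))
  expect_match(attr(ss3$sensitivity, "reason"), "positive")
  expect_equal(ss3$specificity, 1)
})

test_that("ROC is a monotone staircase whose AUC matches Mann-Whitney", {
  ref <- c(rep(100, 6), rep(600, 6))
  sep <- toy_cohort(ref, ref + 10)
  expect_equal(roc_curve(sep, 332)$auc, 1)

  set.seed(99)
  for (i in 1:20) {
    n <- 40
    co <- toy_cohort(runif(n, 50, 900), sample(runif(n, 50, 900)))
    r <- roc_curve(co, 332)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_equal(r$auc,
                 mann_whitney_auc(co$predicted_pmol_L,
                                  co$reference_pmol_L < 332))
    # AUC invariant under strictly monotone transform of predictions
    co2 <- co; co2$predicted_pmol_L <- log(co2$predicted_pmol_L)
    expect_equal(roc_curve(co2, 332)$auc, r$auc)
  }

  # label-independent predictions give chance-level AUC at large n
  set.seed(7)
  big <- toy_cohort(runif(4000, 50, 900), runif(4000, 50, 900))
  expect_equal(roc_curve(big, 332)$auc, 0.5, tolerance = 0.05)

  expect_error(roc_curve(toy_cohort(rep(500, 4), rep(1, 4)), 332),
               class = "lfa_input_error")
})

test_that("ROC agrees with pROC on a random cohort", {
  skip_if_not_installed("pROC")
  set.seed(12)
  co <- toy_cohort(runif(100, 50, 900), runif(100, 50, 900) +
                     0.5 * runif(100, 50, 900))
  got <- roc_curve(co, 332)$auc
  want <- as.numeric(pROC::auc(
    pROC::roc(response = co$reference_pmol_L < 332,
              predictor = co$predicted_pmol_L,
              direction = ">", levels = c(FALSE, TRUE), quiet = TRUE)))
  expect_equal(got, want)
})

test_that("sens_spec coincides with the ROC point at the same cut-off", {
  set.seed(5)
  co <- toy_cohort(runif(60, 50, 900), runif(60, 50, 900))
  cutoff <- 332
  ss <- sens_spec(co, cutoff)
  r <- roc_curve(co, cutoff)
  pt <- r$points[r$points$cutoff == cutoff, ]
  if (nrow(pt) == 0) {
    # cut-off not among predicted values: recompute with it included
    call <- co$predicted_pmol_L < cutoff
    truth <- co$reference_pmol_L < cutoff
    pt <- data.frame(fpr = sum(call & !truth) / sum(!truth),
                     tpr = sum(call & truth) / sum(truth))
  }
  expect_equal(ss$sensitivity, pt$tpr[1])
  expect_equal(1 - ss$specificity, pt$fpr[1])
})

test_that("diagnostic_summary bundles the cohort metrics coherently", {
  crv <- b12_reference_curve()
  co <- predict_cohort(generate_cohort(120, curve = crv, analytic_cv = 0.05,
                                       seed = 17L), crv)
  s <- diagnostic_summary(co)
  expect_s3_class(s, "diagnostic_summary")
  expect_equal(s$per_cutoff$cutoff, c(150, 221, 258, 332))
  expect_true(all(s$per_cutoff$sensitivity >= 0 &
                    s$per_cutoff$sensitivity <= 1, na.rm = TRUE))
  expect_true(abs(s$median_bias_pct) < 5)
  expect_gt(s$pearson$estimate, 0.9)
  expect_gt(s$auc, 0.95)
  expect_error(diagnostic_summary(co, cutoffs = c(300, 200)),
               class = "lfa_config_error")
})
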