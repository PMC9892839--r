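labels_from_counts <- function(tp, fn, tn, fp) {
  list(truth = rep(c("T", "T", "NT", "NT"), c(tp, fn, tn, fp)),
       pred = rep(c("T", "NT", "NT", "T"), c(tp, fn, tn, fp)))
}

test_that("confusion metrics reproduce the hand-evaluated example", {
  l <- labels_from_counts(14, 9, 16, 7)
  r <- confusion_metrics(l$truth, l$pred)
  expect_equal(r$SE, 14 / 23)
  expect_equal(r$SP, 16 / 23)
  expect_equal(r$BAC, (14 / 23 + 16 / 23) / 2)
  expect_equal(r$PLR, 2.0, tolerance = 1e-12)
  expect_equal(r$NLR, 0.5625, tolerance = 1e-4)
  expect_equal(r$DOR, 32 / 9, tolerance = 1e-12)
})

test_that("metric identities hold for random confusion matrices", {
  set.seed(1)
  for (i in 1:200) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    tn <- sample(0:20, 1); fp <- sample(0:20, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    l <- labels_from_counts(tp, fn, tn, fp)
    r <- confusion_metrics(l$truth, l$pred)
    expect_equal(r$BAC, (r$SE + r$SP) / 2)
    if (r$SP < 1) expect_equal(r$PLR, r$SE / (1 - r$SP))
    if (r$SP > 0) expect_equal(r$NLR, (1 - r$SE) / r$SP)
    if (is.finite(r$PLR) && is.finite(r$NLR) && r$NLR > 0) {
      expect_equal(r$DOR, r$PLR / r$NLR)
    }
    expect_equal(c(r$TP, r$FN, r$TN, r$FP), c(tp, fn, tn, fp))
  }
})

test_that("degenerate confusion matrices yield explicit infinities", {
  perfect <- labels_from_counts(5, 0, 5, 0)
  r <- confusion_metrics(perfect$truth, perfect$pred)
  expect_equal(r$SE, 1); expect_equal(r$SP, 1); expect_equal(r$BAC, 1)
  expect_identical(r$PLR, Inf)
  expect_equal(r$NLR, 0)
  allnt <- labels_from_counts(0, 5, 5, 0)
  r2 <- confusion_metrics(allnt$truth, allnt$pred)
  expect_equal(r2$SE, 0); expect_equal(r2$SP, 1); expect_equal(r2$BAC, 0.5)
  expect_error(confusion_metrics(rep("T", 4), rep("T", 4)), "both classes")
})

test_that("permutation p-value follows the add-one formula at the extremes", {
  n <- 20
  ids <- sprintf("P%02d", 1:n)
  lab <- stats::setNames(rep(c("T", "NT"), n / 2), ids)
  roster <- data.frame(subject_id = ids, group = unname(lab), protocol = "P1",
                       stringsAsFactors = FALSE)
  plan <- build_lpo_plan(roster, seed = 1)
  # perfectly separating score beats every permutation: p = 1/(B+1)
  x <- matrix(ifelse(lab == "T", 1, 0) + 0, ncol = 1,
              dimnames = list(ids, "s"))
  pt <- permutation_test_bac(classifier_spec("logistic"), plan, x, lab,
                             n_permutations = 99, seed = 2)
  expect_equal(pt$p_value, 1 / 100)
  expect_equal(pt$bac_observed, 1)
  expect_length(pt$bac_null, 99)
  # the reported p always equals the add-one formula applied to the
  # returned null sample, and ties count against the observed value
  set.seed(3)
  xr <- matrix(stats::rnorm(n), ncol = 1, dimnames = list(ids, "s"))
  pr <- permutation_test_bac(classifier_spec("logistic"), plan, xr, lab,
                             n_permutations = 49, seed = 4)
  expect_equal(pr$p_value,
               (1 + sum(pr$bac_null >= pr$bac_observed - 1e-12)) / 50)
  expect_gte(pr$p_value, 1 / 50)
  expect_lte(pr$p_value, 1)
})

test_that("aggregation applies the 3-of-5 rule and is monotone", {
  a <- aggregate_bootstraps(c(0.01, 0.04, 0.049, 0.2, 0.6))
  expect_equal(a$n_significant, 3)
  expect_equal(a$threshold, 3)
  expect_true(a$decision)
  expect_false(aggregate_bootstraps(rep(0.06, 5))$decision)
  expect_equal(aggregate_bootstraps(rep(1, 5))$threshold, 3)
  expect_error(aggregate_bootstraps(numeric(0)), "empty")
  # lowering any p-value never flips a true decision to false
  set.seed(4)
  for (i in 1:50) {
    p <- stats::runif(5)
    base <- aggregate_bootstraps(p)$decision
    j <- sample(5, 1)
    p2 <- p; p2[j] <- p2[j] * stats::runif(1)
    if (base) expect_true(aggregate_bootstraps(p2)$decision)
  }
})

test_that("signed-rank test matches exact enumeration", {
  r <- wilcoxon_median_bac(c(0.60, 0.62, 0.58, 0.61, 0.59))
  expect_equal(r$p_value, 1 / 32)
  expect_equal(r$statistic, 15)
  expect_equal(wilcoxon_median_bac(c(0.4, 0.45, 0.3, 0.49))$p_value, 1)
  # replicates exactly at chance are dropped
  expect_equal(wilcoxon_median_bac(c(0.5, 0.6, 0.7, 0.65, 0.62))$p_value,
               wilcoxon_median_bac(c(0.6, 0.7, 0.65, 0.62))$p_value)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    # distinct magnitudes with random signs: no zeros, no ties in |d|
    bacs <- 0.5 + sample(1:30, n) * sample(c(-1, 1), n, TRUE) / 100
    ours <- wilcoxon_median_bac(bacs)
    ref <- stats::wilcox.test(bacs, mu = 0.5, alternative = "greater",
                              exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the multimodal gate admits only significant modalities", {
  rep_for <- function(mod, dec) list(modality = mod, decision = dec)
  none <- multimodal_gate(list(rep_for("smri", FALSE), rep_for("gen", FALSE)))
  expect_length(none, 0)
  expect_match(attr(none, "message"), "no multimodal model")
  one <- multimodal_gate(list(rep_for("smri", TRUE), rep_for("gen", FALSE)))
  expect_equal(as.character(one), "smri")
  all3 <- multimodal_gate(list(rep_for("smri", TRUE), rep_for("gen", TRUE),
                               rep_for("env", TRUE)))
  expect_setequal(as.character(all3), c("smri", "gen", "env"))
  expect_error(multimodal_gate(list()), "at least one")
})

test_that("overfitting report quantifies resubstitution optimism", {
  expect_equal(overfitting_report(c(0.7, 0.8), c(0.7, 0.8))$mean_gap, 0)
  expect_equal(overfitting_report(rep(1, 4), rep(0.5, 4))$mean_gap, 0.5)
  expect_error(overfitting_report(1:3 / 10, 1:4 / 10), "equal length")
  # a null-data SVM shows a positive train-test gap
  s <- lpo_setup(seed = 21)
  res <- run_nested_cv(classifier_spec("linear_svm"), s$plan, s$X, s$labels)
  rep <- overfitting_report(res$train_bac,
                            rep(observed_bac(res), length(res$train_bac)))
  expect_gt(rep$mean_gap, 0.1)
  expect_true(rep$ci[1] <= rep$mean_gap && rep$mean_gap <= rep$ci[2])
})

test_that("the replicate table uses the mean-sd-range layout", {
  reports <- lapply(1:5, function(i) {
    l <- labels_from_counts(10 + i, 13 - i, 12, 11)
    confusion_metrics(l$truth, l$pred)
  })
  tab <- format_performance_table(reports, c(0.01, 0.2, 0.03, 0.6, 0.04))
  expect_equal(tab$measure,
               c("SE (%)", "SP (%)", "BAC (%)", "PLR", "NLR", "DOR",
                 "Significant models"))
  expect_match(tab$value[1], "^\\d+\\.\\d ± \\d+\\.\\d \\[")
  expect_equal(tab$value[7], "3 of 5")
})
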