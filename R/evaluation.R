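#' Confusion-matrix performance measures
#'
#' Sensitivity (SE), specificity (SP), balanced accuracy
#' (BAC = (SE + SP) / 2), positive and negative likelihood ratios
#' (PLR = SE / (1 - SP), NLR = (1 - SE) / SP) and the diagnostic odds ratio
#' (DOR = PLR / NLR), with the transitioning group (`T`) as the positive
#' class. Undefined ratios (SP = 1 or SP = 0, or a zero NLR) are reported as
#' explicit `Inf` / `NaN`, never silently replaced.
#'
#' @param truth,predicted `T`/`NT` label vectors, or pass a
#'   `nested_cv_result` / prediction data frame as `truth`.
#' @return a `perf_report` list with the counts and the six measures.
#' @export
confusion_metrics <- function(truth, predicted = NULL) {
  if (inherits(truth, "nested_cv_result")) truth <- truth$predictions
  if (is.data.frame(truth)) {
    predicted <- truth$predicted_label
    truth <- truth$true_label
  }
  truth_T <- as.character(truth) == "T"
  pred_T <- as.character(predicted) == "T"
  if (!any(truth_T) || all(truth_T)) {
    stop("both classes must be present in the truth labels", call. = FALSE)
  }
  tp <- sum(truth_T & pred_T)
  fn <- sum(truth_T & !pred_T)
  tn <- sum(!truth_T & !pred_T)
  fp <- sum(!truth_T & pred_T)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  plr <- if (sp < 1) se / (1 - sp) else Inf
  nlr <- if (sp > 0) (1 - se) / sp else Inf
  dor <- plr / nlr # Inf/0 conventions propagate; 0/0 and Inf/Inf give NaN
  structure(list(TP = tp, FN = fn, TN = tn, FP = fp,
                 SE = se, SP = sp, BAC = (se + sp) / 2,
                 PLR = plr, NLR = nlr, DOR = dor),
            class = "perf_report")
}

#' @export
print.perf_report <- function(x, ...) {
  cat(sprintf(
    "SE %.3f  SP %.3f  BAC %.3f  PLR %.3g  NLR %.3g  DOR %.3g  (TP %d FN %d TN %d FP %d)\n",
    x$SE, x$SP, x$BAC, x$PLR, x$NLR, x$DOR, x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Permutation test of the balanced accuracy against chance
#'
#' Tests whether the out-of-fold balanced accuracy exceeds the 50% chance
#' level. For each permutation the labels are shuffled, the complete
#' analysis — fold construction, all inner-cycle preparation and tuning —
#' is re-run, and the p-value is the add-one estimate
#' `(1 + #\{BAC_perm >= BAC_obs\}) / (1 + n_permutations)`.
#'
#' With `roster` supplied (the calibrated scheme, used by the pipeline):
#' labels are permuted *stratified by scan protocol* and the CV plan is
#' rebuilt from the permuted labels with the same scheme and seed. The
#' observed and permuted statistics are then exchangeable under the null by
#' construction, which makes the test valid; it also keeps the
#' leave-one-pair-out parity requirement satisfiable for every permutation.
#' Without a roster, the labels are permuted over the whole subsample and
#' the fold structure is kept fixed; because the observed folds are built
#' from the true labels (balanced training partitions) while permuted
#' labels are not, this naive variant is anti-conservative and is retained
#' only for comparison.
#'
#' The single-feature logistic specification automatically uses the simple
#' leave-one-pair-out path (no inner cycle), matching the design for the
#' polygenic and environmental risk scores.
#'
#' @inheritParams run_nested_cv
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param roster optional data frame (`subject_id`, `group`, `protocol`)
#'   covering the plan's subjects; enables the stratified
#'   permutation-with-rebuilt-folds scheme described above.
#' @return a `bac_permutation` list: `p_value`, `bac_observed`, `bac_null`
#'   (the null sample), `n_permutations`, plus the observed `result`.
#' @export
permutation_test_bac <- function(spec, plan, features, labels,
                                 n_permutations = 1000L, seed = 1L,
                                 prep = prep_recipe(), roster = NULL) {
  n_permutations <- check_count(n_permutations, "n_permutations")
  X <- feature_matrix(features)
  ids <- rownames(X)
  lab <- normalize_labels(labels, ids)
  simple <- spec$kind == "logistic" && ncol(X) == 1L
  batch_svm <- spec$kind == "linear_svm" && prep$minmax && !prep$pca &&
    !prep$forward_select
  runner <- function(l, pl) {
    if (simple) {
      fit_simple_lpo_logistic(X, l, pl, spec$decision_threshold)
    } else {
      run_nested_cv(spec, pl, features, l, prep)
    }
  }
  # fast single-label BAC through the compiled engines where the recipe
  # allows it; identical to the R path (asserted in the test suite)
  fast_bac <- function(y01, pl) {
    tr <- lapply(pl$folds, function(f) match(f$train_ids, ids))
    te <- lapply(pl$folds, function(f) match(f$test_ids, ids))
    if (simple) {
      as.numeric(.lpo_logistic_bac_batch(X[, 1], matrix(y01), tr, te,
                                         spec$decision_threshold))
    } else {
      itr <- lapply(pl$folds, function(f) {
        lapply(f$inner_folds, function(g) match(g$train_ids, ids))
      })
      ivl <- lapply(pl$folds, function(f) {
        lapply(f$inner_folds, function(g) match(g$val_ids, ids))
      })
      as.numeric(.svm_nested_bac_batch(X, matrix(y01), tr, te, itr, ivl,
                                       sort(spec$grid$svm_C)))
    }
  }
  obs <- runner(lab, plan)
  bac_obs <- bac_from_labels(obs$predictions$true_label == "T",
                             obs$predictions$predicted_label == "T")

  if (!is.null(roster)) {
    roster <- check_roster(roster)
    if (!setequal(roster$subject_id, ids)) {
      stop("roster and features cover different subjects", call. = FALSE)
    }
    strata <- split(seq_len(nrow(roster)), roster$protocol)
    bac_null <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        r2 <- roster
        for (i in strata) r2$group[i] <- roster$group[i][sample.int(length(i))]
        plan_b <- rebuild_plan(plan, r2, light = simple)
        lab_b <- stats::setNames(r2$group, r2$subject_id)[ids]
        if (simple || batch_svm) {
          fast_bac(as.numeric(lab_b == "T"), plan_b)
        } else {
          r <- runner(lab_b, plan_b)
          bac_from_labels(r$predictions$true_label == "T",
                          r$predictions$predicted_label == "T")
        }
      }, numeric(1))
    })
  } else if (simple || batch_svm) {
    # fixed-plan variant, batched in one compiled call
    tr_idx <- lapply(plan$folds, function(f) match(f$train_ids, ids))
    te_idx <- lapply(plan$folds, function(f) match(f$test_ids, ids))
    y01 <- as.numeric(lab == "T")
    Ymat <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(b) y01[sample.int(length(y01))],
             numeric(length(y01)))
    })
    bac_null <- if (simple) {
      as.numeric(.lpo_logistic_bac_batch(X[, 1], Ymat, tr_idx, te_idx,
                                         spec$decision_threshold))
    } else {
      in_tr <- lapply(plan$folds, function(f) {
        lapply(f$inner_folds, function(g) match(g$train_ids, ids))
      })
      in_val <- lapply(plan$folds, function(f) {
        lapply(f$inner_folds, function(g) match(g$val_ids, ids))
      })
      as.numeric(.svm_nested_bac_batch(X, Ymat, tr_idx, te_idx, in_tr,
                                       in_val, sort(spec$grid$svm_C)))
    }
  } else {
    bac_null <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        perm <- lab
        perm[] <- lab[sample.int(length(lab))]
        r <- runner(perm, plan)
        bac_from_labels(r$predictions$true_label == "T",
                        r$predictions$predicted_label == "T")
      }, numeric(1))
    })
  }
  p <- (1 + sum(bac_null >= bac_obs - 1e-12)) / (1 + n_permutations)
  structure(list(p_value = p, bac_observed = bac_obs, bac_null = bac_null,
                 n_permutations = n_permutations, result = obs),
            class = "bac_permutation")
}

#' @export
print.bac_permutation <- function(x, ...) {
  cat(sprintf("<bac_permutation: observed BAC %.3f, p = %.4g (%d permutations)>\n",
              x$bac_observed, x$p_value, x$n_permutations))
  invisible(x)
}

#' Aggregate bootstrap-replicate permutation p-values
#'
#' A configuration is declared significant when its balanced accuracy beats
#' chance (permutation p below `alpha`) in at least
#' `ceiling(min_significant_fraction * n)` of its bootstrap replicates —
#' the 3-of-5 rule at the default fraction 0.6 with five replicates.
#'
#' @param p_values permutation p-values, one per bootstrap replicate.
#' @param alpha significance level (default 0.05).
#' @param min_significant_fraction required fraction of significant
#'   replicates (default 0.6).
#' @return list with `n_significant`, `threshold` and the boolean
#'   `decision`.
#' @export
aggregate_bootstraps <- function(p_values, alpha = 0.05,
                                 min_significant_fraction = 0.6) {
  if (length(p_values) == 0) stop("empty p-value list", call. = FALSE)
  n_sig <- sum(p_values < alpha)
  thr <- ceiling(min_significant_fraction * length(p_values))
  list(n_significant = n_sig, threshold = thr, decision = n_sig >= thr)
}

#' One-tailed Wilcoxon signed-rank test of the median BAC against chance
#'
#' Exact one-sided p-value for the hypothesis that the median balanced
#' accuracy across bootstrap replicates exceeds the chance level: replicates
#' exactly at chance are dropped, absolute deviations receive midranks, and
#' the null distribution of the positive-rank sum is enumerated over all
#' 2^n sign assignments (n up to 20; beyond that the normal approximation is
#' used).
#'
#' @param bacs balanced accuracies across bootstrap replicates.
#' @param chance the chance level (default 0.5).
#' @return a `psytrans_test` with the positive-rank-sum statistic.
#' @export
wilcoxon_median_bac <- function(bacs, chance = 0.5) {
  d <- bacs - chance
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(test_result(0, 1, "wilcoxon_signed_rank",
                                 "one_sided_greater"))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= 20) {
    # generating-function DP over doubled midranks (integers)
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1) # counts[s + 1] = #assignments with sum s
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w_obs))
    p <- sum(counts[(w2 + 1):length(counts)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    sg <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p <- stats::pnorm((w_obs - mu) / sg, lower.tail = FALSE)
  }
  test_result(w_obs, p, "wilcoxon_signed_rank", "one_sided_greater")
}

#' Multimodal admission gate
#'
#' Applies the study's gate: only modalities for which the aggregate
#' decision holds are admitted to a multimodal model. With no admitted
#' modality, the returned set is empty and the attached message records that
#' no multimodal model is trained.
#'
#' @param reports list of reports, each with a boolean `decision` and a
#'   `modality` label (see [run_experiment_grid()] output).
#' @return character vector of admitted modalities (possibly empty), with
#'   attribute `message`.
#' @export
multimodal_gate <- function(reports) {
  if (length(reports) == 0) stop("at least one report required", call. = FALSE)
  admitted <- unique(unlist(lapply(reports, function(r) {
    if (isTRUE(r$decision)) r$modality else NULL
  })))
  admitted <- as.character(admitted %||% character(0))
  msg <- if (length(admitted) == 0) {
    "no modality passed the gate: no multimodal model trained"
  } else {
    sprintf("admitted: %s", paste(admitted, collapse = ", "))
  }
  structure(admitted, message = msg)
}

#' Train-versus-test overfitting diagnostic
#'
#' Mean resubstitution-minus-test balanced-accuracy gap with a bootstrap
#' percentile confidence interval, quantifying the optimism of the fitted
#' models.
#'
#' @param train_bacs,test_bacs paired balanced accuracies.
#' @param n_boot bootstrap resamples for the interval.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `mean_gap`, `ci` (two-sided percentile interval) and
#'   the per-pair `gaps`.
#' @export
overfitting_report <- function(train_bacs, test_bacs, n_boot = 2000L,
                               conf = 0.95, seed = 1L) {
  if (length(train_bacs) != length(test_bacs)) {
    stop("paired sequences of equal length required", call. = FALSE)
  }
  gaps <- train_bacs - test_bacs
  ci <- if (length(gaps) > 1) {
    with_seed(seed, {
      bm <- vapply(seq_len(n_boot), function(b) {
        mean(gaps[sample.int(length(gaps), replace = TRUE)])
      }, numeric(1))
      stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    })
  } else c(NA_real_, NA_real_)
  list(mean_gap = mean(gaps), ci = ci, gaps = gaps)
}

fmt_stat <- function(v, pct = FALSE) {
  if (pct) v <- 100 * v
  fin <- v[is.finite(v)]
  if (length(fin) == 0) return("undefined")
  sprintf("%.1f ± %.1f [%.1f, %.1f]", mean(fin),
          if (length(fin) > 1) stats::sd(fin) else 0, min(fin), max(fin))
}

#' Replicate summary table in the results-table layout
#'
#' One row per performance measure, formatted `mean +/- SD [min, max]`
#' across bootstrap replicates (SE/SP/BAC as percentages), plus the count of
#' significant replicates.
#'
#' @param reports list of `perf_report`s, one per replicate.
#' @param p_values matching permutation p-values.
#' @param alpha significance level for the replicate count.
#' @return data frame with columns `measure` and `value`.
#' @export
format_performance_table <- function(reports, p_values, alpha = 0.05) {
  get <- function(f) vapply(reports, `[[`, numeric(1), f)
  data.frame(
    measure = c("SE (%)", "SP (%)", "BAC (%)", "PLR", "NLR", "DOR",
                "Significant models"),
    value = c(fmt_stat(get("SE"), TRUE), fmt_stat(get("SP"), TRUE),
              fmt_stat(get("BAC"), TRUE), fmt_stat(get("PLR")),
              fmt_stat(get("NLR")), fmt_stat(get("DOR")),
              sprintf("%d of %d", sum(p_values < alpha), length(p_values))),
    stringsAsFactors = FALSE)
}
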