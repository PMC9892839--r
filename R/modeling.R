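#' Classifier specification
#'
#' Three classifier families are supported, matching the study design:
#' a linear-kernel SVM tuned over the cost grid (used for the sMRI feature
#' families), a plain logistic regression (single-score predictors), and an
#' elastic-net logistic regression tuned over the mixing/penalty grid
#' (SNP, eQTL and environmental feature sets, via glmnet).
#'
#' @param kind `"linear_svm"`, `"logistic"` or `"elastic_net"`.
#' @param grid hyperparameter grids, see [default_grids()].
#' @param decision_threshold probability threshold for the probabilistic
#'   models (default 0.5). The SVM assigns by the sign of the decision
#'   value.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("linear_svm", "logistic", "elastic_net"),
                            grid = default_grids(),
                            decision_threshold = 0.5) {
  kind <- match.arg(kind)
  structure(list(kind = kind, grid = grid,
                 decision_threshold = decision_threshold),
            class = "classifier_spec")
}

#' Per-fold feature preparation recipe
#'
#' Declares, up front, the preparation fitted inside each training
#' partition: robust PCA (voxel families), min-max scaling (always fitted on
#' training rows only), and greedy forward selection (regional families).
#' TIV normalisation is a per-subject operation and is applied ahead of the
#' engine via [scale_to_tiv()].
#'
#' @param minmax scale each feature to \[0, 1\] with training statistics.
#' @param pca apply [robust_pca_reduce()] before scaling.
#' @param forward_select apply [greedy_forward_select()] on each outer
#'   training set.
#' @param variance_target,retain_fraction,pca_center parameters passed
#'   through to the respective operations.
#' @return a `prep_recipe`.
#' @export
prep_recipe <- function(minmax = TRUE, pca = FALSE, forward_select = FALSE,
                        variance_target = 0.8, retain_fraction = 0.1,
                        pca_center = "median") {
  structure(list(minmax = isTRUE(minmax), pca = isTRUE(pca),
                 forward_select = isTRUE(forward_select),
                 variance_target = variance_target,
                 retain_fraction = retain_fraction,
                 pca_center = pca_center),
            class = "prep_recipe")
}

# Balanced accuracy from logical truth/prediction (positive class = TRUE).
# When one class is absent (possible in tiny validation folds) the available
# rate is used alone.
bac_from_labels <- function(truth_T, pred_T) {
  se <- if (any(truth_T)) mean(pred_T[truth_T]) else NA_real_
  sp <- if (any(!truth_T)) mean(!pred_T[!truth_T]) else NA_real_
  mean(c(se, sp), na.rm = TRUE)
}

feature_matrix <- function(features) {
  if (inherits(features, "modality_features")) features$values else features
}

normalize_labels <- function(labels, ids) {
  lab <- as.character(labels)
  names(lab) <- names(labels)
  if (is.null(names(lab))) stop("labels must be named by subject id",
                                call. = FALSE)
  if (!all(ids %in% names(lab))) {
    stop("labels missing for some subjects", call. = FALSE)
  }
  if (!all(lab %in% c("T", "NT"))) {
    stop("labels must be 'T' or 'NT'", call. = FALSE)
  }
  lab[ids]
}

apply_prep <- function(prep, Xtr, Xte) {
  if (prep$pca) {
    r <- robust_pca_reduce(Xtr, Xte, variance_target = prep$variance_target,
                           n_inner = nrow(Xtr), center = prep$pca_center)
    Xtr <- r$train
    Xte <- r$test
  }
  if (prep$minmax) {
    m <- minmax_fit_apply(Xtr, Xte)
    Xtr <- m$train
    Xte <- m$test
  }
  list(train = Xtr, test = Xte)
}

svm_decide <- function(Xtr, ytr, Xte, C, seed = 0L, max_pass = 150L,
                       tol = 0.05) {
  .svm_dcd_grid(Xtr, ytr, Xte, C, max_pass, tol, seed)
}

tune_svm <- function(grid_C, fold, Xtr, ytr_pm, prep) {
  acc <- matrix(NA_real_, length(fold$inner_folds), length(grid_C))
  for (i in seq_along(fold$inner_folds)) {
    g <- fold$inner_folds[[i]]
    itr <- match(g$train_ids, rownames(Xtr))
    ival <- match(g$val_ids, rownames(Xtr))
    pp <- apply_prep(prep, Xtr[itr, , drop = FALSE],
                     Xtr[ival, , drop = FALSE])
    dec <- svm_decide(pp$train, ytr_pm[itr], pp$test, grid_C)$test_decision
    acc[i, ] <- vapply(seq_along(grid_C), function(c) {
      bac_from_labels(ytr_pm[ival] > 0, dec[, c] > 0)
    }, numeric(1))
  }
  # first maximum = smallest C on ties (grid is ascending in C)
  list(C = grid_C[which.max(colMeans(acc))])
}

tune_enet <- function(grid, fold, Xtr, yfac, prep) {
  alphas <- grid$enet_l1
  lams <- sort(grid$enet_lambda, decreasing = TRUE)
  acc <- array(0, c(length(alphas), length(lams)))
  usable <- Filter(function(g) {
    length(unique(yfac[match(g$train_ids, rownames(Xtr))])) == 2
  }, fold$inner_folds)
  if (length(usable) == 0) {
    stop("every inner training fold contains a single class", call. = FALSE)
  }
  nfold <- length(usable)
  for (g in usable) {
    itr <- match(g$train_ids, rownames(Xtr))
    ival <- match(g$val_ids, rownames(Xtr))
    pp <- apply_prep(prep, Xtr[itr, , drop = FALSE],
                     Xtr[ival, , drop = FALSE])
    truth <- yfac[itr]
    val_T <- yfac[ival] == "T"
    for (a in seq_along(alphas)) {
      fit <- glmnet::glmnet(pp$train, truth, family = "binomial",
                            alpha = alphas[a], lambda = lams,
                            standardize = FALSE)
      pr <- stats::predict(fit, newx = pp$test, s = lams, type = "response")
      acc[a, ] <- acc[a, ] + vapply(seq_along(lams), function(l) {
        bac_from_labels(val_T, pr[, l] > 0.5)
      }, numeric(1)) / nfold
    }
  }
  # column-major scan over (alpha asc) x (lambda desc): first maximum is the
  # largest lambda, then the smallest l1 mixing, on ties
  best <- which.max(acc)
  a <- (best - 1L) %% length(alphas) + 1L
  l <- (best - 1L) %/% length(alphas) + 1L
  list(l1 = alphas[a], lambda = lams[l], lambda_path = lams)
}

#' Fit one outer fold of the nested cross-validation
#'
#' Runs the full inner cycle on the fold's training partition: per-fold
#' preparation (PCA / min-max, fitted on inner-training rows only), grid
#' evaluation by mean inner-fold balanced accuracy, deterministic
#' tie-breaking (smallest cost; largest penalty then smallest mixing for the
#' elastic net), refit of the winning configuration on the full outer
#' training set, and prediction of the outer test set. The resubstitution
#' (outer-train) balanced accuracy is recorded for the overfitting
#' diagnostic. Greedy forward selection, when enabled, is fitted on the
#' outer-training partition via its inner folds before tuning.
#'
#' @param spec a [classifier_spec()].
#' @param fold one element of a [cv_plans] plan's `folds`.
#' @param features numeric matrix (rows named by subject id) or
#'   `modality_features`.
#' @param labels `T`/`NT` labels named by subject id.
#' @param prep a [prep_recipe()].
#' @return list with `predictions` (one row per outer-test subject:
#'   `subject_id`, `outer_index`, `true_label`, `predicted_label`,
#'   `decision_value`), `train_bac`, and `chosen` hyperparameters.
#' @export
fit_predict_fold <- function(spec, fold, features, labels,
                             prep = prep_recipe()) {
  X <- feature_matrix(features)
  lab <- normalize_labels(labels, rownames(X))
  Xtr <- X[fold$train_ids, , drop = FALSE]
  Xte <- X[fold$test_ids, , drop = FALSE]
  ytr <- lab[fold$train_ids]
  if (length(unique(ytr)) < 2) {
    stop("single-class outer training set", call. = FALSE)
  }
  if (prep$forward_select) {
    inner_idx <- lapply(fold$inner_folds, function(g) {
      list(train = match(g$train_ids, fold$train_ids),
           val = match(g$val_ids, fold$train_ids))
    })
    sel <- greedy_forward_select(Xtr, ytr, inner_idx,
                                 retain_fraction = prep$retain_fraction)
    Xtr <- Xtr[, sel, drop = FALSE]
    Xte <- Xte[, sel, drop = FALSE]
    prep <- prep_recipe(minmax = prep$minmax, pca = prep$pca,
                        forward_select = FALSE,
                        variance_target = prep$variance_target,
                        retain_fraction = prep$retain_fraction,
                        pca_center = prep$pca_center)
  }
  ytr_pm <- ifelse(ytr == "T", 1, -1)
  yfac <- factor(ytr, levels = c("NT", "T"))
  if (spec$kind == "linear_svm") {
    chosen <- tune_svm(spec$grid$svm_C, fold, Xtr, ytr_pm, prep)
    pp <- apply_prep(prep, Xtr, Xte)
    sv <- svm_decide(pp$train, ytr_pm, pp$test, chosen$C)
    dec_te <- sv$test_decision[, 1]
    dec_tr <- sv$train_decision[, 1]
    pred_te <- dec_te > 0
    pred_tr <- dec_tr > 0
  } else if (spec$kind == "elastic_net") {
    chosen <- tune_enet(spec$grid, fold, Xtr, yfac, prep)
    pp <- apply_prep(prep, Xtr, Xte)
    fit <- glmnet::glmnet(pp$train, yfac, family = "binomial",
                          alpha = chosen$l1, lambda = chosen$lambda_path,
                          standardize = FALSE)
    dec_te <- stats::predict(fit, newx = pp$test, s = chosen$lambda,
                             type = "response")[, 1]
    dec_tr <- stats::predict(fit, newx = pp$train, s = chosen$lambda,
                             type = "response")[, 1]
    chosen$lambda_path <- NULL
    pred_te <- dec_te > spec$decision_threshold
    pred_tr <- dec_tr > spec$decision_threshold
  } else { # logistic: no hyperparameters
    chosen <- list()
    pp <- apply_prep(prep, Xtr, Xte)
    beta <- fit_logistic(pp$train, yfac == "T")
    dec_te <- stats::plogis(cbind(1, pp$test[, beta$keep, drop = FALSE])
                            %*% beta$coef)[, 1]
    dec_tr <- stats::plogis(cbind(1, pp$train[, beta$keep, drop = FALSE])
                            %*% beta$coef)[, 1]
    pred_te <- dec_te > spec$decision_threshold
    pred_tr <- dec_tr > spec$decision_threshold
  }
  list(
    predictions = data.frame(
      subject_id = fold$test_ids,
      outer_index = fold$outer_index,
      true_label = lab[fold$test_ids],
      predicted_label = ifelse(pred_te, "T", "NT"),
      decision_value = as.numeric(dec_te),
      stringsAsFactors = FALSE),
    train_bac = bac_from_labels(ytr == "T", pred_tr),
    chosen = chosen
  )
}

# Logistic fit with constant columns dropped (keeps the intercept-only
# degenerate case well defined).
fit_logistic <- function(X, yT) {
  keep <- which(apply(X, 2, function(v) stats::sd(v) > 0))
  coef <- .logistic_irls(cbind(1, X[, keep, drop = FALSE]), as.numeric(yT))
  list(coef = coef, keep = keep)
}

#' Run a full nested cross-validation
#'
#' Applies [fit_predict_fold()] to every outer fold of the plan and
#' concatenates the out-of-fold predictions: exactly one prediction per
#' subject.
#'
#' @inheritParams fit_predict_fold
#' @param plan a `cv_plan` covering exactly the subjects of `features`.
#' @return a `nested_cv_result`: list with `predictions`, per-fold
#'   `train_bac`, per-fold `chosen` hyperparameters and the plan `scheme`.
#' @export
run_nested_cv <- function(spec, plan, features, labels,
                          prep = prep_recipe()) {
  X <- feature_matrix(features)
  plan_ids <- sort(unique(unlist(lapply(plan$folds, `[[`, "test_ids"))))
  if (!setequal(plan_ids, rownames(X))) {
    stop("plan and features cover different subjects", call. = FALSE)
  }
  fits <- lapply(plan$folds, function(fold) {
    fit_predict_fold(spec, fold, features, labels, prep)
  })
  structure(list(
    predictions = do.call(rbind, lapply(fits, `[[`, "predictions")),
    train_bac = vapply(fits, `[[`, numeric(1), "train_bac"),
    chosen = lapply(fits, `[[`, "chosen"),
    scheme = plan$scheme),
    class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  bac <- bac_from_labels(x$predictions$true_label == "T",
                         x$predictions$predicted_label == "T")
  cat(sprintf("<nested_cv_result %s: %d predictions, outer BAC %.3f, mean train BAC %.3f>\n",
              x$scheme, nrow(x$predictions), bac, mean(x$train_bac)))
  invisible(x)
}

#' Simple leave-one-pair-out logistic regression on a single score
#'
#' The single-feature path used for the polygenic and environmental risk
#' scores: no inner cycle and no hyperparameters. For each outer pair, a
#' logistic regression is fitted on the remaining subjects and the held-out
#' pair is classified by thresholding the fitted probability at 0.5. A
#' constant training score degenerates to the intercept-only fit, i.e. the
#' training majority class (ties predict NT).
#'
#' @param x single-column numeric matrix (rows named by subject id) or a
#'   named numeric vector.
#' @param labels `T`/`NT` labels named by subject id.
#' @param plan a `cv_plan` (LPO in the study design).
#' @param decision_threshold probability threshold (default 0.5).
#' @return a `nested_cv_result`.
#' @export
fit_simple_lpo_logistic <- function(x, labels, plan,
                                    decision_threshold = 0.5) {
  if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "score"))
  }
  if (ncol(x) != 1L) {
    stop("the simple logistic path takes exactly one feature", call. = FALSE)
  }
  lab <- normalize_labels(labels, rownames(x))
  xs <- x[, 1]
  names(xs) <- rownames(x)
  preds <- lapply(plan$folds, function(fold) {
    xtr <- xs[fold$train_ids]
    ytr <- lab[fold$train_ids] == "T"
    if (stats::sd(xtr) > 0) {
      beta <- .logistic_irls(cbind(1, xtr), as.numeric(ytr))
      eta_te <- beta[1] + beta[2] * xs[fold$test_ids]
    } else {
      p <- mean(ytr)
      b0 <- stats::qlogis(min(max(p, 1e-12), 1 - 1e-12))
      eta_te <- rep(b0, length(fold$test_ids))
    }
    prob <- stats::plogis(eta_te)
    data.frame(subject_id = fold$test_ids,
               outer_index = fold$outer_index,
               true_label = lab[fold$test_ids],
               predicted_label = ifelse(prob > decision_threshold, "T", "NT"),
               decision_value = as.numeric(prob),
               stringsAsFactors = FALSE)
  })
  structure(list(predictions = do.call(rbind, preds),
                 train_bac = rep(NA_real_, length(plan$folds)),
                 chosen = vector("list", length(plan$folds)),
                 scheme = plan$scheme),
            class = "nested_cv_result")
}

#' Write out-of-fold predictions as TSV
#'
#' @param result a `nested_cv_result`.
#' @param path output TSV path.
#' @export
write_predictions_tsv <- function(result, path) {
  utils::write.table(result$predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
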