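gauss_setup <- function(n = 40, p = 10, d = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("G%03d", 1:n)
  lab <- stats::setNames(rep(c("T", "NT"), each = n / 2), ids)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(ids, paste0("f", 1:p)))
  X[lab == "T", ] <- X[lab == "T", ] + d
  roster <- data.frame(subject_id = ids, group = unname(lab),
                       protocol = rep(c("P1", "P2"), n / 2),
                       stringsAsFactors = FALSE)
  list(X = X, labels = lab, roster = roster)
}

test_that("well-separated classes reach perfect outer balanced accuracy", {
  s <- gauss_setup(n = 40, p = 10, d = 4, seed = 1)
  plan <- build_lpo_plan(s$roster, seed = 2)
  res <- run_nested_cv(classifier_spec("linear_svm"), plan, s$X, s$labels)
  expect_equal(observed_bac(res), 1.0)
  expect_equal(nrow(res$predictions), 40)
  # brute-force linear-discriminant oracle confirms separability
  mu_t <- colMeans(s$X[s$labels == "T", ])
  mu_n <- colMeans(s$X[s$labels == "NT", ])
  w <- mu_t - mu_n
  proj <- s$X %*% w
  cut <- mean(c(mean(proj[s$labels == "T"]), mean(proj[s$labels == "NT"])))
  expect_equal(mean((proj > cut) == (s$labels == "T")), 1.0)
})

test_that("pure-noise features give chance-level accuracy on average", {
  bacs <- vapply(1:8, function(i) {
    s <- gauss_setup(n = 32, p = 8, d = 0, seed = 10 + i)
    plan <- build_lpo_plan(s$roster, seed = 20 + i)
    observed_bac(run_nested_cv(classifier_spec("linear_svm"), plan,
                               s$X, s$labels))
  }, numeric(1))
  expect_gt(mean(bacs), 0.35)
  expect_lt(mean(bacs), 0.65)
})

test_that("nested CV is deterministic and covers each subject once", {
  s <- gauss_setup(n = 24, p = 6, d = 1, seed = 3)
  plan <- build_lpo_plan(s$roster, seed = 4)
  r1 <- run_nested_cv(classifier_spec("linear_svm"), plan, s$X, s$labels)
  r2 <- run_nested_cv(classifier_spec("linear_svm"), plan, s$X, s$labels)
  expect_identical(r1, r2)
  expect_setequal(r1$predictions$subject_id, rownames(s$X))
  expect_false(anyDuplicated(r1$predictions$subject_id) > 0)
  # chosen costs always come from the grid
  expect_true(all(unlist(r1$chosen) %in% default_grids()$svm_C))
  # dropping a fold drops exactly its subjects
  plan2 <- plan
  dropped <- plan2$folds[[1]]$test_ids
  plan2$folds <- plan2$folds[-1]
  preds <- do.call(rbind, lapply(plan2$folds, function(f) {
    fit_predict_fold(classifier_spec("linear_svm"), f, s$X,
                     s$labels)$predictions
  }))
  expect_false(any(dropped %in% preds$subject_id))
})

test_that("no preparation step leaks outer-test information", {
  # canary: a feature that equals the label on outer-test rows only. With
  # leak-free preparation the training rows of that feature are pure noise,
  # so any single run can be lifted or sunk by the random sign of its
  # trained weight, but the average over seeds must stay at chance; a
  # preparation step that saw the test rows would lift it systematically.
  bacs <- vapply(1:10, function(i) {
    s <- gauss_setup(n = 32, p = 6, d = 0, seed = 50 + i)
    plan <- build_lpo_plan(s$roster, seed = 60 + i)
    preds <- do.call(rbind, lapply(plan$folds, function(f) {
      canary <- s$X
      canary[f$test_ids, 1] <- ifelse(s$labels[f$test_ids] == "T", 10, -10)
      fit_predict_fold(classifier_spec("linear_svm"), f, canary,
                       s$labels)$predictions
    }))
    mean(c(mean(preds$predicted_label[preds$true_label == "T"] == "T"),
           mean(preds$predicted_label[preds$true_label == "NT"] == "NT")))
  }, numeric(1))
  expect_gt(mean(bacs), 0.3)
  expect_lt(mean(bacs), 0.7)
})

test_that("the compiled linear SVM agrees with a reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  cors <- mismatches <- numeric(20)
  for (i in 1:20) {
    n <- 40; p <- 10
    X <- matrix(stats::runif(n * p), n, p)
    y <- rep(c(1, -1), n / 2)
    X[y == 1, 1:3] <- X[y == 1, 1:3] + 0.5
    Xte <- matrix(stats::runif(30 * p), 30, p)
    C <- sample(c(0.125, 1, 8), 1)
    d1 <- psytrans:::svm_decide(X, y, Xte, C, max_pass = 2000,
                                tol = 1e-4)$test_decision[, 1]
    m <- e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
    dv <- attr(stats::predict(m, Xte, decision.values = TRUE),
               "decision.values")
    d2 <- dv[, 1] * (if (colnames(dv) == "1/-1") 1 else -1)
    cors[i] <- stats::cor(d1, d2)
    mismatches[i] <- mean(sign(d1) != sign(d2))
  }
  expect_gt(mean(cors), 0.98)
  expect_lt(mean(mismatches), 0.05)
})

test_that("the compiled logistic solver matches glm coefficients", {
  set.seed(9)
  for (i in 1:10) {
    n <- 60
    X <- cbind(1, matrix(stats::rnorm(n * 3), n, 3))
    beta <- c(-0.3, 0.8, -0.5, 0.2)
    y <- as.numeric(stats::runif(n) < stats::plogis(X %*% beta))
    if (length(unique(y)) < 2) next
    b_ours <- psytrans:::.logistic_irls(X, y)
    b_glm <- stats::glm.fit(X, y, family = stats::binomial())$coefficients
    expect_equal(as.numeric(b_ours), unname(b_glm), tolerance = 1e-6)
  }
})

test_that("elastic net with no mixing and tiny penalty approaches plain glm", {
  set.seed(10)
  n <- 300
  ids <- sprintf("E%03d", 1:n)
  X <- matrix(stats::rnorm(n * 5), n, 5,
              dimnames = list(ids, paste0("f", 1:5)))
  eta <- X %*% c(1, -0.7, 0.4, 0, 0.2)
  lab <- stats::setNames(
    ifelse(stats::runif(n) < stats::plogis(eta), "T", "NT"), ids)
  fit_ref <- stats::glm.fit(cbind(1, X), lab == "T",
                            family = stats::binomial())$coefficients
  fit_en <- glmnet::glmnet(X, factor(lab, levels = c("NT", "T")),
                           family = "binomial", alpha = 0,
                           lambda = c(0.1, 0.01, 1e-5), standardize = FALSE)
  co <- as.numeric(stats::coef(fit_en, s = 1e-5))
  expect_equal(co, unname(fit_ref), tolerance = 1e-2)
})

test_that("elastic-net tuning selects the tie-broken grid maximum", {
  # independent re-derivation of the mean inner-fold BAC surface, then the
  # declared tie-break: largest penalty first, smallest mixing second
  set.seed(11)
  n <- 16
  ids <- sprintf("N%02d", 1:n)
  X <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(ids, paste0("f", 1:4)))
  lab <- stats::setNames(rep(c("T", "NT"), n / 2), ids)
  fold <- list(outer_index = 1, test_ids = ids[1:2], train_ids = ids[3:16],
               inner_folds = list(
                 list(train_ids = ids[3:9], val_ids = ids[10:16]),
                 list(train_ids = ids[10:16], val_ids = ids[3:9])))
  res <- suppressWarnings(
    fit_predict_fold(classifier_spec("elastic_net"), fold, X, lab,
                     prep_recipe(minmax = FALSE)))
  g <- default_grids()
  lams <- sort(g$enet_lambda, decreasing = TRUE)
  yfac <- factor(lab, levels = c("NT", "T"))
  acc <- matrix(0, length(g$enet_l1), length(lams))
  for (f in fold$inner_folds) {
    for (a in seq_along(g$enet_l1)) {
      fit <- suppressWarnings(
        glmnet::glmnet(X[f$train_ids, ], yfac[match(f$train_ids, ids)],
                       family = "binomial", alpha = g$enet_l1[a],
                       lambda = lams, standardize = FALSE))
      pr <- stats::predict(fit, newx = X[f$val_ids, ], s = lams,
                           type = "response")
      truth <- yfac[match(f$val_ids, ids)] == "T"
      acc[a, ] <- acc[a, ] + vapply(seq_along(lams), function(l) {
        mean(c(mean(pr[truth, l] > 0.5), mean(pr[!truth, l] <= 0.5)))
      }, numeric(1))
    }
  }
  best <- which.max(acc) # column-major: lambda desc outer, l1 asc inner
  exp_l1 <- g$enet_l1[(best - 1) %% length(g$enet_l1) + 1]
  exp_lam <- lams[(best - 1) %/% length(g$enet_l1) + 1]
  expect_equal(res$chosen$l1, exp_l1)
  expect_equal(res$chosen$lambda, exp_lam)
})

test_that("simple LPO logistic path follows the single-score contract", {
  n <- 46
  ids <- sprintf("L%03d", 1:n)
  lab <- stats::setNames(rep(c("T", "NT"), n / 2), ids)
  roster <- data.frame(subject_id = ids, group = unname(lab), protocol = "P1",
                       stringsAsFactors = FALSE)
  plan <- build_lpo_plan(roster, seed = 13)
  expect_length(plan$folds, 23)
  # perfectly separating score
  x <- matrix(ifelse(lab == "T", 1, 0) + 0, ncol = 1,
              dimnames = list(ids, "score"))
  res <- fit_simple_lpo_logistic(x, lab, plan)
  expect_equal(nrow(res$predictions), 46)
  expect_equal(observed_bac(res), 1.0)
  # constant score: intercept-only fit; balanced training gives P(T) = 0.5,
  # not above threshold, so everyone is called NT and BAC is 0.5
  xc <- matrix(rep(2.5, n), ncol = 1, dimnames = list(ids, "score"))
  resc <- fit_simple_lpo_logistic(xc, lab, plan)
  expect_true(all(resc$predictions$predicted_label == "NT"))
  expect_equal(observed_bac(resc), 0.5)
  expect_equal(unique(resc$predictions$decision_value), 0.5)
  expect_error(fit_simple_lpo_logistic(cbind(x, x), lab, plan),
               "exactly one feature")
  # predictions round-trip through the TSV writer
  tmp <- file.path(tempdir(), "preds.tsv")
  write_predictions_tsv(res, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(nrow(back), 46)
  expect_equal(back$predicted_label, res$predictions$predicted_label)
  unlink(tmp)
})

test_that("single-class outer training sets are rejected", {
  s <- gauss_setup(n = 12, p = 3, d = 0, seed = 14)
  plan <- build_lpo_plan(s$roster, seed = 15)
  lab_bad <- stats::setNames(rep("T", 12), rownames(s$X))
  lab_bad[plan$folds[[1]]$test_ids] <- c("T", "NT")
  expect_error(
    fit_predict_fold(classifier_spec("linear_svm"), plan$folds[[1]],
                     s$X, lab_bad),
    "single-class")
})
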