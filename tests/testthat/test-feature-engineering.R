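roi_fixture <- function(n = 12, p = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n * p, 10), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("f%02d", 1:p)))
  tiv <- stats::setNames(stats::runif(n, 1300, 1700), rownames(v))
  modality_features(v, "ROIGM", tiv = tiv)
}

test_that("TIV scaling divides by TIV once and only once", {
  f <- roi_fixture()
  s <- scale_to_tiv(f)
  expect_equal(s$values, f$values / f$tiv)
  expect_null(s$tiv)
  expect_error(scale_to_tiv(s), "consumed")
  z <- f; z$values[] <- 0
  expect_true(all(scale_to_tiv(z)$values == 0))
  surf <- modality_features(f$values, "ROISurface", tiv = f$tiv)
  expect_error(scale_to_tiv(surf), "regional volume")
  expect_equal(scale_to_tiv(f)$values[1, 1],
               unname(f$values[1, 1] / f$tiv[1]))
})

test_that("min-max scaling is train-fitted, unclamped, constant-safe", {
  tr <- matrix(c(10, 20, 5, 5), 2, dimnames = list(NULL, c("a", "b")))
  te <- matrix(c(15, 25, 7, 5), 2, dimnames = list(NULL, c("a", "b")))
  m <- minmax_fit_apply(tr, te)
  expect_equal(m$train[, "a"], c(0, 1))
  expect_equal(m$test[, "a"], c(0.5, 1.5)) # outside the range, unclamped
  expect_equal(m$train[, "b"], c(0, 0))    # constant feature maps to 0
  expect_equal(m$test[, "b"], c(0, 0))
  expect_error(minmax_fit_apply(tr, te[, c("b", "a")]), "names differ")
  # training data itself always lands exactly in [0, 1] with both ends hit
  set.seed(2)
  X <- matrix(stats::rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  s <- minmax_fit_apply(X)$train
  expect_equal(unname(apply(s, 2, min)), rep(0, 10))
  expect_equal(unname(apply(s, 2, max)), rep(1, 10))
})

test_that("robust PCA honours the variance target and the n/2 cap", {
  # rank-1 structure: a single component suffices
  set.seed(3)
  u <- stats::rnorm(30)
  X1 <- outer(u, stats::rnorm(8)) + matrix(stats::rnorm(240, sd = 1e-4), 30)
  colnames(X1) <- paste0("v", 1:8)
  r1 <- robust_pca_reduce(X1, variance_target = 0.8)
  expect_equal(r1$model$n_components, 1)
  # cap binds before the variance target on isotropic noise
  set.seed(4)
  X2 <- matrix(stats::rnorm(20 * 100), 20, 100,
               dimnames = list(NULL, paste0("v", 1:100)))
  r2 <- robust_pca_reduce(X2, variance_target = 0.8, n_inner = 20)
  expect_equal(r2$model$component_cap, 10)
  expect_equal(r2$model$n_components, 10)
  expect_lt(max(r2$model$explained), 0.8)
  expect_equal(robust_pca_reduce(X2, n_inner = 36)$model$component_cap, 18)
  # loadings orthonormal
  L <- r2$model$components
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(robust_pca_reduce(X2[1, , drop = FALSE]), "2 training")
})

test_that("robust PCA projects test rows with training statistics only", {
  set.seed(5)
  X <- matrix(stats::rnorm(25 * 12), 25, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  Xte <- matrix(stats::rnorm(5 * 12), 5, 12,
                dimnames = list(NULL, paste0("v", 1:12)))
  r <- robust_pca_reduce(X, Xte, variance_target = 1, n_inner = 25)
  m <- r$model
  z <- sweep(sweep(Xte[, names(m$centers)], 2, m$centers), 2, m$scales, "/")
  expect_equal(unname(r$test), unname(z %*% m$components))
  # reconstruction error is non-increasing in the component count
  zt <- sweep(sweep(X, 2, m$centers), 2, m$scales, "/")
  errs <- vapply(seq_len(m$n_components), function(k) {
    Lk <- m$components[, 1:k, drop = FALSE]
    sum((zt - zt %*% Lk %*% t(Lk))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  # zero-MAD features are dropped, not propagated
  Xc <- cbind(X, const = 5)
  rc <- robust_pca_reduce(Xc, variance_target = 0.8)
  expect_false("const" %in% rownames(rc$model$components))
  # the reduction model serialises with its loadings intact
  tmp <- file.path(tempdir(), "reduction.json")
  write_reduction_model(r$model, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$n_components, r$model$n_components)
  expect_equal(unname(unlist(back$loadings[[1]])),
               unname(r$model$components[, 1]), tolerance = 1e-12)
  unlink(tmp)
})

test_that("forward selection returns the deterministic retained count", {
  set.seed(6)
  n <- 24
  lab <- rep(c("T", "NT"), each = n / 2)
  folds <- lapply(1:3, function(f) {
    val <- c(seq(f, n / 2, by = 3), n / 2 + seq(f, n / 2, by = 3))
    list(train = setdiff(seq_len(n), val), val = val)
  })
  X64 <- matrix(stats::rnorm(n * 64), n, 64,
                dimnames = list(NULL, sprintf("r%03d", 1:64)))
  sel <- greedy_forward_select(X64, lab, folds)
  expect_length(sel, 6) # 10% of 64, floored
  X272 <- matrix(stats::rnorm(n * 272), n, 272,
                 dimnames = list(NULL, sprintf("r%03d", 1:272)))
  expect_length(greedy_forward_select(X272, lab, folds), 27)
  X5 <- X64[, 1:5]
  expect_length(greedy_forward_select(X5, lab, folds), 1) # minimum of one
})

test_that("forward selection finds a separating feature first", {
  set.seed(7)
  n <- 24
  lab <- rep(c("T", "NT"), each = n / 2)
  X <- matrix(stats::rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  X[lab == "T", 13] <- X[lab == "T", 13] + 10 # feature 13 separates alone
  folds <- lapply(1:3, function(f) {
    val <- c(seq(f, n / 2, by = 3), n / 2 + seq(f, n / 2, by = 3))
    list(train = setdiff(seq_len(n), val), val = val)
  })
  sel <- greedy_forward_select(X, lab, folds)
  expect_equal(sel[1], "f13")
  # brute-force oracle: feature 13 has the best single-feature inner BAC
  single_bac <- vapply(seq_len(20), function(j) {
    mean(vapply(folds, function(fo) {
      m <- minmax_fit_apply(X[fo$train, j, drop = FALSE],
                            X[fo$val, j, drop = FALSE])
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, m$train), lab[fo$train] == "T",
                       family = stats::binomial()))
      pr <- stats::plogis(cbind(1, m$test) %*% fit$coefficients)
      mean(c(mean(pr[lab[fo$val] == "T"] > 0.5),
             mean(pr[lab[fo$val] == "NT"] <= 0.5)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(which.max(single_bac), 13)
  # single-class inner training folds are rejected
  bad <- list(list(train = which(lab == "T"), val = which(lab == "NT")))
  expect_error(greedy_forward_select(X, lab, bad), "single class")
})
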