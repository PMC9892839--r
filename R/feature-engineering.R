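#' Normalise regional volumes by total intracranial volume
#'
#' Divides each regional gray- or white-matter volume by the subject's total
#' intracranial volume (TIV) and consumes the TIV column; a second call on
#' the result is an error. This is a per-subject operation fitted to nothing,
#' so it may be applied once, ahead of any train/test split.
#'
#' @param features a `modality_features` of family `ROIGM` or `ROIWM` with
#'   TIV present.
#' @return the normalised `modality_features` (TIV dropped).
#' @export
scale_to_tiv <- function(features) {
  stopifnot(inherits(features, "modality_features"))
  if (!features$family %in% c("ROIGM", "ROIWM")) {
    stop("TIV scaling applies to regional volume families (ROIGM, ROIWM)",
         call. = FALSE)
  }
  if (is.null(features$tiv)) {
    stop("TIV absent (already consumed by a previous scaling?)", call. = FALSE)
  }
  if (any(features$tiv <= 0)) stop("TIV must be positive", call. = FALSE)
  out <- features
  out$values <- features$values / features$tiv
  out$tiv <- NULL
  out
}

#' Min-max scaling fitted on training rows only
#'
#' Scales each feature to \[0, 1\] using the training minimum and maximum.
#' Test values falling outside the training range are *not* clamped (they
#' map linearly outside \[0, 1\]); a constant training feature maps to 0
#' everywhere.
#'
#' @param train,test numeric matrices with identical column names (`test`
#'   may be `NULL`).
#' @return list with scaled `train` and `test`.
#' @export
minmax_fit_apply <- function(train, test = NULL) {
  stopifnot(is.matrix(train), nrow(train) >= 1)
  if (!is.null(test) && !identical(colnames(train), colnames(test))) {
    stop("train and test feature names differ", call. = FALSE)
  }
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rg <- hi - lo
  const <- rg == 0
  rg[const] <- 1
  sc <- function(m) {
    out <- sweep(sweep(m, 2, lo, "-"), 2, rg, "/")
    if (any(const)) out[, const] <- 0
    out
  }
  list(train = sc(train), test = if (is.null(test)) NULL else sc(test))
}

#' Robust PCA reduction for voxel-based features
#'
#' Centers each feature by its training median and scales by its MAD
#' (features with zero MAD are dropped), then eigendecomposes the training
#' covariance. The smallest number of components whose cumulative explained
#' variance reaches `variance_target` is retained, truncated at
#' `floor(n_inner / 2)` components (the sample-size cap); the minimum is one
#' component. Test rows are projected with the training loadings. A
#' `center = "mean"` switch gives classic mean/SD PCA.
#'
#' @param train,test numeric matrices (`test` may be `NULL`).
#' @param variance_target cumulative explained-variance target (default 0.8).
#' @param n_inner the training sample size that caps the component count
#'   (defaults to `nrow(train)`).
#' @param center `"median"` (robust, the default) or `"mean"`.
#' @return list with `train`, `test` (score matrices) and `model`
#'   (a `reduction_model` with centers, scales, loadings and the retained
#'   component count).
#' @export
robust_pca_reduce <- function(train, test = NULL, variance_target = 0.8,
                              n_inner = nrow(train),
                              center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(is.matrix(train))
  if (nrow(train) < 2) stop("need at least 2 training subjects", call. = FALSE)
  if (!is.null(test) && !identical(colnames(train), colnames(test))) {
    stop("train and test feature names differ", call. = FALSE)
  }
  if (center == "median") {
    ctr <- apply(train, 2, stats::median)
    scl <- apply(train, 2, stats::mad)
  } else {
    ctr <- colMeans(train)
    scl <- apply(train, 2, stats::sd)
  }
  keep <- scl > 0
  if (!any(keep)) stop("all features have zero spread", call. = FALSE)
  std <- function(m) sweep(sweep(m[, keep, drop = FALSE], 2, ctr[keep], "-"),
                           2, scl[keep], "/")
  ztr <- std(train)
  # eigendecomposition via SVD of the centered-scaled training matrix
  sv <- svd(ztr)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-12
  ev <- ev[pos]
  cum <- cumsum(ev) / sum(ev)
  cap <- max(1L, floor(n_inner / 2))
  k <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  k <- min(k, cap, length(ev))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(train)[keep]
  colnames(loadings) <- sprintf("PC%02d", seq_len(k))
  model <- structure(list(centers = ctr[keep], scales = scl[keep],
                          components = loadings, n_components = k,
                          variance_target = variance_target,
                          component_cap = cap,
                          explained = cum[seq_len(k)]),
                     class = "reduction_model")
  proj <- function(m) {
    s <- std(m) %*% loadings
    rownames(s) <- rownames(m)
    s
  }
  list(train = proj(train), test = if (is.null(test)) NULL else proj(test),
       model = model)
}

#' Serialise a reduction model to JSON
#'
#' @param model a `reduction_model`.
#' @param path output path.
#' @export
write_reduction_model <- function(model, path) {
  stopifnot(inherits(model, "reduction_model"))
  jsonlite::write_json(
    list(centers = as.list(model$centers), scales = as.list(model$scales),
         loadings = apply(model$components, 2, as.list),
         n_components = model$n_components,
         variance_target = model$variance_target,
         component_cap = model$component_cap),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Greedy forward feature selection under the inner cross-validation cycle
#'
#' Stepwise wrapper selection for the regional feature families: starting
#' from the empty set, each step adds the candidate feature that maximises
#' the mean inner-fold balanced accuracy of a linear SVM trained on the
#' current set plus the candidate (ties broken by lowest feature index), and
#' stops when the top `retain_fraction` of features (at least one,
#' `floor(retain_fraction * p)` otherwise) have been selected. Only inner
#' folds of the outer-training partition are ever inspected, so outer-test
#' labels cannot leak into the selection.
#'
#' @param train numeric matrix of outer-training rows.
#' @param labels factor/character labels (`T`/`NT`) aligned with `train`
#'   rows.
#' @param inner_folds list of folds, each a list with integer row indices
#'   `train` and `val` into `train`.
#' @param retain_fraction fraction of features to keep (default 0.1).
#' @param svm_cost fixed SVM cost used for the candidate evaluations.
#' @return character vector of selected feature names, in selection order.
#' @export
greedy_forward_select <- function(train, labels, inner_folds,
                                  retain_fraction = 0.1, svm_cost = 1) {
  stopifnot(is.matrix(train), length(labels) == nrow(train))
  p <- ncol(train)
  m <- max(1L, floor(retain_fraction * p))
  y <- ifelse(as.character(labels) == "T", 1, -1)
  # degenerate single-class inner training folds carry no ranking
  # information and are skipped; with none left the search is undefined
  inner_folds <- Filter(function(f) length(unique(y[f$train])) == 2,
                        inner_folds)
  if (length(inner_folds) == 0) {
    stop("every inner training fold contains a single class", call. = FALSE)
  }
  selected <- integer(0)
  remaining <- seq_len(p)
  while (length(selected) < m) {
    scores <- vapply(remaining, function(j) {
      cols <- c(selected, j)
      accs <- vapply(inner_folds, function(f) {
        mm <- minmax_fit_apply(train[f$train, cols, drop = FALSE],
                               train[f$val, cols, drop = FALSE])
        dec <- .svm_dcd_grid(mm$train, y[f$train], mm$test, svm_cost,
                             1000L, 1e-4, 0L)$test_decision[, 1]
        bac_from_labels(y[f$val] > 0, dec > 0)
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    best <- remaining[which.max(scores)] # which.max: lowest index on ties
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  colnames(train)[selected]
}
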