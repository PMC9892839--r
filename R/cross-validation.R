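#' Nested cross-validation plans
#'
#' Three nested schemes are supported, mirroring the study design for a
#' multi-protocol cohort:
#' * **LSO** (leave-one scan-acquisition-protocol-out): one outer fold per
#'   protocol, whose subjects form the test set;
#' * **LPO** (leave-one-pair-out): outer folds are seeded random pairings of
#'   one ARMS-T with one ARMS-NT from the same protocol, every subject
#'   tested exactly once;
#' * **KFOLD**: classic stratified k-fold on the transition label.
#'
#' Inner folds are a stratified `inner_k`-fold (default 5) over each outer
#' training set, used for hyperparameter tuning only.
#'
#' @name cv_plans
NULL

check_roster <- function(roster) {
  need <- c("subject_id", "group", "protocol")
  if (!is.data.frame(roster) || !all(need %in% names(roster))) {
    stop("`roster` must be a data frame with subject_id, group, protocol",
         call. = FALSE)
  }
  if (anyDuplicated(roster$subject_id)) {
    stop("duplicate subject ids in roster", call. = FALSE)
  }
  roster
}

# Stratified k-fold over ids; strata are shuffled then dealt round-robin
# with a counter carried across strata, so fold sizes differ by at most one
# both within every stratum and in total.
stratified_kfold <- function(ids, strata, k) {
  fold <- integer(length(ids))
  offset <- 0L
  for (s in unique(strata)) {
    i <- which(strata == s)
    i <- i[sample.int(length(i))]
    fold[i] <- (offset + seq_along(i) - 1L) %% k + 1L
    offset <- offset + length(i)
  }
  lapply(seq_len(k), function(f) {
    list(train_ids = ids[fold != f], val_ids = ids[fold == f])
  })
}

make_inner <- function(roster, train_ids, inner_k) {
  if (inner_k == 0L) return(list()) # light plans: no inner cycle needed
  sub <- roster[match(train_ids, roster$subject_id), , drop = FALSE]
  stratified_kfold(sub$subject_id, sub$group, inner_k)
}

# Rebuild a plan of the same scheme, seed and inner structure on a
# (possibly relabelled) roster; `light` skips the inner folds.
rebuild_plan <- function(plan, roster, light = FALSE) {
  ik <- if (light) 0L else plan$inner_k
  switch(plan$scheme,
         LSO = build_lso_plan(roster, ik, plan$seed),
         LPO = build_lpo_plan(roster, ik, plan$seed),
         KFOLD = build_kfold_plan(roster, k = length(plan$folds),
                                  inner_k = ik, seed = plan$seed))
}

new_cv_plan <- function(scheme, folds, seed, inner_k) {
  structure(list(scheme = scheme, folds = folds, seed = as.integer(seed),
                 inner_k = as.integer(inner_k)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan %s: %d outer folds, inner %d-fold, seed %d>\n",
              x$scheme, length(x$folds), x$inner_k, x$seed))
  invisible(x)
}

#' @rdname cv_plans
#' @param roster data frame with columns `subject_id`, `group` (`T`/`NT`)
#'   and `protocol` (see [subsample_roster()]).
#' @param inner_k inner fold count (default 5).
#' @param seed integer seed for the fold assignments.
#' @return a `cv_plan`: scheme tag plus a list of outer folds, each with
#'   `train_ids`, `test_ids` and stratified `inner_folds`.
#' @export
build_lso_plan <- function(roster, inner_k = 5L, seed = 1L) {
  roster <- check_roster(roster)
  protos <- sort(unique(roster$protocol))
  if (length(protos) < 2) {
    stop("LSO needs at least 2 protocols", call. = FALSE)
  }
  with_seed(seed, {
    folds <- lapply(seq_along(protos), function(i) {
      test <- roster$subject_id[roster$protocol == protos[i]]
      train <- setdiff(roster$subject_id, test)
      list(outer_index = i, test_ids = test, train_ids = train,
           inner_folds = make_inner(roster, train, inner_k))
    })
    new_cv_plan("LSO", folds, seed, inner_k)
  })
}

#' @rdname cv_plans
#' @export
build_lpo_plan <- function(roster, inner_k = 5L, seed = 1L) {
  roster <- check_roster(roster)
  with_seed(seed, {
    pairs <- list()
    for (pr in sort(unique(roster$protocol))) {
      t_ids <- roster$subject_id[roster$protocol == pr & roster$group == "T"]
      n_ids <- roster$subject_id[roster$protocol == pr & roster$group == "NT"]
      if (length(t_ids) != length(n_ids)) {
        stop(sprintf("protocol %s has %d T but %d NT: LPO needs per-protocol parity",
                     pr, length(t_ids), length(n_ids)), call. = FALSE)
      }
      if (length(t_ids) == 0) next
      t_ids <- t_ids[sample.int(length(t_ids))]
      n_ids <- n_ids[sample.int(length(n_ids))]
      pairs <- c(pairs, lapply(seq_along(t_ids),
                               function(j) c(t_ids[j], n_ids[j])))
    }
    folds <- lapply(seq_along(pairs), function(i) {
      test <- pairs[[i]]
      train <- setdiff(roster$subject_id, test)
      list(outer_index = i, test_ids = test, train_ids = train,
           inner_folds = make_inner(roster, train, inner_k))
    })
    new_cv_plan("LPO", folds, seed, inner_k)
  })
}

#' @rdname cv_plans
#' @param k outer fold count for the k-fold scheme (default 5).
#' @export
build_kfold_plan <- function(roster, k = 5L, inner_k = 5L, seed = 1L) {
  roster <- check_roster(roster)
  k <- check_count(k, "k", min = 2L)
  counts <- table(roster$group)
  if (any(counts < k)) {
    stop(sprintf("every class must have at least k = %d subjects", k),
         call. = FALSE)
  }
  with_seed(seed, {
    outer <- stratified_kfold(roster$subject_id, roster$group, k)
    folds <- lapply(seq_len(k), function(i) {
      list(outer_index = i, test_ids = outer[[i]]$val_ids,
           train_ids = outer[[i]]$train_ids,
           inner_folds = make_inner(roster, outer[[i]]$train_ids, inner_k))
    })
    new_cv_plan("KFOLD", folds, seed, inner_k)
  })
}

#' The hyperparameter grids
#'
#' The linear-SVM cost grid is `2^l` for `l` in -5..4 (10 values); the
#' elastic-net mixing grid is 0, 0.1, ..., 1 (11 values) crossed with the
#' penalty grid 0.01, 0.02, ..., 1 (100 values).
#'
#' @return list with `svm_C`, `enet_l1`, `enet_lambda`.
#' @export
default_grids <- function() {
  list(svm_C = 2^(-5:4),
       enet_l1 = seq(0, 1, by = 0.1),
       enet_lambda = seq(0.01, 1, by = 0.01))
}

#' Serialise a CV plan to JSON for audit
#'
#' @param plan a `cv_plan`.
#' @param path output path.
#' @export
write_cv_plan <- function(plan, path) {
  stopifnot(inherits(plan, "cv_plan"))
  jsonlite::write_json(
    list(scheme = plan$scheme, seed = plan$seed, inner_k = plan$inner_k,
         folds = lapply(plan$folds, function(f) {
           list(outer_index = f$outer_index, train_ids = f$train_ids,
                test_ids = f$test_ids,
                inner_folds = lapply(f$inner_folds, function(g) {
                  list(train_ids = g$train_ids, val_ids = g$val_ids)
                }))
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
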