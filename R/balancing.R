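#' Matching criteria for balanced subsampling
#'
#' A candidate ARMS-NT draw is accepted only if the drawn group is not
#' distinguishable from the ARMS-T group on age (two-sided Mann-Whitney U,
#' p above `age_p_threshold`) and sex (two-sided chi-square, p above
#' `sex_p_threshold`), with scan-protocol matching done one-to-one when
#' `protocol_one_to_one` is set.
#'
#' @param age_p_threshold,sex_p_threshold acceptance thresholds in (0, 1).
#' @param protocol_one_to_one draw exactly as many ARMS-NT per protocol as
#'   there are ARMS-T in that protocol.
#' @param max_attempts rejection-sampling budget.
#' @return a `match_criteria` list.
#' @export
match_criteria <- function(age_p_threshold = 0.05, sex_p_threshold = 0.05,
                           protocol_one_to_one = TRUE, max_attempts = 10000L) {
  stopifnot(age_p_threshold > 0, age_p_threshold < 1,
            sex_p_threshold > 0, sex_p_threshold < 1)
  max_attempts <- check_count(max_attempts, "max_attempts")
  structure(list(age_p_threshold = age_p_threshold,
                 sex_p_threshold = sex_p_threshold,
                 protocol_one_to_one = isTRUE(protocol_one_to_one),
                 max_attempts = max_attempts),
            class = "match_criteria")
}

sex_match_p <- function(cohort_rows) {
  tab <- table(factor(cohort_rows$transition, levels = c("T", "NT")),
               factor(cohort_rows$sex, levels = c("male", "female")))
  # a zero sex margin means both groups are single-sex and identical in
  # proportion; the expected-count statistic is undefined but the matching
  # question has the trivial answer
  if (any(colSums(tab) == 0)) return(1)
  chi_square_2x2(unclass(tab))$p_value
}

draw_nt <- function(t_rows, nt_pool, one_to_one) {
  if (one_to_one) {
    picked <- lapply(split(seq_len(nrow(nt_pool)), nt_pool$protocol), identity)
    want <- table(factor(t_rows$protocol, levels = names(picked)))
    unlist(lapply(names(picked), function(pr) {
      k <- want[[pr]]
      if (k == 0L) return(character(0))
      pool <- picked[[pr]]
      nt_pool$subject_id[pool[sample.int(length(pool), k)]]
    }), use.names = FALSE)
  } else {
    nt_pool$subject_id[sample.int(nrow(nt_pool), nrow(t_rows))]
  }
}

#' Draw one group-balanced, demographically matched subsample
#'
#' Retains every ARMS-T subject and selects an equal number of ARMS-NT
#' subjects by seeded rejection sampling: protocol-stratified uniform draws
#' are repeated until the drawn ARMS-NT group matches the ARMS-T group on
#' age and sex per the [match_criteria()], or the attempt budget is
#' exhausted.
#'
#' @param cohort a `cohort_table`.
#' @param criteria a [match_criteria()].
#' @param seed integer seed; the subsample is a pure function of
#'   (cohort, criteria, seed).
#' @return a `balanced_subsample` with the two id sets, the attempt count
#'   and the accepted draw's age/sex p-values.
#' @export
balance_subsample <- function(cohort, criteria = match_criteria(), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  t_rows <- cohort[cohort$transition == "T", , drop = FALSE]
  nt_pool <- cohort[cohort$transition == "NT", , drop = FALSE]
  if (nrow(t_rows) == 0 || nrow(nt_pool) < nrow(t_rows)) {
    stop("need at least one ARMS-T and an ARMS-NT pool of at least the same size",
         call. = FALSE)
  }
  if (criteria$protocol_one_to_one) {
    want <- table(factor(t_rows$protocol, levels = unique(cohort$protocol)))
    have <- table(factor(nt_pool$protocol, levels = unique(cohort$protocol)))
    short <- names(want)[want > have]
    if (length(short) > 0) {
      stop(sprintf(
        "ARMS-NT pool smaller than ARMS-T count in protocol(s): %s",
        paste(short, collapse = ", ")), call. = FALSE)
    }
  }
  with_seed(seed, {
    best <- list(score = -Inf, age_p = NA_real_, sex_p = NA_real_)
    for (attempt in seq_len(criteria$max_attempts)) {
      nt_ids <- draw_nt(t_rows, nt_pool, criteria$protocol_one_to_one)
      nt_rows <- nt_pool[match(nt_ids, nt_pool$subject_id), , drop = FALSE]
      age_p <- mann_whitney_u(t_rows$age_years, nt_rows$age_years)$p_value
      sex_p <- sex_match_p(rbind(t_rows, nt_rows))
      if (age_p > criteria$age_p_threshold &&
          sex_p > criteria$sex_p_threshold) {
        return(structure(list(
          subject_ids_T = t_rows$subject_id,
          subject_ids_NT = nt_ids,
          attempt_count = attempt,
          age_p = age_p, sex_p = sex_p, seed = as.integer(seed)),
          class = "balanced_subsample"))
      }
      score <- min(age_p - criteria$age_p_threshold,
                   sex_p - criteria$sex_p_threshold)
      if (score > best$score) best <- list(score = score, age_p = age_p,
                                           sex_p = sex_p)
    }
    stop(sprintf(
      "matching failed after %d attempts (best draw: age p = %.3f, sex p = %.3f)",
      criteria$max_attempts, best$age_p, best$sex_p), call. = FALSE)
  })
}

#' @export
print.balanced_subsample <- function(x, ...) {
  cat(sprintf(
    "<balanced_subsample: %d T + %d NT, %d attempt(s), age p = %.3f, sex p = %.3f>\n",
    length(x$subject_ids_T), length(x$subject_ids_NT), x$attempt_count,
    x$age_p, x$sex_p))
  invisible(x)
}

#' Draw the bootstrap replicates of the balanced subsample
#'
#' Repeats [balance_subsample()] with replicate seeds derived
#' deterministically from the master seed. Replicates are independent draws:
#' an ARMS-NT subject may appear in several replicates but never twice
#' within one.
#'
#' @param cohort a `cohort_table`.
#' @param criteria a [match_criteria()].
#' @param n_replicates number of bootstrap replicates (the study design
#'   uses 5).
#' @param seed master integer seed.
#' @return list of `balanced_subsample` objects.
#' @export
bootstrap_subsamples <- function(cohort, criteria = match_criteria(),
                                 n_replicates = 5L, seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  seeds <- derive_seeds(seed, n_replicates)
  lapply(seeds, function(s) balance_subsample(cohort, criteria, seed = s))
}

#' Roster of a balanced subsample
#'
#' @param subsample a `balanced_subsample`.
#' @param cohort the `cohort_table` it was drawn from.
#' @return data frame with `subject_id`, `group` (`T`/`NT`), `protocol`,
#'   `age_years`, `sex`, ordered T block first.
#' @export
subsample_roster <- function(subsample, cohort) {
  stopifnot(inherits(subsample, "balanced_subsample"))
  ids <- c(subsample$subject_ids_T, subsample$subject_ids_NT)
  rows <- cohort[match(ids, cohort$subject_id), , drop = FALSE]
  data.frame(subject_id = rows$subject_id,
             group = rows$transition,
             protocol = rows$protocol,
             age_years = rows$age_years,
             sex = rows$sex,
             stringsAsFactors = FALSE)
}

#' Write a subsample manifest and its JSON sidecar
#'
#' @param subsamples list of `balanced_subsample` objects.
#' @param cohort the source `cohort_table`.
#' @param path TSV path for the manifest (`replicate_index`, `subject_id`,
#'   `group`, `protocol`); a `.json` sidecar with seeds and accepted
#'   p-values is written next to it.
#' @return invisibly, the manifest data frame.
#' @export
write_subsample_manifest <- function(subsamples, cohort, path) {
  rows <- do.call(rbind, lapply(seq_along(subsamples), function(i) {
    r <- subsample_roster(subsamples[[i]], cohort)
    cbind(replicate_index = i, r[c("subject_id", "group", "protocol")])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  side <- lapply(subsamples, function(s) {
    list(seed = s$seed, attempt_count = s$attempt_count,
         age_p = s$age_p, sex_p = s$sex_p)
  })
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(rows)
}
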