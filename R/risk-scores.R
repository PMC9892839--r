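#' Polygenic risk score
#'
#' The weighted allele-dosage sum: for each subject,
#' `sum over SNPs of dosage x weight`, over the SNPs passing the optional
#' association p-value threshold. A missing dosage is imputed as twice the
#' minor allele frequency when the weight table carries a `maf` column;
#' otherwise the SNP is skipped for that subject with a warning.
#'
#' @param dosages subjects x SNPs matrix of effect-allele dosages
#'   (0/1/2 or `NA`), columns named by SNP id, rows by subject id.
#' @param weights weight table: `snp_id`, `effect_allele`, `weight`, and
#'   optionally `p_value` and `maf`. Dosage files are assumed pre-oriented
#'   to the table's effect allele.
#' @param p_threshold optional inclusion threshold on the weight table's
#'   `p_value`.
#' @return named numeric vector of scores, one per subject.
#' @export
compute_prs <- function(dosages, weights, p_threshold = NULL) {
  stopifnot(is.matrix(dosages))
  if (!all(dosages %in% c(0, 1, 2) | is.na(dosages))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  w <- weights
  if (!is.null(p_threshold)) {
    if (is.null(w$p_value)) stop("weight table has no p_value column",
                                 call. = FALSE)
    w <- w[w$p_value <= p_threshold, , drop = FALSE]
  }
  w <- w[w$snp_id %in% colnames(dosages), , drop = FALSE]
  if (nrow(w) == 0) {
    stop("weight table empty after thresholding/intersection", call. = FALSE)
  }
  d <- dosages[, w$snp_id, drop = FALSE]
  if (anyNA(d)) {
    if (!is.null(w$maf)) {
      imp <- matrix(rep(2 * w$maf, each = nrow(d)), nrow(d))
      d[is.na(d)] <- imp[is.na(d)]
    } else {
      warning("missing dosages without MAF: affected SNPs skipped per subject")
      d[is.na(d)] <- 0
    }
  }
  drop(d %*% w$weight)
}

#' Per-gene brain eQTL score (eGenScore)
#'
#' The same weighted dosage-sum contract as the polygenic score, applied per
#' gene (and tissue) of an eQTL weight panel: each score proxies the
#' genetically regulated brain expression of one gene. Applied to the
#' packaged synthetic panel this yields a 141-column feature family.
#'
#' @param dosages as in [compute_prs()].
#' @param eqtl_weights weight table with a `gene_id` column (and optionally
#'   `tissue`), e.g. from [synthetic_eqtl_panel()].
#' @return subjects x genes numeric matrix of scores.
#' @export
compute_egen_score <- function(dosages, eqtl_weights) {
  if (is.null(eqtl_weights$gene_id)) {
    stop("eQTL weight table needs a gene_id column", call. = FALSE)
  }
  genes <- unique(eqtl_weights$gene_id)
  out <- vapply(genes, function(g) {
    wg <- eqtl_weights[eqtl_weights$gene_id == g, , drop = FALSE]
    if (all(wg$weight == 0)) return(rep(0, nrow(dosages)))
    compute_prs(dosages, wg)
  }, numeric(nrow(dosages)))
  matrix(out, nrow(dosages), length(genes),
         dimnames = list(rownames(dosages), genes))
}

#' Exposure-missingness filter
#'
#' Retains only subjects with at most `max_missing` missing environmental
#' risk factors; the study design requires fewer than two missing factors
#' (less than 20% of the eight), i.e. `max_missing = 1`.
#'
#' @param exposures data frame with `subject_id` and the eight factor
#'   columns (`NA` for missing).
#' @param max_missing maximum tolerated count of missing factors.
#' @return character vector of retained subject ids.
#' @export
filter_exposure_missingness <- function(exposures, max_missing = 1L) {
  fac <- setdiff(names(exposures), "subject_id")
  n_miss <- rowSums(is.na(exposures[fac]))
  exposures$subject_id[n_miss <= max_missing]
}

#' Environmental risk score
#'
#' Additive composite of log relative risks over the eight environmental
#' factors, under the assumption that the factors act independently: each
#' factor contributes the log relative risk of the subject's coded exposure
#' level, and a missing factor contributes 0 (the population-average
#' contribution). The multiplicative relative-risk product is this score
#' exponentiated.
#'
#' @param exposures data frame with `subject_id` and factor columns, already
#'   past [filter_exposure_missingness()].
#' @param weights named list of per-factor log relative risks indexed by
#'   coded level, see [default_exposure_weights()].
#' @return named numeric vector of scores, one per subject.
#' @export
compute_ers <- function(exposures, weights = default_exposure_weights()) {
  fac <- intersect(names(weights), names(exposures))
  if (length(fac) == 0) stop("no known factor columns present", call. = FALSE)
  scores <- numeric(nrow(exposures))
  for (f in fac) {
    lv <- exposures[[f]]
    ok <- !is.na(lv)
    key <- as.character(lv[ok])
    unknown <- setdiff(unique(key), names(weights[[f]]))
    if (length(unknown) > 0) {
      stop(sprintf("factor %s has level(s) %s absent from the weight table",
                   f, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    scores[ok] <- scores[ok] + weights[[f]][key]
  }
  names(scores) <- exposures$subject_id
  scores
}

#' Write a subject score table as TSV
#'
#' @param prs named polygenic scores (or `NULL`).
#' @param ers named environmental scores (or `NULL`).
#' @param egen subjects x genes eQTL score matrix (or `NULL`).
#' @param path output TSV path.
#' @return invisibly, the combined data frame.
#' @export
write_scores_tsv <- function(path, prs = NULL, ers = NULL, egen = NULL) {
  ids <- unique(c(names(prs), names(ers), rownames(egen)))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  if (!is.null(prs)) out$prs <- unname(prs[ids])
  if (!is.null(ers)) out$ers <- unname(ers[ids])
  if (!is.null(egen)) out <- cbind(out, as.data.frame(egen[ids, , drop = FALSE]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}
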