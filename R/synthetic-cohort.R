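#' Effect specification for synthetic cohorts
#'
#' Controls how much group signal the generators inject. `n_informative`
#' features (chosen reproducibly from `seed`) have their ARMS-T group mean
#' shifted by `cohens_d` within-group standard deviations; `cohens_d = 0`
#' defines the null regime in which transition status carries no information.
#'
#' @param n_informative non-negative count of signal-carrying features.
#' @param cohens_d standardised mean difference between the ARMS-T and
#'   ARMS-NT groups on informative features.
#' @param seed integer seed governing which features are informative.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(n_informative = 0L, cohens_d = 0, seed = 1L) {
  n_informative <- check_count(n_informative, "n_informative", min = 0L)
  stopifnot(is.numeric(cohens_d), length(cohens_d) == 1L, is.finite(cohens_d))
  structure(list(n_informative = n_informative, cohens_d = cohens_d,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

#' Generate a synthetic At-Risk Mental State cohort roster
#'
#' Emulates the structure of a clinical high-risk cohort followed for
#' transition to a first episode of psychosis: `n_T` transitioning (ARMS-T)
#' and `n_NT` non-transitioning (ARMS-NT) subjects with age, sex, scan
#' acquisition protocol and follow-up time. Ages are drawn from a normal
#' distribution (mean 23, sd 4.5) truncated to \[14, 45\]; sex is
#' Bernoulli(0.55) male; protocols are multinomial over three protocols.
#' Non-transitioning subjects have at least two years of follow-up (the
#' definition of a stable non-transition label); transitioning subjects
#' transition within two years.
#'
#' @param n_T,n_NT positive counts of transitioning / non-transitioning
#'   subjects.
#' @param protocol_mix proportions over the three scan protocols, summing
#'   to 1.
#' @param seed integer seed; the roster is a pure function of the arguments.
#' @return a `cohort_table` data frame with columns `subject_id`,
#'   `age_years`, `sex`, `protocol`, `transition`, `followup_years`.
#' @examples
#' co <- generate_cohort(23, 76, seed = 1)
#' table(co$transition)
#' @export
generate_cohort <- function(n_T, n_NT, protocol_mix = c(1, 1, 1) / 3,
                            seed = 1L) {
  n_T <- check_count(n_T, "n_T")
  n_NT <- check_count(n_NT, "n_NT")
  if (length(protocol_mix) != 3L || any(protocol_mix < 0) ||
      abs(sum(protocol_mix) - 1) > 1e-8) {
    stop("`protocol_mix` must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  }
  n <- n_T + n_NT
  with_seed(seed, {
    age <- rnorm(4L * n, mean = 23, sd = 4.5)
    age <- age[age >= 14 & age <= 45][seq_len(n)]
    if (anyNA(age)) { # pathologically unlucky truncation; top up
      extra <- rnorm(20L * n, 23, 4.5)
      age <- c(age[!is.na(age)], extra[extra >= 14 & extra <= 45])[seq_len(n)]
    }
    sex <- ifelse(runif(n) < 0.55, "male", "female")
    protocol <- sample(c("P1", "P2", "P3"), n, replace = TRUE,
                       prob = protocol_mix)
    transition <- rep(c("T", "NT"), c(n_T, n_NT))
    followup <- ifelse(transition == "T", runif(n, 0.2, 2), runif(n, 2, 5))
    out <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age_years = age,
      sex = sex,
      protocol = protocol,
      transition = transition,
      followup_years = followup,
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Container for a subjects-by-features modality table
#'
#' @param values numeric matrix, rows named by subject id.
#' @param family one of `ROIGM`, `ROIWM`, `ROISurface`, `VBGM`, `VBWM`,
#'   `SNP`, `EQTL`, `ENV`, `SCORE`.
#' @param tiv optional named positive vector of total intracranial volumes.
#' @return a `modality_features` object.
#' @export
modality_features <- function(values, family, tiv = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  family <- match.arg(family, c("ROIGM", "ROIWM", "ROISurface", "VBGM",
                                "VBWM", "SNP", "EQTL", "ENV", "SCORE"))
  if (!is.null(tiv)) {
    tiv <- tiv[rownames(values)]
    if (anyNA(tiv) || any(tiv <= 0)) {
      stop("`tiv` must be positive and cover every subject", call. = FALSE)
    }
  }
  structure(list(values = values, family = family, tiv = tiv),
            class = "modality_features")
}

#' @export
print.modality_features <- function(x, ...) {
  cat(sprintf("<modality_features %s: %d subjects x %d features%s>\n",
              x$family, nrow(x$values), ncol(x$values),
              if (is.null(x$tiv)) "" else ", with TIV"))
  invisible(x)
}

informative_idx <- function(p, effect) {
  k <- min(effect$n_informative, p)
  if (k == 0L) return(integer(0))
  with_seed(effect$seed, sample.int(p, k))
}

gen_family <- function(cohort, p, family, base_mean, effect, scanner_effect,
                       tiv, tiv_coupled, seed) {
  n <- nrow(cohort)
  idx <- informative_idx(p, effect)
  with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    # scanner effect: additive per-protocol offset in within-group SD units
    off <- scanner_effect * c(P1 = -1, P2 = 0, P3 = 1)[cohort$protocol]
    x <- x + off
    if (length(idx) > 0 && effect$cohens_d != 0) {
      x[cohort$transition == "T", idx] <-
        x[cohort$transition == "T", idx] + effect$cohens_d
    }
    x <- x + base_mean
    if (tiv_coupled) {
      # larger heads carry proportionally larger regional volumes, which is
      # what makes normalising by intracranial volume worthwhile
      x <- x * (tiv / 1500)
    }
    colnames(x) <- sprintf("%s_%03d", family, seq_len(p))
    rownames(x) <- cohort$subject_id
    modality_features(x, family, tiv = tiv)
  })
}

#' Generate the five synthetic structural-MRI feature families
#'
#' Produces regional gray-matter volumes (64 features), regional white-matter
#' volumes (64), surface measures (272), and voxel-based gray/white matter
#' maps at a configurable reduced scale, each with a positive total
#' intracranial volume (TIV). Regional volumes are coupled to TIV so that
#' TIV normalisation is meaningful; a per-protocol additive offset (default
#' 0.3 within-group SD) emulates scanner effects so the site-aware
#' cross-validation schemes are genuinely exercised. Informative features
#' have group means separated by `effect$cohens_d` within-group SDs.
#'
#' @param cohort a `cohort_table`.
#' @param effect an [effect_spec()]; applied independently to each family.
#' @param voxel_scale number of columns for each voxel-based family
#'   (a scale parameter standing in for the full voxel counts).
#' @param scanner_effect per-protocol offset size in within-group SD units.
#' @return named list of five `modality_features` objects:
#'   `ROIGM`, `ROIWM`, `ROISurface`, `VBGM`, `VBWM`.
#' @export
generate_smri_features <- function(cohort, effect = effect_spec(),
                                   voxel_scale = 2000L,
                                   scanner_effect = 0.3) {
  if (!inherits(cohort, "cohort_table") || nrow(cohort) == 0) {
    stop("`cohort` must be a non-empty cohort_table", call. = FALSE)
  }
  voxel_scale <- check_count(voxel_scale, "voxel_scale")
  base_seed <- effect$seed
  tiv <- with_seed(base_seed + 11L, {
    v <- rnorm(nrow(cohort), 1500, 100)
    v[v < 900] <- 900
    names(v) <- cohort$subject_id
    v
  })
  fams <- list(
    ROIGM = list(p = 64L, base = 10, coupled = TRUE),
    ROIWM = list(p = 64L, base = 10, coupled = TRUE),
    ROISurface = list(p = 272L, base = 3, coupled = FALSE),
    VBGM = list(p = voxel_scale, base = 0.5, coupled = FALSE),
    VBWM = list(p = voxel_scale, base = 0.5, coupled = FALSE)
  )
  out <- lapply(seq_along(fams), function(i) {
    f <- fams[[i]]
    gen_family(cohort, f$p, names(fams)[i], f$base,
               effect = structure(list(n_informative = effect$n_informative,
                                       cohens_d = effect$cohens_d,
                                       seed = effect$seed + i),
                                  class = "effect_spec"),
               scanner_effect = scanner_effect, tiv = tiv,
               tiv_coupled = f$coupled, seed = base_seed + 100L + i)
  })
  names(out) <- names(fams)
  out
}

#' Generate synthetic SNP dosages and a matching weight table
#'
#' Dosages are binomial(2, MAF) counts of the effect allele, with minor
#' allele frequencies uniform over `maf_range`. Under a non-null
#' [effect_spec()], the effect-allele frequency of the informative SNPs is
#' shifted in the ARMS-T group so that the dosage mean difference equals
#' `cohens_d` dosage SDs; their weights are constrained positive so the
#' polygenic score inherits the signal. The weight table carries the SNP id,
#' effect allele, per-allele log-odds weight, association p-value and MAF.
#'
#' @param cohort a `cohort_table`.
#' @param n_snps number of SNPs.
#' @param maf_range interval within (0, 0.5] for the minor allele frequency.
#' @param effect an [effect_spec()].
#' @return list with `dosages` (subjects x SNPs integer matrix) and
#'   `weights` (data frame: `snp_id`, `effect_allele`, `weight`, `p_value`,
#'   `maf`).
#' @export
generate_genotypes <- function(cohort, n_snps = 500L,
                               maf_range = c(0.05, 0.5),
                               effect = effect_spec()) {
  if (!inherits(cohort, "cohort_table") || nrow(cohort) == 0) {
    stop("`cohort` must be a non-empty cohort_table", call. = FALSE)
  }
  n_snps <- check_count(n_snps, "n_snps")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  n <- nrow(cohort)
  idx <- informative_idx(n_snps, effect)
  with_seed(effect$seed + 23L, {
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    freq <- matrix(rep(maf, each = n), n, n_snps)
    if (length(idx) > 0 && effect$cohens_d != 0) {
      shift <- effect$cohens_d * sqrt(2 * maf[idx] * (1 - maf[idx])) / 2
      fT <- pmin(pmax(maf[idx] + shift, 0.005), 0.995)
      freq[cohort$transition == "T", idx] <-
        matrix(rep(fT, each = sum(cohort$transition == "T")),
               sum(cohort$transition == "T"), length(idx))
    }
    dos <- matrix(rbinom(n * n_snps, 2L, as.vector(freq)), n, n_snps)
    rownames(dos) <- cohort$subject_id
    colnames(dos) <- sprintf("rs%06d", seq_len(n_snps))
    w <- rnorm(n_snps, 0, 0.05)
    if (length(idx) > 0) w[idx] <- abs(w[idx]) + 0.02
    weights <- data.frame(
      snp_id = colnames(dos),
      effect_allele = sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
      weight = w,
      p_value = ifelse(seq_len(n_snps) %in% idx,
                       runif(n_snps, 0, 1e-4), runif(n_snps)),
      maf = maf,
      stringsAsFactors = FALSE
    )
    list(dosages = dos, weights = weights)
  })
}

#' Build a synthetic per-gene brain eQTL weight panel
#'
#' Assigns each of `n_genes` genes (default 141, the size of the
#' psychosis-associated brain gene panel the score family emulates) a small
#' set of SNPs drawn from an existing weight table, with expression-effect
#' weights and a brain tissue label. The panel is synthetic: it emulates the
#' shape of a brain eQTL catalogue, not its content.
#'
#' @param snp_ids character vector of available SNP ids.
#' @param n_genes number of genes in the panel.
#' @param seed integer seed.
#' @return data frame with `snp_id`, `effect_allele`, `weight`, `gene_id`,
#'   `tissue`.
#' @export
synthetic_eqtl_panel <- function(snp_ids, n_genes = 141L, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  with_seed(seed, {
    rows <- lapply(seq_len(n_genes), function(g) {
      k <- sample(1:6, 1)
      data.frame(
        snp_id = sample(snp_ids, k),
        effect_allele = sample(c("A", "C", "G", "T"), k, replace = TRUE),
        weight = rnorm(k, 0, 0.3),
        gene_id = sprintf("GENE%03d", g),
        tissue = sample(c("frontal_cortex", "hippocampus", "cerebellum",
                          "anterior_cingulate"), 1),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

# The eight environmental risk factors and their coded levels.
exposure_factor_levels <- function() {
  list(tobacco = 0:1, cannabis = 0:2, migrant = 0:1, ethnic_minority = 0:1,
       urbanicity = 0:2, parental_age = 0:2, childhood_trauma = 0:1,
       season_of_birth = 0:1)
}

#' Default log relative-risk weights for the eight environmental factors
#'
#' Synthetic defaults of plausible magnitude (relative risks between 1.1 and
#' 2.0 for the at-risk levels); the environmental risk score is additive in
#' these log relative risks under the factor-independence assumption.
#'
#' @return named list, one numeric vector per factor, entries named by coded
#'   level, values log relative risks (reference level 0 maps to 0).
#' @export
default_exposure_weights <- function() {
  rr <- list(
    tobacco = c("0" = 1, "1" = 1.2),
    cannabis = c("0" = 1, "1" = 1.4, "2" = 1.9),
    migrant = c("0" = 1, "1" = 1.5),
    ethnic_minority = c("0" = 1, "1" = 1.8),
    urbanicity = c("0" = 1, "1" = 1.2, "2" = 1.5),
    parental_age = c("0" = 1, "1" = 1.3, "2" = 1.5),
    childhood_trauma = c("0" = 1, "1" = 2.0),
    season_of_birth = c("0" = 1, "1" = 1.1)
  )
  lapply(rr, log)
}

#' Generate the eight synthetic environmental risk-factor exposures
#'
#' Exposure levels are multinomial draws; under a non-null [effect_spec()]
#' the ARMS-T level probabilities are exponentially tilted towards the
#' at-risk levels (tilt proportional to `cohens_d` times the level's log
#' relative risk), so the resulting environmental risk score separates the
#' groups. Missing entries are completely at random at `missing_rate`.
#'
#' @param cohort a `cohort_table`.
#' @param missing_rate probability in \[0, 1) that any cell is missing.
#' @param effect an [effect_spec()]; only `cohens_d` and `seed` are used
#'   (all eight factors carry the tilt when `cohens_d != 0`).
#' @return data frame with `subject_id` and one column per factor (integer
#'   codes, `NA` for missing).
#' @export
generate_exposures <- function(cohort, missing_rate = 0.1,
                               effect = effect_spec()) {
  if (!inherits(cohort, "cohort_table") || nrow(cohort) == 0) {
    stop("`cohort` must be a non-empty cohort_table", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  lv <- exposure_factor_levels()
  lw <- default_exposure_weights()
  base_p <- list(tobacco = c(0.65, 0.35), cannabis = c(0.55, 0.3, 0.15),
                 migrant = c(0.75, 0.25), ethnic_minority = c(0.7, 0.3),
                 urbanicity = c(0.3, 0.4, 0.3), parental_age = c(0.6, 0.25, 0.15),
                 childhood_trauma = c(0.7, 0.3), season_of_birth = c(0.73, 0.27))
  n <- nrow(cohort)
  is_t <- cohort$transition == "T"
  with_seed(effect$seed + 37L, {
    cols <- lapply(names(lv), function(f) {
      p0 <- base_p[[f]]
      pt <- p0 * exp(effect$cohens_d * lw[[f]])
      pt <- pt / sum(pt)
      x <- integer(n)
      x[!is_t] <- sample(lv[[f]], sum(!is_t), replace = TRUE, prob = p0)
      x[is_t] <- sample(lv[[f]], sum(is_t), replace = TRUE, prob = pt)
      x
    })
    names(cols) <- names(lv)
    out <- cbind(data.frame(subject_id = cohort$subject_id,
                            stringsAsFactors = FALSE),
                 as.data.frame(cols))
    if (missing_rate > 0) {
      cells <- matrix(runif(n * length(lv)) < missing_rate, n, length(lv))
      for (j in seq_along(lv)) out[[j + 1L]][cells[, j]] <- NA_integer_
    }
    out
  })
}
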