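#' Pipeline configuration
#'
#' Assembles the experiment grid configuration: which feature families to
#' run, the cohort shapes per modality, the effect injected by the synthetic
#' generators, replicate and permutation counts, and the preparation
#' parameters. Presets reproduce the study's cohort shapes:
#' `"paper-smri"` (23 transitioning + 76 non-transitioning, three
#' protocols), `"paper-genetic"` (21 + 54) and `"paper-environment"`
#' (37 + 97 before the missingness filter).
#'
#' Manipulations are constrained to the legal family/manipulation pairs:
#' forward selection only for the regional sMRI families, robust PCA only
#' for the voxel families, no manipulation for the score and tabular
#' families.
#'
#' @param families feature families to run (subset of `ROIGM`, `ROIWM`,
#'   `ROISurface`, `VBGM`, `VBWM`, `SNP`, `EQTL`, `ENV`, `PRS`, `ERS`).
#' @param schemes CV schemes for the sMRI families (subset of `LSO`,
#'   `LPO`, `KFOLD`); the non-imaging families always run the design's
#'   LPO-based schemes.
#' @param preset optional cohort-shape preset (see above); `NULL` keeps
#'   `cohorts`.
#' @param cohorts named list of `c(n_T, n_NT)` per modality
#'   (`smri`, `genetic`, `environmental`).
#' @param effect an [effect_spec()] shared by the generators.
#' @param n_replicates bootstrap replicates (default 5).
#' @param n_permutations label permutations per replicate (default 1000).
#' @param alpha significance level (default 0.05).
#' @param min_significant_fraction aggregation fraction (default 0.6).
#' @param voxel_scale columns per voxel family.
#' @param n_snps SNPs in the synthetic dosage matrix.
#' @param n_genes genes in the synthetic eQTL panel (default 141).
#' @param variance_target,retain_fraction,inner_k preparation parameters.
#' @param seed master seed: every downstream draw derives from it.
#' @param output_dir optional directory for TSV/JSON outputs.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(families = c("ROIGM", "ROIWM", "ROISurface",
                                         "VBGM", "VBWM", "SNP", "EQTL",
                                         "ENV", "PRS", "ERS"),
                            schemes = c("LSO", "LPO", "KFOLD"),
                            preset = NULL,
                            cohorts = list(smri = c(23, 76),
                                           genetic = c(21, 54),
                                           environmental = c(37, 97)),
                            effect = effect_spec(),
                            n_replicates = 5L, n_permutations = 1000L,
                            alpha = 0.05, min_significant_fraction = 0.6,
                            voxel_scale = 2000L, n_snps = 500L,
                            n_genes = 141L,
                            variance_target = 0.8, retain_fraction = 0.1,
                            inner_k = 5L, seed = 1L, output_dir = NULL) {
  families <- match.arg(families, several.ok = TRUE)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (!is.null(preset)) {
    shapes <- list(
      "paper-smri" = list(smri = c(23, 76)),
      "paper-genetic" = list(genetic = c(21, 54)),
      "paper-environment" = list(environmental = c(37, 97)))
    if (!preset %in% names(shapes)) {
      stop(sprintf("unknown preset '%s'", preset), call. = FALSE)
    }
    cohorts[names(shapes[[preset]])] <- shapes[[preset]]
  }
  structure(list(families = families, schemes = schemes, cohorts = cohorts,
                 effect = effect, n_replicates = n_replicates,
                 n_permutations = n_permutations, alpha = alpha,
                 min_significant_fraction = min_significant_fraction,
                 voxel_scale = voxel_scale, n_snps = n_snps,
                 n_genes = n_genes, variance_target = variance_target,
                 retain_fraction = retain_fraction, inner_k = inner_k,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

family_modality <- function(family) {
  switch(family,
         ROIGM = , ROIWM = , ROISurface = , VBGM = , VBWM = "smri",
         SNP = , EQTL = , PRS = "genetic",
         ENV = , ERS = "environmental")
}

#' Enumerate the legal experiment combinations of a configuration
#'
#' Regional sMRI families run with and without forward selection under each
#' requested scheme; voxel families run with robust PCA under each scheme;
#' SNP, eQTL and environmental-factor families run the elastic net under
#' nested LPO; the polygenic and environmental risk scores run the simple
#' LPO logistic path.
#'
#' @param config a [pipeline_config()].
#' @return data frame with `family`, `modality`, `manipulation`, `scheme`,
#'   `classifier`.
#' @export
experiment_combinations <- function(config) {
  rows <- list()
  add <- function(family, manipulation, scheme, classifier) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, modality = family_modality(family),
      manipulation = manipulation, scheme = scheme, classifier = classifier,
      stringsAsFactors = FALSE)
  }
  for (f in intersect(c("ROIGM", "ROIWM", "ROISurface"), config$families)) {
    for (s in config$schemes) {
      add(f, "none", s, "linear_svm")
      add(f, "forward_selection", s, "linear_svm")
    }
  }
  for (f in intersect(c("VBGM", "VBWM"), config$families)) {
    for (s in config$schemes) add(f, "robust_pca", s, "linear_svm")
  }
  for (f in intersect(c("SNP", "EQTL", "ENV"), config$families)) {
    add(f, "none", "LPO", "elastic_net")
  }
  for (f in intersect(c("PRS", "ERS"), config$families)) {
    add(f, "none", "LPO", "logistic_simple")
  }
  do.call(rbind, rows)
}

validate_combo <- function(family, manipulation) {
  legal <- switch(family,
                  ROIGM = , ROIWM = , ROISurface = c("none", "forward_selection"),
                  VBGM = , VBWM = "robust_pca",
                  "none")
  if (!manipulation %in% legal) {
    stop(sprintf("manipulation '%s' is not legal for family %s",
                 manipulation, family), call. = FALSE)
  }
  invisible(TRUE)
}

# Assemble the per-modality synthetic data used by the grid.
build_grid_data <- function(config) {
  seeds <- derive_seeds(config$seed, 6L)
  data <- list()
  if (any(vapply(config$families, family_modality, "") == "smri")) {
    co <- generate_cohort(config$cohorts$smri[1], config$cohorts$smri[2],
                          seed = seeds[1])
    eff <- config$effect
    eff$seed <- seeds[2]
    fams <- generate_smri_features(co, eff, voxel_scale = config$voxel_scale)
    fams$ROIGM <- scale_to_tiv(fams$ROIGM)
    fams$ROIWM <- scale_to_tiv(fams$ROIWM)
    data$smri <- list(cohort = co, features = fams)
  }
  if (any(vapply(config$families, family_modality, "") == "genetic")) {
    co <- generate_cohort(config$cohorts$genetic[1], config$cohorts$genetic[2],
                          seed = seeds[3])
    eff <- config$effect
    eff$seed <- seeds[4]
    gt <- generate_genotypes(co, n_snps = config$n_snps, effect = eff)
    panel <- synthetic_eqtl_panel(gt$weights$snp_id, n_genes = config$n_genes,
                                  seed = seeds[4])
    feats <- list()
    if ("SNP" %in% config$families) {
      feats$SNP <- modality_features(gt$dosages + 0.0, "SNP")
    }
    if ("EQTL" %in% config$families) {
      feats$EQTL <- modality_features(compute_egen_score(gt$dosages, panel),
                                      "EQTL")
    }
    if ("PRS" %in% config$families) {
      prs <- compute_prs(gt$dosages, gt$weights)
      feats$PRS <- modality_features(matrix(prs, ncol = 1,
                                            dimnames = list(names(prs), "prs")),
                                     "SCORE")
    }
    data$genetic <- list(cohort = co, features = feats)
  }
  if (any(vapply(config$families, family_modality, "") == "environmental")) {
    co <- generate_cohort(config$cohorts$environmental[1],
                          config$cohorts$environmental[2], seed = seeds[5])
    eff <- config$effect
    eff$seed <- seeds[6]
    expo <- generate_exposures(co, missing_rate = 0.08, effect = eff)
    feats <- list()
    if ("ERS" %in% config$families) {
      keep <- filter_exposure_missingness(expo, max_missing = 1L)
      ers <- compute_ers(expo[expo$subject_id %in% keep, , drop = FALSE])
      feats$ERS <- modality_features(matrix(ers, ncol = 1,
                                            dimnames = list(names(ers), "ers")),
                                     "SCORE")
    }
    if ("ENV" %in% config$families) {
      cc <- filter_exposure_missingness(expo, max_missing = 0L)
      sub <- expo[expo$subject_id %in% cc, , drop = FALSE]
      m <- as.matrix(sub[setdiff(names(sub), "subject_id")])
      rownames(m) <- sub$subject_id
      feats$ENV <- modality_features(m + 0.0, "ENV")
    }
    data$environmental <- list(cohort = co, features = feats)
  }
  data
}

combo_prep <- function(combo, config) {
  prep_recipe(minmax = TRUE,
              pca = combo$manipulation == "robust_pca",
              forward_select = combo$manipulation == "forward_selection",
              variance_target = config$variance_target,
              retain_fraction = config$retain_fraction)
}

combo_plan <- function(scheme, roster, inner_k, seed) {
  switch(scheme,
         LSO = build_lso_plan(roster, inner_k, seed),
         LPO = build_lpo_plan(roster, inner_k, seed),
         KFOLD = build_kfold_plan(roster, k = 5L, inner_k = inner_k,
                                  seed = seed))
}

#' Run the full experiment grid
#'
#' Executes every legal combination of feature family, manipulation and CV
#' scheme on synthetic data generated from the configuration's master seed:
#' per combination, the five (by default) matched balanced bootstrap
#' replicates are drawn, the nested cross-validation is run and its balanced
#' accuracy permutation-tested on each replicate, and the per-combination
#' significance decision is made by the 3-of-5 aggregation rule. Finally the
#' multimodal gate is applied across combinations; with no admitted
#' modality, no multimodal model is trained (the expected outcome under the
#' null configuration). With `output_dir` set, per-combination summary
#' tables (results-table layout) and a JSON run manifest are written.
#'
#' @param config a [pipeline_config()].
#' @return a `grid_result`: list of per-combination reports (each with the
#'   replicate performance reports, permutation p-values, train-set BACs and
#'   aggregate decision), the admitted modality set, and the combination
#'   table.
#' @export
run_experiment_grid <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  combos <- experiment_combinations(config)
  for (i in seq_len(nrow(combos))) {
    validate_combo(combos$family[i], combos$manipulation[i])
  }
  data <- build_grid_data(config)
  # one replicate set per feature family (each feature set has its own
  # final sample, as subjects differ in feature availability), shared by
  # that family's scheme/manipulation combinations
  fam_seeds <- derive_seeds(config$seed + 1L, length(unique(combos$family)))
  names(fam_seeds) <- unique(combos$family)
  subsamples <- lapply(unique(combos$family), function(f) {
    mod <- family_modality(f)
    cohort <- data[[mod]]$cohort
    have <- rownames(data[[mod]]$features[[f]]$values)
    sub_cohort <- cohort[cohort$subject_id %in% have, , drop = FALSE]
    class(sub_cohort) <- class(cohort)
    bootstrap_subsamples(sub_cohort, match_criteria(),
                         n_replicates = config$n_replicates,
                         seed = fam_seeds[[f]])
  })
  names(subsamples) <- unique(combos$family)

  combo_seeds <- derive_seeds(config$seed + 2L, nrow(combos))
  reports <- lapply(seq_len(nrow(combos)), function(i) {
    combo <- combos[i, ]
    mod <- combo$modality
    feats <- data[[mod]]$features[[combo$family]]
    cohort <- data[[mod]]$cohort
    rep_seeds <- derive_seeds(combo_seeds[i], config$n_replicates)
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      sub <- subsamples[[combo$family]][[r]]
      roster <- subsample_roster(sub, cohort)
      plan <- combo_plan(combo$scheme, roster, config$inner_k, rep_seeds[r])
      fmat <- feats$values[roster$subject_id, , drop = FALSE]
      labels <- roster$group
      names(labels) <- roster$subject_id
      if (combo$classifier == "logistic_simple") {
        spec <- classifier_spec("logistic")
      } else {
        spec <- classifier_spec(combo$classifier)
      }
      pt <- permutation_test_bac(spec, plan,
                                 modality_features(fmat, feats$family),
                                 labels,
                                 n_permutations = config$n_permutations,
                                 seed = rep_seeds[r],
                                 prep = combo_prep(combo, config),
                                 roster = roster)
      list(perf = confusion_metrics(pt$result),
           p_value = pt$p_value,
           train_bac = mean(pt$result$train_bac))
    })
    p_values <- vapply(reps, `[[`, numeric(1), "p_value")
    agg <- aggregate_bootstraps(p_values, config$alpha,
                                config$min_significant_fraction)
    list(family = combo$family, modality = mod,
         manipulation = combo$manipulation, scheme = combo$scheme,
         classifier = combo$classifier,
         replicates = lapply(reps, `[[`, "perf"),
         p_values = p_values,
         train_bacs = vapply(reps, `[[`, numeric(1), "train_bac"),
         n_significant = agg$n_significant, decision = agg$decision)
  })
  admitted <- multimodal_gate(reports)
  out <- structure(list(reports = reports, admitted = admitted,
                        combinations = combos, config = config),
                   class = "grid_result")
  if (!is.null(config$output_dir)) write_grid_outputs(out)
  out
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result: %d combinations, %d significant; %s>\n",
              length(x$reports),
              sum(vapply(x$reports, `[[`, logical(1), "decision")),
              attr(x$admitted, "message")))
  invisible(x)
}

write_grid_outputs <- function(result) {
  dir.create(result$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (rep in result$reports) {
    tab <- format_performance_table(rep$replicates, rep$p_values,
                                    result$config$alpha)
    write_tsv(tab, file.path(result$config$output_dir,
                             sprintf("results_%s_%s_%s.tsv", rep$family,
                                     rep$manipulation, rep$scheme)))
  }
  manifest <- list(
    seed = result$config$seed,
    n_replicates = result$config$n_replicates,
    n_permutations = result$config$n_permutations,
    alpha = result$config$alpha,
    combinations = result$combinations,
    decisions = lapply(result$reports, function(r) {
      list(family = r$family, manipulation = r$manipulation,
           scheme = r$scheme, p_values = r$p_values,
           n_significant = r$n_significant, decision = r$decision)
    }),
    admitted = as.character(result$admitted),
    gate_message = attr(result$admitted, "message"))
  jsonlite::write_json(manifest,
                       file.path(result$config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(result)
}

#' Write the synthetic inputs of a preset to TSV files
#'
#' Convenience generator for the delimited-text interfaces: a phenotype
#' table and the per-family feature/dosage/weight/exposure tables for one
#' modality preset.
#'
#' @param preset `"paper-smri"`, `"paper-genetic"` or `"paper-environment"`.
#' @param dir output directory.
#' @param seed integer seed.
#' @param effect an [effect_spec()].
#' @param voxel_scale,n_snps scale parameters.
#' @return invisibly, the vector of written paths.
#' @export
simulate_preset <- function(preset, dir, seed = 1L, effect = effect_spec(),
                            voxel_scale = 2000L, n_snps = 500L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(name) file.path(dir, name)
  if (preset == "paper-smri") {
    co <- generate_cohort(23, 76, seed = seed)
    write_phenotype_tsv(co, put("phenotype.tsv"))
    fams <- generate_smri_features(co, effect, voxel_scale = voxel_scale)
    for (f in names(fams)) {
      write_features_tsv(fams[[f]], put(sprintf("features_%s.tsv", f)))
    }
    paths <- c(put("phenotype.tsv"),
               put(sprintf("features_%s.tsv", names(fams))))
  } else if (preset == "paper-genetic") {
    co <- generate_cohort(21, 54, seed = seed)
    write_phenotype_tsv(co, put("phenotype.tsv"))
    gt <- generate_genotypes(co, n_snps = n_snps, effect = effect)
    write_dosage_tsv(gt$dosages, put("dosages.tsv"))
    write_weight_tsv(gt$weights, put("weights.tsv"))
    write_weight_tsv(synthetic_eqtl_panel(gt$weights$snp_id, seed = seed),
                     put("eqtl_weights.tsv"))
    paths <- put(c("phenotype.tsv", "dosages.tsv", "weights.tsv",
                   "eqtl_weights.tsv"))
  } else if (preset == "paper-environment") {
    co <- generate_cohort(37, 97, seed = seed)
    write_phenotype_tsv(co, put("phenotype.tsv"))
    write_exposure_tsv(generate_exposures(co, effect = effect),
                       put("exposures.tsv"))
    paths <- put(c("phenotype.tsv", "exposures.tsv"))
  } else {
    stop(sprintf("unknown preset '%s'", preset), call. = FALSE)
  }
  invisible(paths)
}
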