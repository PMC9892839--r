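# Shared fixtures: small synthetic cohorts and ready-made nested-CV setups.

make_cohort_df <- function(transition, protocol, age, sex) {
  out <- data.frame(
    subject_id = sprintf("X%03d", seq_along(transition)),
    age_years = age, sex = sex, protocol = protocol,
    transition = transition,
    followup_years = ifelse(transition == "NT", 3, 1),
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# A balanced LPO setup on a generated cohort: roster, labels, plan and the
# TIV-normalised regional gray-matter features.
lpo_setup <- function(seed, n_informative = 0, d = 0, n_T = 23, n_NT = 76) {
  seeds <- seed * 13L + 0:3
  co <- generate_cohort(n_T, n_NT, seed = seeds[1])
  sub <- balance_subsample(co, seed = seeds[2])
  roster <- subsample_roster(sub, co)
  fams <- generate_smri_features(co, effect_spec(n_informative, d, seeds[3]),
                                 voxel_scale = 10)
  X <- scale_to_tiv(fams$ROIGM)$values[roster$subject_id, , drop = FALSE]
  labels <- stats::setNames(roster$group, roster$subject_id)
  plan <- build_lpo_plan(roster, seed = seeds[4])
  list(cohort = co, roster = roster, X = X, labels = labels, plan = plan)
}

observed_bac <- function(result) {
  p <- result$predictions
  mean(c(mean(p$predicted_label[p$true_label == "T"] == "T"),
         mean(p$predicted_label[p$true_label == "NT"] == "NT")))
}
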