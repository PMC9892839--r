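dos_fixture <- function(n = 4, snps = c("rs1", "rs2", "rs3"), seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * length(snps), replace = TRUE), n,
              dimnames = list(sprintf("P%02d", 1:n), snps))
  w <- data.frame(snp_id = snps,
                  effect_allele = c("A", "C", "G")[seq_along(snps)],
                  weight = c(0.1, -0.2, 0.3)[seq_along(snps)],
                  p_value = c(1e-6, 0.02, 0.5)[seq_along(snps)],
                  stringsAsFactors = FALSE)
  list(d = d, w = w)
}

test_that("polygenic score is the weighted dosage sum", {
  f <- dos_fixture()
  d <- f$d
  d["P01", ] <- c(1, 2, 0)
  s <- compute_prs(d, f$w)
  expect_equal(unname(s["P01"]), 1 * 0.1 + 2 * (-0.2) + 0 * 0.3)
  d0 <- d; d0[] <- 0
  expect_equal(unname(compute_prs(d0, f$w)), rep(0, 4))
  # linearity in the weights
  w2 <- f$w; w2$weight <- 2 * w2$weight
  expect_equal(compute_prs(d, w2), 2 * compute_prs(d, f$w))
  # permuting SNP columns never changes a score
  expect_equal(compute_prs(d[, c(3, 1, 2)], f$w), compute_prs(d, f$w))
  # thresholding at 1 is a no-op
  expect_equal(compute_prs(d, f$w, p_threshold = 1), compute_prs(d, f$w))
  expect_equal(unname(compute_prs(d, f$w, p_threshold = 1e-3)["P01"]), 0.1)
  expect_error(compute_prs(d, f$w, p_threshold = 1e-12), "empty")
  bad <- d; bad[1, 1] <- 3
  expect_error(compute_prs(bad, f$w), "0, 1, 2")
})

test_that("scores equal an independent per-subject loop oracle", {
  set.seed(2)
  snps <- sprintf("rs%03d", 1:30)
  d <- matrix(sample(0:2, 100 * 30, replace = TRUE), 100,
              dimnames = list(sprintf("S%03d", 1:100), snps))
  w <- data.frame(snp_id = snps, effect_allele = "A",
                  weight = stats::rnorm(30), stringsAsFactors = FALSE)
  s <- compute_prs(d, w)
  for (i in sample(100, 100)) {
    acc <- 0
    for (j in seq_along(snps)) acc <- acc + d[i, j] * w$weight[j]
    expect_equal(unname(s[i]), acc)
  }
})

test_that("missing dosages are MAF-imputed or skipped with a warning", {
  f <- dos_fixture()
  d <- f$d
  d["P02", "rs2"] <- NA
  w_maf <- f$w
  w_maf$maf <- c(0.2, 0.4, 0.1)
  s <- compute_prs(d, w_maf)
  manual <- sum(c(d["P02", "rs1"], 2 * 0.4, d["P02", "rs3"]) * f$w$weight)
  expect_equal(unname(s["P02"]), manual)
  expect_warning(compute_prs(d, f$w), "skipped")
})

test_that("per-gene eQTL scores follow the same contract, 141 genes by default", {
  set.seed(3)
  snps <- sprintf("rs%04d", 1:200)
  d <- matrix(sample(0:2, 20 * 200, replace = TRUE), 20,
              dimnames = list(sprintf("S%02d", 1:20), snps))
  panel <- synthetic_eqtl_panel(snps, seed = 4)
  sc <- compute_egen_score(d, panel)
  expect_equal(ncol(sc), 141)
  expect_equal(rownames(sc), rownames(d))
  # single-SNP gene: dosage 2, weight 0.5 -> 1
  one <- data.frame(snp_id = "rs0001", effect_allele = "A", weight = 0.5,
                    gene_id = "G1", stringsAsFactors = FALSE)
  d1 <- matrix(2, 1, 1, dimnames = list("S1", "rs0001"))
  expect_equal(unname(compute_egen_score(d1, one)[1, 1]), 1.0)
  # all-zero weights give a zero score for every subject
  zero <- panel[panel$gene_id == panel$gene_id[1], ]
  zero$weight <- 0
  expect_true(all(compute_egen_score(d, zero) == 0))
})

test_that("the missingness filter implements the fewer-than-two rule", {
  ex <- data.frame(subject_id = c("A", "B", "C"),
                   tobacco = c(1, NA, NA), cannabis = c(0, NA, 1),
                   migrant = 0, ethnic_minority = 0, urbanicity = 1,
                   parental_age = 0, childhood_trauma = c(1, 0, NA),
                   season_of_birth = 0, stringsAsFactors = FALSE)
  expect_equal(filter_exposure_missingness(ex), "A")          # <2 missing
  ex$cannabis[2] <- 1
  expect_setequal(filter_exposure_missingness(ex), c("A", "B"))
  expect_setequal(filter_exposure_missingness(ex, max_missing = 8),
                  c("A", "B", "C"))
})

test_that("environmental risk score is additive in log relative risks", {
  w <- default_exposure_weights()
  ref <- data.frame(subject_id = "R", tobacco = 0, cannabis = 0, migrant = 0,
                    ethnic_minority = 0, urbanicity = 0, parental_age = 0,
                    childhood_trauma = 0, season_of_birth = 0,
                    stringsAsFactors = FALSE)
  expect_equal(unname(compute_ers(ref, w)), 0)
  # a single cannabis exposure at relative risk 2 contributes log 2
  w2 <- w
  w2$cannabis <- log(c("0" = 1, "1" = 2, "2" = 4))
  one <- ref; one$cannabis <- 1
  expect_equal(unname(compute_ers(one, w2)), log(2))
  # two independent factors add on the log scale
  w2$migrant <- log(c("0" = 1, "1" = 1.5))
  two <- one; two$migrant <- 1
  expect_equal(unname(compute_ers(two, w2)), log(2) + log(1.5))
  # missing factors contribute the population average, i.e. zero
  mis <- one; mis$childhood_trauma <- NA
  expect_equal(compute_ers(mis, w2), compute_ers(one, w2))
  bad <- one; bad$urbanicity <- 7
  expect_error(compute_ers(bad, w2), "absent from the weight table")
})

test_that("score tables round-trip through the TSV writer", {
  prs <- c(A = 0.5, B = -0.2)
  ers <- c(A = 1.1, B = 0)
  tmp <- file.path(tempdir(), "scores.tsv")
  write_scores_tsv(tmp, prs = prs, ers = ers)
  back <- utils::read.delim(tmp)
  expect_equal(back$prs, unname(prs))
  expect_equal(back$ers, unname(ers))
  unlink(tmp)
})
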