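sim_cc <- function(n_case, n_control, maf, or, seed) {
  # retrospective case-control draw used only inside tests
  snps <- data.frame(snp_id = "rsX", maf = maf, chromosome = "1",
                     position = 1000)
  gd <- simulate_genotypes(population_spec(
    ceiling(3 * (n_case + n_control)), snps, seed = seed))
  gd <- assign_phenotypes(gd, disease_model(0, c(rsX = log(or))),
                          seed = seed + 1)
  keep <- c(which(gd$phenotype == 1)[seq_len(n_case)],
            which(gd$phenotype == 0)[seq_len(n_control)])
  gd$genotypes <- gd$genotypes[keep, , drop = FALSE]
  gd$phenotype <- gd$phenotype[keep]
  gd$sample_ids <- gd$sample_ids[keep]
  rownames(gd$genotypes) <- gd$sample_ids
  gd
}

test_that("genotype QC flags monomorphic, HWE-failing and low-call markers", {
  set.seed(49)
  G <- cbind(mono = rep(0L, 100),
             hwe = c(rep(0L, 25), rep(2L, 25), rep(0L, 25), rep(2L, 25)),
             lowcall = c(rep(NA_integer_, 50), rep(1L, 25), rep(0L, 25)),
             good = rbinom(100, 2, 0.5))
  ph <- rep(c(1L, 0L), 50)
  gd <- genotype_dataset(G, phenotype = ph)
  qc <- genotype_qc(gd, hwe_alpha = 1e-3, call_rate_min = 0.9)
  rep_ <- qc$report
  expect_true(rep_$monomorphic[rep_$snp_id == "mono"])
  expect_true(rep_$hwe_fail[rep_$snp_id == "hwe"])
  expect_true(rep_$low_call_rate[rep_$snp_id == "lowcall"])
  expect_false(rep_$excluded[rep_$snp_id == "good"])
  expect_equal(colnames(qc$filtered$genotypes), "good")
  expect_error(genotype_qc(genotype_dataset(G, phenotype = rep(1L, 100))),
               "no controls")
})

test_that("QC never passes a SNP whose control HWE p is below threshold", {
  set.seed(50)
  for (i in 1:10) {
    G <- matrix(rbinom(400, 2, runif(4, 0.1, 0.5)), 100, 4,
                dimnames = list(NULL, sprintf("s%d", 1:4)))
    ph <- rep(c(0L, 1L), 50)
    gd <- genotype_dataset(G, phenotype = ph)
    qc <- genotype_qc(gd, hwe_alpha = 0.5)  # deliberately aggressive alpha
    for (s in colnames(qc$filtered$genotypes)) {
      g <- G[ph == 0, s]
      p <- hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p_value
      expect_gte(p, 0.5)
    }
  }
})

test_that("log-additive fit matches the direct Newton ML oracle", {
  gd <- sim_cc(20, 20, 0.3, 1.8, seed = 51)
  fit <- fit_log_additive(gd, "rsX")
  orc <- oracle_logistic_newton(gd$genotypes[, "rsX"], gd$phenotype)
  expect_equal(fit$beta1, orc$beta[2], tolerance = 1e-6)
  expect_equal(fit$se, orc$se[2], tolerance = 1e-6)
  # OR and CI are exact transforms of beta1 and its SE
  expect_equal(fit$odds_ratio, exp(fit$beta1))
  expect_equal(fit$ci_low, exp(fit$beta1 - 1.96 * fit$se))
  expect_equal(fit$ci_high, exp(fit$beta1 + 1.96 * fit$se))
})

test_that("balanced null genotypes give OR near 1; separation is structured", {
  G <- matrix(rep(c(0L, 1L, 2L), 40), 120, 1, dimnames = list(NULL, "s"))
  gd <- genotype_dataset(G, phenotype = rep(c(1L, 0L), 60))
  # identical dosage distribution in both classes by construction
  gd$genotypes[, 1] <- rep(c(0L, 0L, 1L, 1L, 2L, 2L), 20)
  fit <- fit_log_additive(gd, "s")
  expect_equal(fit$beta1, 0, tolerance = 1e-8)
  expect_equal(fit$odds_ratio, 1, tolerance = 1e-8)
  expect_equal(fit$p_value, 1, tolerance = 1e-6)

  Gs <- matrix(c(rep(2L, 30), rep(0L, 30)), 60, 1,
               dimnames = list(NULL, "s"))
  sep <- fit_log_additive(genotype_dataset(Gs, phenotype = rep(c(1L, 0L),
                                                               each = 30)),
                          "s")
  expect_equal(sep$status, "separation")
  expect_true(is.na(sep$p_value))

  mono <- fit_log_additive(genotype_dataset(
    matrix(1L, 10, 1, dimnames = list(NULL, "s")),
    phenotype = rep(c(0L, 1L), 5)), "s")
  expect_equal(mono$status, "not_estimable")
})

test_that("Wald p agrees with the Cochran-Armitage trend test asymptotically", {
  # moderate effect so both p-values sit away from the extreme tail, where
  # the Wald and score approximations genuinely coincide
  gd <- sim_cc(1000, 1000, 0.3, 1.15, seed = 52)
  fit <- fit_log_additive(gd, "rsX")
  tab <- table(factor(gd$phenotype, 0:1), factor(gd$genotypes[, 1], 0:2))
  tt <- stats::prop.trend.test(tab[2, ], colSums(tab), score = 0:2)
  ratio <- fit$p_value / tt$p.value
  expect_gt(ratio, 1 / 1.2)
  expect_lt(ratio, 1.2)
})

test_that("dataset combination concatenates individuals over shared SNPs", {
  d1 <- sim_cc(94, 135, 0.3, 1.0, seed = 53); d1$label <- "discovery"
  d2 <- sim_cc(100, 425, 0.3, 1.0, seed = 54); d2$label <- "replication"
  d2$sample_ids <- paste0("r_", d2$sample_ids)
  rownames(d2$genotypes) <- d2$sample_ids
  comb <- combine_datasets(d1, d2)
  expect_equal(sum(comb$phenotype == 1), 194)
  expect_equal(sum(comb$phenotype == 0), 560)
  expect_equal(comb$label, "combined")

  empty <- genotype_dataset(matrix(integer(0), 0, 1,
                                   dimnames = list(NULL, "rsX")),
                            phenotype = integer(0))
  expect_equal(nrow(combine_datasets(d1, empty)$genotypes),
               nrow(d1$genotypes))

  expect_error(combine_datasets(d1, d1), "overlapping sample ids")
  d3 <- d2
  d3$counted_allele[] <- "A"
  expect_error(combine_datasets(d1, d3), "counted-allele mismatch")
})

test_that("combined allele frequencies are allele-count-weighted means", {
  expect_equal(round(pooled_allele_freq(0.429, 94, 0.389, 100), 3), 0.408)
  expect_equal(round(pooled_allele_freq(0.301, 135, 0.300, 425), 3), 0.300)
  expect_equal(round(pooled_allele_freq(0.120, 94, 0.195, 100), 3), 0.159)
  expect_equal(pooled_allele_freq(0.2, 50, 0.4, 50), 0.3)
  expect_error(pooled_allele_freq(0.5, 0, 0.5, 10), "> 0")
})

test_that("Bonferroni threshold is alpha over the number of tests", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("concordance classifies replication patterns", {
  res <- data.frame(
    snp_id = rep(c("same", "opp", "weak"), 2),
    dataset = rep(c("discovery", "replication"), each = 3),
    beta1 = c(log(1.88), log(0.45), log(1.4),
              log(1.50), log(1.58), log(1.1)),
    p_value = c(0.004, 0.001, 0.03, 0.015, 0.007, 0.5),
    odds_ratio = c(1.88, 0.45, 1.4, 1.50, 1.58, 1.1),
    status = "ok", stringsAsFactors = FALSE)
  cc <- concordance_report(res)
  cls <- setNames(cc$classification, cc$snp_id)
  expect_equal(unname(cls["same"]), "replicated_same_direction")
  expect_equal(unname(cls["opp"]), "significant_opposite_directions")
  expect_equal(unname(cls["weak"]), "not_replicated")
})

test_that("fitted OR recovers the generative per-allele effect at large n", {
  gd <- sim_cc(5000, 5000, 0.3, 1.65, seed = 55)
  fit <- fit_log_additive(gd, "rsX")
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$beta1 - log(1.65)), 3 * fit$se)
})
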