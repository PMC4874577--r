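snp_df <- function(maf, n = length(maf)) {
  data.frame(snp_id = sprintf("snp%d", seq_len(n)), maf = maf,
             chromosome = "1", position = seq_len(n) * 1000)
}

test_that("genotypes follow Hardy-Weinberg proportions and degenerate limits", {
  gd <- simulate_genotypes(population_spec(10000, snp_df(0.5), seed = 1))
  props <- as.numeric(table(factor(gd$genotypes[, 1], 0:2))) / 10000
  se <- sqrt(c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)) / 10000)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))

  gd0 <- simulate_genotypes(population_spec(100, snp_df(1e-6), seed = 2))
  expect_true(all(gd0$genotypes == 0))

  expect_error(population_spec(10, snp_df(0.7)), "maf")
  expect_error(population_spec(10, snp_df(0)), "maf")
})

test_that("haplotype blocks reproduce the specified LD", {
  snps <- snp_df(c(0.5, 0.5), 2)
  blk <- data.frame(snp1 = c(1, 0), snp2 = c(1, 0), freq = c(0.5, 0.5))
  gd <- simulate_genotypes(population_spec(2000, snps, ld_blocks = list(blk),
                                           seed = 3))
  expect_equal(pairwise_r2(gd$genotypes[, 1], gd$genotypes[, 2]), 1.0)
  # block frequencies must sum to one
  bad <- data.frame(snp1 = c(1, 0), snp2 = c(1, 0), freq = c(0.6, 0.5))
  expect_error(population_spec(10, snps, ld_blocks = list(bad)), "sum to 1")
})

test_that("phenotype assignment follows the logistic disease model", {
  gd <- simulate_genotypes(population_spec(10000, snp_df(0.3), seed = 4))
  null_gd <- assign_phenotypes(gd, disease_model(0), seed = 5)
  expect_lt(abs(mean(null_gd$phenotype) - 0.5), 3 * sqrt(0.25 / 10000))

  none <- assign_phenotypes(gd, disease_model(-50), seed = 6)
  expect_equal(sum(none$phenotype), 0)

  # per-dosage empirical odds recover exp(effect) within 3 SE
  big <- simulate_genotypes(population_spec(50000, snp_df(0.3), seed = 7))
  big <- assign_phenotypes(big, disease_model(-1, c(snp1 = log(1.65))),
                           seed = 8)
  tab <- table(factor(big$genotypes[, 1], 0:2), factor(big$phenotype, 0:1))
  log_or_01 <- log(tab["1", "1"] * tab["0", "0"] /
                     (tab["1", "0"] * tab["0", "1"]))
  se_01 <- sqrt(1 / tab["1", "1"] + 1 / tab["0", "0"] +
                  1 / tab["1", "0"] + 1 / tab["0", "1"])
  expect_lt(abs(log_or_01 - log(1.65)), 3 * se_01)
})

test_that("sample quantification QC applies the replicate-SD and volume rules", {
  masses <- matrix(100, 10, 3, dimnames = list(sprintf("S%d", 1:10), NULL))
  vols <- rep(4, 10)
  qc <- sample_quant_qc(masses, vols)
  expect_length(qc$excluded, 0)

  masses2 <- masses
  masses2[3, ] <- c(80, 100, 120)  # SD 20 >> 3% of mean
  qc2 <- sample_quant_qc(masses2, vols)
  expect_equal(qc2$reasons$sample_id, "S3")
  expect_equal(qc2$reasons$reason, "replicate_sd")

  # volume outlier: direct evaluation of the 2-SD-from-median rule
  vols3 <- c(rep(4, 9), 10)
  expect_gt(abs(10 - median(vols3)), 2 * sd(vols3))
  qc3 <- sample_quant_qc(masses, vols3)
  expect_equal(qc3$reasons$reason, "volume_outlier")
  expect_equal(qc3$reasons$sample_id, "S10")

  expect_error(sample_quant_qc(matrix(100, 2, 1), c(1, 2)), "replicates")
})

test_that("pool frequencies are mass-weighted dosage averages", {
  G <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(NULL, "snp1"))
  gd <- genotype_dataset(G)
  ps <- pool_spec("case", n_bio_replicates = 2, mass_cv = 0)
  pools <- build_pools(gd, gd$sample_ids, ps, seed = 1)
  expect_identical(unname(pools[, "snp1"]), c(0.5, 0.5))

  G2 <- matrix(2L, 4, 1, dimnames = list(NULL, "snp1"))
  pools2 <- build_pools(genotype_dataset(G2), sprintf("S%d", 1:4),
                        pool_spec("case", mass_cv = 0.3), seed = 2)
  expect_true(all(pools2 == 1))

  expect_error(build_pools(gd, character(0), ps), "empty")

  # Monte-Carlo: with mass noise the mean pool frequency tracks the cohort
  gd3 <- simulate_genotypes(population_spec(100, snp_df(0.3), seed = 9))
  cohort <- mean(gd3$genotypes[, 1]) / 2
  ps3 <- pool_spec("case", n_bio_replicates = 200, mass_cv = 0.05)
  pools3 <- build_pools(gd3, gd3$sample_ids, ps3, seed = 10)
  expect_lt(abs(mean(pools3[, 1]) - cohort), 0.01)
})

test_that("pool membership must match the pool's group", {
  G <- matrix(1L, 4, 1, dimnames = list(NULL, "snp1"))
  gd <- genotype_dataset(G, phenotype = c(1, 1, 0, 0))
  expect_error(build_pools(gd, gd$sample_ids, pool_spec("case")),
               "inconsistent")
  p <- build_pools(gd, gd$sample_ids[1:2], pool_spec("case", mass_cv = 0))
  expect_equal(unname(p[1, 1]), 0.5)
})

test_that("noise-free symmetric intensities collapse to the pool frequency", {
  am0 <- array_model(gain_sd = 0.2, kappa_A = 1, kappa_B = 1, chi = 0,
                     mm_level = 0, noise_sd = 0, array_effect_sd = 0.1)
  q <- simulate_intensities(list(case = freq_matrix(0.7, "s1"),
                                 control = freq_matrix(0.7, "s1")),
                            am0, pool_spec("case"), seed = 11)
  ras <- quartet_ras(q$PM_A, q$MM_A, q$PM_B, q$MM_B)
  expect_equal(ras, rep(0.7, nrow(q)), tolerance = 1e-12)

  q0 <- simulate_intensities(list(case = freq_matrix(0, "s1"),
                                  control = freq_matrix(0, "s1")),
                             am0, pool_spec("case"), seed = 12)
  expect_equal(quartet_ras(q0$PM_A, q0$MM_A, q0$PM_B, q0$MM_B),
               rep(0, nrow(q0)), tolerance = 1e-12)

  # asymmetric affinities bias RAS exactly as the generative formula says
  am_bias <- array_model(gain_sd = 0, kappa_A = 1.2, kappa_B = 0.8, chi = 0,
                         mm_level = 0, noise_sd = 0, array_effect_sd = 0)
  qb <- simulate_intensities(list(case = freq_matrix(0.5, "s1"),
                                  control = freq_matrix(0.5, "s1")),
                             am_bias, pool_spec("case"), seed = 13)
  expect_equal(quartet_ras(qb$PM_A, qb$MM_A, qb$PM_B, qb$MM_B),
               rep(0.6, nrow(qb)), tolerance = 1e-12)
})

test_that("generators are bit-reproducible for a fixed seed", {
  spec <- population_spec(50, snp_df(runif(20, 0.1, 0.5)), seed = 14)
  expect_identical(simulate_genotypes(spec), simulate_genotypes(spec))

  gd <- simulate_genotypes(spec)
  p1 <- build_pools(gd, gd$sample_ids, pool_spec("case"), seed = 15)
  p2 <- build_pools(gd, gd$sample_ids, pool_spec("case"), seed = 15)
  expect_identical(p1, p2)

  pools <- list(case = p1, control = p1)
  q1 <- simulate_intensities(pools, array_model(), pool_spec("case"), seed = 16)
  q2 <- simulate_intensities(pools, array_model(), pool_spec("case"), seed = 16)
  expect_identical(q1, q2)
})
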