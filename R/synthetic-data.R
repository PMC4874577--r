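# Synthetic data generation: case-control genotypes under a logistic disease
# model, equimolar DNA pooling with per-sample mass noise, and probe-intensity
# generation whose expected RAS tracks the pool allele frequency.

#' Specify a simulated population
#'
#' @param n_individuals number of individuals to simulate
#' @param snps data.frame with columns `snp_id`, `maf` (in (0, 0.5]),
#'   `chromosome`, `position` (1-based bp, strictly increasing within each
#'   chromosome)
#' @param ld_blocks optional list of haplotype-frequency tables. Each element
#'   is a data.frame whose first columns are named after >= 2 SNP ids of
#'   `snps` (allele codes 0/1 per haplotype) plus a `freq` column summing to 1.
#'   SNPs in blocks are drawn jointly from the haplotypes; all other SNPs are
#'   drawn independently under Hardy-Weinberg equilibrium.
#' @param seed integer seed used by [simulate_genotypes()]
#' @return an object of class `population_spec`
#' @export
population_spec <- function(n_individuals, snps, ld_blocks = NULL, seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stopf("`n_individuals` must be >= 1")
  req <- c("snp_id", "maf", "chromosome", "position")
  if (!is.data.frame(snps) || !all(req %in% names(snps)))
    stopf("`snps` must be a data.frame with columns %s",
          paste(req, collapse = ", "))
  if (anyDuplicated(snps$snp_id)) stopf("duplicated snp_id in `snps`")
  if (!is.numeric(snps$maf) || any(!is.finite(snps$maf)) ||
      any(snps$maf <= 0) || any(snps$maf > 0.5))
    stopf("`maf` must be finite and in (0, 0.5]")
  for (ch in unique(snps$chromosome)) {
    pos <- snps$position[snps$chromosome == ch]
    if (any(diff(pos) <= 0))
      stopf("positions must be strictly increasing within chromosome %s", ch)
  }
  if (!is.null(ld_blocks)) {
    for (blk in ld_blocks) {
      ids <- setdiff(names(blk), "freq")
      if (length(ids) < 2L || !"freq" %in% names(blk))
        stopf("each LD block needs >= 2 SNP columns and a `freq` column")
      if (!all(ids %in% snps$snp_id))
        stopf("LD block references unknown SNPs: %s",
              paste(setdiff(ids, snps$snp_id), collapse = ", "))
      if (abs(sum(blk$freq) - 1) > 1e-9)
        stopf("haplotype frequencies in an LD block must sum to 1")
      if (!all(unlist(blk[ids]) %in% c(0, 1)))
        stopf("LD block allele codes must be 0/1")
    }
    blk_ids <- unlist(lapply(ld_blocks, function(b) setdiff(names(b), "freq")))
    if (anyDuplicated(blk_ids)) stopf("a SNP appears in two LD blocks")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 snps = as.data.frame(snps), ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Specify a logistic disease model
#'
#' Disease probability for an individual with dosage vector x is
#' `plogis(intercept + sum(effects * x))`; each effect is a per-allele
#' log-odds-ratio on the counted allele of that SNP.
#'
#' @param intercept baseline log-odds of disease
#' @param effects named numeric vector, `snp_id -> log OR per allele`
#' @return an object of class `disease_model`
#' @export
disease_model <- function(intercept = 0, effects = numeric()) {
  if (!is.finite(intercept)) stopf("`intercept` must be finite")
  if (length(effects) && (is.null(names(effects)) || any(!is.finite(effects))))
    stopf("`effects` must be a named finite numeric vector")
  structure(list(intercept = intercept, effects = effects),
            class = "disease_model")
}

#' Specify pool construction and replicate structure
#'
#' Defaults mirror the study design: two biological replicate pools per group,
#' each hybridized in triplicate, 200 ng of DNA contributed per sample.
#'
#' @param group `"case"` or `"control"`
#' @param n_bio_replicates biological replicate pools per group
#' @param n_tech_replicates technical (array) replicates per pool
#' @param target_mass_ng DNA mass contributed per sample (ng)
#' @param mass_cv coefficient of variation of the contributed mass
#'   (log-normal, so masses stay positive)
#' @param quant_cv coefficient of variation of triplicate quantification
#' @return an object of class `pool_spec`
#' @export
pool_spec <- function(group = c("case", "control"), n_bio_replicates = 2L,
                      n_tech_replicates = 3L, target_mass_ng = 200,
                      mass_cv = 0.05, quant_cv = 0.01) {
  group <- match.arg(group)
  if (n_bio_replicates < 1 || n_tech_replicates < 1)
    stopf("replicate counts must be >= 1")
  if (mass_cv < 0 || quant_cv < 0) stopf("CVs must be >= 0")
  if (target_mass_ng <= 0) stopf("`target_mass_ng` must be > 0")
  structure(list(group = group,
                 n_bio_replicates = as.integer(n_bio_replicates),
                 n_tech_replicates = as.integer(n_tech_replicates),
                 target_mass_ng = target_mass_ng,
                 mass_cv = mass_cv, quant_cv = quant_cv),
            class = "pool_spec")
}

#' Specify the generative probe-intensity model
#'
#' A deliberately simple linear-in-frequency model of array hybridization:
#' for pool allele frequency f, a quartet on one array produces
#' `PM_A = G * (kappa_A * f + chi) + e`, `PM_B = G * (kappa_B * (1 - f) + chi) + e`,
#' and mismatch signals around `G * mm_level + e`, all clamped at zero.
#' `G` is a per-quartet multiplicative gain (log-normal, spread `gain_sd`)
#' times a per-array effect (spread `array_effect_sd`). With `chi = mm_level`
#' the mismatch correction removes cross-hybridization in expectation, and
#' with symmetric affinities the expected RAS equals f.
#'
#' @param n_quartets_per_strand probe quartets per strand
#' @param gain_sd log-scale SD of the per-quartet gain
#' @param kappa_A,kappa_B allele probe affinities (> 0); unequal values bias
#'   RAS away from the pool frequency, which is useful for testing
#' @param chi cross-hybridization level added to both PM signals
#' @param mm_level mismatch signal level
#' @param noise_sd additive Gaussian noise SD on every signal
#' @param array_effect_sd log-scale SD of the per-array multiplicative effect
#' @return an object of class `array_model`
#' @export
array_model <- function(n_quartets_per_strand = 3L, gain_sd = 0.15,
                        kappa_A = 1, kappa_B = 1, chi = 0.05,
                        mm_level = 0.05, noise_sd = 0.02,
                        array_effect_sd = 0.10) {
  if (kappa_A <= 0 || kappa_B <= 0) stopf("affinities must be > 0")
  if (any(c(gain_sd, noise_sd, array_effect_sd) < 0))
    stopf("all SDs must be >= 0")
  if (chi < 0 || mm_level < 0) stopf("`chi` and `mm_level` must be >= 0")
  if (n_quartets_per_strand < 1) stopf("need >= 1 quartet per strand")
  structure(list(n_quartets_per_strand = as.integer(n_quartets_per_strand),
                 gain_sd = gain_sd, kappa_A = kappa_A, kappa_B = kappa_B,
                 chi = chi, mm_level = mm_level, noise_sd = noise_sd,
                 array_effect_sd = array_effect_sd),
            class = "array_model")
}

#' Construct a genotype dataset
#'
#' The container used by all individual-genotyping stages: an
#' individuals x SNPs dosage matrix (0/1/2/NA copies of the counted allele),
#' an optional binary phenotype, and the counted allele per SNP.
#'
#' @param genotypes integer matrix, individuals in rows, SNPs in columns;
#'   values 0, 1, 2 or NA; must have column names (SNP ids)
#' @param phenotype optional vector of 0 (control) / 1 (case) per individual
#' @param sample_ids sample identifiers (defaults to rownames or S1..Sn)
#' @param counted_allele character vector (length 1 or one per SNP) naming the
#'   allele whose copies the dosages count
#' @param label dataset label, e.g. `"discovery"`, `"replication"`, `"combined"`
#' @return an object of class `genotype_dataset`
#' @export
genotype_dataset <- function(genotypes, phenotype = NULL, sample_ids = NULL,
                             counted_allele = "B", label = "dataset") {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes))) stopf("`genotypes` needs SNP column names")
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stopf("genotype codes must be 0, 1, 2 or NA")
  storage.mode(genotypes) <- "integer"
  n <- nrow(genotypes)
  sample_ids <- sample_ids %||% rownames(genotypes) %||% sprintf("S%d", seq_len(n))
  if (length(sample_ids) != n) stopf("`sample_ids` length mismatch")
  if (anyDuplicated(sample_ids)) stopf("duplicated sample ids")
  rownames(genotypes) <- sample_ids
  if (!is.null(phenotype)) {
    if (length(phenotype) != n || !all(phenotype %in% c(0L, 1L, NA)))
      stopf("`phenotype` must be 0/1 per individual")
    phenotype <- as.integer(phenotype)
  }
  counted_allele <- rep_len(as.character(counted_allele), ncol(genotypes))
  names(counted_allele) <- colnames(genotypes)
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 sample_ids = sample_ids, counted_allele = counted_allele,
                 label = label),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset '%s': %d individuals x %d SNPs\n",
              x$label, nrow(x$genotypes), ncol(x$genotypes)))
  if (!is.null(x$phenotype))
    cat(sprintf("  cases: %d, controls: %d\n",
                sum(x$phenotype == 1, na.rm = TRUE),
                sum(x$phenotype == 0, na.rm = TRUE)))
  invisible(x)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws dosages independently per SNP as Binomial(2, maf), or jointly from
#' haplotype frequencies for SNPs covered by an LD block. The phenotype is
#' left unset; see [assign_phenotypes()].
#'
#' @param spec a [population_spec()]
#' @return a [genotype_dataset()] with `phenotype = NULL`; dosages count the
#'   minor ("B") allele
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_individuals
  m <- nrow(spec$snps)
  with_seed(spec$seed, {
    G <- matrix(rbinom(n * m, 2L, rep(spec$snps$maf, each = n)), n, m,
                dimnames = list(NULL, spec$snps$snp_id))
    for (blk in spec$ld_blocks %||% list()) {
      ids <- setdiff(names(blk), "freq")
      H <- as.matrix(blk[ids])
      h1 <- sample.int(nrow(H), n, replace = TRUE, prob = blk$freq)
      h2 <- sample.int(nrow(H), n, replace = TRUE, prob = blk$freq)
      G[, ids] <- H[h1, , drop = FALSE] + H[h2, , drop = FALSE]
    }
    genotype_dataset(G, counted_allele = "B", label = "simulated")
  })
}

#' Assign case-control phenotypes under a logistic disease model
#'
#' Each individual becomes a case with probability
#' `plogis(intercept + sum(effects * dosage))`.
#'
#' @param genotypes a [genotype_dataset()]
#' @param model a [disease_model()]
#' @param seed integer seed
#' @return the dataset with `phenotype` filled in
#' @export
assign_phenotypes <- function(genotypes, model, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_dataset"),
            inherits(model, "disease_model"))
  miss <- setdiff(names(model$effects), colnames(genotypes$genotypes))
  if (length(miss))
    stopf("effect SNPs not in dataset: %s", paste(miss, collapse = ", "))
  eta <- rep(model$intercept, nrow(genotypes$genotypes))
  if (length(model$effects)) {
    X <- genotypes$genotypes[, names(model$effects), drop = FALSE]
    if (anyNA(X)) stopf("missing dosages at effect SNPs")
    eta <- eta + as.numeric(X %*% model$effects)
  }
  genotypes$phenotype <- with_seed(seed,
    rbinom(length(eta), 1L, plogis(eta)))
  genotypes
}

#' Sample-level quantification quality control
#'
#' Implements the pooling sample QC: a sample is excluded when the standard
#' deviation of its replicate quantifications exceeds 3% of their mean
#' (reason `"replicate_sd"`), or when its pooled volume lies more than 2
#' standard deviations from the median volume (reason `"volume_outlier"`).
#'
#' @param measured_masses numeric matrix, one row per sample, >= 2 replicate
#'   quantifications per row
#' @param volumes numeric vector of per-sample volumes to be pooled
#' @param sd_frac replicate-SD rule as a fraction of the replicate mean
#' @param volume_sds volume rule in SDs from the median volume
#' @return list with `included` and `excluded` sample indices (named if the
#'   matrix has rownames) and a data.frame `reasons`
#' @export
sample_quant_qc <- function(measured_masses, volumes, sd_frac = 0.03,
                            volume_sds = 2) {
  measured_masses <- as.matrix(measured_masses)
  if (nrow(measured_masses) < 1) stopf("need >= 1 sample")
  if (ncol(measured_masses) < 2) stopf("need >= 2 replicates per sample")
  if (length(volumes) != nrow(measured_masses))
    stopf("`volumes` must have one value per sample")
  ids <- rownames(measured_masses) %||% sprintf("S%d", seq_len(nrow(measured_masses)))
  rep_sd <- apply(measured_masses, 1, sd)
  rep_mean <- rowMeans(measured_masses)
  bad_rep <- rep_sd > sd_frac * rep_mean
  v_sd <- sd(volumes)
  bad_vol <- if (is.na(v_sd) || v_sd == 0) rep(FALSE, length(volumes))
             else abs(volumes - median(volumes)) > volume_sds * v_sd
  reason <- ifelse(bad_rep, "replicate_sd",
                   ifelse(bad_vol, "volume_outlier", NA_character_))
  excluded <- which(bad_rep | bad_vol)
  list(included = ids[setdiff(seq_along(ids), excluded)],
       excluded = ids[excluded],
       reasons = data.frame(sample_id = ids[excluded],
                            reason = reason[excluded],
                            stringsAsFactors = FALSE))
}

#' Build DNA pools from individual genotypes
#'
#' Each biological replicate pool combines the members' DNA in nominally
#' equimolar amounts; the realized per-sample mass is log-normal around the
#' target with coefficient of variation `mass_cv`. The pool allele frequency
#' of a SNP is the mass-weighted dosage sum over members divided by twice the
#' total mass. With `mass_cv = 0` this is exactly the cohort allele frequency.
#'
#' @param genotypes a [genotype_dataset()]
#' @param members sample ids to pool
#' @param poolspec a [pool_spec()]
#' @param seed integer seed
#' @return matrix of pool allele frequencies, `n_bio_replicates` rows x SNP
#'   columns, with attribute `group`
#' @export
build_pools <- function(genotypes, members, poolspec, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_dataset"),
            inherits(poolspec, "pool_spec"))
  if (length(members) == 0) stopf("empty member set")
  if (!all(members %in% genotypes$sample_ids))
    stopf("unknown members: %s",
          paste(setdiff(members, genotypes$sample_ids), collapse = ", "))
  if (!is.null(genotypes$phenotype)) {
    ph <- genotypes$phenotype[match(members, genotypes$sample_ids)]
    want <- if (poolspec$group == "case") 1L else 0L
    if (any(ph != want, na.rm = TRUE))
      stopf("members' phenotypes are inconsistent with group '%s'",
            poolspec$group)
  }
  G <- genotypes$genotypes[members, , drop = FALSE]
  if (anyNA(G)) stopf("pooled members must have complete genotypes")
  nb <- poolspec$n_bio_replicates
  with_seed(seed, {
    freqs <- matrix(NA_real_, nb, ncol(G),
                    dimnames = list(sprintf("bio%d", seq_len(nb)), colnames(G)))
    for (b in seq_len(nb)) {
      if (poolspec$mass_cv > 0) {
        sdlog <- sqrt(log1p(poolspec$mass_cv^2))
        w <- rlnorm(nrow(G), log(poolspec$target_mass_ng) - sdlog^2 / 2, sdlog)
      } else {
        w <- rep(poolspec$target_mass_ng, nrow(G))
      }
      freqs[b, ] <- as.numeric(crossprod(G, w)) / (2 * sum(w))
    }
    structure(freqs, group = poolspec$group)
  })
}

#' Simulate probe-quartet intensities for replicate pooled arrays
#'
#' Generates the full quartet table for `2 x n_bio x n_tech` arrays (cases and
#' controls), both strands, under an [array_model()]. Expected RAS equals the
#' pool allele frequency when affinities are symmetric and `chi = mm_level`.
#'
#' @param pool_freqs named list with elements `case` and `control`, each a
#'   matrix as returned by [build_pools()] (biological replicates x SNPs,
#'   identical SNP columns)
#' @param arraymodel an [array_model()]
#' @param poolspec a [pool_spec()] (supplies `n_tech_replicates`)
#' @param seed integer seed
#' @return data.frame of intensity quartets with columns `snp_id`, `strand`,
#'   `quartet_index`, `array_id`, `group`, `PM_A`, `MM_A`, `PM_B`, `MM_B`
#' @export
simulate_intensities <- function(pool_freqs, arraymodel = array_model(),
                                 poolspec = pool_spec("case"), seed = 1L) {
  stopifnot(inherits(arraymodel, "array_model"),
            inherits(poolspec, "pool_spec"))
  if (!all(c("case", "control") %in% names(pool_freqs)))
    stopf("`pool_freqs` must have elements `case` and `control`")
  snps <- colnames(pool_freqs$case)
  if (is.null(snps) || !identical(snps, colnames(pool_freqs$control)))
    stopf("case and control pools must cover the same SNPs")
  for (g in c("case", "control")) assert_prob(pool_freqs[[g]], g)

  nt <- poolspec$n_tech_replicates
  nq <- arraymodel$n_quartets_per_strand
  arrays <- do.call(rbind, lapply(c("case", "control"), function(g) {
    nb <- nrow(pool_freqs[[g]])
    expand.grid(tech = seq_len(nt), bio = seq_len(nb), group = g,
                stringsAsFactors = FALSE)
  }))
  arrays$array_id <- sprintf("%s_b%d_t%d", arrays$group, arrays$bio, arrays$tech)

  m <- length(snps)
  na <- nrow(arrays)
  # row order: snp (slowest) x strand x quartet x array (fastest)
  idx_snp <- rep(seq_len(m), each = 2L * nq * na)
  idx_strand <- rep(rep(c("sense", "antisense"), each = nq * na), times = m)
  idx_q <- rep(rep(seq_len(nq), each = na), times = 2L * m)
  idx_arr <- rep(seq_len(na), times = 2L * nq * m)
  R <- length(idx_snp)

  with_seed(seed, {
    arr_eff <- if (arraymodel$array_effect_sd > 0)
      rlnorm(na, 0, arraymodel$array_effect_sd) else rep(1, na)
    fc <- t(pool_freqs$case); fn <- t(pool_freqs$control)
    f <- numeric(R)
    is_case <- arrays$group[idx_arr] == "case"
    f[is_case] <- fc[cbind(idx_snp[is_case], arrays$bio[idx_arr[is_case]])]
    f[!is_case] <- fn[cbind(idx_snp[!is_case], arrays$bio[idx_arr[!is_case]])]

    G <- arr_eff[idx_arr]
    if (arraymodel$gain_sd > 0) G <- G * rlnorm(R, 0, arraymodel$gain_sd)
    noise <- function() if (arraymodel$noise_sd > 0)
      rnorm(R, 0, arraymodel$noise_sd) else 0
    pm_a <- pmax(G * (arraymodel$kappa_A * f + arraymodel$chi) + noise(), 0)
    pm_b <- pmax(G * (arraymodel$kappa_B * (1 - f) + arraymodel$chi) + noise(), 0)
    mm_a <- pmax(G * arraymodel$mm_level + noise(), 0)
    mm_b <- pmax(G * arraymodel$mm_level + noise(), 0)
    data.frame(snp_id = snps[idx_snp], strand = idx_strand,
               quartet_index = idx_q, array_id = arrays$array_id[idx_arr],
               group = arrays$group[idx_arr],
               PM_A = pm_a, MM_A = mm_a, PM_B = pm_b, MM_B = mm_b,
               stringsAsFactors = FALSE)
  })
}
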