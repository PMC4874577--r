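# Individual-genotyping stages: marker QC, log-additive logistic association
# with odds ratios and confidence intervals, dataset combination, Bonferroni
# correction and cross-dataset concordance.

#' Marker quality control on an individual-genotype dataset
#'
#' Flags monomorphic markers, markers whose genotype distribution among
#' controls deviates from Hardy-Weinberg equilibrium (exact test,
#' `p < hwe_alpha`), and markers with call rate below `call_rate_min`.
#' Flagged markers are excluded from the filtered dataset.
#'
#' @param dataset a [genotype_dataset()] with phenotypes (controls required)
#' @param hwe_alpha HWE exact-test threshold on controls (default 1e-3)
#' @param call_rate_min minimum per-SNP call rate (default 0.90)
#' @return list with `report` (data.frame `snp_id`, `monomorphic`,
#'   `hwe_fail`, `low_call_rate`, `hwe_p`, `call_rate`, `excluded`),
#'   `filtered` (the dataset restricted to passing SNPs) and `thresholds`
#' @export
genotype_qc <- function(dataset, hwe_alpha = 1e-3, call_rate_min = 0.90) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(dataset$phenotype)) stopf("dataset has no phenotypes")
  ctrl <- dataset$phenotype == 0
  if (!any(ctrl, na.rm = TRUE)) stopf("no controls in dataset")
  G <- dataset$genotypes
  Gc <- G[which(ctrl), , drop = FALSE]
  snps <- colnames(G)
  call_rate <- colMeans(!is.na(G))
  mono <- vapply(seq_along(snps), function(j) {
    g <- G[, j][!is.na(G[, j])]
    length(g) == 0 || sum(g) == 0 || sum(g) == 2 * length(g)
  }, logical(1))
  hwe_p <- vapply(seq_along(snps), function(j)
    hwe_test_dosage(Gc[, j])$p_value, numeric(1))
  hwe_fail <- hwe_p < hwe_alpha
  low_cr <- call_rate < call_rate_min
  excluded <- mono | hwe_fail | low_cr
  report <- data.frame(snp_id = snps, monomorphic = mono,
                       hwe_fail = hwe_fail, low_call_rate = low_cr,
                       hwe_p = hwe_p, call_rate = call_rate,
                       excluded = excluded,
                       stringsAsFactors = FALSE, row.names = NULL)
  filtered <- dataset
  filtered$genotypes <- G[, !excluded, drop = FALSE]
  filtered$counted_allele <- dataset$counted_allele[!excluded]
  list(report = report, filtered = filtered,
       thresholds = c(hwe_alpha = hwe_alpha, call_rate_min = call_rate_min))
}

#' Log-additive logistic association for one SNP
#'
#' Fits `ln(p/(1-p)) = b0 + b1 * x` by maximum likelihood, where x is the
#' 0/1/2 dosage of the counted allele, and reports the Wald test of b1, the
#' odds ratio `exp(b1)` and its 95% CI `exp(b1 +/- 1.96 se)`. Complete or
#' quasi-complete separation (non-convergence or |b1| > 15) is surfaced as a
#' structured result with `status = "separation"` rather than an error, as
#' happens in practice when a rare homozygous genotype class is absent.
#'
#' @param dataset a [genotype_dataset()] with phenotypes
#' @param snp SNP id
#' @return one-row data.frame: `snp_id`, `dataset`, `beta1`, `se`,
#'   `p_value`, `odds_ratio`, `ci_low`, `ci_high`, `case_freq`,
#'   `control_freq`, `n_used`, `status` (`"ok"`, `"separation"`,
#'   `"not_estimable"`)
#' @export
fit_log_additive <- function(dataset, snp) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(dataset$phenotype)) stopf("dataset has no phenotypes")
  if (!snp %in% colnames(dataset$genotypes)) stopf("unknown SNP '%s'", snp)
  x <- dataset$genotypes[, snp]
  y <- dataset$phenotype
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  res <- data.frame(snp_id = snp, dataset = dataset$label,
                    beta1 = NA_real_, se = NA_real_, p_value = NA_real_,
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_,
                    case_freq = allele_freq(x[y == 1])$freq,
                    control_freq = allele_freq(x[y == 0])$freq,
                    n_used = length(x), status = "not_estimable",
                    stringsAsFactors = FALSE)
  if (length(unique(y)) < 2 || length(unique(x)) < 2) return(res)
  fit <- suppressWarnings(
    glm(y ~ x, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100)))
  beta1 <- unname(coef(fit)["x"])
  se <- sqrt(diag(vcov(fit)))["x"]
  if (!fit$converged || !is.finite(beta1) || abs(beta1) > 15) {
    res$status <- "separation"
    return(res)
  }
  res$beta1 <- beta1
  res$se <- unname(se)
  res$p_value <- 2 * pnorm(-abs(beta1 / se))
  res$odds_ratio <- exp(beta1)
  res$ci_low <- exp(beta1 - 1.96 * se)
  res$ci_high <- exp(beta1 + 1.96 * se)
  res$status <- "ok"
  res
}

#' Fit the log-additive model for many SNPs
#'
#' @param dataset a [genotype_dataset()] with phenotypes
#' @param snps SNP ids (default: all)
#' @return data.frame of stacked [fit_log_additive()] results
#' @export
fit_associations <- function(dataset, snps = NULL) {
  snps <- snps %||% colnames(dataset$genotypes)
  if (length(snps) == 0)
    return(data.frame(snp_id = character(), dataset = character(),
                      beta1 = numeric(), se = numeric(),
                      p_value = numeric(), odds_ratio = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      case_freq = numeric(), control_freq = numeric(),
                      n_used = integer(), status = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(snps, function(s) fit_log_additive(dataset, s)))
  rownames(out) <- NULL
  out
}

#' Combine two genotype datasets
#'
#' Concatenates the individuals of two datasets over their shared SNPs for a
#' combined re-analysis. Sample ids must be disjoint and the counted allele
#' must agree for every shared SNP (no silent re-orientation).
#'
#' @param d1,d2 [genotype_dataset()] objects
#' @param label label of the result (default `"combined"`)
#' @return a [genotype_dataset()]
#' @export
combine_datasets <- function(d1, d2, label = "combined") {
  stopifnot(inherits(d1, "genotype_dataset"), inherits(d2, "genotype_dataset"))
  if (ncol(d2$genotypes) == 0 || nrow(d2$genotypes) == 0) {
    d1$label <- label
    return(d1)
  }
  if (ncol(d1$genotypes) == 0 || nrow(d1$genotypes) == 0) {
    d2$label <- label
    return(d2)
  }
  overlap <- intersect(d1$sample_ids, d2$sample_ids)
  if (length(overlap))
    stopf("overlapping sample ids: %s",
          paste(head(overlap, 5), collapse = ", "))
  shared <- intersect(colnames(d1$genotypes), colnames(d2$genotypes))
  if (length(shared) == 0) stopf("datasets share no SNPs")
  mismatch <- shared[d1$counted_allele[shared] != d2$counted_allele[shared]]
  if (length(mismatch))
    stopf("counted-allele mismatch (re-orient explicitly first): %s",
          paste(mismatch, collapse = ", "))
  G <- rbind(d1$genotypes[, shared, drop = FALSE],
             d2$genotypes[, shared, drop = FALSE])
  ph <- if (is.null(d1$phenotype) || is.null(d2$phenotype)) NULL
        else c(d1$phenotype, d2$phenotype)
  genotype_dataset(G, phenotype = ph,
                   sample_ids = c(d1$sample_ids, d2$sample_ids),
                   counted_allele = d1$counted_allele[shared], label = label)
}

#' Allele-count-weighted combined allele frequency
#'
#' Combines the allele frequency of the same group across two datasets,
#' weighting by allele counts (2 per individual):
#' `(2 n1 f1 + 2 n2 f2) / (2 n1 + 2 n2)`.
#'
#' @param freq1,freq2 allele frequencies in [0, 1]
#' @param n1,n2 numbers of individuals
#' @return combined frequency
#' @export
pooled_allele_freq <- function(freq1, n1, freq2, n2) {
  assert_prob(freq1, "freq1"); assert_prob(freq2, "freq2")
  if (any(c(n1, n2) <= 0)) stopf("individual counts must be > 0")
  (2 * n1 * freq1 + 2 * n2 * freq2) / (2 * n1 + 2 * n2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1)
#' @param m_tests number of tests (>= 1)
#' @return `alpha / m_tests`
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests) {
  if (alpha <= 0 || alpha >= 1) stopf("`alpha` must be in (0, 1)")
  if (missing(m_tests) || m_tests < 1) stopf("`m_tests` must be >= 1")
  alpha / m_tests
}

#' Cross-dataset concordance of association results
#'
#' Classifies each SNP tested in two datasets as
#' `replicated_same_direction` (nominally significant in both with the odds
#' ratio on the same side of 1), `significant_opposite_directions`
#' (significant in both, opposite sides), or `not_replicated`.
#'
#' @param results data.frame of [fit_log_additive()] results over >= 2
#'   datasets (a `dataset` column distinguishes them)
#' @param datasets the two dataset labels to compare (default: the
#'   `"discovery"` and `"replication"` labels)
#' @param alpha nominal significance level (default 0.05)
#' @return data.frame per SNP: significance and OR direction per dataset and
#'   `classification`
#' @export
concordance_report <- function(results,
                               datasets = c("discovery", "replication"),
                               alpha = 0.05) {
  if (length(datasets) != 2) stopf("`datasets` must name two datasets")
  r1 <- results[results$dataset == datasets[1], ]
  r2 <- results[results$dataset == datasets[2], ]
  shared <- intersect(r1$snp_id, r2$snp_id)
  if (length(shared) == 0) stopf("no SNP tested in both datasets")
  i1 <- match(shared, r1$snp_id); i2 <- match(shared, r2$snp_id)
  sig1 <- r1$status[i1] == "ok" & r1$p_value[i1] < alpha
  sig2 <- r2$status[i2] == "ok" & r2$p_value[i2] < alpha
  dir1 <- sign(r1$beta1[i1]); dir2 <- sign(r2$beta1[i2])
  cls <- ifelse(sig1 & sig2 & dir1 == dir2, "replicated_same_direction",
         ifelse(sig1 & sig2, "significant_opposite_directions",
                "not_replicated"))
  data.frame(snp_id = shared,
             sig_1 = sig1, or_1 = r1$odds_ratio[i1],
             sig_2 = sig2, or_2 = r2$odds_ratio[i2],
             classification = cls, stringsAsFactors = FALSE,
             row.names = NULL)
}
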