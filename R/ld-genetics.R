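# Population-genetic utilities: pairwise r2 (EM from unphased genotypes or
# direct from phased haplotypes), exact and chi-square Hardy-Weinberg tests,
# and allele frequency / call-rate computation.

#' Allele frequency and call rate of one SNP
#'
#' @param g dosage vector (0/1/2/NA copies of the counted allele)
#' @return list with `freq` (counted-allele frequency, NA if all missing) and
#'   `call_rate`
#' @export
allele_freq <- function(g) {
  n_called <- sum(!is.na(g))
  list(freq = if (n_called == 0) NA_real_ else sum(g, na.rm = TRUE) / (2 * n_called),
       call_rate = n_called / length(g))
}

# r2 from two-locus haplotype frequencies c(pAB, pAb, paB, pab)
hap_freq_r2 <- function(p) {
  pA <- p[1] + p[2]
  pB <- p[1] + p[3]
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- p[1] - pA * pB
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# EM estimate of two-locus haplotype frequencies from unphased dosages.
# Phase is only ambiguous for double heterozygotes; initialization at
# linkage equilibrium, convergence when frequencies change < tol.
em_haplotype_freqs <- function(g1, g2, max_iter = 100L, tol = 1e-8) {
  n <- length(g1)
  pA <- sum(g1) / (2 * n)
  pB <- sum(g2) / (2 * n)
  # fixed haplotype contributions from phase-unambiguous genotypes
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  cnt <- function(i, j) tab[i + 1L, j + 1L]
  fixed <- c(AB = 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2),
             Ab = 2 * cnt(2, 0) + cnt(2, 1) + cnt(1, 0),
             aB = 2 * cnt(0, 2) + cnt(0, 1) + cnt(1, 2),
             ab = 2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0))
  ndh <- cnt(1, 1)  # double heterozygotes: AB/ab or Ab/aB
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    new_p <- fixed + ndh * c(w, 1 - w, 1 - w, w)
    new_p <- new_p / (2 * n)
    if (max(abs(new_p - p)) < tol) { p <- new_p; break }
    p <- new_p
  }
  p
}

#' Pairwise linkage disequilibrium r-squared
#'
#' With `method = "em"`, two-locus haplotype frequencies are estimated from
#' unphased dosage vectors by expectation-maximization and
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))`. With `method = "phased"`, `g1`/`g2`
#' are haplotype allele vectors (0/1, two per individual, aligned) and
#' haplotypes are counted directly.
#'
#' @param g1,g2 dosage vectors (EM) or haplotype vectors (phased)
#' @param method `"em"` or `"phased"`
#' @param max_iter,tol EM control parameters
#' @return r-squared in [0, 1]; NA (with a warning) if either locus is
#'   monomorphic after pairwise removal of missing values
#' @export
pairwise_r2 <- function(g1, g2, method = c("em", "phased"),
                        max_iter = 100L, tol = 1e-8) {
  method <- match.arg(method)
  if (length(g1) != length(g2)) stopf("`g1` and `g2` must have equal length")
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(g1) == 0) stopf("no complete pairs")
  if (method == "phased") {
    if (!all(c(g1, g2) %in% c(0, 1)))
      stopf("phased input must be 0/1 haplotype vectors")
    p <- c(mean(g1 == 1 & g2 == 1), mean(g1 == 1 & g2 == 0),
           mean(g1 == 0 & g2 == 1), mean(g1 == 0 & g2 == 0))
  } else {
    if (!all(c(g1, g2) %in% 0:2)) stopf("dosages must be 0/1/2")
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) {
      warning("monomorphic SNP: r2 undefined", call. = FALSE)
      return(NA_real_)
    }
    p <- em_haplotype_freqs(g1, g2, max_iter, tol)
  }
  r2 <- hap_freq_r2(p)
  if (is.na(r2)) warning("monomorphic SNP: r2 undefined", call. = FALSE)
  r2
}

#' Pairwise r-squared matrix for a genotype matrix
#'
#' @param G dosage matrix, individuals x SNPs (column names = SNP ids)
#' @param method passed to [pairwise_r2()]
#' @return symmetric matrix of r2 with unit diagonal for polymorphic SNPs;
#'   NA where undefined; attribute `method` records the estimator
#' @export
ld_matrix <- function(G, method = c("em", "phased")) {
  method <- match.arg(method)
  m <- ncol(G)
  ids <- colnames(G) %||% sprintf("snp%d", seq_len(m))
  R <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  poly <- apply(G, 2, function(g) length(unique(g[!is.na(g)])) > 1)
  diag(R) <- ifelse(poly, 1, NA_real_)
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (poly[i] && poly[j]) {
        r2 <- suppressWarnings(pairwise_r2(G[, i], G[, j], method = method))
        R[i, j] <- R[j, i] <- r2
      }
    }
  }
  structure(R, method = method)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the exact test: conditional on the observed allele counts, all
#' possible heterozygote counts are enumerated and the probabilities of
#' tables as or less probable than the observed one are summed. The
#' chi-square test (1 df, no continuity correction) is available for large
#' panels. Monomorphic markers return p = 1 with a flag.
#'
#' @param hom_ref,het,hom_alt genotype counts
#' @param method `"exact"` or `"chi2"`
#' @return list with `p_value`, `method`, `counts`, `flag`
#' @export
hwe_test <- function(hom_ref, het, hom_alt, method = c("exact", "chi2")) {
  method <- match.arg(method)
  counts <- c(hom_ref = hom_ref, het = het, hom_alt = hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stopf("total genotype count must be > 0")
  n_alt <- 2 * hom_alt + het
  n_ref <- 2 * hom_ref + het
  if (n_alt == 0 || n_ref == 0)
    return(list(p_value = 1, method = method, counts = counts,
                flag = "monomorphic"))
  if (method == "chi2") {
    p <- n_alt / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((counts - e)^2 / e)
    return(list(p_value = pchisq(stat, 1, lower.tail = FALSE),
                method = "chi2", counts = counts, flag = NA_character_,
                statistic = stat))
  }
  n_rare <- min(n_alt, n_ref)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- lfactorial(n) - lfactorial((n_rare - hets) / 2) -
    lfactorial(hets) - lfactorial((2 * n - n_rare - hets) / 2) +
    hets * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
    lfactorial(2 * n)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(het, hets)]
  p_value <- min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
  list(p_value = p_value, method = "exact", counts = counts,
       flag = NA_character_)
}

# convenience: HWE test straight from a dosage vector
hwe_test_dosage <- function(g, method = "exact") {
  g <- g[!is.na(g)]
  hwe_test(sum(g == 0), sum(g == 1), sum(g == 2), method = method)
}
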