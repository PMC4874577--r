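---
title: "Pooled-DNA GWAS with poolscan: models and methods"
author: "poolscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-DNA GWAS with poolscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

# The problem

Genome-wide association studies of rare or hard-to-ascertain phenotypes are
often run in two stages: a cheap *pooled* discovery stage, in which equimolar
DNA from all cases and all controls is hybridized to genotyping arrays as two
pools, and an individual-genotyping stage for the handful of markers the
pools prioritize. poolscan implements the full analysis chain of such a
design: allele-frequency estimation from probe intensities (allelotyping),
three complementary SNP-prioritization methods, and the case-control
association stages on individual genotypes.

# Relative Allele Scores

On the arrays modelled here each SNP is interrogated by quartets of
perfect-match (PM) and mismatch (MM) probes for both alleles, on both
strands. For quartet $i$ of one strand, the mismatch-corrected allele
signals are

$$A_i = \max(\mathrm{PM}_A - \overline{\mathrm{MM}}, 0), \qquad
  B_i = \max(\mathrm{PM}_B - \overline{\mathrm{MM}}, 0), \qquad
  \overline{\mathrm{MM}} = \tfrac{1}{2}(\mathrm{MM}_A + \mathrm{MM}_B),$$

and the quartet's relative allele signal is $s_i = A_i / (A_i + B_i)$. The
Relative Allele Score (RAS) of a SNP on one array is the median of the
defined $s_i$ per strand, averaged over the strands. The RAS is the pooled
analogue of an allele frequency: under pooling, its expectation tracks the
frequency of the A-labelled allele in the pool.

Several small conventions in this chain were genuinely open and are package
decisions:

* **Strand combination.** Each strand's median is computed separately and
  available strands are averaged; a SNP assayed on one strand uses that
  strand alone.
* **Even counts.** The median of an even number of quartet values is the
  mean of the central pair.
* **Undefined quartets.** A quartet with $A_i + B_i = 0$ carries no allele
  signal and is excluded from the median rather than treated as 0.5.
* **Normalization.** Array-level gain differences are removed by quantile
  normalization of all probe signals across arrays
  (`limma::normalizeQuantiles`) before RAS computation. It is on by default
  and switchable; the per-quartet ratio is scale-invariant, so this mainly
  stabilizes the mismatch correction across chips. A pure per-array
  multiplicative gain is removed exactly (this is asserted in the tests).
* **Orientation.** RAS is computed on the A/B probe labels as annotated;
  no re-orientation by observed frequency.

Markers on sex chromosomes, in copy-number-variable regions, or in the
mitochondrial genome (which is not copy-number-normalized at pooling) are
removed before summarization, with counts by reason.

The per-SNP summary over the replicate arrays is the mean case RAS, mean
control RAS, their difference (`ras_diff`) and the between-array variances.
The Pearson correlation between the two mean vectors is the pooling-stage
technical QC statistic.

# Prioritization

Pooled designs have no single agreed ranking statistic, so three
complementary methods are run and their union is carried forward.

**|RAS difference| ranking.** Markers strictly above an 8% background level
feed the cluster method; the selection tier keeps markers at or (inclusively)
above 12%, ranked by decreasing absolute difference with genomic-order tie
breaks. The default list takes the top 48.

**LD-weighted clusters.** Above-background SNPs are assigned to a *genic
cluster* when they lie within a gene or within a flank of 10% of the gene
length (rounded down to whole bases) on either side — genic assignment takes
precedence — and the remainder are tiled per chromosome into non-overlapping
100 kb windows. "Sliding window without overlap" is self-contradictory if
read literally, so the tiling is greedy and deterministic: a window is
anchored at the leftmost unassigned above-background SNP, all
above-background SNPs inside it are consumed, and the process repeats.
Windows with fewer than five SNPs form no cluster. Each cluster's **LD
score** counts its independent high-LD signals: on the graph whose edges
join member pairs with $r^2 \ge 0.8$, the score is the number of connected
components of size at least two. Components rather than cliques define a
signal because chains of $r^2 \ge 0.8$ pairs represent one underlying
haplotype signal and component counting is deterministic; singletons score
zero under a literal reading of "at least two SNPs contribute one point" (a
switch can count them for sensitivity analysis). Clusters with score at
least 5 are selected and contribute one representative: a member already in
the |RAS difference| selection if any (the one with highest absolute
difference), otherwise the highest-|RAS difference| member with MAF > 0.05
for which genotyping primers can be designed; a cluster with no eligible
member contributes nothing. LD comes from a user-supplied reference genotype
panel via the package's own $r^2$ machinery (two-locus haplotype EM from
unphased genotypes, or direct counting of phased haplotypes), not from any
remote resource.

**Combined Z-test.** The exact variance decomposition of the combined test
used in earlier pooled studies is not reprinted anywhere accessible, so the
package implements a documented reconstruction. For one SNP,

$$Z = \frac{\bar{R}_{case} - \bar{R}_{ctrl}}
          {\sqrt{V_{samp} + V_{exp}}}, \qquad
  V_{samp} = \bar{p}(1-\bar{p})\Big(\frac{1}{2N_{case}} +
             \frac{1}{2N_{ctrl}}\Big), \qquad
  V_{exp} = \frac{s^2_{case}}{k_{case}} + \frac{s^2_{ctrl}}{k_{ctrl}},$$

where $\bar{p}$ is the mean RAS over all arrays, $N$ are the numbers of
individuals in the pools, $s^2$ the between-array variances and $k$ the
numbers of arrays. $V_{samp}$ is the binomial sampling variance of allele
frequencies estimated from finite pools; $V_{exp}$ is the experimental
(array) variance. Both components are returned for inspection. The p-value
is two-sided normal; the default list keeps the top 49.

The overlap report gives the pairwise and triple intersections of the three
selections and the union with per-SNP provenance; the union satisfies
inclusion–exclusion exactly.

# Individual-genotyping stages

**QC.** Markers are excluded when monomorphic, when the exact
Hardy-Weinberg test on *controls* gives $p < 10^{-3}$, or when the call
rate falls below 0.90. The source design states only a "very low call rate"
for its exclusions, so the 0.90 default is a reconstruction from
conventional GWAS practice and is configurable. The exact HWE test
enumerates all heterozygote counts conditional on the observed allele
counts and sums the probabilities of tables no more probable than the
observed one (with a $1+10^{-12}$ tie guard); a 1-df chi-square alternative
is available for large panels.

**Association.** The log-additive model
$\ln\!\big(p/(1-p)\big) = \beta_0 + \beta_1 X$, with $X \in \{0,1,2\}$
counting the declared allele, is fitted by maximum likelihood through
`stats::glm` (tight convergence: $10^{-10}$, up to 100 iterations). The
Wald p-value, $\mathrm{OR} = e^{\beta_1}$ and the 95% CI
$e^{\beta_1 \pm 1.96\,\mathrm{se}}$ are reported. Complete or
quasi-complete separation — non-convergence or $|\beta_1| > 15$ on the
log-odds scale, as happens when a rare homozygote class is absent — is
surfaced as a structured `separation` status, never a crash. No covariates
are included: the design matches cases and controls on the known risk
factors instead. The tests cross-check the fit against an independent
Newton iteration on the 2×3 genotype-table likelihood.

**Workflow.** Prioritized SNPs are first genotyped in the discovery
individuals (technical validation; a marker is validated when nominally
associated at $p < 0.05$), validated markers are tested in the independent
replication dataset, and markers significant in both are re-fitted on the
concatenated individuals (individuals are merged, not effects — this is not
a meta-analysis). Combination requires disjoint sample ids and identical
counted alleles; allele-frequency combination across datasets weights by
allele counts. The concordance report classifies each marker as replicated
in the same direction, significant in opposite directions, or not
replicated, and the Bonferroni threshold is $\alpha/m$ over the validated
tests. Every stage records its SNP funnel (in = out + excluded by reason)
in the run manifest, and rerunning a configuration with the same seed
reproduces byte-identical result tables.

# The synthetic-data generator

No raw pooled-array data is distributed, so the generator produces data
with exactly the statistical structure the analysis assumes:

* **Genotypes** are drawn per SNP under Hardy-Weinberg equilibrium at the
  specified MAF, or jointly from haplotype-frequency tables where LD blocks
  are specified.
* **Phenotypes** follow the logistic disease model: an individual with
  dosage vector $x$ is a case with probability
  $\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j)$.
* **Sample QC** mirrors the pooling bench rules: a sample is excluded when
  its replicate quantification SD exceeds 3% of the replicate mean or its
  pooled volume lies more than 2 SDs from the median volume.
* **Pools** combine nominally equimolar DNA; the realized per-sample mass
  is log-normal (strictly positive) around a 200 ng target with a 5%
  coefficient of variation. The pool allele frequency is the mass-weighted
  dosage average; with zero mass noise it equals the cohort frequency
  exactly. Two biological replicate pools per group are built and each is
  hybridized on three arrays — the 2 × 3 replicate structure of the study
  design, giving twelve RAS values per SNP.
* **Intensities** follow a deliberately simple linear-in-frequency model:
  $\mathrm{PM}_A = G(\kappa_A f + \chi) + \varepsilon$,
  $\mathrm{PM}_B = G(\kappa_B (1-f) + \chi) + \varepsilon$, mismatch
  signals around $G\,m + \varepsilon$, all clamped at zero, with a
  log-normal per-quartet gain and per-array effect. This is the simplest
  model in which RAS is identifiable and can be biased for testing
  (asymmetric $\kappa$), and with $\chi = m$ the mismatch correction is
  unbiased, so zero-noise symmetric settings give RAS equal to the pool
  frequency to machine precision — the anchor oracle for the whole
  allelotyping path.

What the generator does **not** emulate: probe-sequence thermodynamics,
CEL-level array artefacts, population structure or admixture, genotyping
batch effects, or linkage beyond the explicitly specified blocks. Passing
tests therefore demonstrate the correctness of the analysis chain under its
own assumptions, not robustness to real-array pathologies. The array noise
magnitudes of the original experiment are unknown; the noise knobs are
exposed as parameters with moderate defaults rather than claimed as
calibrated values. Seeds are explicit everywhere; the pipeline derives
per-stage seeds from one master seed by fixed offsets, and all generators
are bit-reproducible given a seed.

# Verification problem sizes and design choices

The test-suite and acceptance checks use problem sizes chosen once, by
design:

* **Technical-null correlation.** The replicate-correlation QC is a
  *technical* statistic (the same pools on replicate arrays), so its null
  simulation gives both groups identical pool frequencies and varies only
  array noise over 10,000 SNPs. Resampling distinct case and control
  cohorts at the default cohort sizes would cap the correlation near 0.985
  from cohort sampling alone, which is not what that QC measures.
* **Type-I error of the combined Z.** 10,000 null SNPs with full cohort
  resampling at the default pool sizes (92 cases, 129 controls), so that
  both variance components are genuinely exercised; the empirical rejection
  rate at $\alpha = 0.05$ must sit inside the 95% binomial band.
* **Effect recovery.** A generative per-allele OR of 1.65 at MAF 0.3 is
  recovered by the log-additive fit at 5,000 cases / 5,000 controls over
  100 replicates.
* **End-to-end detection.** The spiked-SNP scenario (one risk SNP, OR 1.65,
  among 999 nulls) uses 1,000 cases and 1,000 controls per dataset. At
  these sizes the association stages have power above 0.99 and the
  combined-Z signal is ≈ 7.5 SD, so a high detection-rate bound over 20
  seeds tests the pipeline's plumbing rather than the sampling luck of a
  marginally powered cohort. The generator's *defaults* remain the original
  cohort sizes (94/135 discovery, 100/425 replication), under which
  detection of an OR-1.65 variant is — realistically — not guaranteed.

Numerical choices: the haplotype EM initializes at linkage equilibrium and
stops when frequencies move less than $10^{-8}$ (at most 100 iterations);
EM $r^2$ from unphased genotypes and direct phased $r^2$ coincide up to an
$O(n^{-1/2})$ phase-information term (identical when no double
heterozygotes occur, which the tests assert separately); ranking ties are
broken by |Z| then genomic order then SNP id, so all orderings are total
and deterministic.

# Limitations

poolscan analyzes intensity tables, not CEL files, and expects annotations
as input rather than retrieving them. The cluster windows are SNP-anchored;
absolute cluster counts depend on that anchoring choice and are not
comparable across different tilings. The combined Z-test is a reconstruction
and is labelled as such. No imputation, stratification correction, tag-SNP
selection or effect-level meta-analysis is provided.
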