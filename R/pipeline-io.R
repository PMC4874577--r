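# File formats, configuration and end-to-end orchestration of the
# discovery -> technical-validation -> replication -> combined workflow.

#' Read an intensity-quartet table
#'
#' @param path TSV with header columns `snp_id`, `strand`, `quartet_index`,
#'   `array_id`, `group`, `PM_A`, `MM_A`, `PM_B`, `MM_B`
#' @return validated data.frame of intensity quartets
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stopf("missing input file: %s", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "strand", "quartet_index", "array_id", "group",
           "PM_A", "MM_A", "PM_B", "MM_B")
  miss <- setdiff(req, names(x))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  bad <- which(!x$strand %in% c("sense", "antisense"))
  if (length(bad))
    stopf("unknown strand token at row(s) %s", paste(head(bad, 5), collapse = ", "))
  sig <- as.matrix(x[, c("PM_A", "MM_A", "PM_B", "MM_B")])
  neg <- which(rowSums(!is.finite(sig) | sig < 0) > 0)
  if (length(neg))
    stopf("negative or non-numeric signal at row(s) %s",
          paste(head(neg, 5), collapse = ", "))
  key <- paste(x$snp_id, x$strand, x$quartet_index, x$array_id)
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("duplicated quartet key: %s", key[dup[1]])
  x
}

#' Write an intensity-quartet table
#'
#' @param quartets intensity quartet data.frame
#' @param path output TSV path
#' @export
write_intensity_table <- function(quartets, path) write_tsv(quartets, path)

#' Read a SNP annotation table
#'
#' @param path TSV with columns `snp_id`, `chromosome`, `position` and
#'   optionally `is_sex`, `is_cnv`, `is_mito`, `gene_id`, `gene_start`,
#'   `gene_end`, `designable`, `maf`
#' @return validated annotation data.frame (flag columns filled with FALSE
#'   when absent)
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("missing input file: %s", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "chromosome", "position")
  miss <- setdiff(req, names(x))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(x$position) | x$position <= 0))
    stopf("positions must be positive")
  for (fl in c("is_sex", "is_cnv", "is_mito"))
    x[[fl]] <- if (fl %in% names(x)) as.logical(x[[fl]]) else FALSE
  if ("gene_id" %in% names(x)) {
    has <- !is.na(x$gene_id) & nzchar(x$gene_id)
    if (any(has)) {
      if (!all(c("gene_start", "gene_end") %in% names(x)))
        stopf("gene_id present but gene interval columns missing")
      if (any(is.na(x$gene_start[has])) || any(is.na(x$gene_end[has])))
        stopf("gene interval required when gene_id is present")
      if (any(x$gene_end[has] < x$gene_start[has]))
        stopf("inverted gene interval (gene_end < gene_start)")
    }
  }
  x
}

#' Read an individual-genotype dataset
#'
#' Two plain-text formats are supported. `"tsv"`: a table with `sample_id`,
#' `phenotype` (0 = control, 1 = case) and one 0/1/2/NA dosage column per
#' SNP. `"ped"`: a PLINK text PED/MAP pair (`path` is the PED; the MAP is
#' found by extension); phenotypes coded 1 = control, 2 = case; dosages count
#' `counted_allele` per SNP (by default the lexicographically first allele
#' observed at the marker).
#'
#' @param path input path
#' @param format `"tsv"` or `"ped"`
#' @param counted_allele optional named character vector, SNP id -> counted
#'   allele (PED only)
#' @param label dataset label
#' @return a [genotype_dataset()]
#' @export
read_genotypes <- function(path, format = c("tsv", "ped"),
                           counted_allele = NULL, label = "dataset") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("missing input file: %s", path)
  if (format == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "phenotype") %in% names(x)))
      stopf("TSV genotypes need `sample_id` and `phenotype` columns")
    if (!all(x$phenotype %in% c(0, 1)))
      stopf("phenotype must be 0/1")
    snps <- setdiff(names(x), c("sample_id", "phenotype"))
    G <- as.matrix(x[, snps, drop = FALSE])
    if (!all(G %in% c(0, 1, 2) | is.na(G)))
      stopf("dosages must be 0/1/2/NA")
    return(genotype_dataset(G, phenotype = x$phenotype,
                            sample_ids = x$sample_id,
                            counted_allele = counted_allele %||% "B",
                            label = label))
  }
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path) || !file.exists(map_path))
    stopf("missing MAP file for %s", path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE)
  snps <- map[[2]]
  ped <- utils::read.table(path, stringsAsFactors = FALSE)
  if (ncol(ped) != 6 + 2 * length(snps))
    stopf("PED has %d columns, expected %d", ncol(ped), 6 + 2 * length(snps))
  pheno_raw <- ped[[6]]
  if (!all(pheno_raw %in% c(1, 2)))
    stopf("PED phenotype must be 1 (control) / 2 (case), got: %s",
          paste(unique(setdiff(pheno_raw, c(1, 2))), collapse = ", "))
  G <- matrix(NA_integer_, nrow(ped), length(snps),
              dimnames = list(NULL, snps))
  counted <- character(length(snps))
  for (j in seq_along(snps)) {
    a1 <- as.character(ped[[6 + 2 * j - 1]])
    a2 <- as.character(ped[[6 + 2 * j]])
    obs <- setdiff(unique(c(a1, a2)), "0")
    if (length(obs) > 2)
      stopf("more than two alleles at %s: %s", snps[j],
            paste(obs, collapse = ", "))
    ca <- counted_allele[[snps[j]]] %||% sort(obs)[1]
    if (!is.null(counted_allele[[snps[j]]]) && length(obs) && !ca %in% obs)
      stopf("counted allele '%s' not observed at %s", ca, snps[j])
    miss <- a1 == "0" | a2 == "0"
    G[, j] <- (a1 == ca) + (a2 == ca)
    G[miss, j] <- NA_integer_
    counted[j] <- ca %||% NA_character_
  }
  genotype_dataset(G, phenotype = as.integer(pheno_raw == 2),
                   sample_ids = as.character(ped[[2]]),
                   counted_allele = counted, label = label)
}

#' Write a genotype dataset as TSV
#'
#' @param dataset a [genotype_dataset()]
#' @param path output TSV path
#' @export
write_genotypes <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  out <- data.frame(sample_id = dataset$sample_ids,
                    phenotype = dataset$phenotype %||%
                      rep(NA_integer_, length(dataset$sample_ids)),
                    dataset$genotypes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

# ---------------------------------------------------------------------------
# configuration

#' Pipeline configuration with study defaults
#'
#' Defaults are the discovery-phase constants of the pooled design: 8%
#' background and 12% selection thresholds on |RAS difference|, top 48 SNPs
#' by |RAS difference|, cluster LD-score minimum 5, top 49 by combined
#' Z-test, exact-HWE alpha 1e-3 on controls, call-rate minimum 0.90 and a
#' nominal 0.05 validation level. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults; `scenario` takes a
#'   [scenario_config()]
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1L, normalize = TRUE,
              ras_background = 0.08, ras_tier = 0.12,
              top_k_rasdiff = 48L, top_k_ztest = 49L,
              cluster_min_score = 5L, ld_r2_threshold = 0.8,
              hwe_alpha = 1e-3, call_rate_min = 0.90, alpha = 0.05,
              output_dir = NULL, simulate = TRUE,
              scenario = scenario_config())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (k in c("ras_background", "ras_tier", "alpha", "hwe_alpha",
              "call_rate_min", "ld_r2_threshold"))
    assert_prob(cfg[[k]], k)
  structure(cfg, class = "pipeline_config")
}

#' Synthetic scenario configuration
#'
#' Defines the simulated study the pipeline runs on when `simulate = TRUE`.
#' Defaults mirror the study design: a discovery dataset of 94 cases and 135
#' controls (pooled in duplicate after sample QC, allelotyped in triplicate)
#' and an independent replication dataset of 100 cases and 425 controls.
#'
#' @param n_snps number of SNPs
#' @param n_case_discovery,n_control_discovery discovery cohort sizes
#' @param n_case_replication,n_control_replication replication cohort sizes
#' @param n_reference reference-panel individuals used for LD computation
#' @param maf_range population minor-allele-frequency range
#' @param prevalence population disease prevalence (sets the disease-model
#'   intercept)
#' @param risk_snps data.frame with `maf` and `or` per spiked risk SNP (may
#'   have zero rows for a null scenario)
#' @param genic_fraction fraction of SNPs placed inside genes
#' @param mass_cv,quant_cv pooling mass / quantification CVs
#' @param array arguments for [array_model()] as a list
#' @return a `scenario_config` list
#' @export
scenario_config <- function(n_snps = 1000L,
                            n_case_discovery = 94L,
                            n_control_discovery = 135L,
                            n_case_replication = 100L,
                            n_control_replication = 425L,
                            n_reference = 120L,
                            maf_range = c(0.05, 0.5),
                            prevalence = 0.3,
                            risk_snps = data.frame(maf = 0.3, or = 1.65),
                            genic_fraction = 0.3,
                            mass_cv = 0.05, quant_cv = 0.01,
                            array = list()) {
  structure(list(n_snps = as.integer(n_snps),
                 n_case_discovery = as.integer(n_case_discovery),
                 n_control_discovery = as.integer(n_control_discovery),
                 n_case_replication = as.integer(n_case_replication),
                 n_control_replication = as.integer(n_control_replication),
                 n_reference = as.integer(n_reference),
                 maf_range = maf_range, prevalence = prevalence,
                 risk_snps = risk_snps, genic_fraction = genic_fraction,
                 mass_cv = mass_cv, quant_cv = quant_cv, array = array),
            class = "scenario_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments
#'   (`scenario` may be a nested mapping of [scenario_config()] arguments)
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("missing config file: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenario)) {
    if (!is.null(raw$scenario$risk_snps))
      raw$scenario$risk_snps <- as.data.frame(raw$scenario$risk_snps)
    if (!is.null(raw$scenario$maf_range))
      raw$scenario$maf_range <- as.numeric(raw$scenario$maf_range)
    raw$scenario <- do.call(scenario_config, raw$scenario)
  }
  do.call(pipeline_config, raw)
}

# ---------------------------------------------------------------------------
# scenario simulation

# annotation table for a simulated marker panel: SNPs tiled over chromosomes
# 1..22 at ~4 kb spacing, a fraction of them inside 20 kb genes
simulate_annotation <- function(scen, snp_ids, mafs, seed) {
  m <- length(snp_ids)
  chrom <- as.character(rep_len(1:22, m))
  o <- order(chrom_rank(chrom))
  with_seed(seed, {
    pos <- integer(m)
    for (ch in unique(chrom))
      pos[chrom == ch] <- cumsum(sample(1000:8000, sum(chrom == ch),
                                        replace = TRUE))
    genic <- runif(m) < scen$genic_fraction
    gene_id <- ifelse(genic, sprintf("GENE%s_%d", chrom, pos %/% 50000L), "")
    gene_start <- ifelse(genic, pmax(pos - 10000L, 1L), NA_real_)
    gene_end <- ifelse(genic, pos + 10000L, NA_real_)
    designable <- runif(m) < 0.95
    data.frame(snp_id = snp_ids, chromosome = chrom, position = pos,
               is_sex = FALSE, is_cnv = FALSE, is_mito = FALSE,
               gene_id = gene_id, gene_start = gene_start,
               gene_end = gene_end, designable = designable, maf = mafs,
               stringsAsFactors = FALSE)[order(chrom_rank(chrom), pos), ]
  })
}

# draw a case-control cohort of fixed sizes from a simulated population
simulate_cohort <- function(pspec, model, n_case, n_control, seed,
                            label = "dataset") {
  gd <- simulate_genotypes(pspec)
  gd <- assign_phenotypes(gd, model, seed = seed + 1L)
  cases <- which(gd$phenotype == 1L)
  ctrls <- which(gd$phenotype == 0L)
  if (length(cases) < n_case || length(ctrls) < n_control)
    stopf("simulated population too small for the requested cohort")
  keep <- c(cases[seq_len(n_case)], ctrls[seq_len(n_control)])
  gd$genotypes <- gd$genotypes[keep, , drop = FALSE]
  gd$phenotype <- gd$phenotype[keep]
  gd$sample_ids <- sprintf("%s_%s", label, gd$sample_ids[keep])
  rownames(gd$genotypes) <- gd$sample_ids
  gd$label <- label
  gd
}

#' Simulate a complete pooled-GWAS scenario
#'
#' Generates the annotation, discovery and replication cohorts, LD reference
#' panel, sample quantification QC, duplicate case/control pools and
#' replicate array intensities for a [scenario_config()].
#'
#' @param scen a [scenario_config()]
#' @param seed integer master seed; per-stage seeds are derived by fixed
#'   offsets
#' @return list with `annotation`, `discovery`, `replication`, `reference`
#'   (genotype matrix), `quartets`, `pool_sizes`, `sample_qc`, `risk_snp_ids`
#' @export
simulate_scenario <- function(scen, seed = 1L) {
  stopifnot(inherits(scen, "scenario_config"))
  seed <- as.integer(seed)
  m <- scen$n_snps
  n_risk <- nrow(scen$risk_snps)
  if (n_risk > m) stopf("more risk SNPs than SNPs")
  mafs <- with_seed(seed + 11L,
                    runif(m, scen$maf_range[1], scen$maf_range[2]))
  snp_ids <- sprintf("rs%06d", seq_len(m))
  risk_ids <- character(0)
  if (n_risk > 0) {
    # spike risk SNPs at evenly spaced panel positions
    at <- floor(seq(m %/% 2, by = max(m %/% (n_risk + 1L), 1L),
                    length.out = n_risk)) %% m + 1L
    mafs[at] <- scen$risk_snps$maf
    risk_ids <- snp_ids[at]
  }
  annotation <- simulate_annotation(scen, snp_ids, mafs, seed + 12L)
  snps <- data.frame(snp_id = annotation$snp_id, maf = annotation$maf,
                     chromosome = annotation$chromosome,
                     position = annotation$position,
                     stringsAsFactors = FALSE)
  effects <- numeric(0)
  if (n_risk > 0) {
    effects <- log(scen$risk_snps$or)
    names(effects) <- risk_ids
  }
  model <- disease_model(intercept = log(scen$prevalence /
                                           (1 - scen$prevalence)),
                         effects = effects)
  pop_n_disc <- ceiling(1.6 * max(scen$n_case_discovery / scen$prevalence,
                                  scen$n_control_discovery /
                                    (1 - scen$prevalence)))
  pop_n_repl <- ceiling(1.6 * max(scen$n_case_replication / scen$prevalence,
                                  scen$n_control_replication /
                                    (1 - scen$prevalence)))
  discovery <- simulate_cohort(
    population_spec(pop_n_disc, snps, seed = seed + 21L), model,
    scen$n_case_discovery, scen$n_control_discovery, seed + 22L, "discovery")
  replication <- simulate_cohort(
    population_spec(pop_n_repl, snps, seed = seed + 31L), model,
    scen$n_case_replication, scen$n_control_replication, seed + 32L,
    "replication")
  reference <- simulate_genotypes(
    population_spec(scen$n_reference, snps, seed = seed + 41L))$genotypes

  # sample quantification QC on the discovery cohort, then pooling
  n_disc <- length(discovery$sample_ids)
  qc <- with_seed(seed + 51L, {
    masses <- matrix(200 * exp(rnorm(n_disc * 3, 0, scen$quant_cv)),
                     n_disc, 3, dimnames = list(discovery$sample_ids, NULL))
    volumes <- 200 / (rowMeans(masses) / 4)  # volume to reach target mass
    sample_quant_qc(masses, volumes)
  })
  pooled <- intersect(qc$included, discovery$sample_ids)
  ph <- discovery$phenotype[match(pooled, discovery$sample_ids)]
  case_members <- pooled[ph == 1L]
  ctrl_members <- pooled[ph == 0L]
  ps_case <- pool_spec("case", mass_cv = scen$mass_cv,
                       quant_cv = scen$quant_cv)
  ps_ctrl <- pool_spec("control", mass_cv = scen$mass_cv,
                       quant_cv = scen$quant_cv)
  pools <- list(case = build_pools(discovery, case_members, ps_case,
                                   seed = seed + 61L),
                control = build_pools(discovery, ctrl_members, ps_ctrl,
                                      seed = seed + 62L))
  am <- do.call(array_model, scen$array)
  quartets <- simulate_intensities(pools, am, ps_case, seed = seed + 71L)
  list(annotation = annotation, discovery = discovery,
       replication = replication, reference = reference,
       quartets = quartets,
       pool_sizes = c(case = length(case_members),
                      control = length(ctrl_members)),
       sample_qc = qc, risk_snp_ids = risk_ids)
}

# ---------------------------------------------------------------------------
# orchestration

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s: %s", stage, conditionMessage(e)))
}

#' Run the full pooled-GWAS pipeline
#'
#' Executes allelotyping (normalization, RAS, marker QC, summaries), the
#' three prioritization methods and their union, technical validation by
#' individual genotyping in the discovery dataset (nominal p < 0.05),
#' association in the replication dataset, the combined analysis for SNPs
#' significant in both, the concordance report and the Bonferroni threshold.
#' With `simulate = TRUE` the inputs come from [simulate_scenario()];
#' otherwise supply them via `inputs`.
#'
#' @param config a [pipeline_config()]
#' @param inputs optional list with the elements returned by
#'   [simulate_scenario()] (used when `config$simulate` is FALSE)
#' @return list with all stage outputs plus a `manifest` recording the
#'   SNP funnel (counts in/out by exclusion reason per stage), parameters and
#'   output file paths; if `config$output_dir` is set, stage tables are
#'   written there as TSV
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  scen <- if (config$simulate)
    run_stage("simulate", simulate_scenario(config$scenario, config$seed))
  else inputs %||% stopf("`inputs` required when simulate = FALSE")
  manifest <- list(parameters = unclass(config)[c(
    "seed", "normalize", "ras_background", "ras_tier", "top_k_rasdiff",
    "top_k_ztest", "cluster_min_score", "ld_r2_threshold", "hwe_alpha",
    "call_rate_min", "alpha")])

  # ---- allelotyping -------------------------------------------------------
  rt <- run_stage("allelotyping",
                  ras_table(scen$quartets, normalize = config$normalize))
  mqc <- run_stage("marker_qc",
                   qc_filter_markers(rownames(rt$ras), scen$annotation))
  rt$ras <- rt$ras[mqc$kept, , drop = FALSE]
  summaries <- run_stage("summarize", summarize_ras(rt))
  summaries <- merge(summaries,
                     scen$annotation[, c("snp_id", "chromosome", "position")],
                     by = "snp_id", sort = FALSE)
  repcor <- run_stage("replicate_correlation", replicate_correlation(summaries))
  manh <- run_stage("manhattan", manhattan_export(summaries, scen$annotation))
  manifest$allelotyping <- list(
    snps_in = length(mqc$kept) + nrow(mqc$removed),
    removed_by_reason = as.list(mqc$counts),
    snps_out = nrow(summaries),
    dropped_no_group_mean = length(attr(summaries, "dropped") %||% character()),
    replicate_correlation = repcor$r)

  # ---- prioritization -----------------------------------------------------
  above_bg <- run_stage("rasdiff_background",
                        rank_by_rasdiff(summaries, config$ras_background,
                                        inclusive = FALSE))
  tier <- rank_by_rasdiff(summaries, config$ras_tier, inclusive = TRUE)
  sel_rasdiff <- head(tier$snp_id, config$top_k_rasdiff)

  assignment <- run_stage("clusters",
                          assign_clusters(above_bg$snp_id, scen$annotation))
  ld <- run_stage("ld", {
    member_ids <- unique(assignment$members$snp_id)
    if (length(member_ids))
      ld_matrix(scen$reference[, member_ids, drop = FALSE])
    else matrix(numeric(0), 0, 0)
  })
  kept_clusters <- run_stage("cluster_scores",
                             select_clusters(assignment, ld,
                                             config$cluster_min_score,
                                             config$ld_r2_threshold))
  ann_idx <- match(assignment$members$snp_id, scen$annotation$snp_id)
  sum_idx <- match(assignment$members$snp_id, summaries$snp_id)
  member_info <- data.frame(
    cluster_id = assignment$members$cluster_id,
    snp_id = assignment$members$snp_id,
    abs_ras_diff = summaries$abs_ras_diff[sum_idx],
    maf = scen$annotation$maf[ann_idx] %||% NA_real_,
    designable = scen$annotation$designable[ann_idx] %||% TRUE,
    stringsAsFactors = FALSE)
  reps <- vapply(kept_clusters$cluster_id, function(cid)
    choose_representative(member_info[member_info$cluster_id == cid, ],
                          sel_rasdiff), character(1))
  kept_clusters$representative <- unname(reps)
  sel_cluster <- unname(reps[!is.na(reps)])

  ztab <- run_stage("ztest", {
    zt <- combined_z_table(rt, scen$pool_sizes["case"],
                           scen$pool_sizes["control"])
    merge(zt, scen$annotation[, c("snp_id", "chromosome", "position")],
          by = "snp_id", sort = FALSE)
  })
  sel_ztest <- rank_by_z(ztab, config$top_k_ztest)$snp_id

  overlap <- selection_overlap(list(rasdiff = sel_rasdiff,
                                    cluster = sel_cluster,
                                    ztest = sel_ztest))
  union_snps <- overlap$union$snp_id
  manifest$prioritization <- list(
    above_background = nrow(above_bg), tier = nrow(tier),
    selected_rasdiff = length(sel_rasdiff),
    clusters_formed = nrow(assignment$clusters),
    clusters_selected = nrow(kept_clusters),
    selected_cluster = length(sel_cluster),
    selected_ztest = length(sel_ztest),
    union = length(union_snps),
    overlap_pairwise = as.list(overlap$pairwise),
    overlap_triple = overlap$triple)

  # ---- technical validation in the discovery dataset ----------------------
  disc_union <- scen$discovery
  disc_union$genotypes <- disc_union$genotypes[,
    intersect(union_snps, colnames(disc_union$genotypes)), drop = FALSE]
  disc_qc <- run_stage("discovery_qc",
                       genotype_qc(disc_union, config$hwe_alpha,
                                   config$call_rate_min))
  assoc_disc <- run_stage("discovery_association",
                          fit_associations(disc_qc$filtered))
  validated <- assoc_disc$snp_id[assoc_disc$status == "ok" &
                                   assoc_disc$p_value < config$alpha]
  manifest$technical_validation <- list(
    snps_in = length(union_snps),
    failed_qc = sum(disc_qc$report$excluded),
    not_estimable = sum(assoc_disc$status != "ok"),
    tested = sum(assoc_disc$status == "ok"),
    validated = length(validated))

  # ---- replication --------------------------------------------------------
  repl <- scen$replication
  repl$genotypes <- repl$genotypes[,
    intersect(validated, colnames(repl$genotypes)), drop = FALSE]
  if (ncol(repl$genotypes) > 0) {
    repl_qc <- run_stage("replication_qc",
                         genotype_qc(repl, config$hwe_alpha,
                                     config$call_rate_min))
    assoc_repl <- run_stage("replication_association",
                            fit_associations(repl_qc$filtered))
  } else {
    repl_qc <- NULL
    assoc_repl <- assoc_disc[0, ]
  }
  manifest$replication <- list(
    snps_in = length(validated),
    failed_qc = if (is.null(repl_qc)) 0L else sum(repl_qc$report$excluded),
    tested = sum(assoc_repl$status == "ok"))

  # ---- combined analysis and reporting ------------------------------------
  sig_repl <- assoc_repl$snp_id[assoc_repl$status == "ok" &
                                  assoc_repl$p_value < config$alpha]
  sig_both <- intersect(validated, sig_repl)
  assoc_comb <- if (length(sig_both)) {
    comb <- run_stage("combine",
                      combine_datasets(scen$discovery, scen$replication))
    run_stage("combined_association", fit_associations(comb, sig_both))
  } else assoc_disc[0, ]
  all_assoc <- rbind(assoc_disc, assoc_repl, assoc_comb)
  concordance <- if (nrow(assoc_repl))
    run_stage("concordance",
              concordance_report(all_assoc, alpha = config$alpha))
  else NULL
  bonf <- bonferroni_threshold(config$alpha,
                               max(1L, sum(assoc_disc$status == "ok" &
                                             assoc_disc$snp_id %in%
                                             validated)))
  manifest$combined <- list(
    significant_in_both = length(sig_both),
    replicated_same_direction = if (is.null(concordance)) 0L
      else sum(concordance$classification == "replicated_same_direction"),
    bonferroni_threshold = bonf)

  out <- list(ras = rt, summaries = summaries, manhattan = manh,
              replicate_correlation = repcor,
              selection = list(rasdiff = sel_rasdiff, cluster = sel_cluster,
                               ztest = sel_ztest, overlap = overlap),
              clusters = kept_clusters, cluster_assignment = assignment,
              ztest = ztab,
              association = list(discovery = assoc_disc,
                                 replication = assoc_repl,
                                 combined = assoc_comb),
              concordance = concordance,
              bonferroni_threshold = bonf,
              risk_snp_ids = scen$risk_snp_ids %||% character(),
              manifest = manifest)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    ras_out <- data.frame(snp_id = rownames(rt$ras), rt$ras,
                          check.names = FALSE)
    write_tsv(ras_out, p("ras.tsv"))
    write_tsv(manh, p("manhattan.tsv"))
    write_tsv(data.frame(snp_id = sel_rasdiff), p("selection_rasdiff.tsv"))
    write_tsv(data.frame(snp_id = sel_cluster), p("selection_cluster.tsv"))
    write_tsv(data.frame(snp_id = sel_ztest), p("selection_ztest.tsv"))
    write_tsv(kept_clusters, p("clusters.tsv"))
    write_tsv(overlap$union, p("venn.tsv"))
    write_tsv(assoc_disc, p("assoc_discovery.tsv"))
    write_tsv(assoc_repl, p("assoc_replication.tsv"))
    write_tsv(assoc_comb, p("assoc_combined.tsv"))
    if (!is.null(concordance)) write_tsv(concordance, p("concordance.tsv"))
    files <- list.files(config$output_dir, pattern = "\\.tsv$",
                        full.names = TRUE)
    manifest$outputs <- as.list(tools::md5sum(files))
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    out$manifest <- manifest
  }
  out
}
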