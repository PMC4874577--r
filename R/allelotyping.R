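# Relative Allele Score (RAS) computation from probe quartets, marker QC,
# replicate summaries and RAS differences: the pooled-GWAS discovery stage.

#' Relative allele signal of one probe quartet
#'
#' For a quartet with perfect-match and mismatch signals for both alleles, the
#' average mismatch `MM = (MM_A + MM_B)/2` is subtracted from each PM signal
#' (clamped at zero) and the quartet's relative allele signal is
#' `A / (A + B)`. The value is undefined (NA) when both corrected signals are
#' zero, since such a quartet carries no allele information.
#'
#' All arguments are vectorized.
#'
#' @param PM_A,MM_A,PM_B,MM_B non-negative fluorescence signals
#' @return numeric vector in [0, 1], NA where undefined
#' @export
quartet_ras <- function(PM_A, MM_A, PM_B, MM_B) {
  sig <- cbind(PM_A, MM_A, PM_B, MM_B)
  if (any(!is.finite(sig)) || any(sig < 0))
    stopf("signals must be finite and >= 0")
  mm <- (MM_A + MM_B) / 2
  a <- pmax(PM_A - mm, 0)
  b <- pmax(PM_B - mm, 0)
  out <- a / (a + b)
  out[a + b == 0] <- NA_real_
  out
}

#' RAS of one SNP on one array
#'
#' Per strand, the median of the defined quartet signals (mean of the central
#' pair for an even count); the SNP-array RAS is the mean of the strand
#' medians over strands with at least one defined quartet, or NA if none.
#'
#' @param values numeric quartet signals (from [quartet_ras()])
#' @param strand strand label per value (`"sense"`/`"antisense"`)
#' @return single RAS value or NA
#' @export
snp_array_ras <- function(values, strand) {
  if (length(values) == 0) stopf("need >= 1 quartet")
  if (length(strand) != length(values)) stopf("`strand` length mismatch")
  meds <- tapply(values, strand, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else median(v)
  })
  meds <- meds[!is.na(meds)]
  if (length(meds) == 0) NA_real_ else mean(meds)
}

#' Quantile-normalize quartet intensities across arrays
#'
#' Stacks the four signals of every (SNP, strand, quartet) into one intensity
#' vector per array and quantile-normalizes the arrays against each other,
#' removing array-level distributional (gain) differences before RAS
#' computation. Requires every probe to be measured on every array.
#'
#' @param quartets intensity quartet data.frame (see [read_intensity_table()])
#' @return the quartet table with normalized signals, same row order
#' @export
normalize_intensities <- function(quartets) {
  qt <- data.table::as.data.table(quartets)
  qt[, J := .I]
  key <- qt[, paste(snp_id, strand, quartet_index, sep = "\r")]
  arrays <- sort(unique(qt$array_id))
  probes <- sort(unique(key))
  n_sig <- 4L
  M <- matrix(NA_real_, length(probes) * n_sig, length(arrays),
              dimnames = list(NULL, arrays))
  ri <- match(key, probes)
  ci <- match(qt$array_id, arrays)
  for (k in seq_len(n_sig)) {
    col <- c("PM_A", "MM_A", "PM_B", "MM_B")[k]
    M[cbind(ri + (k - 1L) * length(probes), ci)] <- qt[[col]]
  }
  if (anyNA(M))
    stopf("cannot quantile-normalize: probes are not measured on every array")
  N <- limma::normalizeQuantiles(M)
  out <- as.data.frame(quartets)
  for (k in seq_len(n_sig)) {
    col <- c("PM_A", "MM_A", "PM_B", "MM_B")[k]
    out[[col]] <- pmax(N[cbind(ri + (k - 1L) * length(probes), ci)], 0)
  }
  out
}

#' Compute the RAS table from intensity quartets
#'
#' Applies optional cross-array quantile normalization, computes per-quartet
#' relative allele signals, per-strand medians and per-array RAS values for
#' every SNP.
#'
#' @param quartets intensity quartet data.frame
#' @param normalize quantile-normalize across arrays first? (default TRUE)
#' @return an object of class `ras_table`: list with `ras` (SNP x array
#'   matrix, NA where undefined) and `arrays` (data.frame `array_id`, `group`)
#' @export
ras_table <- function(quartets, normalize = TRUE) {
  req <- c("snp_id", "strand", "quartet_index", "array_id", "group",
           "PM_A", "MM_A", "PM_B", "MM_B")
  if (!all(req %in% names(quartets)))
    stopf("quartet table must have columns %s", paste(req, collapse = ", "))
  if (normalize) quartets <- normalize_intensities(quartets)
  qt <- data.table::as.data.table(quartets)
  qt[, s_value := quartet_ras(PM_A, MM_A, PM_B, MM_B)]
  strand_med <- qt[!is.na(s_value),
                   .(med = median(s_value)),
                   by = .(snp_id, array_id, strand)]
  per_array <- strand_med[, .(ras = mean(med)), by = .(snp_id, array_id)]
  arrays <- unique(qt[, .(array_id, group)])
  data.table::setorder(arrays, array_id)
  snps <- sort(unique(qt$snp_id))
  M <- matrix(NA_real_, length(snps), nrow(arrays),
              dimnames = list(snps, arrays$array_id))
  M[cbind(match(per_array$snp_id, snps),
          match(per_array$array_id, arrays$array_id))] <- per_array$ras
  structure(list(ras = M, arrays = as.data.frame(arrays)),
            class = "ras_table")
}

#' @export
print.ras_table <- function(x, ...) {
  cat(sprintf("ras_table: %d SNPs x %d arrays (%d case, %d control)\n",
              nrow(x$ras), ncol(x$ras), sum(x$arrays$group == "case"),
              sum(x$arrays$group == "control")))
  invisible(x)
}

#' Marker-level quality-control filter
#'
#' Removes SNPs flagged as lying on sex chromosomes, in copy-number-variable
#' regions, or in the mitochondrial genome (mitochondrial markers cannot be
#' normalized for copy number at the pooling stage). SNPs without annotation
#' are removed with reason `"unannotated"`.
#'
#' @param snp_ids SNP ids to filter
#' @param annotations annotation data.frame (see [read_annotation()])
#' @return list with `kept` (ids), `removed` (data.frame id/reason) and
#'   `counts` (named vector of removals by reason)
#' @export
qc_filter_markers <- function(snp_ids, annotations) {
  i <- match(snp_ids, annotations$snp_id)
  chrom <- toupper(as.character(annotations$chromosome[i]))
  reason <- rep(NA_character_, length(snp_ids))
  reason[is.na(i)] <- "unannotated"
  is_sex <- !is.na(i) & (chrom %in% c("X", "Y") |
                           (annotations$is_sex[i] %in% TRUE))
  is_mito <- !is.na(i) & (chrom %in% c("MT", "M") |
                            (annotations$is_mito[i] %in% TRUE))
  is_cnv <- !is.na(i) & (annotations$is_cnv[i] %in% TRUE)
  reason[is.na(reason) & is_sex] <- "sex_chromosome"
  reason[is.na(reason) & is_cnv] <- "cnv_region"
  reason[is.na(reason) & is_mito] <- "mitochondrial"
  removed <- !is.na(reason)
  counts <- table(factor(reason[removed],
                         levels = c("sex_chromosome", "cnv_region",
                                    "mitochondrial", "unannotated")))
  list(kept = snp_ids[!removed],
       removed = data.frame(snp_id = snp_ids[removed],
                            reason = reason[removed],
                            stringsAsFactors = FALSE),
       counts = counts)
}

#' Summarize RAS values over replicate arrays
#'
#' Per-SNP mean RAS over case arrays and over control arrays (ignoring
#' missing values), their difference, and between-array variances. SNPs with
#' no defined value in one of the groups are dropped and reported via the
#' `"dropped"` attribute.
#'
#' @param rt a [ras_table()]
#' @return data.frame with columns `snp_id`, `mean_case_ras`,
#'   `mean_control_ras`, `ras_diff`, `abs_ras_diff`, `case_var`,
#'   `control_var`, `n_case_arrays`, `n_control_arrays`
#' @export
summarize_ras <- function(rt) {
  stopifnot(inherits(rt, "ras_table"))
  case_cols <- rt$arrays$array_id[rt$arrays$group == "case"]
  ctrl_cols <- rt$arrays$array_id[rt$arrays$group == "control"]
  Mc <- rt$ras[, case_cols, drop = FALSE]
  Mn <- rt$ras[, ctrl_cols, drop = FALSE]
  nc <- rowSums(!is.na(Mc))
  nn <- rowSums(!is.na(Mn))
  mc <- rowMeans(Mc, na.rm = TRUE)
  mn <- rowMeans(Mn, na.rm = TRUE)
  row_var <- function(M, mu, k) {
    v <- rowSums((M - mu)^2, na.rm = TRUE) / pmax(k - 1L, 1L)
    v[k < 2L] <- NA_real_
    v
  }
  out <- data.frame(snp_id = rownames(rt$ras),
                    mean_case_ras = mc, mean_control_ras = mn,
                    ras_diff = mc - mn, abs_ras_diff = abs(mc - mn),
                    case_var = row_var(Mc, mc, nc),
                    control_var = row_var(Mn, mn, nn),
                    n_case_arrays = nc, n_control_arrays = nn,
                    stringsAsFactors = FALSE, row.names = NULL)
  keep <- nc >= 1L & nn >= 1L
  dropped <- out$snp_id[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Pearson correlation between mean case and mean control RAS
#'
#' The pooling-stage technical QC statistic: over SNPs, the correlation
#' between the average RAS of the case arrays and of the control arrays.
#' A high value indicates low technical variability of the pooling method.
#'
#' @param rt a [ras_table()] (or a data.frame already produced by
#'   [summarize_ras()])
#' @return list with `r`, `n` (SNPs used) and `flag` (NA unless degenerate)
#' @export
replicate_correlation <- function(rt) {
  s <- if (inherits(rt, "ras_table")) summarize_ras(rt) else rt
  s <- s[is.finite(s$mean_case_ras) & is.finite(s$mean_control_ras), ]
  if (nrow(s) < 3) stopf("need >= 3 SNPs with defined means in both groups")
  if (var(s$mean_case_ras) == 0 || var(s$mean_control_ras) == 0)
    return(list(r = NA_real_, n = nrow(s), flag = "zero_variance"))
  list(r = cor(s$mean_case_ras, s$mean_control_ras), n = nrow(s),
       flag = NA_character_)
}

#' Export Manhattan-style table of |RAS difference| by genomic position
#'
#' @param summaries output of [summarize_ras()]
#' @param annotations annotation data.frame with `snp_id`, `chromosome`,
#'   `position`
#' @return data.frame (`chromosome`, `position`, `snp_id`, `abs_ras_diff`)
#'   sorted by chromosome then position, with attribute `thresholds`
#'   `c(background = 0.08, tier = 0.12)`
#' @export
manhattan_export <- function(summaries, annotations) {
  out <- merge(summaries[, c("snp_id", "abs_ras_diff")],
               annotations[, c("snp_id", "chromosome", "position")],
               by = "snp_id")
  out <- out[order(chrom_rank(out$chromosome), out$position), ,
             drop = FALSE]
  out <- out[, c("chromosome", "position", "snp_id", "abs_ras_diff")]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(background = 0.08, tier = 0.12)
  out
}
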