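# Discovery-phase SNP prioritization: |RAS difference| ranking, the
# LD-weighted cluster method, and the combined Z-test, plus the overlap
# accounting between the three selections.

#' Rank SNPs by absolute RAS difference
#'
#' Two tiers are used in the discovery phase: markers strictly above the 8%
#' background level (`inclusive = FALSE`) feed the cluster method, while the
#' selection tier keeps markers at or above 12% (`inclusive = TRUE`).
#'
#' @param summaries output of [summarize_ras()]; if columns `chromosome` and
#'   `position` are present they break ties in the ordering
#' @param threshold |RAS difference| threshold
#' @param inclusive keep SNPs with `abs_ras_diff >= threshold` (TRUE) or
#'   strictly `> threshold` (FALSE)
#' @return the qualifying rows sorted by decreasing `abs_ras_diff`, ties by
#'   chromosome then position
#' @export
rank_by_rasdiff <- function(summaries, threshold = 0.12, inclusive = TRUE) {
  keep <- if (inclusive) summaries$abs_ras_diff >= threshold
          else summaries$abs_ras_diff > threshold
  out <- summaries[keep & !is.na(summaries$abs_ras_diff), , drop = FALSE]
  cr <- if ("chromosome" %in% names(out)) chrom_rank(out$chromosome)
        else rep(0L, nrow(out))
  pos <- if ("position" %in% names(out)) out$position else rep(0L, nrow(out))
  out <- out[order(-out$abs_ras_diff, cr, pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign above-threshold SNPs to genic and intergenic clusters
#'
#' A SNP lying within a gene, or within a flank of 10% of the gene length on
#' either side, joins that gene's cluster (genic assignment takes
#' precedence). Remaining SNPs are tiled per chromosome into non-overlapping
#' 100 kb windows anchored at the leftmost unassigned SNP; a window forms an
#' intergenic cluster only if it contains at least `min_intergenic` SNPs,
#' otherwise its SNPs are reported as unclustered.
#'
#' @param snp_ids above-threshold SNP ids (threshold already applied)
#' @param annotations annotation data.frame; genic SNPs need `gene_id`,
#'   `gene_start`, `gene_end`
#' @param window_size intergenic window width in bp (default 100 kb)
#' @param min_intergenic minimum SNPs per intergenic cluster (default 5)
#' @return list with `clusters` (data.frame: `cluster_id`, `kind`,
#'   `chromosome`, `start`, `end`, `n_members`), `members` (data.frame:
#'   `cluster_id`, `snp_id`) and `unclustered` (ids)
#' @export
assign_clusters <- function(snp_ids, annotations, window_size = 100000L,
                            min_intergenic = 5L) {
  i <- match(snp_ids, annotations$snp_id)
  if (anyNA(i))
    stopf("unannotated SNPs: %s", paste(snp_ids[is.na(i)], collapse = ", "))
  ann <- annotations[i, , drop = FALSE]
  has_gene <- !is.na(ann$gene_id %||% rep(NA, nrow(ann))) &
    nzchar(as.character(ann$gene_id %||% ""))
  genic <- rep(FALSE, length(snp_ids))
  g_start <- g_end <- rep(NA_real_, length(snp_ids))
  if (any(has_gene)) {
    len <- ann$gene_end[has_gene] - ann$gene_start[has_gene] + 1
    flank <- floor(0.10 * len)
    g_start[has_gene] <- ann$gene_start[has_gene] - flank
    g_end[has_gene] <- ann$gene_end[has_gene] + flank
    genic[has_gene] <- ann$position[has_gene] >= g_start[has_gene] &
      ann$position[has_gene] <= g_end[has_gene]
  }
  clusters <- list(); members <- list(); unclustered <- character()
  if (any(genic)) {
    for (gid in unique(ann$gene_id[genic])) {
      sel <- genic & ann$gene_id == gid
      cid <- sprintf("genic_%s", gid)
      clusters[[cid]] <- data.frame(
        cluster_id = cid, kind = "genic",
        chromosome = ann$chromosome[sel][1],
        start = min(g_start[sel]), end = max(g_end[sel]),
        n_members = sum(sel), stringsAsFactors = FALSE)
      members[[cid]] <- data.frame(cluster_id = cid,
                                   snp_id = snp_ids[sel],
                                   stringsAsFactors = FALSE)
    }
  }
  rest <- which(!genic)
  if (length(rest)) {
    k <- 0L
    for (ch in unique(ann$chromosome[rest])) {
      idx <- rest[ann$chromosome[rest] == ch]
      idx <- idx[order(ann$position[idx])]
      while (length(idx)) {
        anchor <- ann$position[idx[1]]
        inwin <- idx[ann$position[idx] <= anchor + window_size - 1]
        if (length(inwin) >= min_intergenic) {
          k <- k + 1L
          cid <- sprintf("intergenic_%d", k)
          clusters[[cid]] <- data.frame(
            cluster_id = cid, kind = "intergenic", chromosome = ch,
            start = anchor, end = anchor + window_size - 1,
            n_members = length(inwin), stringsAsFactors = FALSE)
          members[[cid]] <- data.frame(cluster_id = cid,
                                       snp_id = snp_ids[inwin],
                                       stringsAsFactors = FALSE)
        } else {
          unclustered <- c(unclustered, snp_ids[inwin])
        }
        idx <- setdiff(idx, inwin)
      }
    }
  }
  list(clusters = if (length(clusters)) do.call(rbind, clusters)
       else data.frame(cluster_id = character(), kind = character(),
                       chromosome = character(), start = numeric(),
                       end = numeric(), n_members = integer()),
       members = if (length(members)) do.call(rbind, members)
       else data.frame(cluster_id = character(), snp_id = character()),
       unclustered = unclustered)
}

#' LD score of a cluster
#'
#' Every set of at least two member SNPs connected by pairwise r2 >= `r2_min`
#' represents a single LD signal and contributes one point: the score is the
#' number of connected components of size >= 2 in the graph whose edges join
#' member pairs with high LD. Singletons contribute nothing (optionally
#' counted via `count_singletons` for sensitivity analysis). Member pairs
#' absent from the LD matrix are treated as r2 = 0.
#'
#' @param member_ids SNP ids of the cluster members
#' @param ld symmetric r2 matrix with SNP ids as dimnames ([ld_matrix()])
#' @param r2_min LD threshold (default 0.8)
#' @param count_singletons count single SNPs as signals too? (default FALSE)
#' @return integer LD score
#' @export
ld_score <- function(member_ids, ld, r2_min = 0.8, count_singletons = FALSE) {
  if (length(member_ids) == 0) return(0L)
  if (count_singletons && length(member_ids) == 1) return(1L)
  have <- member_ids[member_ids %in% rownames(ld)]
  edges <- NULL
  if (length(have) >= 2) {
    sub <- ld[have, have, drop = FALSE]
    sub[is.na(sub)] <- 0
    pairs <- which(upper.tri(sub) & sub >= r2_min, arr.ind = TRUE)
    if (nrow(pairs))
      edges <- data.frame(from = have[pairs[, 1]], to = have[pairs[, 2]])
  }
  g <- igraph::graph_from_data_frame(
    edges %||% data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = member_ids))
  comp <- igraph::components(g)
  score <- sum(comp$csize >= 2)
  if (count_singletons) score <- score + sum(comp$csize == 1)
  as.integer(score)
}

#' Score clusters and keep those above a minimum LD score
#'
#' @param assignment output of [assign_clusters()]
#' @param ld r2 matrix covering the member SNPs
#' @param min_score minimum LD score (default 5)
#' @param r2_min LD threshold passed to [ld_score()]
#' @return the `clusters` data.frame with an `ld_score` column, filtered to
#'   `ld_score >= min_score`; attribute `all_scores` keeps every cluster
#' @export
select_clusters <- function(assignment, ld, min_score = 5L, r2_min = 0.8) {
  cl <- assignment$clusters
  cl$ld_score <- vapply(cl$cluster_id, function(cid) {
    ld_score(assignment$members$snp_id[assignment$members$cluster_id == cid],
             ld, r2_min = r2_min)
  }, integer(1))
  out <- cl[cl$ld_score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_scores") <- cl
  out
}

#' Choose the representative SNP of a cluster
#'
#' Members already selected by the |RAS difference| method are preferred
#' (highest `abs_ras_diff` among them); otherwise the member with highest
#' `abs_ras_diff` among those with MAF > `maf_min` for which genotyping
#' primers can be designed. Returns NA when no member qualifies, mirroring
#' clusters that cannot be taken to genotyping.
#'
#' @param members data.frame with `snp_id`, `abs_ras_diff`, `maf`,
#'   `designable`
#' @param rasdiff_selected character vector of SNPs selected by the
#'   |RAS difference| method
#' @param maf_min minor-allele-frequency floor (default 0.05, exclusive)
#' @return a single `snp_id` or `NA_character_`
#' @export
choose_representative <- function(members, rasdiff_selected,
                                  maf_min = 0.05) {
  stopifnot(all(c("snp_id", "abs_ras_diff") %in% names(members)))
  in_ras <- members$snp_id %in% rasdiff_selected
  if (any(in_ras)) {
    cand <- members[in_ras, ]
    return(cand$snp_id[which.max(cand$abs_ras_diff)])
  }
  ok <- (members$maf %||% rep(NA_real_, nrow(members))) > maf_min &
    (members$designable %||% rep(TRUE, nrow(members))) %in% TRUE
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NA_character_)
  cand <- members[ok, ]
  cand$snp_id[which.max(cand$abs_ras_diff)]
}

#' Combined Z-test for one SNP's pooled RAS values
#'
#' Tests the case-control difference in mean RAS, accounting for both
#' sampling error (the binomial variance of allele frequencies estimated
#' from finite pools of individuals) and experimental error (the
#' between-array variance of the replicate RAS values):
#' `V_samp = pbar (1 - pbar) (1/(2 N_case) + 1/(2 N_control))` with `pbar`
#' the mean RAS over all arrays, `V_exp = var_case/k_case +
#' var_control/k_control`, and `Z = (mean_case - mean_control) /
#' sqrt(V_samp + V_exp)` with a two-sided normal p-value. This variance
#' decomposition is a reconstruction of the combined test used for pooled
#' GWAS ranking; both components are returned for inspection.
#'
#' @param case_ras,control_ras RAS values over the replicate arrays (>= 2
#'   per group)
#' @param n_case,n_control numbers of individuals in the pools
#' @return list with `z`, `p_value`, `d`, `v_sampling`, `v_experimental`,
#'   `flag`
#' @export
combined_z <- function(case_ras, control_ras, n_case, n_control) {
  if (length(case_ras) < 2 || length(control_ras) < 2)
    stopf("need >= 2 arrays per group")
  if (n_case < 1 || n_control < 1) stopf("pool sizes must be >= 1")
  d <- mean(case_ras) - mean(control_ras)
  pbar <- mean(c(case_ras, control_ras))
  v_samp <- pbar * (1 - pbar) * (1 / (2 * n_case) + 1 / (2 * n_control))
  v_exp <- var(case_ras) / length(case_ras) +
    var(control_ras) / length(control_ras)
  v <- v_samp + v_exp
  if (v == 0) {
    if (d == 0)
      return(list(z = 0, p_value = 1, d = 0, v_sampling = 0,
                  v_experimental = 0, flag = "zero_variance"))
    stopf("zero total variance with a nonzero difference")
  }
  z <- d / sqrt(v)
  list(z = z, p_value = 2 * pnorm(-abs(z)), d = d, v_sampling = v_samp,
       v_experimental = v_exp, flag = NA_character_)
}

#' Combined Z-test over a whole RAS table
#'
#' Vectorized version of [combined_z()] applied to every SNP of a
#' [ras_table()]. SNPs with fewer than two defined values in either group
#' are returned with NA statistics.
#'
#' @param rt a [ras_table()]
#' @param n_case,n_control numbers of individuals in the pools
#' @return data.frame `snp_id`, `z`, `p_value`, `d`, `v_sampling`,
#'   `v_experimental`
#' @export
combined_z_table <- function(rt, n_case, n_control) {
  stopifnot(inherits(rt, "ras_table"))
  Mc <- rt$ras[, rt$arrays$array_id[rt$arrays$group == "case"], drop = FALSE]
  Mn <- rt$ras[, rt$arrays$array_id[rt$arrays$group == "control"], drop = FALSE]
  kc <- rowSums(!is.na(Mc)); kn <- rowSums(!is.na(Mn))
  mc <- rowMeans(Mc, na.rm = TRUE); mn <- rowMeans(Mn, na.rm = TRUE)
  vc <- rowSums((Mc - mc)^2, na.rm = TRUE) / pmax(kc - 1, 1)
  vn <- rowSums((Mn - mn)^2, na.rm = TRUE) / pmax(kn - 1, 1)
  k_all <- rowSums(!is.na(rt$ras))
  pbar <- rowSums(rt$ras, na.rm = TRUE) / k_all
  d <- mc - mn
  v_samp <- pbar * (1 - pbar) * (1 / (2 * n_case) + 1 / (2 * n_control))
  v_exp <- vc / pmax(kc, 1) + vn / pmax(kn, 1)
  z <- d / sqrt(v_samp + v_exp)
  ok <- kc >= 2 & kn >= 2
  z[!ok] <- NA_real_
  data.frame(snp_id = rownames(rt$ras), z = z,
             p_value = 2 * pnorm(-abs(z)), d = d, v_sampling = v_samp,
             v_experimental = v_exp, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Rank SNPs by combined Z-test p-value
#'
#' @param ztab output of [combined_z_table()]; optional `chromosome` and
#'   `position` columns refine the tie-break
#' @param top_k number of SNPs to keep
#' @return the `top_k` rows with smallest p-value; ties broken by decreasing
#'   |Z|, then genomic order, then SNP id
#' @export
rank_by_z <- function(ztab, top_k = 49L) {
  out <- ztab[!is.na(ztab$p_value), , drop = FALSE]
  cr <- if ("chromosome" %in% names(out)) chrom_rank(out$chromosome)
        else rep(0L, nrow(out))
  pos <- if ("position" %in% names(out)) out$position else rep(0L, nrow(out))
  out <- out[order(out$p_value, -abs(out$z), cr, pos, out$snp_id), ,
             drop = FALSE]
  out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Overlap accounting between the three selection methods
#'
#' @param sets named list of three character vectors of SNP ids (e.g.
#'   `rasdiff`, `cluster`, `ztest`)
#' @return list with `sizes`, `pairwise` (named intersection counts),
#'   `triple`, and `union` (data.frame `snp_id`, `methods`)
#' @export
selection_overlap <- function(sets) {
  if (length(sets) != 3 || is.null(names(sets)))
    stopf("`sets` must be a named list of three SNP id vectors")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pairwise <- vapply(pairs, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])), integer(1))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = "&")
  triple <- length(Reduce(intersect, sets))
  all_ids <- sort(unique(unlist(sets)))
  methods <- vapply(all_ids, function(id)
    paste(nm[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = ","), character(1))
  list(sizes = vapply(sets, length, integer(1)),
       pairwise = pairwise, triple = triple,
       union = data.frame(snp_id = all_ids, methods = unname(methods),
                          stringsAsFactors = FALSE))
}
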