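summ <- function(abs_diffs, ids = sprintf("s%d", seq_along(abs_diffs))) {
  data.frame(snp_id = ids, abs_ras_diff = abs_diffs,
             stringsAsFactors = FALSE)
}

test_that("RAS-difference ranking honours the tier operators", {
  s <- summ(c(0.19, 0.13, 0.09, 0.05))
  bg <- rank_by_rasdiff(s, 0.08, inclusive = FALSE)
  expect_equal(bg$abs_ras_diff, c(0.19, 0.13, 0.09))
  tier <- rank_by_rasdiff(s, 0.12, inclusive = TRUE)
  expect_equal(nrow(tier), 2)
  expect_equal(nrow(rank_by_rasdiff(summ(c(0.01, 0.02)), 0.08,
                                    inclusive = FALSE)), 0)
  # boundary: exactly at threshold
  expect_equal(nrow(rank_by_rasdiff(summ(0.12), 0.12, inclusive = TRUE)), 1)
  expect_equal(nrow(rank_by_rasdiff(summ(0.08), 0.08, inclusive = FALSE)), 0)
})

ann_for_clusters <- function() {
  data.frame(
    snp_id = sprintf("s%d", 1:12),
    chromosome = c(rep("1", 8), rep("2", 4)),
    position = c(15000, 20900, 22000, 100000, 120000, 150000, 170000, 185000,
                 5000, 30000, 60000, 500000),
    gene_id = c("G1", "G1", "", "", "", "", "", "", "", "", "", ""),
    gene_start = c(10000, 10000, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    gene_end = c(20000, 20000, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

test_that("cluster assignment: genic flanks, 100 kb windows, 5-SNP minimum", {
  ann <- ann_for_clusters()
  res <- assign_clusters(ann$snp_id, ann)
  memb <- split(res$members$snp_id, res$members$cluster_id)

  # s1 inside gene; s2 at 20900 within the 10% downstream flank
  # (gene length 10001 -> flank 1000 -> genic through 21000)
  expect_setequal(memb$genic_G1, c("s1", "s2"))
  # s3 at 22000 is outside the flank, joins the intergenic tiling
  expect_false("s3" %in% memb$genic_G1)

  # chr1 window anchored at s3 (22000) spans to 121999: s3,s4,s5 -> only 3
  # SNPs, no cluster; next window anchored at 150000 has 3 SNPs, no cluster
  # chr2 has 4 SNPs in any window -> none
  inter <- res$clusters[res$clusters$kind == "intergenic", ]
  expect_equal(nrow(inter), 0)
  expect_setequal(res$unclustered,
                  c("s3", "s4", "s5", "s6", "s7", "s8", "s9", "s10",
                    "s11", "s12"))

  # five SNPs spanning 90 kb form one intergenic cluster; four do not
  ann5 <- data.frame(snp_id = sprintf("t%d", 1:5), chromosome = "3",
                     position = c(1000, 20000, 40000, 70000, 91000),
                     stringsAsFactors = FALSE)
  r5 <- assign_clusters(ann5$snp_id, ann5)
  expect_equal(nrow(r5$clusters), 1)
  expect_equal(r5$clusters$kind, "intergenic")
  expect_equal(r5$clusters$n_members, 5)
  r4 <- assign_clusters(ann5$snp_id[1:4], ann5[1:4, ])
  expect_equal(nrow(r4$clusters), 0)

  expect_error(assign_clusters(c("s1", "zzz"), ann), "unannotated")
})

test_that("cluster assignment is a partition of the above-threshold SNPs", {
  set.seed(40)
  m <- 80
  ann <- data.frame(
    snp_id = sprintf("p%d", 1:m),
    chromosome = as.character(sample(1:3, m, TRUE)),
    position = sample(1:5e6, m),
    gene_id = ifelse(runif(m) < 0.3, sprintf("G%d", sample(1:5, m, TRUE)), ""),
    stringsAsFactors = FALSE)
  ann$gene_start <- ifelse(ann$gene_id != "", pmax(ann$position - 5000, 1), NA)
  ann$gene_end <- ifelse(ann$gene_id != "", ann$position + 5000, NA)
  res <- assign_clusters(ann$snp_id, ann)
  assigned <- res$members$snp_id
  expect_equal(anyDuplicated(assigned), 0)
  expect_setequal(c(assigned, res$unclustered), ann$snp_id)
})

test_that("LD score counts high-LD connected components of size >= 2", {
  mk <- function(ids, pairs) {
    R <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    diag(R) <- 1
    for (p in pairs) R[p[[1]], p[[2]]] <- R[p[[2]], p[[1]]] <- p[[3]]
    R
  }
  ld2 <- mk(c("a", "b"), list(list("a", "b", 0.9)))
  expect_equal(ld_score(c("a", "b"), ld2), 1L)

  ld4 <- mk(letters[1:4], list(list("a", "b", 0.85), list("c", "d", 0.95)))
  expect_equal(ld_score(letters[1:4], ld4), 2L)

  ld6 <- mk(letters[1:6],
            list(list("a", "b", 0.85), list("a", "c", 0.85),
                 list("b", "c", 0.85), list("d", "e", 0.82)))
  expect_equal(ld_score(letters[1:6], ld6), 2L)

  # singletons score zero unless asked to count
  expect_equal(ld_score("a", ld2), 0L)
  expect_equal(ld_score("a", ld2, count_singletons = TRUE), 1L)
  # pairs missing from the matrix are treated as r2 = 0
  expect_equal(ld_score(c("a", "b", "zz"), ld2), 1L)
})

test_that("LD score equals the exhaustive component oracle on random graphs", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    ids <- sprintf("v%d", 1:n)
    R <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    diag(R) <- 1
    adj <- R >= 0.8
    diag(adj) <- FALSE
    expect_equal(ld_score(ids, R, r2_min = 0.8),
                 oracle_component_score(adj))
  }
})

test_that("cluster selection keeps LD scores at or above the minimum", {
  assignment <- list(
    clusters = data.frame(cluster_id = c("c1", "c2", "c3"), kind = "genic",
                          chromosome = "1", start = 1, end = 10,
                          n_members = 2, stringsAsFactors = FALSE),
    members = data.frame(cluster_id = rep(c("c1", "c2", "c3"), each = 2),
                         snp_id = sprintf("m%d", 1:6),
                         stringsAsFactors = FALSE))
  ids <- sprintf("m%d", 1:6)
  R <- matrix(0, 6, 6, dimnames = list(ids, ids)); diag(R) <- 1
  R["m1", "m2"] <- R["m2", "m1"] <- 0.9
  sel <- select_clusters(assignment, R, min_score = 1)
  expect_equal(sel$cluster_id, "c1")
  expect_equal(attr(sel, "all_scores")$ld_score, c(1L, 0L, 0L))
  expect_equal(nrow(select_clusters(assignment, R, min_score = 5)), 0)
})

test_that("representative choice prefers RAS-selected, then MAF/designability", {
  memb <- data.frame(snp_id = c("x", "y"), abs_ras_diff = c(0.10, 0.14),
                     maf = c(0.2, 0.3), designable = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(choose_representative(memb, rasdiff_selected = "x"), "x")

  memb2 <- data.frame(snp_id = c("x", "y"), abs_ras_diff = c(0.11, 0.13),
                      maf = c(0.10, 0.02), designable = c(TRUE, TRUE),
                      stringsAsFactors = FALSE)
  expect_equal(choose_representative(memb2, character(0)), "x")

  memb3 <- transform(memb2, designable = FALSE)
  expect_true(is.na(choose_representative(memb3, character(0))))
})

test_that("combined Z-test matches independent arithmetic and its limits", {
  # vectors with exact means 0.55/0.45 and exact variance 1e-4
  dev <- c(-1, -1, -1, 1, 1, 1) * sqrt(5 * 1e-4 / 6)
  case <- 0.55 + dev
  ctrl <- 0.45 + dev
  expect_equal(var(case), 1e-4)
  res <- combined_z(case, ctrl, 92, 129)
  v_samp <- 0.5 * 0.5 * (1 / 184 + 1 / 258)
  v_exp <- 1e-4 / 6 + 1e-4 / 6
  expect_equal(res$v_sampling, v_samp)
  expect_equal(res$v_experimental, v_exp)
  expect_equal(res$z, 0.1 / sqrt(v_samp + v_exp))
  expect_equal(res$z, 2.058, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0396, tolerance = 1e-2)

  eq <- combined_z(c(0.5, 0.52, 0.48), c(0.48, 0.5, 0.52), 92, 129)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  # inflating the experimental variance strictly shrinks |Z|
  wide <- combined_z(0.55 + 2 * dev, 0.45 + 2 * dev, 92, 129)
  expect_lt(abs(wide$z), abs(res$z))

  expect_error(combined_z(0.5, c(0.4, 0.5), 92, 129), ">= 2")
})

test_that("Z ranking is by p, then |Z|, then genomic order", {
  zt <- data.frame(snp_id = c("a", "b", "c", "d"),
                   z = c(1.0, 3.5, -2.0, -3.5),
                   p_value = c(0.2, 0.001, 0.05, 0.001),
                   stringsAsFactors = FALSE)
  top <- rank_by_z(zt, 2)
  expect_setequal(top$snp_id, c("b", "d"))
  expect_equal(rank_by_z(zt, 10)$snp_id[3:4], c("c", "a"))
})

test_that("selection overlap counts satisfy inclusion-exclusion", {
  r <- selection_overlap(list(A = "a", B = "b", C = "c"))
  expect_true(all(r$pairwise == 0) && r$triple == 0)
  expect_equal(nrow(r$union), 3)

  r2 <- selection_overlap(list(A = c("1", "2", "3"), B = c("2", "3"),
                               C = "3"))
  expect_equal(unname(r2$pairwise), c(2L, 1L, 1L))
  expect_equal(r2$triple, 1)
  expect_equal(nrow(r2$union), 3)
  expect_equal(r2$union$methods[r2$union$snp_id == "3"], "A,B,C")

  same <- selection_overlap(list(A = c("x", "y"), B = c("x", "y"),
                                 C = c("x", "y")))
  expect_equal(same$triple, 2)

  # property: |union| = sum|sets| - sum|pairwise| + |triple|
  set.seed(42)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(0:15, 1)))
    names(sets) <- c("A", "B", "C")
    r <- selection_overlap(sets)
    expect_equal(nrow(r$union),
                 sum(r$sizes) - sum(r$pairwise) + r$triple)
  }
})
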