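# Independent oracles used to cross-check the package implementations.

# connected components by exhaustive depth-first search on an adjacency
# matrix; returns the number of components with >= 2 vertices
oracle_component_score <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  score <- 0L
  for (v in seq_len(n)) {
    if (seen[v]) next
    stack <- v
    comp <- integer(0)
    while (length(stack)) {
      u <- stack[[1]]
      stack <- stack[-1]
      if (seen[u]) next
      seen[u] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, which(adj[u, ] & !seen))
    }
    if (length(comp) >= 2) score <- score + 1L
  }
  score
}

# exact conditional HWE p-value via binomial-coefficient combinatorics
# (independent route from the package's log-factorial recursion)
oracle_hwe_exact <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  n_alt <- 2 * hom_alt + het
  n_ref <- 2 * hom_ref + het
  if (n_alt == 0 || n_ref == 0) return(1)
  nr <- min(n_alt, n_ref)
  hets <- seq(nr %% 2, nr, by = 2)
  pr <- vapply(hets, function(h) {
    n1 <- (nr - h) / 2
    choose(n, n1) * choose(n - n1, h) * 2^h / choose(2 * n, nr)
  }, numeric(1))
  obs <- pr[match(het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# maximum-likelihood logistic fit of y ~ dosage by direct Newton iteration
# on the 2 x 3 genotype-table log-likelihood
oracle_logistic_newton <- function(x, y, max_iter = 200, tol = 1e-12) {
  counts <- table(factor(y, 0:1), factor(x, 0:2))
  g <- 0:2
  n1 <- as.numeric(counts[2, ])   # cases per dosage
  nt <- as.numeric(colSums(counts))
  b <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- b[1] + b[2] * g
    p <- 1 / (1 + exp(-eta))
    grad <- c(sum(n1 - nt * p), sum(g * (n1 - nt * p)))
    w <- nt * p * (1 - p)
    H <- -matrix(c(sum(w), sum(w * g), sum(w * g), sum(w * g^2)), 2, 2)
    step <- solve(H, grad)
    b <- b - step
    if (max(abs(step)) < tol) break
  }
  eta <- b[1] + b[2] * g
  p <- 1 / (1 + exp(-eta))
  w <- nt * p * (1 - p)
  info <- matrix(c(sum(w), sum(w * g), sum(w * g), sum(w * g^2)), 2, 2)
  se <- sqrt(diag(solve(info)))
  list(beta = b, se = se)
}

# sort-based median (mean of central pair for even counts)
oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
}

# small helper: genotype_dataset from raw pieces
make_gd <- function(G, pheno, label = "test") {
  colnames(G) <- colnames(G) %||% sprintf("snp%d", seq_len(ncol(G)))
  poolscan::genotype_dataset(G, phenotype = pheno, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pool-frequency matrix (2 identical biological replicates) from a
# frequency vector
freq_matrix <- function(f, ids = sprintf("s%04d", seq_along(f))) {
  matrix(rep(f, each = 2), 2, length(f),
         dimnames = list(c("bio1", "bio2"), ids))
}
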