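`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so that
#' seeded generators do not disturb the caller's random stream. All poolscan
#' generators funnel their randomness through this helper, which is what makes
#' them bit-reproducible for a fixed seed.
#'
#' @param seed single integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Integer rank for chromosome labels: 1..22, X, Y, MT, then anything else.
chrom_rank <- function(chrom) {
  chrom <- toupper(as.character(chrom))
  chrom <- sub("^CHR", "", chrom)
  r <- suppressWarnings(as.integer(chrom))
  r[chrom == "X"] <- 23L
  r[chrom == "Y"] <- 24L
  r[chrom %in% c("MT", "M")] <- 25L
  r[is.na(r)] <- 26L + as.integer(factor(chrom[is.na(r)]))
  r
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("`%s` must be numeric in [0, 1]", name)
  invisible(x)
}

# deterministic TSV writer used for all pipeline outputs
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
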