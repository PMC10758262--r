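# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Vectorized D / D' / r2 from carrier (or allele) frequencies.
# D' normalizes by the theoretical maximum of |D| given the margins; at D = 0
# it is defined as 0. Statistics are NA (undefined) when a margin is 0 or 1.
.ld_stats <- function(p_a, p_b, p_ab) {
  d <- p_ab - p_a * p_b
  den <- p_a * (1 - p_a) * p_b * (1 - p_b)
  defined <- is.finite(den) & den > 0
  r2 <- ifelse(defined, d * d / den, NA_real_)
  d_max <- ifelse(d > 0,
                  pmin(p_a * (1 - p_b), p_b * (1 - p_a)),
                  pmin(p_a * p_b, (1 - p_a) * (1 - p_b)))
  d_prime <- ifelse(defined, ifelse(d == 0, 0, d / d_max), NA_real_)
  list(d = ifelse(defined, d, NA_real_), d_prime = d_prime, r2 = r2,
       defined = defined)
}

# All-pairs r2 between the columns of two binary matrices (population moments:
# frequencies divide by n). Undefined entries (monomorphic column) are NA.
.r2_matrix <- function(x, y = x) {
  n <- nrow(x)
  p_a <- colMeans(x)
  p_b <- colMeans(y)
  p11 <- crossprod(x, y) / n
  d <- p11 - outer(p_a, p_b)
  den <- outer(p_a * (1 - p_a), p_b * (1 - p_b))
  r2 <- d * d / den
  r2[den <= 0] <- NA_real_
  list(r2 = r2, d = d, p_a = p_a, p_b = p_b, p11 = p11)
}

# Column indices of H whose variant position falls in [start, end) on chrom.
.region_cols <- function(h, region) {
  which(h$variants$chrom == region$chrom &
          h$variants$pos >= region$start &
          h$variants$pos < region$end)
}

# Carrier indicator matrix (haplotypes x regions) for a RegionSet.
.indicator_matrix <- function(h, regions) {
  n <- nrow(h$values)
  out <- matrix(0L, n, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cc <- .region_cols(h, regions[i, ])
    if (length(cc))
      out[, i] <- as.integer(rowSums(h$values[, cc, drop = FALSE]) > 0)
  }
  colnames(out) <- regions$name
  out
}

# Joint 2x2 table for two Bernoulli margins with Pearson correlation rho.
# Errors when rho is infeasible for the margins (Frechet-Hoeffding bounds).
.joint_table <- function(qa, qb, rho) {
  p11 <- qa * qb + rho * sqrt(qa * (1 - qa) * qb * (1 - qb))
  lo <- max(0, qa + qb - 1)
  hi <- min(qa, qb)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop(sprintf(
      "carrier correlation %.3f infeasible for margins (%.4f, %.4f): joint frequency %.5f outside Frechet bounds [%.5f, %.5f]",
      rho, qa, qb, p11, lo, hi))
  p11 <- min(max(p11, lo), hi)
  c(p11 = p11, p10 = qa - p11, p01 = qb - p11, p00 = 1 - qa - qb + p11)
}

# Write a data.frame as TSV with `#key=value` config-echo header lines.
.write_tsv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(config))
    writeLines(paste0("#", names(config), "=", unlist(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
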