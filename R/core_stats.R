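#' Carrier profile of a region
#'
#' Collapses the rare variants inside a region into a per-haplotype binary
#' carrier indicator: 1 iff the haplotype carries at least one minor allele at
#' a variant whose (0-based) position lies in `[start, end)` on the region's
#' chromosome. The mean of the indicator is the region's cumulative minor
#' allele frequency (cMAF).
#'
#' @param h A `HaplotypeMatrix`.
#' @param region A single region: one row of a `RegionSet`, or any list with
#'   `name`, `chrom`, `start`, `end`.
#' @return A `CarrierProfile`: list with `region_name`, `indicator` (integer
#'   0/1 vector over haplotypes) and `cmaf`.
#' @export
carrier_profile <- function(h, region) {
  stopifnot(inherits(h, "HaplotypeMatrix"))
  cc <- .region_cols(h, region)
  n <- nrow(h$values)
  ind <- if (length(cc)) as.integer(rowSums(h$values[, cc, drop = FALSE]) > 0)
         else integer(n)
  structure(list(region_name = as.character(region$name), indicator = ind,
                 cmaf = mean(ind)),
            class = "CarrierProfile")
}

#' Joint carrier frequency of two regions
#'
#' Fraction of haplotypes carrying at least one rare variant in both regions
#' (the cumulative analogue of the two-locus haplotype frequency P_AB).
#'
#' @param a,b `CarrierProfile` objects over the same haplotypes.
#' @return A frequency in `[0, 1]`.
#' @export
joint_carrier_freq <- function(a, b) {
  if (length(a$indicator) != length(b$indicator))
    stop("carrier profiles have different haplotype counts (",
         length(a$indicator), " vs ", length(b$indicator), ")")
  mean(a$indicator == 1L & b$indicator == 1L)
}

# assemble a CLDResult from frequencies
.cld_result <- function(name_a, name_b, p_a, p_b, p_ab, n) {
  s <- .ld_stats(p_a, p_b, p_ab)
  structure(list(region_a = name_a, region_b = name_b,
                 p_a = p_a, p_b = p_b, p_ab = p_ab,
                 d = s$d, d_prime = s$d_prime, r2 = s$r2,
                 n = n, defined = s$defined),
            class = "CLDResult")
}

#' Cumulative linkage disequilibrium between two regions
#'
#' Applies the classical LD formulas to region-level carrier frequencies:
#' with cMAFs `p_a`, `p_b` and joint carrier frequency `p_ab`,
#' `D = p_ab - p_a * p_b`, `r2 = D^2 / (p_a (1-p_a) p_b (1-p_b))`, and `D'`
#' normalizes D by its theoretical maximum given the margins. When either
#' cMAF is 0 or 1 the statistics are undefined and flagged (`defined = FALSE`,
#' values `NA`) rather than silently 0.
#'
#' @param a,b `CarrierProfile` objects over the same haplotypes (length >= 2).
#' @return A `CLDResult`: list with `region_a`, `region_b`, `p_a`, `p_b`,
#'   `p_ab`, `d`, `d_prime`, `r2`, `n`, `defined`.
#' @export
cld <- function(a, b) {
  n <- length(a$indicator)
  if (n < 2) stop("need at least 2 haplotypes")
  p_ab <- joint_carrier_freq(a, b)
  .cld_result(a$region_name, b$region_name, a$cmaf, b$cmaf, p_ab, n)
}

#' @export
print.CLDResult <- function(x, ...) {
  cat(sprintf("cLD %s ~ %s (n = %d haplotypes)\n", x$region_a, x$region_b, x$n))
  cat(sprintf("  p_a = %.4g  p_b = %.4g  p_ab = %.4g\n", x$p_a, x$p_b, x$p_ab))
  if (x$defined)
    cat(sprintf("  D = %.4g  D' = %.4g  r2 = %.4g\n", x$d, x$d_prime, x$r2))
  else cat("  statistics undefined (a cMAF is 0 or 1)\n")
  invisible(x)
}

#' Standard LD between two variants
#'
#' Single-variant r2 from minor-allele frequencies and the joint minor-allele
#' haplotype frequency. Monomorphic columns yield an undefined (flagged)
#' result.
#'
#' @param h A `HaplotypeMatrix`.
#' @param i,j Distinct variant column indices.
#' @return A `CLDResult` whose region names are the variant identifiers.
#' @export
ld <- function(h, i, j) {
  stopifnot(inherits(h, "HaplotypeMatrix"), i != j)
  x <- h$values[, i]
  y <- h$values[, j]
  id <- function(k) paste0(h$variants$chrom[k], ":", h$variants$pos[k] + 1L,
                           "_", h$variants$ref_alt[k])
  .cld_result(id(i), id(j), mean(x), mean(y), mean(x == 1L & y == 1L),
              nrow(h$values))
}

#' Gene-pair averaged LD
#'
#' The LD of a gene pair is the average r2 over cross-region rare variant
#' pairs. When the number of pairs exceeds `max_pairs`, that many pairs are
#' sampled uniformly without replacement (seeded). Variant pairs with
#' undefined r2 are excluded from the mean and counted.
#'
#' @param h A `HaplotypeMatrix` (already restricted to rare variants).
#' @param region_a,region_b Single regions (rows of a `RegionSet`).
#' @param max_pairs Sampling cap on cross-region variant pairs (default 2000).
#' @param rng_seed Seed used only when sampling is needed.
#' @return List with `mean_r2`, `n_pairs_used`, `n_undefined`, `defined`.
#' @export
gene_pair_ld <- function(h, region_a, region_b, max_pairs = 2000,
                         rng_seed = NULL) {
  ca <- .region_cols(h, region_a)
  cb <- .region_cols(h, region_b)
  if (!length(ca) || !length(cb))
    stop("both regions must contain at least one variant column")
  total <- length(ca) * length(cb)
  if (total <= max_pairs) {
    r2 <- .r2_matrix(h$values[, ca, drop = FALSE],
                     h$values[, cb, drop = FALSE])$r2
    vals <- as.vector(r2)
  } else {
    pick <- .with_seed(rng_seed, sample.int(total, max_pairs))
    ia <- ca[((pick - 1L) %% length(ca)) + 1L]
    ib <- cb[((pick - 1L) %/% length(ca)) + 1L]
    x <- h$values[, ia, drop = FALSE]
    y <- h$values[, ib, drop = FALSE]
    n <- nrow(x)
    p_a <- colMeans(x)
    p_b <- colMeans(y)
    p11 <- colMeans(x * y)
    vals <- .ld_stats(p_a, p_b, p11)$r2
  }
  n_undef <- sum(is.na(vals))
  used <- sum(!is.na(vals))
  list(mean_r2 = if (used) mean(vals, na.rm = TRUE) else NA_real_,
       n_pairs_used = used, n_undefined = n_undef, defined = used > 0)
}

#' Rare-common cLD between a common variant and a region
#'
#' One side is a single (typically common) variant, the other a region's rare
#' carrier indicator: `p_a` is the variant's MAF, `p_b` the region cMAF, and
#' `p_ab` the fraction of haplotypes carrying the variant's minor allele and
#' at least one regional rare allele.
#'
#' @param h A `HaplotypeMatrix`.
#' @param common_variant Variant column index.
#' @param region A single region.
#' @return A `CLDResult`.
#' @export
rare_common_cld <- function(h, common_variant, region) {
  stopifnot(inherits(h, "HaplotypeMatrix"))
  x <- h$values[, common_variant]
  b <- carrier_profile(h, region)
  id <- paste0(h$variants$chrom[common_variant], ":",
               h$variants$pos[common_variant] + 1L)
  .cld_result(id, b$region_name, mean(x),
              b$cmaf, mean(x == 1L & b$indicator == 1L), nrow(h$values))
}

#' Pairwise cLD over a region set
#'
#' Computes a `CLDResult` row for every unordered region pair (optionally
#' restricted to pairs on the same chromosome). Midpoint-to-midpoint distance
#' is reported for same-chromosome pairs.
#'
#' @param h A `HaplotypeMatrix` (restricted to rare variants by the caller).
#' @param regions A `RegionSet` with >= 2 regions.
#' @param same_chrom_only Keep only same-chromosome pairs.
#' @return data.frame sorted by (chrom_a, region_a, region_b) with columns
#'   `region_a`, `region_b`, `chrom_a`, `chrom_b`, `distance`, `n_hap`, `p_a`,
#'   `p_b`, `p_ab`, `d`, `d_prime`, `r2`, `defined`.
#' @export
pairwise_cld <- function(h, regions, same_chrom_only = FALSE) {
  stopifnot(inherits(h, "HaplotypeMatrix"), nrow(regions) >= 2)
  ind <- .indicator_matrix(h, regions)
  n <- nrow(ind)
  r <- nrow(regions)
  p <- colMeans(ind)
  p11 <- crossprod(ind) / n
  idx <- which(upper.tri(p11), arr.ind = TRUE)
  if (same_chrom_only)
    idx <- idx[regions$chrom[idx[, 1]] == regions$chrom[idx[, 2]], , drop = FALSE]
  i <- idx[, 1]; j <- idx[, 2]
  mid <- (regions$start + regions$end) / 2
  s <- .ld_stats(p[i], p[j], p11[idx])
  out <- data.frame(
    region_a = regions$name[i], region_b = regions$name[j],
    chrom_a = regions$chrom[i], chrom_b = regions$chrom[j],
    distance = ifelse(regions$chrom[i] == regions$chrom[j],
                      abs(mid[i] - mid[j]), NA_real_),
    n_hap = n, p_a = p[i], p_b = p[j], p_ab = p11[idx],
    d = s$d, d_prime = s$d_prime, r2 = s$r2, defined = s$defined,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom_a, out$region_a, out$region_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
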