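#' Synthetic phased rare-variant fixture generator
#'
#' Generates a phased haplotype matrix with a specified rare-variant MAF
#' spectrum and tunable between-region carrier correlation, together with its
#' regions and a truth table. Per region, per-variant MAF targets are drawn
#' uniformly from `[maf_low, maf_high]` and imply a region cMAF
#' `q = 1 - prod(1 - maf_s)`; the per-haplotype carrier indicator is drawn
#' first (Bernoulli with that cMAF, jointly across designated region pairs
#' via the 2x2 table matching the target correlation `rho`), and carrier
#' haplotypes are then assigned at least one rare allele, each variant
#' included with its conditional probability `maf_s / q`. Regions are laid
#' consecutively on one chromosome so pair distances span the geometric
#' distance groups.
#'
#' An infeasible `rho` for the implied margins is an error naming the
#' Frechet bound.
#'
#' @param n_hap Number of haplotypes (must be even: 2 per diploid sample).
#' @param n_regions Number of regions.
#' @param variants_per_region Rare variants per region (scalar or vector).
#' @param maf_low,maf_high Per-variant MAF target range,
#'   `0 < maf_low <= maf_high < 0.5`.
#' @param rho Target carrier correlation applied to consecutive disjoint
#'   region pairs (1,2), (3,4), ...; 0 leaves all regions independent.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @param region_span Width of each region in bp.
#' @param region_gap Gap between consecutive regions in bp.
#' @return List with `h` (`HaplotypeMatrix`), `regions` (`RegionSet`) and
#'   `truth` (list: `cmaf` target per region, `rho`, `cor_pairs` matrix of
#'   correlated index pairs, `variant_maf` targets per region).
#' @export
make_fixture <- function(n_hap = 200, n_regions = 40, variants_per_region = 30,
                         maf_low = 0.001, maf_high = 0.004, rho = 0, seed = 1,
                         chrom = "chr1", region_span = 20000,
                         region_gap = 30000) {
  stopifnot(n_hap >= 2, n_hap %% 2 == 0, n_regions >= 1,
            maf_low > 0, maf_low <= maf_high, maf_high < 0.5, abs(rho) <= 1)
  vpr <- rep_len(variants_per_region, n_regions)
  .with_seed(seed, {
    maf_t <- lapply(vpr, function(v) stats::runif(v, maf_low, maf_high))
    q <- vapply(maf_t, function(m) 1 - prod(1 - m), 0)
    cor_pairs <- if (rho != 0 && n_regions >= 2)
      cbind(seq(1, n_regions - 1, by = 2), seq(2, n_regions, by = 2))
    else matrix(integer(0), 0, 2)
    ind <- matrix(0L, n_hap, n_regions)
    done <- rep(FALSE, n_regions)
    for (k in seq_len(nrow(cor_pairs))) {
      i <- cor_pairs[k, 1]; j <- cor_pairs[k, 2]
      jt <- .joint_table(q[i], q[j], rho)
      cell <- sample.int(4, n_hap, replace = TRUE, prob = jt)
      ind[, i] <- as.integer(cell %in% c(1, 2))
      ind[, j] <- as.integer(cell %in% c(1, 3))
      done[c(i, j)] <- TRUE
    }
    for (r in which(!done))
      ind[, r] <- stats::rbinom(n_hap, 1, q[r])
    # allele assignment: carriers get >=1 variant; variant s with prob maf_s/q
    cols <- list(); meta <- list()
    pos_cursor <- 0L
    starts <- integer(n_regions)
    for (r in seq_len(n_regions)) {
      starts[r] <- pos_cursor
      m <- maf_t[[r]]
      v <- length(m)
      block <- matrix(0L, n_hap, v)
      carriers <- which(ind[, r] == 1L)
      for (i in carriers) {
        hit <- stats::runif(v) < m / q[r]
        if (!any(hit)) hit[sample.int(v, 1, prob = m)] <- TRUE
        block[i, hit] <- 1L
      }
      pos <- pos_cursor + sort(sample.int(region_span, v))
      cols[[r]] <- block
      meta[[r]] <- data.frame(chrom = chrom, pos = pos,
                              ref_alt = "A>T", maf = colMeans(block),
                              missing = 0L, stringsAsFactors = FALSE)
      pos_cursor <- pos_cursor + region_span + region_gap
    }
    values <- do.call(cbind, cols)
    sample_ids <- data.frame(sample = rep(sprintf("S%04d", seq_len(n_hap / 2)),
                                          each = 2),
                             haplotype = rep(1:2, n_hap / 2),
                             stringsAsFactors = FALSE)
    rownames(values) <- paste0(sample_ids$sample, "_", sample_ids$haplotype)
    h <- structure(list(values = values, variants = do.call(rbind, meta),
                        sample_ids = sample_ids),
                   class = "HaplotypeMatrix")
    regions <- as_region_set(data.frame(
      name = sprintf("GENE%03d", seq_len(n_regions)), chrom = chrom,
      start = starts, end = starts + region_span, stringsAsFactors = FALSE))
    list(h = h, regions = regions,
         truth = list(cmaf = q, rho = rho, cor_pairs = cor_pairs,
                      variant_maf = maf_t))
  })
}
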