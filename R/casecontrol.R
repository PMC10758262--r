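#' Delta-cLD screening between case and control cohorts
#'
#' Computes cLD per region pair separately in the two cohorts and their
#' absolute difference delta = |cLD_case - cLD_control|, the screening
#' statistic for candidate interacting gene pairs. By default the
#' rare-variant filter is applied on the pooled cohort so both cohorts use
#' the identical variant set; per-cohort filtering is available.
#'
#' @param h_case,h_control `HaplotypeMatrix` objects (>= 4 haplotypes each)
#'   over the same variant universe.
#' @param regions A `RegionSet`.
#' @param maf_cutoff Rare-variant MAF cutoff applied before the statistic
#'   (`NULL` to skip filtering).
#' @param pool_filter Determine rare status on the pooled cohorts (default)
#'   rather than per cohort.
#' @param same_chrom_only Restrict to same-chromosome pairs (default TRUE).
#' @return data.frame with `region_a`, `region_b`, `cld_case`, `cld_control`,
#'   `delta`, `defined`, `rank` (1-based by descending delta over defined
#'   records; ties broken by (region_a, region_b) lexicographic order).
#' @export
delta_cld <- function(h_case, h_control, regions, maf_cutoff = 0.005,
                      pool_filter = TRUE, same_chrom_only = TRUE) {
  stopifnot(inherits(h_case, "HaplotypeMatrix"),
            inherits(h_control, "HaplotypeMatrix"))
  if (nrow(h_case$values) < 4) stop("case cohort has fewer than 4 haplotypes")
  if (nrow(h_control$values) < 4) stop("control cohort has fewer than 4 haplotypes")
  if (!is.null(maf_cutoff)) {
    if (pool_filter) {
      pooled_maf <- (colSums(h_case$values) + colSums(h_control$values)) /
        (nrow(h_case$values) + nrow(h_control$values))
      keep <- pooled_maf > 0 & pooled_maf < maf_cutoff
      subset_cols <- function(h) {
        h$values <- h$values[, keep, drop = FALSE]
        h$variants <- h$variants[keep, , drop = FALSE]
        h$variants$maf <- colMeans(h$values)
        h
      }
      h_case <- subset_cols(h_case)
      h_control <- subset_cols(h_control)
    } else {
      h_case <- filter_rare(h_case, maf_cutoff)
      h_control <- filter_rare(h_control, maf_cutoff)
    }
  }
  pc <- pairwise_cld(h_case, regions, same_chrom_only = same_chrom_only)
  pt <- pairwise_cld(h_control, regions, same_chrom_only = same_chrom_only)
  out <- data.frame(region_a = pc$region_a, region_b = pc$region_b,
                    cld_case = pc$r2, cld_control = pt$r2,
                    delta = abs(pc$r2 - pt$r2),
                    defined = pc$defined & pt$defined,
                    stringsAsFactors = FALSE)
  out$rank <- NA_integer_
  def <- which(out$defined)
  if (length(def)) {
    ord <- def[order(-out$delta[def], out$region_a[def], out$region_b[def])]
    out$rank[ord] <- seq_along(ord)
  }
  out[order(is.na(out$rank), out$rank), , drop = FALSE]
}

#' Top-k delta-cLD pairs and their gene set
#'
#' Returns the first k defined records by descending delta (deterministic
#' tie-break) and the deduplicated union of member genes for downstream
#' enrichment; k pairs can yield up to 2k genes.
#'
#' @param records Output of [delta_cld()].
#' @param k Number of pairs to keep (truncated with a warning if larger than
#'   the defined-record count).
#' @return List with `pairs` (data.frame) and `genes` (character vector).
#' @export
top_pairs <- function(records, k) {
  def <- records[records$defined, , drop = FALSE]
  def <- def[order(def$rank), , drop = FALSE]
  if (k > nrow(def)) {
    warning("k = ", k, " exceeds the ", nrow(def),
            " defined records; truncating")
    k <- nrow(def)
  }
  top <- def[seq_len(k), , drop = FALSE]
  list(pairs = top, genes = unique(c(top$region_a, top$region_b)))
}
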