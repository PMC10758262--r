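#' Geometric distance-bin edges for gene pairs
#'
#' Upper edges `first_edge * ratio^k`, k = 0..n_bins-1. With the defaults
#' (35 kb, ratio 2, 13 bins) the top edge is 35 kb * 2^12 = 143,360,000 bp,
#' just under the longest human chromosome, giving the conventional 13
#' distance groups. Group k (0-based) covers `(edge[k-1], edge[k]]`, with
#' group 0 covering `(0, first_edge]`.
#'
#' @param first_edge First upper edge in bp (default 35000).
#' @param ratio Geometric ratio (default 2).
#' @param n_bins Number of groups (default 13).
#' @return Numeric vector of upper edges.
#' @export
distance_bins <- function(first_edge = 35000, ratio = 2, n_bins = 13) {
  stopifnot(first_edge > 0, ratio > 1, n_bins >= 1)
  first_edge * ratio^(0:(n_bins - 1))
}

#' Distance-group membership
#'
#' @param distance Numeric vector of gene-pair distances (bp).
#' @param edges Upper edges from [distance_bins()].
#' @return Integer 0-based group per distance (`NA` beyond the last edge).
#' @export
distance_group <- function(distance, edges) {
  g <- findInterval(distance, edges, left.open = TRUE)
  g[g >= length(edges) | is.na(distance)] <- NA_integer_
  as.integer(g)
}

#' Label region pairs by joint membership in interaction regions
#'
#' A region is "in" an interaction region when its interval overlaps an
#' annotation interval by at least 1 bp. Pairs with both members in are
#' labelled `in_interaction`, with neither `not_in_interaction`; pairs with
#' exactly one member inside are labelled `discarded` (and excluded from all
#' downstream comparisons).
#'
#' @param pairs data.frame from [pairwise_cld()].
#' @param regions The `RegionSet` the pairs were computed on.
#' @param interaction_regions data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) on the same coordinates as `regions`. An empty table
#'   labels everything `not_in_interaction`.
#' @param statistic Column of `pairs` carried as the pair statistic
#'   (default `"r2"`).
#' @return A `PairLabelTable` data.frame: `region_a`, `region_b`, `distance`,
#'   `label`, `statistic`.
#' @export
label_pairs <- function(pairs, regions, interaction_regions,
                        statistic = "r2") {
  in_anchor <- vapply(seq_len(nrow(regions)), function(i) {
    if (is.null(interaction_regions) || nrow(interaction_regions) == 0)
      return(FALSE)
    any(interaction_regions$chrom == regions$chrom[i] &
          interaction_regions$start < regions$end[i] &
          interaction_regions$end > regions$start[i])
  }, logical(1))
  names(in_anchor) <- regions$name
  ia <- in_anchor[pairs$region_a]
  ib <- in_anchor[pairs$region_b]
  label <- ifelse(ia & ib, "in_interaction",
                  ifelse(!ia & !ib, "not_in_interaction", "discarded"))
  data.frame(region_a = pairs$region_a, region_b = pairs$region_b,
             distance = pairs$distance, label = label,
             statistic = pairs[[statistic]], stringsAsFactors = FALSE)
}

#' Distance-matched variant-pair LD comparison
#'
#' Mirrors the gene-level comparison at the single-variant level: for each
#' labelled (`in_interaction`) gene pair up to `n_pairs` cross-region rare
#' variant pairs are sampled, and each is matched to a variant pair drawn
#' from the unlabelled gene pairs minimizing the absolute distance
#' difference (ties broken toward the smaller distance). Class averages of
#' r2 over the matched sets are returned.
#'
#' @param pairs A `PairLabelTable` (from [label_pairs()]).
#' @param h The `HaplotypeMatrix` of rare variants.
#' @param regions The `RegionSet`.
#' @param n_pairs Cap on sampled variant pairs per labelled gene pair.
#' @param seed Seed for all sampling.
#' @return List with `mean_in`, `mean_matched`, `n_matched`, and a `matches`
#'   data.frame (`query_dist`, `matched_dist`, `r2_in`, `r2_matched`).
#' @export
matched_ld_sample <- function(pairs, h, regions, n_pairs = 2000, seed = 1) {
  in_rows <- pairs[pairs$label == "in_interaction", , drop = FALSE]
  out_rows <- pairs[pairs$label == "not_in_interaction", , drop = FALSE]
  if (nrow(in_rows) == 0) stop("no labelled (in_interaction) gene pairs")
  if (nrow(out_rows) == 0) stop("no unlabelled gene pairs to match against")
  reg <- regions
  rownames(reg) <- reg$name
  draw <- function(rowset) {
    res <- list()
    for (k in seq_len(nrow(rowset))) {
      ca <- .region_cols(h, reg[rowset$region_a[k], ])
      cb <- .region_cols(h, reg[rowset$region_b[k], ])
      if (!length(ca) || !length(cb)) next
      total <- length(ca) * length(cb)
      pick <- if (total <= n_pairs) seq_len(total)
              else sample.int(total, n_pairs)
      ia <- ca[((pick - 1L) %% length(ca)) + 1L]
      ib <- cb[((pick - 1L) %/% length(ca)) + 1L]
      r2 <- .ld_stats(colMeans(h$values[, ia, drop = FALSE]),
                      colMeans(h$values[, ib, drop = FALSE]),
                      colMeans(h$values[, ia, drop = FALSE] *
                                 h$values[, ib, drop = FALSE]))$r2
      res[[length(res) + 1L]] <- data.frame(
        dist = abs(h$variants$pos[ia] - h$variants$pos[ib]), r2 = r2)
    }
    out <- do.call(rbind, res)
    out[!is.na(out$r2), , drop = FALSE]
  }
  .with_seed(seed, {
    qry <- draw(in_rows)
    pool <- draw(out_rows)
    if (is.null(pool) || nrow(pool) == 0)
      stop("no defined variant pairs in the unlabelled pool")
    if (is.null(qry) || nrow(qry) == 0)
      stop("no defined variant pairs in the labelled set")
    pool <- pool[order(pool$dist), , drop = FALSE]
    # nearest pool distance; ties resolved to the smaller distance
    j <- findInterval(qry$dist, pool$dist)
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, nrow(pool))
    d_lo <- abs(qry$dist - pool$dist[lo])
    d_hi <- abs(qry$dist - pool$dist[hi])
    take <- ifelse(j < 1L, hi, ifelse(d_lo <= d_hi, lo, hi))
    matches <- data.frame(query_dist = qry$dist,
                          matched_dist = pool$dist[take],
                          r2_in = qry$r2, r2_matched = pool$r2[take])
    list(mean_in = mean(matches$r2_in),
         mean_matched = mean(matches$r2_matched),
         n_matched = nrow(matches), matches = matches)
  })
}

#' Stratified 2x2 counts of label versus statistic cutoff
#'
#' Within each distance group, counts gene pairs by label
#' (in/not-in interaction) and by whether the statistic exceeds the stratum
#' cutoff. The default cutoff is the within-stratum median (0.5 quantile) of
#' the defined statistics; a pooled median over all strata is available.
#' Strata lacking either label (or with no defined statistic) are dropped
#' with a note; discarded pairs never enter.
#'
#' @param p A `PairLabelTable`.
#' @param edges Distance-bin upper edges (default [distance_bins()]).
#' @param cutoff `"stratum_median"` (default) or `"pooled_median"`.
#' @return A `StratifiedTable`: list with `tables` (2x2xK array: rows
#'   in/not, columns above/below), `strata` (group indices), `cutoffs`,
#'   `dropped` (group indices dropped).
#' @export
stratified_counts <- function(p, edges = distance_bins(),
                              cutoff = c("stratum_median", "pooled_median")) {
  cutoff <- match.arg(cutoff)
  keep <- p$label %in% c("in_interaction", "not_in_interaction") &
    !is.na(p$statistic) & !is.na(p$distance)
  p <- p[keep, , drop = FALSE]
  p$group <- distance_group(p$distance, edges)
  p <- p[!is.na(p$group), , drop = FALSE]
  if (!nrow(p)) stop("no usable pairs after distance binning")
  pooled <- stats::median(p$statistic)
  groups <- sort(unique(p$group))
  tabs <- list(); cuts <- c(); used <- c(); dropped <- c()
  for (g in groups) {
    pg <- p[p$group == g, , drop = FALSE]
    if (length(unique(pg$label)) < 2) { dropped <- c(dropped, g); next }
    cut <- if (cutoff == "stratum_median") stats::median(pg$statistic) else pooled
    above <- pg$statistic > cut
    tab <- rbind(in_interaction = c(sum(pg$label == "in_interaction" & above),
                                    sum(pg$label == "in_interaction" & !above)),
                 not_in_interaction = c(sum(pg$label == "not_in_interaction" & above),
                                        sum(pg$label == "not_in_interaction" & !above)))
    colnames(tab) <- c("above", "below")
    tabs[[length(tabs) + 1L]] <- tab
    cuts <- c(cuts, cut)
    used <- c(used, g)
  }
  if (!length(tabs)) stop("all strata dropped (each needs both labels present)")
  arr <- array(unlist(tabs), dim = c(2, 2, length(tabs)),
               dimnames = list(c("in_interaction", "not_in_interaction"),
                               c("above", "below"), NULL))
  if (length(dropped))
    message("dropped ", length(dropped), " stratum/strata lacking a label: group(s) ",
            paste(dropped, collapse = ", "))
  structure(list(tables = arr, strata = used, cutoffs = cuts,
                 dropped = dropped),
            class = "StratifiedTable")
}

#' Mantel-Haenszel test across stratified 2x2 tables
#'
#' Classical Mantel-Haenszel common odds-ratio estimate and chi-square test
#' over the strata of a `StratifiedTable`, with the 0.5 continuity correction
#' on by default (sparse long-distance strata).
#'
#' @param t A `StratifiedTable` (or a 2x2xK array).
#' @param correct Apply the continuity correction (default TRUE).
#' @return List with `or` (MH common odds ratio), `statistic`, `p_value`,
#'   `defined`.
#' @export
mantel_haenszel <- function(t, correct = TRUE) {
  arr <- if (inherits(t, "StratifiedTable")) t$tables else t
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  if (dim(arr)[3] == 1) {
    # stats::mantelhaen.test requires >= 2 strata; for a single stratum the
    # MH statistic reduces to this closed form with the same correction
    a <- arr[1, 1, 1]; b <- arr[1, 2, 1]; cc <- arr[2, 1, 1]; d <- arr[2, 2, 1]
    n <- a + b + cc + d
    if (n < 2 || (a + b) * (cc + d) * (a + cc) * (b + d) == 0)
      return(list(or = NA_real_, statistic = NA_real_, p_value = NA_real_,
                  defined = FALSE))
    e <- (a + b) * (a + cc) / n
    v <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
    dev <- abs(a - e) - if (correct) 0.5 else 0
    stat <- max(dev, 0)^2 / v
    return(list(or = (a * d) / (b * cc),
                statistic = stat,
                p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                defined = TRUE))
  }
  res <- tryCatch(stats::mantelhaen.test(arr, correct = correct),
                  error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic))
    return(list(or = NA_real_, statistic = NA_real_, p_value = NA_real_,
                defined = FALSE))
  list(or = unname(res$estimate), statistic = unname(res$statistic),
       p_value = res$p.value, defined = TRUE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum of probabilities of all
#' tables (with the observed margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab)$p.value
}

#' Cutoff-ratio curve of labelled versus unlabelled pairs
#'
#' For each cutoff c, counts the gene pairs with statistic above c in each
#' label class and reports both the raw count ratio in/not and the
#' class-size-normalized ratio (each count divided by its class total), the
#' latter comparable across unbalanced classes. The ratio is `Inf` when the
#' unlabelled count hits 0 while the labelled count is positive, and `NA`
#' when both are 0.
#'
#' @param p A `PairLabelTable`.
#' @param cutoffs Ascending statistic cutoffs.
#' @return data.frame with `cutoff`, `n_in`, `n_not`, `ratio`, `norm_ratio`.
#' @export
cutoff_ratio_curve <- function(p, cutoffs) {
  stopifnot(!is.unsorted(cutoffs))
  keep <- p$label %in% c("in_interaction", "not_in_interaction") &
    !is.na(p$statistic)
  p <- p[keep, , drop = FALSE]
  tot_in <- sum(p$label == "in_interaction")
  tot_not <- sum(p$label == "not_in_interaction")
  n_in <- vapply(cutoffs, function(c)
    sum(p$label == "in_interaction" & p$statistic > c), 0)
  n_not <- vapply(cutoffs, function(c)
    sum(p$label == "not_in_interaction" & p$statistic > c), 0)
  ratio <- ifelse(n_not > 0, n_in / n_not, ifelse(n_in > 0, Inf, NA_real_))
  norm <- ifelse(n_not > 0 & tot_in > 0 & tot_not > 0,
                 (n_in / tot_in) / (n_not / tot_not),
                 ifelse(n_in > 0, Inf, NA_real_))
  data.frame(cutoff = cutoffs, n_in = n_in, n_not = n_not,
             ratio = ratio, norm_ratio = norm)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests whether a selected gene set is enriched for members of a reference
#' database within a gene universe: with `q` the overlap, `m` the database
#' size, `n` the non-database universe size and `k` the selection size, the
#' p-value is `P(X >= q)` for `X ~ Hypergeometric(m, n, k)`.
#'
#' @param selected Character vector of selected genes (subset of `universe`).
#' @param database Character vector of database genes (subset of `universe`).
#' @param universe Character vector of all genes.
#' @return List with `q`, `m`, `n`, `k`, `p_value`.
#' @export
hypergeom_enrichment <- function(selected, database, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  selected <- unique(selected)
  database <- unique(database)
  if (!all(selected %in% universe)) stop("selected genes outside the universe")
  if (!all(database %in% universe)) stop("database genes outside the universe")
  q <- length(intersect(selected, database))
  m <- length(database)
  n <- length(universe) - m
  k <- length(selected)
  list(q = q, m = m, n = n, k = k,
       p_value = stats::phyper(q - 1, m, n, k, lower.tail = FALSE))
}
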