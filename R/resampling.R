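#' Assign region pairs to cMAF bins
#'
#' Each defined pair is summarized by a single pair-level cMAF (mean of the
#' two region cMAFs by default; `min`/`max` available) and assigned to the
#' half-open bin containing it: below the first edge, then `[e1, e2)`, ...;
#' summaries at an edge fall in the right-hand bin. Pairs at or above the last
#' edge are discarded (and counted), following the convention that gene pairs
#' with cMAF above 0.40 are excluded from the stability comparison.
#'
#' @param pairs data.frame from [pairwise_cld()] (columns `p_a`, `p_b`,
#'   `defined`).
#' @param edges Strictly increasing bin edges; default `c(0.05, 0.1, 0.2, 0.4)`
#'   yields the four conventional bins <0.05, 0.05-0.10, 0.10-0.20, 0.20-0.40.
#' @param summary Pair-level cMAF summary: `"mean"` (default), `"min"` or
#'   `"max"`.
#' @return The input with columns `cmaf_summary`, `bin` (integer, NA for
#'   discarded/undefined) and `bin_label`; attribute `n_discarded`.
#' @export
bin_by_cmaf <- function(pairs, edges = c(0.05, 0.10, 0.20, 0.40),
                        summary = c("mean", "min", "max")) {
  summary <- match.arg(summary)
  stopifnot(all(diff(edges) > 0))
  s <- switch(summary,
              mean = (pairs$p_a + pairs$p_b) / 2,
              min = pmin(pairs$p_a, pairs$p_b),
              max = pmax(pairs$p_a, pairs$p_b))
  bin <- findInterval(s, edges) + 1L      # edge value -> right-hand bin
  bin[bin > length(edges)] <- NA_integer_ # at/above last edge: discarded
  bin[!pairs$defined] <- NA_integer_
  labels <- c(paste0("<", edges[1]),
              paste0("[", edges[-length(edges)], ",", edges[-1], ")"))
  pairs$cmaf_summary <- s
  pairs$bin <- bin
  pairs$bin_label <- ifelse(is.na(bin), NA_character_, labels[bin])
  attr(pairs, "bin_labels") <- labels
  attr(pairs, "n_discarded") <- sum(pairs$defined & s >= edges[length(edges)])
  pairs
}

#' Half-sample bootstrap stability of cLD versus gene-pair LD
#'
#' Implements the subsampling protocol used to compare the stability of the
#' two statistics: in each iteration, half of the haplotypes
#' (`floor(n_hap/2)`) are drawn without replacement; over the sampled gene
#' pairs (same-chromosome pairs among `n_genes` sampled regions) the
#' bin-averaged cLD and bin-averaged gene-pair LD are recorded; after all
#' iterations each (bin, statistic) series is divided by its own mean so that
#' spread is read relative to the mean. Pair-to-bin assignment uses the
#' full-sample cMAFs and is fixed across iterations.
#'
#' @param h A `HaplotypeMatrix` of rare variants.
#' @param regions A `RegionSet`.
#' @param n_iter Bootstrap iterations (default 1000).
#' @param n_genes Number of regions sampled (default 1000, capped at the
#'   region count).
#' @param seed Seed driving all randomness.
#' @param edges cMAF bin edges, as in [bin_by_cmaf()].
#' @param summary Pair-level cMAF summary for binning.
#' @param max_pairs Cap on variant pairs per gene pair for the LD side.
#' @return A `cld_bootstrap`: list with `bin_labels`, matrices `cld` and `ld`
#'   (`n_iter` x bins, mean-normalized), `empty_frac` (fraction of iterations
#'   in which a bin had no defined pair), `unstable` flags (empty in >= 10% of
#'   iterations), `n_iter`, `n_pairs`.
#' @export
bootstrap_stability <- function(h, regions, n_iter = 1000, n_genes = 1000,
                                seed = 1, edges = c(0.05, 0.10, 0.20, 0.40),
                                summary = "mean", max_pairs = 2000) {
  stopifnot(inherits(h, "HaplotypeMatrix"), nrow(h$values) >= 4,
            nrow(regions) >= 2)
  n <- nrow(h$values)
  .with_seed(seed, {
    n_genes <- min(n_genes, nrow(regions))
    regs <- regions[sort(sample.int(nrow(regions), n_genes)), , drop = FALSE]
    cols <- lapply(seq_len(nrow(regs)), function(i) .region_cols(h, regs[i, ]))
    keep <- lengths(cols) > 0
    regs <- regs[keep, , drop = FALSE]
    cols <- cols[keep]
    r <- nrow(regs)
    if (r < 2) stop("fewer than 2 sampled regions contain variants")
    same <- outer(regs$chrom, regs$chrom, "==") & upper.tri(diag(r))
    idx <- which(same, arr.ind = TRUE)
    # fixed binning from full-sample cMAFs
    full_ind <- .indicator_matrix(h, regs)
    q <- colMeans(full_ind)
    s <- switch(summary, mean = (q[idx[, 1]] + q[idx[, 2]]) / 2,
                min = pmin(q[idx[, 1]], q[idx[, 2]]),
                max = pmax(q[idx[, 1]], q[idx[, 2]]))
    bin <- findInterval(s, edges) + 1L
    bin[bin > length(edges)] <- NA_integer_
    usable <- !is.na(bin)
    idx <- idx[usable, , drop = FALSE]
    bin <- bin[usable]
    if (!nrow(idx)) stop("no gene pairs fall inside the cMAF bins")
    n_bins <- length(edges)
    labels <- c(paste0("<", edges[1]),
                paste0("[", edges[-length(edges)], ",", edges[-1], ")"))
    # variant-column bookkeeping for the LD side
    allcols <- sort(unique(unlist(cols)))
    colmap <- lapply(cols, function(cc) match(cc, allcols))
    half <- floor(n / 2)
    vc <- matrix(NA_real_, n_iter, n_bins)
    vl <- matrix(NA_real_, n_iter, n_bins)
    sample_pairs <- any(vapply(seq_len(nrow(idx)), function(k)
      length(cols[[idx[k, 1]]]) * length(cols[[idx[k, 2]]]), 0) > max_pairs)
    for (it in seq_len(n_iter)) {
      rows <- sample.int(n, half)
      xs <- h$values[rows, allcols, drop = FALSE]
      storage.mode(xs) <- "double"
      ind <- matrix(0L, half, r)
      for (g in seq_len(r))
        ind[, g] <- as.integer(
          rowSums(xs[, colmap[[g]], drop = FALSE]) > 0)
      cres <- .r2_matrix(ind)$r2
      cld_p <- cres[idx]
      # LD side: one big cross-product, then small per-pair blocks
      cp <- crossprod(xs)
      pa <- colMeans(xs)
      va <- pa * (1 - pa)
      ld_p <- vapply(seq_len(nrow(idx)), function(k) {
        ci <- colmap[[idx[k, 1]]]
        cj <- colmap[[idx[k, 2]]]
        d <- cp[ci, cj, drop = FALSE] / half - outer(pa[ci], pa[cj])
        den <- outer(va[ci], va[cj])
        block <- d * d / den
        block[den <= 0] <- NA_real_
        if (sample_pairs && length(block) > max_pairs)
          block <- block[sample.int(length(block), max_pairs)]
        if (all(is.na(block))) NA_real_ else mean(block, na.rm = TRUE)
      }, 0)
      for (b in seq_len(n_bins)) {
        inb <- bin == b
        if (any(inb & !is.na(cld_p)))
          vc[it, b] <- mean(cld_p[inb], na.rm = TRUE)
        if (any(inb & !is.na(ld_p)))
          vl[it, b] <- mean(ld_p[inb], na.rm = TRUE)
      }
    }
    norm <- function(m) {
      for (b in seq_len(ncol(m))) {
        mu <- mean(m[, b], na.rm = TRUE)
        if (is.finite(mu) && mu > 0) m[, b] <- m[, b] / mu
      }
      m
    }
    empty_frac <- colMeans(is.na(vc) | is.na(vl))
    structure(list(bin_labels = labels, cld = norm(vc), ld = norm(vl),
                   empty_frac = empty_frac, unstable = empty_frac >= 0.10,
                   n_iter = n_iter, n_pairs = tabulate(bin, n_bins)),
              class = "cld_bootstrap")
  })
}

#' Per-bin bootstrap spread summary
#'
#' Standard deviation of the mean-normalized cLD and LD series in each bin
#' and their ratio; because both series have mean 1, the sd is directly a
#' coefficient of variation and the ratio compares relative instability.
#'
#' @param d A `cld_bootstrap` object.
#' @return data.frame with `bin`, `n_pairs`, `sd_cld`, `sd_ld`, `ratio`,
#'   `unstable`.
#' @export
stability_summary <- function(d) {
  stopifnot(inherits(d, "cld_bootstrap"))
  sd_c <- apply(d$cld, 2, stats::sd, na.rm = TRUE)
  sd_l <- apply(d$ld, 2, stats::sd, na.rm = TRUE)
  data.frame(bin = d$bin_labels, n_pairs = d$n_pairs,
             sd_cld = sd_c, sd_ld = sd_l,
             ratio = ifelse(sd_l > 0, sd_c / sd_l, NA_real_),
             unstable = d$unstable, stringsAsFactors = FALSE)
}

#' @export
print.cld_bootstrap <- function(x, ...) {
  cat("Half-sample bootstrap,", x$n_iter, "iterations\n")
  print(stability_summary(x))
  invisible(x)
}
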