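#' Empirical 2x2 cell probabilities from two carrier profiles
#'
#' Tabulates the four carrier-combination frequencies (both, A-only, B-only,
#' neither) that parameterize the multinomial haplotype-table model underlying
#' the asymptotic variance of cLD. For single variants the same table is built
#' from the two-locus haplotype counts, so one variance formula serves LD and
#' cLD alike.
#'
#' @param a,b `CarrierProfile` objects over the same haplotypes.
#' @return A `CellProbs`: named numeric vector `(p11, p10, p01, p00)`.
#' @export
cell_probs_from_profiles <- function(a, b) {
  if (length(a$indicator) != length(b$indicator))
    stop("carrier profiles have different haplotype counts")
  p11 <- mean(a$indicator == 1L & b$indicator == 1L)
  cell_probs(p11, a$cmaf - p11, b$cmaf - p11, 1 - a$cmaf - b$cmaf + p11)
}

#' Construct a CellProbs table
#'
#' @param p11,p10,p01,p00 Cell probabilities (both, A-only, B-only, neither);
#'   must be in `[0,1]` and sum to 1.
#' @return A `CellProbs` named numeric vector.
#' @export
cell_probs <- function(p11, p10, p01, p00) {
  p <- c(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("cell probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop("cell probabilities must sum to 1 (got ", sum(p), ")")
  structure(pmin(pmax(p, 0), 1), class = "CellProbs")
}

# Analytic gradient of g(p11,p10,p01) = D^2 / (pA(1-pA) pB(1-pB)) over the
# three free multinomial coordinates (p00 eliminated; the simplex covariance
# is singular in 4 coordinates but full-rank in 3).
.r2_gradient <- function(p) {
  a <- p[["p11"]]; b <- p[["p10"]]; cc <- p[["p01"]]
  p_a <- a + b
  p_b <- a + cc
  d <- a - p_a * p_b
  den <- p_a * (1 - p_a) * p_b * (1 - p_b)
  g <- d * d / den
  d_d <- c(1 - p_a - p_b, -p_b, -p_a)
  d_pa <- c(1, 1, 0)
  d_pb <- c(1, 0, 1)
  d_den <- d_pa * (1 - 2 * p_a) * p_b * (1 - p_b) +
           d_pb * p_a * (1 - p_a) * (1 - 2 * p_b)
  grad <- (2 * d * d_d - g * d_den) / den
  list(value = g, gradient = grad)
}

#' Delta-method asymptotic variance of the r2 statistic
#'
#' Models the four haplotype-table cells as multinomial with probabilities
#' `p` and sample size `n`, approximates the cell frequencies as multivariate
#' normal, and propagates through the r2 functional by a first-order Taylor
#' expansion: `Var = grad(g)' Sigma grad(g) / n` with `Sigma = diag(p) - p p'`
#' over the three free coordinates and the gradient computed analytically.
#' The same formula serves standard LD (two-SNV haplotype table) and cLD
#' (two-region carrier table); only the input table differs.
#'
#' At `D = 0` the gradient of the squared statistic vanishes and the
#' first-order variance is exactly 0; a warning notes that the approximation
#' degenerates there.
#'
#' @param p A `CellProbs` table (all four cells strictly positive; margins not
#'   0 or 1).
#' @param n Haplotype count.
#' @return A `VarianceEstimate`: list with `statistic_value` (r2 at `p`),
#'   `variance`, `n`, `defined` and (when undefined) `reason`.
#' @export
delta_variance <- function(p, n) {
  stopifnot(n > 0)
  p_a <- p[["p11"]] + p[["p10"]]
  p_b <- p[["p11"]] + p[["p01"]]
  if (any(unclass(p) <= 0))
    return(structure(list(statistic_value = NA_real_, variance = NA_real_,
                          n = n, defined = FALSE,
                          reason = "zero multinomial cell"),
                     class = "VarianceEstimate"))
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1)
    return(structure(list(statistic_value = NA_real_, variance = NA_real_,
                          n = n, defined = FALSE,
                          reason = "degenerate margin"),
                     class = "VarianceEstimate"))
  gr <- .r2_gradient(p)
  free <- unclass(p)[c("p11", "p10", "p01")]
  sigma <- diag(free) - tcrossprod(free)
  v <- drop(crossprod(gr$gradient, sigma %*% gr$gradient)) / n
  if (abs(p[["p11"]] - p_a * p_b) < 1e-12)
    warning("D = 0: first-order delta-method variance degenerates to 0 here")
  structure(list(statistic_value = gr$value, variance = max(v, 0), n = n,
                 defined = TRUE),
            class = "VarianceEstimate")
}

#' @export
print.VarianceEstimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("r2 = %.6g, asymptotic Var = %.6g at n = %d\n",
                x$statistic_value, x$variance, as.integer(x$n)))
  else cat("variance undefined:", x$reason, "\n")
  invisible(x)
}

#' Ratio of asymptotic variances Var(cLD) / Var(LD)
#'
#' Evaluates the closed-form delta-method variance at a region-level carrier
#' table and at a single-variant haplotype table and returns their ratio.
#' Because both variances scale as 1/n, the ratio does not depend on n.
#'
#' @param p_cld `CellProbs` for the two-region carrier table.
#' @param p_ld `CellProbs` for the two-SNV haplotype table.
#' @param n Haplotype count (cancels in the ratio).
#' @return List with `ratio`, `var_cld`, `var_ld`, `defined`.
#' @export
variance_ratio <- function(p_cld, p_ld, n) {
  vc <- delta_variance(p_cld, n)
  vl <- delta_variance(p_ld, n)
  if (!vc$defined || !vl$defined || vl$variance <= 0)
    return(list(ratio = NA_real_, var_cld = vc$variance, var_ld = vl$variance,
                defined = FALSE))
  list(ratio = vc$variance / vl$variance, var_cld = vc$variance,
       var_ld = vl$variance, defined = TRUE)
}

#' Asymptotic variance of delta-cLD under case/control independence
#'
#' Assuming no correlation between the case and control cohorts, the variance
#' of the difference `cLD_case - cLD_control` is the sum of the two cohort
#' variances. The folding induced by taking the absolute value
#' `|cLD_case - cLD_control|` is left to callers (the folded distribution is
#' half-normal under the null).
#'
#' @param v_case,v_control `VarianceEstimate` objects.
#' @return List with `variance` and `defined`.
#' @export
delta_cld_variance <- function(v_case, v_control) {
  if (!isTRUE(v_case$defined) || !isTRUE(v_control$defined))
    return(list(variance = NA_real_, defined = FALSE))
  list(variance = v_case$variance + v_control$variance, defined = TRUE)
}
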