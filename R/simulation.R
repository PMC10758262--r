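#' Parameters for the forward-time cLD decay simulator
#'
#' The simulator models two regions (A | recombination point | B) in a
#' growing population with negative selection against individual mutations —
#' the two forces keeping variants rare — and, when `interaction_on`, a
#' synergistic fitness reward for haplotypes carrying mutations in both
#' regions. Per-haplotype fitness is
#' `w = (1 + s_neg)^(m_A + m_B) * (1 + s_syn)^(carrier_A * carrier_B)`,
#' where `m_A`, `m_B` count regional mutations and the carrier flags are the
#' cLD indicators.
#'
#' @param n0 Founder haplotype count (default 500).
#' @param growth_rate Per-generation multiplicative growth (default 1.02).
#' @param mu Expected new mutations per region per generation, each placed on
#'   one random haplotype (default 0.5).
#' @param s_neg Selection coefficient against each mutation, <= 0
#'   (default -0.01).
#' @param s_syn Synergy coefficient rewarding double carriers, >= 0
#'   (default 0.05).
#' @param rec Recombination probability per offspring per generation between
#'   the two regions, in `[0, 0.5]` (default 0.02).
#' @param generations Number of generations (default 50).
#' @param interaction_on Apply the synergy term (default TRUE).
#' @param seed RNG seed.
#' @param p0_a,p0_b Founder carrier frequencies of the two regions
#'   (default 0.2).
#' @param rho0 Founder carrier correlation between the regions (default 0.9),
#'   so that the initial cLD is high and its decay observable.
#' @param founder_variants Variants per region among founders (default 5).
#' @return A `SimParams` list.
#' @export
sim_params <- function(n0 = 500, growth_rate = 1.02, mu = 0.5, s_neg = -0.01,
                       s_syn = 0.05, rec = 0.02, generations = 50,
                       interaction_on = TRUE, seed = 1,
                       p0_a = 0.2, p0_b = 0.2, rho0 = 0.9,
                       founder_variants = 5) {
  stopifnot(n0 >= 2, growth_rate > 0, mu >= 0, s_neg <= 0, s_neg > -1,
            s_syn >= 0, rec >= 0, rec <= 0.5, generations >= 1)
  structure(list(n0 = n0, growth_rate = growth_rate, mu = mu, s_neg = s_neg,
                 s_syn = s_syn, rec = rec, generations = generations,
                 interaction_on = interaction_on, seed = seed,
                 p0_a = p0_a, p0_b = p0_b, rho0 = rho0,
                 founder_variants = founder_variants),
            class = "SimParams")
}

# founder haplotypes: correlated carrier indicators, variants spread among carriers
.sim_founders <- function(p) {
  jt <- .joint_table(p$p0_a, p$p0_b, p$rho0)
  cell <- sample.int(4, p$n0, replace = TRUE, prob = jt)
  car_a <- cell %in% c(1, 2)
  car_b <- cell %in% c(1, 3)
  seed_region <- function(car) {
    m <- matrix(0L, p$n0, p$founder_variants)
    idx <- which(car)
    if (length(idx))
      m[cbind(idx, sample.int(p$founder_variants, length(idx), replace = TRUE))] <- 1L
    m
  }
  list(h = cbind(seed_region(car_a), seed_region(car_b)),
       region = rep(c(1L, 2L), each = p$founder_variants))
}

#' Forward-time simulation of cLD decay
#'
#' Runs the Wright-Fisher-with-selection model of [sim_params()]. Each
#' generation: offspring are sampled from parents with probability
#' proportional to fitness (the new population size follows the growth
#' schedule); with probability `rec` an offspring's region-B segment is
#' replaced by that of an independently sampled parent; new mutations arrive
#' as Poisson(`mu`) fresh variant columns per region, each on one random
#' haplotype; lost columns are pruned. Region cMAFs and cLD r2 are recorded
#' every generation.
#'
#' @param params A `SimParams` object.
#' @return A `SimTrajectory`: list with `trajectory` (data.frame: generation,
#'   pop_size, cmaf_a, cmaf_b, cld, defined), the final haplotype `matrix`
#'   with its `region` assignment vector, and `params`.
#' @export
simulate_decay <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  .with_seed(params$seed, {
    st <- .sim_founders(params)
    h <- st$h
    region <- st$region
    rec_stats <- function(h, region, gen) {
      ia <- rowSums(h[, region == 1L, drop = FALSE]) > 0
      ib <- rowSums(h[, region == 2L, drop = FALSE]) > 0
      s <- .ld_stats(mean(ia), mean(ib), mean(ia & ib))
      data.frame(generation = gen, pop_size = nrow(h),
                 cmaf_a = mean(ia), cmaf_b = mean(ib),
                 cld = s$r2, defined = s$defined)
    }
    traj <- list(rec_stats(h, region, 0L))
    for (gen in seq_len(params$generations)) {
      n <- nrow(h)
      m_a <- rowSums(h[, region == 1L, drop = FALSE])
      m_b <- rowSums(h[, region == 2L, drop = FALSE])
      syn <- if (params$interaction_on) (m_a > 0) * (m_b > 0) else 0
      w <- (1 + params$s_neg)^(m_a + m_b) * (1 + params$s_syn)^syn
      n_next <- max(2L, round(n * params$growth_rate))
      parents <- sample.int(n, n_next, replace = TRUE, prob = w)
      h2 <- h[parents, , drop = FALSE]
      rec_hit <- stats::runif(n_next) < params$rec
      if (any(rec_hit)) {
        donors <- sample.int(n, sum(rec_hit), replace = TRUE, prob = w)
        h2[rec_hit, region == 2L] <- h[donors, region == 2L, drop = FALSE]
      }
      for (rg in 1:2) {
        n_new <- stats::rpois(1, params$mu)
        if (n_new > 0) {
          newcols <- matrix(0L, n_next, n_new)
          newcols[cbind(sample.int(n_next, n_new, replace = TRUE),
                        seq_len(n_new))] <- 1L
          h2 <- cbind(h2, newcols)
          region <- c(region, rep(rg, n_new))
        }
      }
      alive <- colSums(h2) > 0
      h <- h2[, alive, drop = FALSE]
      region <- region[alive]
      if (!any(region == 1L) || !any(region == 2L)) {
        # a region lost all variants: cLD undefined from here on
        traj[[length(traj) + 1L]] <- data.frame(
          generation = gen, pop_size = nrow(h),
          cmaf_a = if (any(region == 1L))
            mean(rowSums(h[, region == 1L, drop = FALSE]) > 0) else 0,
          cmaf_b = if (any(region == 2L))
            mean(rowSums(h[, region == 2L, drop = FALSE]) > 0) else 0,
          cld = NA_real_, defined = FALSE)
        next
      }
      traj[[length(traj) + 1L]] <- rec_stats(h, region, gen)
    }
    structure(list(trajectory = do.call(rbind, traj), matrix = h,
                   region = region, params = params),
              class = "SimTrajectory")
  })
}

#' @export
print.SimTrajectory <- function(x, ...) {
  tr <- x$trajectory
  cat("cLD decay simulation:", max(tr$generation), "generations, final N =",
      tr$pop_size[nrow(tr)], "\n")
  cat(sprintf("  cLD: %.4g (gen 0) -> %s (final)\n", tr$cld[1],
              if (tr$defined[nrow(tr)]) sprintf("%.4g", tr$cld[nrow(tr)])
              else "undefined"))
  invisible(x)
}

#' Inject phasing switch errors into diploid haplotype pairs
#'
#' Haplotype rows are paired into individuals (rows 1-2, 3-4, ...). Walking
#' each individual's variants in genomic order, a swap state is toggled with
#' probability `rate` at every heterozygous position (switches at homozygous
#' sites are undetectable); while the state is on, the two haplotypes'
#' alleles are exchanged — from the toggled site onward — producing the
#' contiguous mis-phased segments characteristic of statistical phasing
#' errors. The per-site allele multiset of every individual is preserved.
#'
#' @param h A `HaplotypeMatrix` with an even number of rows.
#' @param rate Toggle probability per heterozygous position, in `[0, 1]`.
#' @param seed RNG seed.
#' @return A `HaplotypeMatrix` with perturbed phase (identical dimensions and
#'   variant metadata).
#' @export
inject_switch_errors <- function(h, rate, seed = NULL) {
  stopifnot(inherits(h, "HaplotypeMatrix"), rate >= 0, rate <= 1)
  n <- nrow(h$values)
  if (n %% 2 != 0) stop("odd number of haplotype rows; expected diploid pairs")
  if (rate == 0) return(h)
  ord <- order(h$variants$chrom, h$variants$pos)
  .with_seed(seed, {
    for (ind in seq_len(n / 2)) {
      r1 <- 2L * ind - 1L
      r2 <- 2L * ind
      a <- h$values[r1, ord]
      b <- h$values[r2, ord]
      het <- a != b
      toggle <- het & (stats::runif(length(ord)) < rate)
      swapped <- cumsum(toggle) %% 2L == 1L
      if (any(swapped)) {
        tmp <- a[swapped]
        a[swapped] <- b[swapped]
        b[swapped] <- tmp
        h$values[r1, ord] <- a
        h$values[r2, ord] <- b
      }
    }
    h
  })
}

#' Switch-error robustness experiment
#'
#' For each switching error rate, perturbs the phase with
#' [inject_switch_errors()], recomputes all pairwise cLD values, and reports
#' the mean proportion of cLD change `|cLD_err - cLD_true| / cLD_true` over
#' region pairs defined (and nonzero) in both the true and perturbed data.
#'
#' @param h A `HaplotypeMatrix` of rare variants.
#' @param regions A `RegionSet` (>= 2 regions with defined cLD).
#' @param rates Error-rate grid (default 0.01 to 0.10 by 0.01).
#' @param seed Base seed; each rate uses a derived seed.
#' @param same_chrom_only Restrict to same-chromosome pairs.
#' @param min_r2 Minimum true cLD for a pair to enter the average (default
#'   0.05): the proportion of change is ill-conditioned when the baseline is
#'   near zero, so the deviation is quantified on pairs with appreciable
#'   true cLD.
#' @return data.frame with `rate`, `mean_prop_change`, `n_pairs`.
#' @export
switch_error_experiment <- function(h, regions,
                                    rates = seq(0.01, 0.10, by = 0.01),
                                    seed = 1, same_chrom_only = FALSE,
                                    min_r2 = 0.05) {
  truth <- pairwise_cld(h, regions, same_chrom_only = same_chrom_only)
  base_ok <- truth$defined & !is.na(truth$r2) & truth$r2 >= min_r2
  if (!any(base_ok)) stop("no region pairs with defined, nonzero cLD")
  out <- lapply(seq_along(rates), function(k) {
    hp <- inject_switch_errors(h, rates[k], seed = seed + k)
    pert <- pairwise_cld(hp, regions, same_chrom_only = same_chrom_only)
    ok <- base_ok & pert$defined
    data.frame(rate = rates[k],
               mean_prop_change = mean(abs(pert$r2[ok] - truth$r2[ok]) /
                                         truth$r2[ok]),
               n_pairs = sum(ok))
  })
  do.call(rbind, out)
}
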