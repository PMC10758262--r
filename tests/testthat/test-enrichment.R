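test_that("geometric distance groups: 13 bins doubling from 35 kb", {
  edges <- distance_bins()
  expect_length(edges, 13L)
  expect_equal(edges[13], 35000 * 2^12)        # 143,360,000 bp
  expect_equal(edges[1], 35000)
  expect_equal(unique(edges[-1] / edges[-13]), 2)  # exact geometric progression
  expect_true(edges[13] <= 248956422)          # within the longest chromosome
  # membership: 100 kb falls in group 2 (70-140 kb); edges are inclusive
  expect_equal(distance_group(c(100000, 35000, 35001, 143360000, 2e8), edges),
               c(2L, 0L, 1L, 12L, NA_integer_))
})

test_that("pair labelling: both in, one in (discarded), neither in", {
  regs <- as_region_set(data.frame(
    name = c("G1", "G2", "G3"), chrom = "chr1",
    start = c(0L, 1000L, 5000L), end = c(500L, 1500L, 5500L)))
  pairs <- data.frame(region_a = c("G1", "G1", "G2"),
                      region_b = c("G2", "G3", "G3"),
                      distance = c(1000, 5250, 4250), r2 = c(0.5, 0.2, 0.1),
                      stringsAsFactors = FALSE)
  anchors <- data.frame(chrom = "chr1", start = c(400L, 1200L),
                        end = c(600L, 1300L))
  lab <- label_pairs(pairs, regs, anchors)
  expect_equal(lab$label, c("in_interaction", "discarded", "discarded"))
  empty <- label_pairs(pairs, regs, anchors[0, ])
  expect_true(all(empty$label == "not_in_interaction"))
})

test_that("distance matching finds the nearest pool pair (brute-force oracle)", {
  set.seed(14)
  fx <- make_fixture(n_hap = 100, n_regions = 6, variants_per_region = 4,
                     maf_low = 0.02, maf_high = 0.1, rho = 0.5, seed = 14)
  res <- pairwise_cld(fx$h, fx$regions, same_chrom_only = TRUE)
  anchors <- data.frame(chrom = "chr1",
                        start = fx$regions$start[1:2],
                        end = fx$regions$end[1:2])
  lab <- label_pairs(res, fx$regions, anchors)
  m <- matched_ld_sample(lab, fx$h, fx$regions, n_pairs = 50, seed = 3)
  # oracle: brute-force nearest distance over the realized pool
  pool_d <- sort(unique(m$matches$matched_dist))
  for (i in seq_len(nrow(m$matches))) {
    q <- m$matches$query_dist[i]
    expect_equal(abs(m$matches$matched_dist[i] - q),
                 min(abs(pool_d - q)))
  }
  expect_equal(m$n_matched, nrow(m$matches))
  # a pool with no unlabelled material errors
  all_in <- lab; all_in$label <- "in_interaction"
  expect_error(matched_ld_sample(all_in, fx$h, fx$regions), "unlabelled")
})

test_that("stratified counts: hand-computed table and marginal conservation", {
  p <- data.frame(region_a = letters[1:4], region_b = LETTERS[1:4],
                  distance = rep(50000, 4),
                  label = c("in_interaction", "in_interaction",
                            "not_in_interaction", "not_in_interaction"),
                  statistic = c(3, 4, 1, 2), stringsAsFactors = FALSE)
  st <- stratified_counts(p)
  # median cutoff 2.5; in-pairs hold {3,4}: table [[2,0],[0,2]]
  expect_equal(unname(st$tables[, , 1]), rbind(c(2, 0), c(0, 2)))
  expect_equal(st$cutoffs, 2.5)
  expect_equal(sum(st$tables), 4)
  # strata missing a label are dropped with a note
  p2 <- rbind(p, data.frame(region_a = "e", region_b = "E", distance = 500000,
                            label = "in_interaction", statistic = 9))
  expect_message(st2 <- stratified_counts(p2), "dropped 1")
  expect_equal(sum(st2$tables), 4)
  expect_error(stratified_counts(p2[5, ]), "dropped")
})

test_that("Mantel-Haenszel: null strata, single-stratum closed form", {
  # strata all with OR = 1 exactly
  null_tab <- array(rep(c(10, 10, 10, 10), 3), dim = c(2, 2, 3))
  mh0 <- mantel_haenszel(null_tab, correct = FALSE)
  expect_lt(mh0$statistic, 1e-10)
  expect_gt(mh0$p_value, 0.99)
  # single stratum [[10,2],[2,10]]: MH common OR = (10*10)/(2*2) = 25
  one <- array(c(10, 2, 2, 10), dim = c(2, 2, 1))
  expect_equal(mantel_haenszel(one)$or, 25)
})

test_that("Fisher exact matches the hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(0, 2, 2)), 1)
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5))), 2 / choose(10, 5),
               tolerance = 1e-12)
  # enumeration oracle over the support for a sample of small tables
  enum_p <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(m, k)
    pr <- stats::dhyper(support, m, n, k)
    obs <- stats::dhyper(tab[1, 1], m, n, k)
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  set.seed(6)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 3), 2, 2)
    expect_equal(fisher_exact(tab), enum_p(tab), tolerance = 1e-9)
  }
})

test_that("cutoff-ratio curve: null flatness, separation, and monotone trend", {
  set.seed(15)
  # labels independent of the statistic: normalized ratio near 1
  p_null <- data.frame(region_a = "a", region_b = "b", distance = 1,
                       label = sample(rep(c("in_interaction",
                                            "not_in_interaction"), 500)),
                       statistic = runif(1000), stringsAsFactors = FALSE)
  cc <- cutoff_ratio_curve(p_null, c(0.1, 0.3, 0.5))
  expect_true(all(abs(cc$norm_ratio - 1) < 0.25))
  # complete separation: infinity marker at high cutoffs
  p_sep <- data.frame(region_a = "a", region_b = "b", distance = 1,
                      label = rep(c("in_interaction", "not_in_interaction"),
                                  each = 10),
                      statistic = c(seq(0.6, 0.9, length.out = 10),
                                    seq(0.1, 0.4, length.out = 10)))
  cs <- cutoff_ratio_curve(p_sep, c(0.2, 0.5))
  expect_true(is.infinite(cs$ratio[2]))
  # stochastically larger in-class: normalized ratio > 1, non-decreasing trend
  p_mix <- data.frame(region_a = "a", region_b = "b", distance = 1,
                      label = rep(c("in_interaction", "not_in_interaction"),
                                  each = 1000),
                      statistic = c(rbeta(1000, 3, 5), rbeta(1000, 2, 6)))
  cm <- cutoff_ratio_curve(p_mix, seq(0.1, 0.5, by = 0.1))
  expect_true(all(cm$norm_ratio > 1))
  expect_gt(stats::cor(seq_len(5), cm$norm_ratio, method = "spearman"), 0)
})

test_that("hypergeometric enrichment on closed-form cases", {
  u <- paste0("g", 1:10)
  db <- u[1:5]
  # selection identical to the database: p = 1 / C(10,5)
  res <- hypergeom_enrichment(db, db, u)
  expect_equal(res$q, 5)
  expect_equal(res$p_value, 1 / choose(10, 5))
  # overlap at expectation: p of moderate size
  res2 <- hypergeom_enrichment(c(db[1], u[6]), db, u)
  expect_gt(res2$p_value, 0.2)
  expect_error(hypergeom_enrichment(db, db, character(0)), "empty")
  expect_error(hypergeom_enrichment(c(db, "zz"), db, u), "outside")
})
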