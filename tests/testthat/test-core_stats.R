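test_that("the six-haplotype worked example yields its carrier frequencies", {
  toy <- toy_fig1()
  a <- carrier_profile(toy$h, toy$regions[toy$regions$name == "A", ])
  b <- carrier_profile(toy$h, toy$regions[toy$regions$name == "B", ])
  expect_equal(a$cmaf, 2 / 6)
  expect_equal(b$cmaf, 3 / 6)
  expect_equal(a$indicator, c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(b$indicator, c(0L, 0L, 1L, 1L, 1L, 0L))
  expect_equal(joint_carrier_freq(a, b), 1 / 6)
  # these frequencies give D = 0 exactly, hence r2 = 0 and D' = 0
  res <- cld(a, b)
  expect_equal(res$d, 0)
  expect_equal(res$r2, 0)
  expect_equal(res$r2, cor2(a$indicator, b$indicator))
  expect_true(res$defined)
})

test_that("empty regions yield an all-zero carrier profile", {
  toy <- toy_fig1()
  p <- carrier_profile(toy$h, list(name = "empty", chrom = "chr1",
                                   start = 5000L, end = 6000L))
  expect_equal(p$cmaf, 0)
  expect_equal(sum(p$indicator), 0L)
  res <- cld(p, carrier_profile(toy$h, toy$regions[1, ]))
  expect_false(res$defined)
  expect_true(is.na(res$r2))
})

test_that("joint carrier frequency matches an AND-count and self-join", {
  set.seed(42)
  a <- mk_profile(rand_ind(100), "A")
  b <- mk_profile(rand_ind(100), "B")
  expect_equal(joint_carrier_freq(a, b),
               sum(a$indicator & b$indicator) / 100)
  expect_equal(joint_carrier_freq(a, a), a$cmaf)
  expect_error(joint_carrier_freq(a, mk_profile(rand_ind(50))), "different")
})

test_that("cLD matches hand arithmetic on a 2x2 carrier table", {
  # counts over 10 haplotypes: 3 both, 2 A-only, 1 B-only, 4 neither
  a <- mk_profile(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), "A")
  b <- mk_profile(c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0), "B")
  res <- cld(a, b)
  expect_equal(res$d, 0.1)
  expect_equal(res$r2, 0.01 / (0.5 * 0.5 * 0.4 * 0.6))
  expect_equal(res$r2, 1 / 6)
  expect_equal(res$r2, cor2(a$indicator, b$indicator))
})

test_that("identical non-constant indicators give perfect association", {
  a <- mk_profile(c(1, 0, 1, 0), "A")
  res <- cld(a, mk_profile(a$indicator, "B"))
  expect_equal(res$r2, 1)
  expect_equal(res$d_prime, 1)
})

test_that("cLD r2 equals the squared indicator correlation over random draws", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(c(10, 50, 200), 1)
    a <- mk_profile(rand_ind(n), "A")
    b <- mk_profile(rand_ind(n), "B")
    res <- cld(a, b)
    expect_equal(res$r2, cor2(a$indicator, b$indicator), tolerance = 1e-12)
    expect_true(res$r2 >= 0 && res$r2 <= 1 + 1e-12)
    expect_true(abs(res$d_prime) <= 1 + 1e-12)
    expect_identical(res$r2 == 0, res$d == 0)
  }
})

test_that("single-variant LD: identity, perfect repulsion, correlation oracle", {
  h <- mk_h(cbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(0, 1, 0, 1)),
            pos = c(1L, 2L, 3L))
  expect_equal(ld(h, 1, 2)$r2, 1)
  # disjoint carriers at p = 0.5: perfect repulsion, |D'| = 1, r2 = 1
  rep_res <- ld(h, 1, 3)
  expect_equal(rep_res$r2, 1)
  expect_equal(rep_res$d_prime, -1)
  set.seed(7)
  hr <- mk_h(cbind(rand_ind(60), rand_ind(60)), pos = c(1L, 2L))
  expect_equal(ld(hr, 1, 2)$r2, cor2(hr$values[, 1], hr$values[, 2]),
               tolerance = 1e-12)
  # monomorphic column: flagged undefined
  hm <- mk_h(cbind(c(1, 0, 1, 0), c(0, 0, 0, 0)), pos = c(1L, 2L))
  expect_false(ld(hm, 1, 2)$defined)
})

test_that("gene-pair LD reduces, enumerates fully, and is seed-deterministic", {
  set.seed(12)
  vals <- cbind(rand_ind(40), sapply(1:3, function(i) rand_ind(40)),
                sapply(1:4, function(i) rand_ind(40)))
  h <- mk_h(vals, pos = c(10L, 110L, 120L, 130L, 210L, 220L, 230L, 240L))
  r1 <- list(name = "R1", chrom = "chr1", start = 0L, end = 100L)
  r3 <- list(name = "R3", chrom = "chr1", start = 100L, end = 200L)
  r4 <- list(name = "R4", chrom = "chr1", start = 200L, end = 300L)
  # single-variant regions reduce to ld()
  single_a <- list(name = "a", chrom = "chr1", start = 0L, end = 50L)
  expect_equal(gene_pair_ld(h, single_a, r3)$mean_r2,
               mean(sapply(2:4, function(j) ld(h, 1, j)$r2)))
  # 3x4 variants with max_pairs >= 12: mean of all 12 r2 values
  full <- gene_pair_ld(h, r3, r4, max_pairs = 100)
  oracle <- mean(outer(2:4, 5:8, Vectorize(function(i, j)
    cor2(vals[, i], vals[, j]))))
  expect_equal(full$mean_r2, oracle, tolerance = 1e-12)
  expect_equal(full$n_pairs_used, 12L)
  # sampling path is deterministic under a fixed seed
  s1 <- gene_pair_ld(h, r3, r4, max_pairs = 5, rng_seed = 99)
  s2 <- gene_pair_ld(h, r3, r4, max_pairs = 5, rng_seed = 99)
  expect_identical(s1, s2)
  expect_equal(s1$n_pairs_used, 5L)
})

test_that("rare-common cLD reduces correctly and vanishes under independence", {
  set.seed(5)
  region <- list(name = "B", chrom = "chr1", start = 100L, end = 200L)
  # common column identical to the region's carrier indicator
  ind <- rand_ind(50, 0.3)
  h <- mk_h(cbind(ind, ind), pos = c(10L, 150L))
  expect_equal(rare_common_cld(h, 1, region)$r2, 1)
  # single-variant region reduces to ld()
  h2 <- mk_h(cbind(rand_ind(50), rand_ind(50)), pos = c(10L, 150L))
  expect_equal(rare_common_cld(h2, 1, region)$r2, ld(h2, 1, 2)$r2)
  # independence: r2 near 0 at large n (tolerance 3/sqrt(n))
  n <- 20000
  h3 <- mk_h(cbind(rbinom(n, 1, 0.3), rbinom(n, 1, 0.1), rbinom(n, 1, 0.1)),
             pos = c(10L, 150L, 160L))
  expect_lt(rare_common_cld(h3, 1, region)$r2, 3 / sqrt(n))
})

test_that("pairwise cLD enumerates unordered pairs with chromosome filtering", {
  set.seed(3)
  vals <- sapply(1:6, function(i) rand_ind(40, 0.2))
  h <- mk_h(vals, pos = c(10L, 20L, 110L, 120L, 10L, 20L),
            chrom = c(rep("chr1", 4), "chr2", "chr2"))
  regs <- as_region_set(data.frame(
    name = c("G1", "G2", "G3"), chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 100L, 0L), end = c(100L, 200L, 100L)))
  all_pairs <- pairwise_cld(h, regs, same_chrom_only = FALSE)
  expect_equal(nrow(all_pairs), 3L)              # C(3,2)
  same <- pairwise_cld(h, regs, same_chrom_only = TRUE)
  expect_equal(nrow(same), 1L)
  expect_setequal(c(same$region_a, same$region_b), c("G1", "G2"))
  # distance is midpoint-to-midpoint
  expect_equal(same$distance, 100)
  # agreement with the scalar path (symmetry built in: unordered pairs)
  a <- carrier_profile(h, regs[regs$name == "G1", ])
  b <- carrier_profile(h, regs[regs$name == "G2", ])
  expect_equal(same$r2, cld(a, b)$r2)
  expect_equal(cld(a, b)$r2, cld(b, a)$r2)
})

test_that("statistics are invariant to variant column order and to
           carrier-subset additions", {
  set.seed(9)
  vals <- sapply(1:6, function(i) rand_ind(60, 0.15))
  pos <- c(10L, 20L, 30L, 110L, 120L, 130L)
  h <- mk_h(vals, pos = pos)
  regs <- as_region_set(data.frame(name = c("G1", "G2"), chrom = "chr1",
                                   start = c(0L, 100L), end = c(100L, 200L)))
  base <- pairwise_cld(h, regs)
  perm <- sample(6)
  h_perm <- mk_h(vals[, perm], pos = pos[perm])
  expect_equal(pairwise_cld(h_perm, regs)$r2, base$r2)
  # add to G1 a variant whose carriers are a subset of existing carriers
  ind1 <- as.integer(rowSums(vals[, 1:3]) > 0)
  sub <- integer(60)
  sub[which(ind1 == 1)[1:2]] <- 1L
  h_aug <- mk_h(cbind(vals, sub), pos = c(pos, 50L))
  expect_equal(pairwise_cld(h_aug, regs)$r2, base$r2)
})
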