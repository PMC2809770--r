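# Diversity, divergence, Tajima's D, F_IS, Ne, correlations.

test_that("theta_pi matches the unbiased pairwise formula", {
  counts <- matrix(0L, nrow = 4L, ncol = 1L, dimnames = list(c("A","C","G","T")))
  counts[c(1L, 2L), 1L] <- c(2L, 2L)            # {2, 2} of 4 alleles
  expect_close(theta_pi(counts)$theta, 2 / 3, tol = 1e-4)   # 4 of 6 pairs
  # relabelling invariance
  counts2 <- counts[c(3, 1, 4, 2), , drop = FALSE]
  rownames(counts2) <- c("A", "C", "G", "T")
  expect_equal(theta_pi(counts2)$theta, theta_pi(counts)$theta)
  # monomorphic locus
  mono <- matrix(c(5L, 0L, 0L, 0L), nrow = 4L, ncol = 10L)
  expect_equal(theta_pi(mono)$theta, 0)
})

test_that("theta_w uses each site's own harmonic number", {
  # n = 2 everywhere: theta_W = S / L
  counts <- matrix(0L, nrow = 4L, ncol = 5L)
  counts[1L, ] <- 1L; counts[2L, 1:2] <- 1L; counts[1L, 3:5] <- 2L
  tw <- theta_w(counts)
  expect_equal(tw$theta, 2 / 5)
  # one segregating site, n = 4, L = 1: 1 / a_3
  c1 <- matrix(c(3L, 1L, 0L, 0L), nrow = 4L)
  expect_close(theta_w(c1)$theta, 1 / (1 + 1/2 + 1/3), tol = 1e-4)
  # no segregating sites
  expect_equal(theta_w(matrix(c(9L, 0L, 0L, 0L), 4, 3))$theta, 0)
})

test_that("Tajima's D matches the hand-derived singleton value at n = 4", {
  # one segregating site with a singleton among 4 alleles, all coverage 4
  patterns <- c(list(c("A", "A", "A", "C")),
                rep(list(c("A", "A", "A", "A")), 7L))
  locus <- toy_intron_locus(patterns)
  td <- tajima_d(list(locus), "intron", fixed_n = 4L, seed = 1)
  expect_close(td$d, -0.612, tol = 5e-4)
  expect_identical(td$seg_sites, 1L)
  # matching oracle from the published constants, computed independently
  n <- 4; S <- 1; pi_sum <- 0.5
  a1 <- sum(1/(1:3)); a2 <- sum(1/(1:3)^2)
  b1 <- (n+1)/(3*(n-1)); b2 <- 2*(n^2+n+3)/(9*n*(n-1))
  c1 <- b1 - 1/a1; c2 <- b2 - (n+2)/(a1*n) + a2/a1^2
  oracle <- (pi_sum - S/a1) / sqrt(c1/a1*S + c2/(a1^2+a2)*S*(S-1))
  expect_equal(td$d, oracle, tolerance = 1e-12)
})

test_that("Tajima downsampling rejects low-coverage sites", {
  patterns <- list(c(rep("A", 10), rep("C", 9), "N"))   # coverage 19 of 20
  locus <- toy_intron_locus(patterns)
  td <- tajima_d(list(locus), "intron", fixed_n = 20L, seed = 1)
  expect_true(is.na(td$d))
  expect_identical(td$seg_sites, 0L)
})

test_that("theta_pi == theta_w configurations give D = 0", {
  expect_equal(tajima_d_from_totals(3, 3 / sum(1 / (1:19)), 20), 0)
})

test_that("Jukes-Cantor correction behaves across its domain", {
  expect_equal(jc_correct(0), 0)
  expect_close(jc_correct(0.03), 0.03062, tol = 5e-6)
  expect_error(jc_correct(0.75))
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jc_correct(p)) > 0))          # monotone
  expect_true(all(jc_correct(p) >= p - 1e-12))       # correction inflates
  expect_close(jc_uncorrect(jc_correct(0.2)), 0.2, tol = 1e-12)
})

test_that("divergence counting follows the all-allele rule", {
  # site 1: outgroup differs from every sampled allele -> divergent
  # site 2: polymorphic ingroup, outgroup matches one allele -> not divergent
  # site 3: outgroup N -> excluded from numerator and denominator
  patterns <- list(rep("A", 4), c("A", "A", "C", "C"), rep("A", 4))
  locus <- toy_intron_locus(patterns)
  og <- locus$reference
  idx <- 7:9
  og[idx] <- c("G", "C", "N")
  locus$outgroup_close <- og
  dv <- jc_divergence(list(locus), "close", "intron")
  expect_identical(dv$n_div, 1L)
  expect_identical(dv$n_sites, length(locus$site_class[
    locus$site_class == "intron"]) - 1L)
})

test_that("bootstrap by locus is seeded and degenerate for one locus", {
  gen <- shared_sim()
  loci <- gen$loci
  stat <- function(l)
    theta_pi(do.call(cbind, lapply(l, site_base_counts)))$theta
  b1 <- bootstrap_by_locus(stat, loci, n_boot = 50L, seed = 5)
  b2 <- bootstrap_by_locus(stat, loci, n_boot = 50L, seed = 5)
  expect_identical(b1$ci, b2$ci)
  single <- bootstrap_by_locus(stat, loci[1L], n_boot = 20L, seed = 5)
  expect_equal(diff(single$ci), 0)
  expect_equal(single$se, 0)
})

test_that("Weir-Cockerham f matches an independent hand evaluation", {
  # H_obs ~ H_exp: f near zero (exactly 1/(2n-1) at H = 2pq)
  expect_close(fis_weir_cockerham(1L, 2L, 1L), 1 / 7, tol = 1e-12)
  # no heterozygotes, both alleles present
  expect_equal(fis_weir_cockerham(3L, 0L, 2L), 1)
  # monomorphic undefined
  expect_true(is.na(fis_weir_cockerham(5L, 0L, 0L)))
  # 3-individual toy vs direct W&C formula coded independently
  nh <- c(1L, 1L, 1L)
  n <- 3; p <- (2*1 + 1) / 6; q <- 1 - p; h <- 1/3
  b <- n/(n-1) * (p*q - (2*n-1)/(4*n) * h); cc <- h/2
  expect_close(fis_weir_cockerham(1L, 1L, 1L), 1 - cc/(b + cc), tol = 1e-12)
})

test_that("inbred synthetic data shows an excess of positive F_IS", {
  cfg <- sim_config(n_loci = 25L, exon_len = 120L, intron_len = 150L,
                    inbreeding_F = 0.5, missing_rate = 0, grid_2N = 80L,
                    seed = 88L)
  gen <- generate_locus_set(cfg)
  fis <- fis_by_snp(gen$loci)
  expect_gt(nrow(fis), 20L)
  expect_gt(mean(fis$f_is > 0), mean(fis$f_is < 0))
  expect_gt(mean(fis$f_is), 0.2)
})

test_that("Ne from diversity reproduces the two-significant-figure values", {
  expect_equal(ne_from_diversity(0.0079, 3.4e-9), 580000)
  expect_equal(ne_from_diversity(0.017, 5.8e-9), 730000)
  expect_equal(ne_from_diversity(0, 1e-9), 0)
  expect_error(ne_from_diversity(0.01, 0))
})

test_that("Spearman correlation matches brute-force ranks on a toy table", {
  dn <- c(0.1, 0.4, 0.2, 0.9, 0.3)
  th <- c(1.0, 2.0, 1.5, 3.0, 1.2)
  got <- diversity_divergence_correlation(dn, th)
  r_oracle <- 1 - 6 * sum((rank(dn) - rank(th))^2) / (5 * (5^2 - 1))
  expect_close(got$rho, r_oracle, tol = 1e-12)
  expect_equal(diversity_divergence_correlation(1:6, (1:6)^2)$rho, 1)
  expect_error(diversity_divergence_correlation(rep(1, 5), 1:5))
  expect_error(diversity_divergence_correlation(1:4, 1:4))
})

test_that("class summary table has the expected shape and finite values", {
  gen <- shared_sim()
  tab <- class_summary_stats(gen$loci, n_boot = 0L, seed = 3)
  expect_identical(tab$site_class, c("0fold", "2fold", "4fold", "intron"))
  expect_true(all(is.finite(tab$theta_pi_pct)))
  expect_true(all(tab$theta_pi_pct >= 0))
  expect_true(all(tab$seg_sites <= tab$n_sites))
})
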