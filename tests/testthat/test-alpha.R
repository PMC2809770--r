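# Fixation rates, alpha estimators, demographic-bias relation, contrasts.

test_that("relative fixation rate matches its closed form and guards overflow", {
  expect_equal(relative_fixation_rate(0), 1)
  expect_close(relative_fixation_rate(-10), 4.540e-4, tol = 1e-7)
  expect_close(relative_fixation_rate(-10), -10 / (1 - exp(10)), tol = 1e-12)
  expect_equal(relative_fixation_rate(-800), 0)
  expect_equal(relative_fixation_rate(800), 800)
  expect_close(relative_fixation_rate(1e-12), 1, tol = 1e-9)
  v <- relative_fixation_rate(c(-5, 0, 5))
  expect_length(v, 3L)
  expect_true(all(diff(v) > 0))
  expect_error(relative_fixation_rate(NaN))
})

test_that("chain fixation converges to R(S) as the grid grows", {
  # at fixed S = -2*gamma the discrete chain approaches the diffusion value
  gam <- 5
  err <- sapply(c(100L, 400L), function(pop2N) {
    u <- wf_fixation_prob_exact(pop2N, gam / (pop2N / 2))
    abs(pop2N * u / relative_fixation_rate(-2 * gam) - 1)
  })
  expect_lt(err[2L], err[1L])
  expect_lt(err[2L], 0.1)
  # weak selection already agrees tightly at 2N = 100
  u1 <- wf_fixation_prob_exact(100L, 1 / 50)
  expect_lt(abs(100 * u1 / relative_fixation_rate(-2) - 1), 0.01)
})

test_that("mean fixation ratio under the DFE matches brute-force quadrature", {
  for (par in list(c(0.31, 1e4), c(0.3, 1000), c(2, 5))) {
    dfe <- gamma_dfe(par[1L], par[2L])
    got <- dfe_mean_fixation_ratio(dfe)
    u <- (seq_len(2e5) - 0.5) / 2e5      # dense PIT midpoint oracle
    oracle <- mean(relative_fixation_rate(
      -2 * qgamma(u, shape = par[1L], scale = par[2L] / par[1L])))
    expect_close(got, oracle, tol = 1e-5)
  }
  expect_equal(dfe_mean_fixation_ratio(gamma_dfe(0.3, 0)), 1)
  # all-lethal limit
  expect_lt(dfe_mean_fixation_ratio(gamma_dfe(50, 1e6)), 1e-10)
})

test_that("expected deleterious divergence and alpha arithmetic", {
  expect_equal(expected_deleterious_divergence(gamma_dfe(0.3, 0), 0.03), 0.03)
  expect_lt(expected_deleterious_divergence(gamma_dfe(50, 1e6), 0.03), 1e-10)
  expect_equal(alpha_from_divergence(0.02, 0.02), 0)
  expect_equal(alpha_from_divergence(0.02, 0.01), 0.5)
  expect_equal(alpha_from_divergence(0.01, 0.02), -1)  # negatives reported
  expect_error(alpha_from_divergence(0, 0.01))
})

test_that("alpha_FWW evaluates the count formula and its edge cases", {
  mk <- data.frame(D_N = c(6, 4), D_S = c(5, 5), P_N = c(3, 2),
                   P_S = c(5, 5), P_N_gt10 = c(1, 1), P_S_gt10 = c(4, 4))
  got <- alpha_fww(mk, 0)
  expect_close(got$alpha, 1 - (10 * 5) / (10 * 10), tol = 1e-12)
  # strict neutrality: D_N/D_S = sum(P_N)/sum(P_S) -> 0
  mk2 <- data.frame(D_N = 8, D_S = 4, P_N = 6, P_S = 3,
                    P_N_gt10 = 2, P_S_gt10 = 1)
  expect_equal(alpha_fww(mk2, 0)$alpha, 0)
  expect_equal(alpha_fww(mk2, 0.10)$alpha, 0)
  # D_N = 10, D_S = 10, P_N = 5, P_S = 10 -> 0.5
  mk3 <- data.frame(D_N = 10, D_S = 10, P_N = 5, P_S = 10,
                    P_N_gt10 = 0, P_S_gt10 = 0)
  expect_equal(alpha_fww(mk3, 0)$alpha, 0.5)
  # zero denominator undefined with a diagnostic
  mk4 <- data.frame(D_N = 10, D_S = 10, P_N = 5, P_S = 0,
                    P_N_gt10 = 0, P_S_gt10 = 0)
  expect_true(is.na(alpha_fww(mk4, 0)$alpha))
  expect_match(alpha_fww(mk4, 0)$reason, "denominator")
  expect_error(alpha_fww(mk3, 0.2))
})

test_that("MK tables respect coverage, outgroup and threshold rules", {
  # 22 called alleles; singleton (1/20 <= 10% after downsampling likely)
  # vs a 50/50 site that always clears the 10% threshold
  patterns <- list(c(rep("A", 11), rep("C", 11)),      # balanced SNP
                   rep("A", 22),                        # divergent candidate
                   rep("A", 22))                        # og missing -> ignored
  locus <- toy_intron_locus(patterns)
  og <- locus$reference
  og[6L + 2L] <- "G"     # site 2 divergent
  og[6L + 3L] <- "N"     # site 3 ignored
  locus$outgroup_close <- og
  mk <- build_mk_table(list(locus), "close", "intron", fixed_n = 20L,
                       seed = 1L)
  expect_equal(mk$D_S, 1)
  expect_equal(mk$P_S, 1)
  expect_equal(mk$P_S_gt10, 1)        # 50/50 always > 10%
  expect_equal(mk$L_S, sum(locus$site_class == "intron") - 1L)
})

test_that("demographic-bias relation reproduces the published worked values", {
  expect_equal(round(alpha_bias_relation(0.1, 0.2, 1/5), 2), 0.35)
  expect_equal(round(alpha_bias_relation(0.1, 0.2, 1/10), 2), 0.43)
  expect_equal(round(alpha_bias_relation(0.57, 0.31, 5), 2), 0.29)
  expect_equal(round(alpha_bias_relation(0.57, 0.31, 10), 2), 0.12)
  # lambda = 1: no bias for any shape
  for (b in c(0.1, 0.5, 2)) {
    expect_equal(alpha_bias_relation(0.4, b, 1), 0.4)
    expect_equal(alpha_bias_relation(0.4, b, 1, "alpha_est"), 0.4)
  }
  # round trip to 1e-12
  for (lam in c(0.2, 5)) {
    est <- alpha_bias_relation(0.37, 0.31, lam, "alpha_est")
    expect_close(alpha_bias_relation(est, 0.31, lam, "alpha_true"), 0.37,
                 tol = 1e-12)
  }
  # direction: contraction understates, expansion overstates
  expect_lt(alpha_bias_relation(0.4, 0.3, 0.2, "alpha_est"), 0.4)
  expect_gt(alpha_bias_relation(0.4, 0.3, 5, "alpha_est"), 0.4)
  expect_error(alpha_bias_relation(0.4, -1, 2))
})

test_that("bootstrap contrasts: identical data give p near 1, seeded", {
  set.seed(4)
  boot <- rnorm(400, 0.5, 0.1)
  same <- contrast_alpha(boot, boot)
  expect_equal(same$p, 1)
  apart <- contrast_alpha(boot + 1, boot)
  expect_lt(apart$p, 0.01)
  expect_warning(contrast_alpha(rnorm(50), rnorm(50)), "fewer than 100")
})

test_that("estimate_alpha_fww runs on simulated loci with both thresholds", {
  gen <- shared_sim()
  a0 <- estimate_alpha_fww(gen$loci, "close", "4fold", 0, n_boot = 30L,
                           seed = 2L)
  a10 <- estimate_alpha_fww(gen$loci, "close", "4fold", 0.10, n_boot = 30L,
                            seed = 2L)
  expect_s3_class(a0, "alpha_estimate")
  expect_true(is.finite(a0$alpha) && a0$alpha <= 1)
  expect_true(is.finite(a10$alpha))
  # reproducible under the seed
  a0b <- estimate_alpha_fww(gen$loci, "close", "4fold", 0, n_boot = 30L,
                            seed = 2L)
  expect_identical(a0$replicates, a0b$replicates)
})
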