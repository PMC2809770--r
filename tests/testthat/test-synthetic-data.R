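# Synthetic-data generator: configuration, SFS simulation, locus bundles.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(missing_rate = 1.2), "probabilities")
  expect_error(sim_config(dfe_shape = 0), "dfe_shape")
  expect_error(sim_config(dfe_mean_S = -1), "dfe_mean_S")
  expect_error(sim_config(alpha_true = 1), "alpha_true")
  expect_error(sim_config(div_neutral_far = 0.8), "divergences")
  expect_error(sim_config(exon_len = 100), "multiple of 3")
  expect_error(sim_config(demog = list(N1_ratio = 1, N2_ratio = -1,
                                       t_gens = 0)))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("no selection makes 0-fold and neutral SFS indistinguishable", {
  cfg <- sim_config(n_loci = 150L, dfe_mean_S = 0, missing_rate = 0,
                    grid_2N = 80L, seed = 21L)
  sim <- simulate_population_sfs(cfg)
  s0 <- sim[["0fold"]]$spectra[["30"]]
  s4 <- sim[["4fold"]]$spectra[["30"]] + sim[["intron"]]$spectra[["30"]]
  # compare segregating-class shapes with a chi-square test
  seg0 <- s0[-1L]; seg4 <- s4[-1L]
  keep <- seg0 + seg4 > 5
  p <- suppressWarnings(chisq.test(rbind(seg0[keep], seg4[keep]))$p.value)
  expect_gt(p, 0.001)
  # and segregating fractions agree
  f0 <- sum(seg0) / sum(s0); f4 <- sum(seg4) / sum(s4)
  expect_lt(abs(f0 - f4) / f4, 0.2)
})

test_that("constant-size neutral spectrum follows the folded 1/i shape", {
  cfg <- sim_config(n_loci = 400L, dfe_mean_S = 0, missing_rate = 0,
                    demog = list(N1_ratio = 1, N2_ratio = 1, t_gens = 0),
                    grid_2N = 80L, seed = 31L, intron_len = 600L,
                    exon_len = 0L)   # intron-only world for a clean check
  sim <- simulate_population_sfs(cfg)
  obs <- sim[["intron"]]$spectra[["30"]][-1L]
  i <- 1:15
  expected_shape <- 1 / i + 1 / (30 - i)
  expected_shape[15] <- 1 / 15
  expected <- sum(obs) * expected_shape / sum(expected_shape)
  # chi-square GOF against the folded neutral equilibrium
  stat <- sum((obs - expected)^2 / expected)
  expect_lt(stat, qchisq(0.999, df = 14))
})

test_that("a strong DFE suppresses 0-fold diversity", {
  cfg <- sim_config(n_loci = 100L, dfe_mean_S = 1000, dfe_shape = 0.3,
                    missing_rate = 0, grid_2N = 80L, seed = 41L)
  sim <- simulate_population_sfs(cfg)
  f0 <- sfs_segregating(sim[["0fold"]]) / sim[["0fold"]]$total_sites
  f4 <- sfs_segregating(sim[["4fold"]]) / sim[["4fold"]]$total_sites
  expect_lt(f0 / f4, 0.5)
})

test_that("t = 0 step change equals the constant-size case", {
  base <- sim_config(n_loci = 40L, dfe_mean_S = 0, grid_2N = 80L, seed = 5L,
                     demog = list(N1_ratio = 1, N2_ratio = 1, t_gens = 0))
  alt <- base
  alt$demog <- list(N1_ratio = 1, N2_ratio = 3, t_gens = 0)
  expect_identical(simulate_population_sfs(base)[["intron"]]$spectra,
                   simulate_population_sfs(alt)[["intron"]]$spectra)
})

test_that("outputs are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_loci = 3L, exon_len = 60L, intron_len = 60L,
                    grid_2N = 80L, seed = 61L)
  a <- generate_locus_set(cfg)
  b <- generate_locus_set(cfg)
  expect_identical(lapply(a$loci, `[[`, "alleles"),
                   lapply(b$loci, `[[`, "alleles"))
  s1 <- simulate_population_sfs(cfg)
  s2 <- simulate_population_sfs(cfg)
  expect_identical(s1[["0fold"]]$spectra, s2[["0fold"]]$spectra)
})

test_that("missing_rate 0 and inbreeding 0 give full 30-allele coverage", {
  cfg <- sim_config(n_loci = 4L, exon_len = 60L, intron_len = 60L,
                    missing_rate = 0, inbreeding_F = 0, grid_2N = 80L,
                    seed = 71L)
  gen <- generate_locus_set(cfg)
  for (locus in gen$loci)
    expect_true(all(locus$coverage == 30L))
})

test_that("zero close divergence leaves the close outgroup identical", {
  cfg <- sim_config(n_loci = 4L, exon_len = 60L, intron_len = 60L,
                    div_neutral_close = 0, alpha_true = 0,
                    missing_rate = 0, grid_2N = 80L, seed = 81L)
  gen <- generate_locus_set(cfg)
  for (locus in gen$loci) {
    called <- locus$outgroup_close %in% c("A", "C", "G", "T")
    expect_identical(locus$outgroup_close[called],
                     locus$reference[called])
  }
})

test_that("realised far 4-fold divergence hits the target within binomial error", {
  cfg <- sim_config(seed = 91L, grid_2N = 80L)
  gen <- generate_locus_set(cfg)
  dv <- jc_divergence(gen$loci, "far", "4fold")
  p_target <- jc_uncorrect(cfg$div_neutral_far)
  se <- sqrt(p_target * (1 - p_target) / dv$n_sites)
  expect_lt(abs(dv$p_raw - p_target), 4 * se)
  # close outgroup likewise
  dc <- jc_divergence(gen$loci, "close", "4fold")
  p_c <- jc_uncorrect(cfg$div_neutral_close)
  se_c <- sqrt(p_c * (1 - p_c) / dc$n_sites)
  expect_lt(abs(dc$p_raw - p_c), 4 * se_c)
})

test_that("adaptive fraction inflates 0-fold divergence as configured", {
  base <- sim_config(n_loci = 60L, alpha_true = 0, seed = 101L,
                     grid_2N = 80L, missing_rate = 0)
  high <- sim_config(n_loci = 60L, alpha_true = 0.75, seed = 101L,
                     grid_2N = 80L, missing_rate = 0)
  d0 <- jc_divergence(generate_locus_set(base)$loci, "close", "0fold")$d
  d1 <- jc_divergence(generate_locus_set(high)$loci, "close", "0fold")$d
  # 1 / (1 - 0.75) = 4-fold inflation expected
  expect_gt(d1 / d0, 2)
})
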