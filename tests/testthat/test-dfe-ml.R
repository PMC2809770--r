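# Expected spectra, DFE quadrature, likelihood, weighted N, class
# proportions, and a reduced-scale ML fit.

test_that("neutral equilibrium spectrum is the folded 1/i + 1/(n-i) shape", {
  for (demog in list(demographic_model(50, 50, 0),
                     demographic_model(50, 50, 400))) {   # n1 = n2 or t = 0
    ex <- expected_folded_sfs_neutral(demog, 20)
    i <- 1:10
    th <- 1 / i + 1 / (20 - i); th[10] <- 1 / 10
    got <- ex$seg_per_influx[-1L] / sum(ex$seg_per_influx[-1L])
    expect_lt(max(abs(got - th / sum(th))), 0.02)    # discrete-grid wiggle
    expect_equal(order(got), order(th / sum(th)))    # same shape ordering
    expect_close(sum(ex$props), 1, tol = 1e-9)
    expect_true(all(ex$props >= 0))
  }
})

test_that("a recent expansion inflates the singleton fraction", {
  eq <- expected_folded_sfs_neutral(demographic_model(50, 50, 0), 20)
  ex <- expected_folded_sfs_neutral(demographic_model(50, 150, 30), 20)
  sing_eq <- eq$seg_per_influx[2L] / sum(eq$seg_per_influx[-1L])
  sing_ex <- ex$seg_per_influx[2L] / sum(ex$seg_per_influx[-1L])
  expect_gt(sing_ex, sing_eq)
})

test_that("selected spectrum reduces to neutral at S = 0 and dies at strong S", {
  demog <- demographic_model(50, 100, 40)
  neu <- expected_folded_sfs_neutral(demog, 20)
  sel0 <- expected_folded_sfs_selected(demog, 0, 20)
  expect_equal(sel0$seg_per_influx, neu$seg_per_influx)
  strong <- expected_folded_sfs_selected(demog, -40, 20)
  expect_lt(sum(strong$seg_per_influx) / sum(neu$seg_per_influx), 0.3)
  # mass concentrates at singletons
  expect_gt(strong$props[2L] / sum(strong$props[-1L]),
            neu$props[2L] / sum(neu$props[-1L]))
  expect_error(expected_folded_sfs_selected(demog, 2, 20), "positively")
})

test_that("DFE integration: limits and self-convergence", {
  demog <- demographic_model(50, 100, 40)
  # mean_S = 0 gives the neutral spectrum
  ex0 <- integrate_over_dfe(demog, gamma_dfe(0.3, 0), 20)
  expect_equal(ex0$seg_per_influx,
               expected_folded_sfs_neutral(demog, 20)$seg_per_influx)
  # near-point-mass DFE approximates the single-S spectrum
  point <- integrate_over_dfe(demog, gamma_dfe(200, 5), 20, 64L)
  single <- expected_folded_sfs_selected(demog, -5, 20)
  expect_lt(max(abs(point$props - single$props)), 0.02)
  # doubling quadrature changes each cell by < 1e-4
  dfe <- gamma_dfe(0.3, 1000)
  a <- integrate_over_dfe(demog, dfe, 20, 32L)
  b <- integrate_over_dfe(demog, dfe, 20, 64L)
  expect_lt(max(abs(a$props - b$props)), 1e-4)
  expect_error(integrate_over_dfe(demog, dfe, 20, 8L))
})

test_that("multinomial log-likelihood matches hand evaluation", {
  expect_close(multinomial_loglik(c(10, 5), c(2/3, 1/3)),
               10 * log(2/3) + 5 * log(1/3), tol = 1e-9)
  expect_close(multinomial_loglik(c(10, 5), c(2/3, 1/3)), -9.548, tol = 5e-4)
  expect_equal(multinomial_loglik(numeric(0), numeric(0)), 0)
  expect_equal(multinomial_loglik(c(0, 0), c(0.5, 0.5)), 0)
  expect_identical(multinomial_loglik(c(1, 1), c(1, 0)), -Inf)
})

test_that("doubling all observed counts doubles the log-likelihood", {
  demog <- demographic_model(50, 100, 40)
  dfe <- gamma_dfe(0.4, 100)
  neu <- grouped_folded_sfs("4fold", list(`20` = c(900, 40, 20, 10, 8, 6,
                                                   5, 4, 3, 2, 2)))
  sel <- grouped_folded_sfs("0fold", list(`20` = c(980, 12, 4, 1, 1, 1,
                                                   0, 0, 0, 1, 0)))
  double_counts <- function(sfs)
    grouped_folded_sfs(sfs$site_class, lapply(sfs$spectra, `*`, 2))
  l1 <- sfs_loglik(neu, sel, demog, dfe, 0.95, 16L)
  l2 <- sfs_loglik(double_counts(neu), double_counts(sel), demog, dfe,
                   0.95, 16L)
  expect_close(l2, 2 * l1, tol = 1e-8)
  expect_identical(sfs_loglik(neu, sel, demog, dfe, 1.2, 16L), -Inf)
})

test_that("likelihood only depends on class and n, not locus structure", {
  gen <- shared_sim()
  demog <- demographic_model(40, 80, 40)
  dfe <- gamma_dfe(0.3, 500)
  whole <- sfs_loglik(build_grouped_folded_sfs(gen$loci, "4fold",
                                               min_group_sites = 0L),
                      build_grouped_folded_sfs(gen$loci, "0fold",
                                               min_group_sites = 0L),
                      demog, dfe, 0.95, 16L)
  split1 <- build_grouped_folded_sfs(gen$loci[1:10], "4fold",
                                     min_group_sites = 0L)
  split2 <- build_grouped_folded_sfs(gen$loci[11:20], "4fold",
                                     min_group_sites = 0L)
  merged <- grouped_folded_sfs("4fold", {
    ns <- union(names(split1$spectra), names(split2$spectra))
    out <- lapply(ns, function(nm) {
      a <- split1$spectra[[nm]]; b <- split2$spectra[[nm]]
      if (is.null(a)) b else if (is.null(b)) a else a + b
    })
    names(out) <- ns
    out
  })
  whole2 <- sfs_loglik(merged,
                       build_grouped_folded_sfs(gen$loci, "0fold",
                                                min_group_sites = 0L),
                       demog, dfe, 0.95, 16L)
  expect_close(whole2, whole, tol = 1e-8)
})

test_that("weighted recent population size has the stated limits and value", {
  expect_equal(weighted_recent_n(demographic_model(100, 200, 0)), 100)
  expect_close(weighted_recent_n(demographic_model(100, 200, 2e6)), 200,
               tol = 1e-6)
  expect_close(weighted_recent_n(demographic_model(100, 200, 100)),
               100 * exp(-0.25) + 200 * (1 - exp(-0.25)), tol = 1e-12)
  expect_close(weighted_recent_n(demographic_model(100, 200, 100)), 122.1,
               tol = 0.05)
})

test_that("Ne*s class proportions match an independent CDF evaluation", {
  dfe <- gamma_dfe(0.31, 1e4)
  got <- nes_class_proportions(dfe)
  sc <- 1e4 / 0.31
  oracle <- c(pgamma(1, 0.31, scale = sc),
              pgamma(10, 0.31, scale = sc) - pgamma(1, 0.31, scale = sc),
              1 - pgamma(10, 0.31, scale = sc))
  expect_close(got, oracle, tol = 1e-6)
  expect_close(sum(got), 1, tol = 1e-12)
  # limits
  expect_close(nes_class_proportions(gamma_dfe(0.5, 1e9))[3L], 1, tol = 1e-3)
  expect_equal(nes_class_proportions(gamma_dfe(0.5, 0)), c(1, 0, 0))
})

test_that("ML fit recovers a fixed point and a neutral selected class", {
  demog <- demographic_model(40, 80, 40)
  dfe <- gamma_dfe(0.35, 300)
  f0 <- 0.96
  # build synthetic observed spectra directly from the model expectations
  lambda <- (1 - f0) / expected_folded_sfs_neutral(demog, 30)$pop_total
  n_sites <- 3e4
  make_obs <- function(seg, cls) {
    p <- c(1 - lambda * sum(seg[-1L]), lambda * seg[-1L])
    grouped_folded_sfs(cls, list(`30` = round(n_sites * p)))
  }
  neu_obs <- make_obs(expected_folded_sfs_neutral(demog, 30)$seg_per_influx,
                      "4fold")
  sel_obs <- make_obs(integrate_over_dfe(demog, dfe, 30, 24L)$seg_per_influx,
                      "0fold")
  refit <- dfe_stage2_fit(neu_obs, sel_obs, demog, n_quadrature = 24L,
                          n_starts = 3L)
  expect_lt(abs(refit$dfe$shape - 0.35), 0.05)
  expect_lt(abs(refit$f0 - f0), 0.01)
  expect_lt(max(abs(nes_class_proportions(refit$dfe) -
                      nes_class_proportions(dfe))), 0.03)
  # neutral-only "selected" class drives mean_S toward 0
  sel_neutral <- make_obs(expected_folded_sfs_neutral(demog, 30)$seg_per_influx,
                          "0fold")
  null_fit <- dfe_stage2_fit(neu_obs, sel_neutral, demog,
                             n_quadrature = 24L, n_starts = 3L)
  expect_gt(nes_class_proportions(null_fit$dfe)[1L], 0.9)
})

test_that("DFE bootstrap returns usable intervals and feeds contrasts", {
  gen <- shared_sim()
  neu <- build_grouped_folded_sfs(gen$loci, "intron")
  sel <- build_grouped_folded_sfs(gen$loci, "0fold")
  fit <- fit_dfe_ml(neu, sel, grid_2N = 80L, n_quadrature = 16L,
                    n_starts = 2L, seed = 5L)
  bt <- dfe_fit_bootstrap(gen$loci, fit, "intron", n_boot = 20L, seed = 5L)
  expect_identical(dim(bt$replicates), c(20L, 4L))
  expect_true(all(bt$ci[, 1] <= bt$ci[, 2]))
  # class-proportion rows are proportions
  expect_true(all(bt$ci[2:4, ] >= 0 & bt$ci[2:4, ] <= 1))
  # identical replicate sets give p = 1 in a contrast
  p <- suppressWarnings(contrast_alpha(bt$replicates[, "shape"],
                                       bt$replicates[, "shape"])$p)
  expect_equal(p, 1)
})

test_that("full fit driver returns a coherent object", {
  gen <- shared_sim()
  neu <- build_grouped_folded_sfs(gen$loci, "4fold")
  sel <- build_grouped_folded_sfs(gen$loci, "0fold")
  fit <- fit_dfe_ml(neu, sel, grid_2N = 80L, n_quadrature = 16L,
                    n_starts = 2L, seed = 2L)
  expect_s3_class(fit, "dfe_fit")
  expect_true(is.finite(fit$loglik))
  expect_close(sum(fit$nes_class_props), 1, tol = 1e-9)
  expect_gt(fit$f0, 0.5)
  expect_true(fit$demog$n2 / fit$demog$n1 >= 0.1 &&
                fit$demog$n2 / fit$demog$n1 <= 5)
})
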