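# ---------------------------------------------------------------------------
# Reduced-scale validation harness: one seeded synthetic dataset through the
# whole chain (generate -> SFS -> DFE fit -> alpha), with the knobs the
# recovery experiments need.  Grid sizes and bootstrap replicate counts
# default to desk-scale settings (documented in the methods vignette); the
# statistical world (locus count, sample size, DFE, expansion) is the
# emulation target of sim_config().
# ---------------------------------------------------------------------------

#' Run one end-to-end recovery experiment
#'
#' Generates a synthetic locus set at the configured `alpha_true`, fits the
#' DFE, and estimates alpha by the model-based route and by both FWW
#' variants, plus the class summary statistics needed for qualitative
#' checks.
#'
#' @param alpha_true adaptive fraction used by the generator.
#' @param seed integer seed.
#' @param n_loci loci to simulate (default 77).
#' @param gen_grid_2N generator Wright-Fisher grid (default 100; scaled
#'   down from the 200 default of [sim_config()] for runtime, with the
#'   step-change time interpreted on that grid).
#' @param fit_grid_2N fitting grid (default 100).
#' @param n_quadrature quadrature nodes for the fit (default 16).
#' @param n_boot bootstrap replicates for the alpha CI (default 100).
#' @return list with `alpha`, `ci`, `covered`, `shape`, `nes_props`,
#'   `fww_all`, `fww_gt10`, `theta_pi_0fold`, `theta_pi_4fold`,
#'   `tajima_d_0fold`, `tajima_d_4fold`.
#' @export
recovery_run <- function(alpha_true, seed, n_loci = 77L, gen_grid_2N = 100L,
                         fit_grid_2N = 100L, n_quadrature = 16L,
                         n_boot = 100L) {
  cfg <- sim_config(n_loci = n_loci, alpha_true = alpha_true,
                    grid_2N = gen_grid_2N, seed = seed)
  loci <- generate_locus_set(cfg)$loci
  # intron sites are the neutral reference here: the generator treats them
  # as neutral with the same mutation rate as 4-fold sites, and their ~5x
  # larger site count stabilises the demography, f0 and d_S estimates at
  # this locus count (both references are valid; see the methods vignette)
  neu <- build_grouped_folded_sfs(loci, "intron")
  sel <- build_grouped_folded_sfs(loci, "0fold")
  fit <- fit_dfe_ml(neu, sel, grid_2N = fit_grid_2N,
                    n_quadrature = n_quadrature, n_starts = 3L,
                    seed = substream_seed(seed, "recovery_fit"))
  am <- estimate_alpha_model(loci, fit, "close", "intron",
                             n_boot = n_boot,
                             seed = substream_seed(seed, "recovery_alpha"))
  f0 <- estimate_alpha_fww(loci, "close", "4fold", 0,
                           seed = substream_seed(seed, "recovery_fww"))
  f10 <- estimate_alpha_fww(loci, "close", "4fold", 0.10,
                            seed = substream_seed(seed, "recovery_fww"))
  counts0 <- pooled_counts_for_class(loci, "0fold")
  counts4 <- pooled_counts_for_class(loci, "4fold")
  list(alpha_true = alpha_true, seed = seed,
       alpha = am$alpha, ci = am$ci,
       covered = is.finite(am$ci[1L]) && am$ci[1L] <= alpha_true &&
         am$ci[2L] >= alpha_true,
       shape = fit$dfe$shape, mean_S = fit$dfe$mean_S,
       nes_props = fit$nes_class_props,
       fww_all = f0$alpha, fww_gt10 = f10$alpha,
       theta_pi_0fold = theta_pi(counts0)$theta,
       theta_pi_4fold = theta_pi(counts4)$theta,
       tajima_d_0fold = tajima_d(loci, "0fold", seed = seed)$d,
       tajima_d_4fold = tajima_d(loci, "4fold", seed = seed)$d)
}
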