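# ---------------------------------------------------------------------------
# Simulation configuration.  Defaults emulate a multi-locus Sanger
# resequencing study of a wild house mouse population: 77 autosomal
# amplicons mixing exon and intron sequence, 15 diploid individuals (30
# alleles), a close outgroup at ~3% neutral divergence and a distant one at
# ~19%, purifying selection on 0-fold sites drawn from a gamma DFE, a
# recent 2-fold population expansion, and a majority-adaptive fraction of
# amino acid divergence.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' @param n_loci number of loci (amplicons).
#' @param exon_len coding bases per locus (multiple of 3).
#' @param intron_len intronic bases per locus.
#' @param n_individuals diploid individuals sampled (2 alleles each).
#' @param missing_rate probability that a site in a sampled allele is
#'   uncalled (N).
#' @param theta_neutral per-site scaled mutation rate 4*Ne*mu at neutral
#'   sites.
#' @param dfe_shape gamma shape of the DFE of deleterious amino acid
#'   mutations.
#' @param dfe_mean_S mean scaled selection strength E\[Ne*s\] of new
#'   deleterious amino acid mutations.
#' @param demog list `(N1_ratio, N2_ratio, t_gens)`: ancestral and current
#'   population sizes as multiples of the base model grid, and generations
#'   (on the grid) since the step change.
#' @param alpha_true fraction of 0-fold divergence that is adaptive.
#' @param div_neutral_close,div_neutral_far target Jukes-Cantor-corrected
#'   neutral divergences (substitutions/site) to the close and far outgroup.
#' @param inbreeding_F per-individual, per-locus probability that the two
#'   alleles at a site are identical by descent.
#' @param grid_2N chromosomes in the base Wright-Fisher model grid (the
#'   ancestral grid size is `grid_2N * N1_ratio`).
#' @param seed integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 77L, exon_len = 300L, intron_len = 300L,
                       n_individuals = 15L, missing_rate = 0.05,
                       theta_neutral = 0.008, dfe_shape = 0.3,
                       dfe_mean_S = 1000,
                       demog = list(N1_ratio = 1, N2_ratio = 2, t_gens = 100),
                       alpha_true = 0.57, div_neutral_close = 0.03,
                       div_neutral_far = 0.19, inbreeding_F = 0.2,
                       grid_2N = 200L, seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci), exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              n_individuals = as.integer(n_individuals),
              missing_rate = missing_rate, theta_neutral = theta_neutral,
              dfe_shape = dfe_shape, dfe_mean_S = dfe_mean_S, demog = demog,
              alpha_true = alpha_true,
              div_neutral_close = div_neutral_close,
              div_neutral_far = div_neutral_far,
              inbreeding_F = inbreeding_F, grid_2N = as.integer(grid_2N),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  probs <- c(missing_rate = cfg$missing_rate, inbreeding_F = cfg$inbreeding_F)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (cfg$dfe_shape <= 0) stop("dfe_shape must be > 0")
  if (cfg$dfe_mean_S < 0) stop("dfe_mean_S must be >= 0")
  if (cfg$alpha_true < 0 || cfg$alpha_true >= 1)
    stop("alpha_true must lie in [0, 1)")
  divs <- c(cfg$div_neutral_close, cfg$div_neutral_far)
  if (any(divs < 0 | divs >= 0.74))
    stop("divergences must lie in [0, 0.74)")
  if (cfg$exon_len %% 3L != 0L)
    stop("exon_len must be a multiple of 3 (whole codons)")
  if (cfg$n_loci < 1 || cfg$n_individuals < 1)
    stop("n_loci and n_individuals must be positive")
  with(cfg$demog, {
    if (N1_ratio <= 0 || N2_ratio <= 0 || t_gens < 0)
      stop("demog: ratios must be positive and t_gens >= 0")
  })
  if (cfg$theta_neutral <= 0 || cfg$theta_neutral > 0.2)
    stop("theta_neutral out of plausible range (0, 0.2]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_loci, "loci,", x$n_individuals, "diploids;",
      "theta =", x$theta_neutral, "; DFE gamma(shape =", x$dfe_shape,
      ", mean Ne s =", x$dfe_mean_S, "); alpha_true =", x$alpha_true, "\n")
  invisible(x)
}

#' Grid population sizes implied by a configuration
#' @keywords internal
sim_grid_sizes <- function(cfg) {
  list(pop2N1 = as.integer(round(cfg$grid_2N * cfg$demog$N1_ratio)),
       pop2N2 = as.integer(round(cfg$grid_2N * cfg$demog$N2_ratio)),
       t_gens = cfg$demog$t_gens)
}
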