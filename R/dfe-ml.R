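# ---------------------------------------------------------------------------
# Maximum-likelihood inference of a gamma distribution of deleterious
# fitness effects (DFE) plus a step-change demographic model from paired
# neutral/selected grouped folded SFSs.
#
# Model grid and scaling.  Transition matrices are built on a model grid of
# 2N1 chromosomes (default 200) with the current size expressed as a ratio
# N2/N1; only ratios and scaled times are identifiable.  Scaled selection is
# expressed as gamma = Nw * s, where Nw is the pair-coalescence weighted
# recent population size and s is the selection coefficient against the
# mutant homozygote (fitnesses 1, 1 - s/2, 1 - s).
# ---------------------------------------------------------------------------

#' Step-change demographic model
#'
#' @param n1,n2 ancestral and current diploid population sizes, in
#'   transition-matrix grid units (>= 2).
#' @param t generations (on the grid) since the size change (>= 0).
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(n1, n2, t) {
  stopifnot(n1 >= 2, n2 >= 2, t >= 0)
  structure(list(n1 = n1, n2 = n2, t = t), class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> N1 =", x$n1, " N2 =", x$n2, " t =", x$t,
      " (grid units); Nw =", round(weighted_recent_n(x), 1), "\n")
  invisible(x)
}

#' Weighted recent population size
#'
#' A single size summarising a step-change history, weighting the two
#' epochs by the probability that a pair of lineages coalesces after the
#' change: `Nw = N1 * exp(-t / (2 N2)) + N2 * (1 - exp(-t / (2 N2)))`.
#' Limits: `t = 0` gives N1, `t >> N2` gives N2.  This pair-coalescence
#' weighting is this package's documented convention for reducing a
#' two-epoch history to one scale for Ne*s (see the methods vignette).
#'
#' @param demog a [demographic_model()].
#' @return weighted diploid population size.
#' @export
weighted_recent_n <- function(demog) {
  f2 <- 1 - exp(-demog$t / (2 * demog$n2))
  demog$n1 * (1 - f2) + demog$n2 * f2
}

#' Gamma DFE of deleterious mutations
#'
#' @param shape gamma shape parameter (> 0).
#' @param mean_S mean scaled selection strength E\[Ne*s\] over new
#'   deleterious mutations (>= 0; 0 means all mutations neutral).
#' @return object of class `gamma_dfe`.
#' @export
gamma_dfe <- function(shape, mean_S) {
  stopifnot(shape > 0, mean_S >= 0)
  structure(list(shape = shape, mean_S = mean_S), class = "gamma_dfe")
}

#' Proportions of mutations in Ne*s effect classes
#'
#' Gamma CDF mass in \[0, b1), \[b1, b2), \[b2, Inf) for class boundaries
#' `boundaries = c(b1, b2)` (default nearly neutral < 1, intermediate 1-10,
#' strongly deleterious > 10), with Ne*s on the weighted-N scale.
#'
#' @param dfe a [gamma_dfe()].
#' @param boundaries two increasing positive numbers.
#' @return numeric vector of three fractions summing to 1.
#' @export
nes_class_proportions <- function(dfe, boundaries = c(1, 10)) {
  stopifnot(length(boundaries) == 2L, diff(boundaries) > 0)
  if (dfe$mean_S == 0) return(c(1, 0, 0))
  sc <- dfe$mean_S / dfe$shape
  p <- stats::pgamma(boundaries, shape = dfe$shape, scale = sc)
  c(p[1], p[2] - p[1], 1 - p[2])
}

# --- cached population densities --------------------------------------------

.density_cache <- new.env(parent = emptyenv())

#' Clear the internal density cache (memory hygiene between large fits)
#' @export
clear_density_cache <- function() {
  rm(list = ls(.density_cache), envir = .density_cache)
  invisible(NULL)
}

#' @keywords internal
cached_stepchange_density <- function(pop2N1, pop2N2, t_gens, s) {
  key <- paste(pop2N1, pop2N2, t_gens, signif(s, 10), sep = "|")
  val <- .density_cache[[key]]
  if (is.null(val)) {
    val <- wf_stepchange_density(pop2N1, pop2N2, t_gens, s)
    .density_cache[[key]] <- val
  }
  val
}

.sampling_cache <- new.env(parent = emptyenv())

#' @keywords internal
cached_sampling_matrix <- function(pop2N, n) {
  key <- paste(pop2N, n, sep = "|")
  val <- .sampling_cache[[key]]
  if (is.null(val)) {
    val <- wf_folded_sampling_matrix(pop2N, n)
    .sampling_cache[[key]] <- val
  }
  val
}

#' @keywords internal
demog_grid <- function(demog) {
  list(pop2N1 = as.integer(round(2 * demog$n1)),
       pop2N2 = as.integer(round(2 * demog$n2)),
       t_gens = as.integer(round(demog$t)))
}

#' Selection coefficient on the model grid for a scaled effect
#'
#' Maps gamma = Nw*s (positive = deleterious) to the grid selection
#' coefficient, capping at 0.98 (effects too strong for the grid behave as
#' effectively lethal: essentially no polymorphism, no fixation).
#' @keywords internal
gamma_to_s <- function(gam, demog) {
  s <- gam / weighted_recent_n(demog)
  if (s > 0.98) s <- 0.98
  s
}

#' Expected folded sample SFS under neutrality
#'
#' Population allele-frequency density from the Wright-Fisher transition
#' matrix (equilibrium at N1, then t generations at N2), sampled binomially
#' to n alleles and folded.  `seg_per_influx[k + 1]` is the expected number
#' of sites at minor count k (k = 0..floor(n/2)) among currently
#' segregating sites per unit mutational influx; `props` normalises it to
#' sum to 1.  The monomorphic class enters the likelihood through the f0
#' scaling, not here.
#'
#' @param demog a [demographic_model()].
#' @param n sample size in alleles (>= 2).
#' @return list with `n`, `seg_per_influx`, `props`, `pop_total` (total
#'   segregating density per influx).
#' @export
expected_folded_sfs_neutral <- function(demog, n) {
  expected_folded_sfs_selected(demog, 0, n)
}

#' Expected folded sample SFS under semidominant selection
#'
#' As [expected_folded_sfs_neutral()] but with scaled selection
#' `Nes` (<= 0 for deleterious mutations; `Nes = -gamma` corresponds to
#' fitnesses 1, 1 - s/2, 1 - s with s = gamma / Nw).
#'
#' @param demog a [demographic_model()].
#' @param Nes scaled selection coefficient of the mutant (0 = neutral,
#'   negative = deleterious).
#' @param n sample size in alleles.
#' @return list as in [expected_folded_sfs_neutral()].
#' @export
expected_folded_sfs_selected <- function(demog, Nes, n) {
  stopifnot(n >= 2, is.finite(Nes))
  if (Nes > 0)
    stop("positively selected polymorphism is not modelled; Nes must be <= 0")
  g <- demog_grid(demog)
  s <- gamma_to_s(-Nes, demog)
  dens <- cached_stepchange_density(g$pop2N1, g$pop2N2, g$t_gens, s)
  seg <- as.vector(cached_sampling_matrix(attr(dens, "pop2N"), n) %*% dens)
  tot <- sum(seg)
  list(n = n, seg_per_influx = seg,
       props = if (tot > 0) seg / tot else seg,
       pop_total = sum(dens))
}

# --- DFE quadrature ---------------------------------------------------------

#' Fixed log-spaced quadrature grid over gamma = Ne*s
#'
#' Node positions are independent of the DFE parameters so that expensive
#' node spectra can be cached while (shape, mean_S) vary during
#' optimisation.  Gamma-distribution mass below the lowest edge is assigned
#' to an effectively neutral node and mass above the highest edge to an
#' effectively lethal node (no polymorphism).
#'
#' @param n_quadrature number of interior nodes (>= 16).
#' @param gamma_max upper grid limit (defaults to the grid's representable
#'   maximum, 0.98 * Nw).
#' @keywords internal
dfe_quadrature_grid <- function(n_quadrature, gamma_max) {
  stopifnot(n_quadrature >= 16)
  edges <- exp(seq(log(1e-4), log(gamma_max), length.out = n_quadrature + 1L))
  nodes <- sqrt(edges[-1] * edges[-length(edges)])   # log-midpoints
  list(edges = edges, nodes = nodes)
}

#' @keywords internal
dfe_quadrature_weights <- function(grid, dfe) {
  sc <- dfe$mean_S / dfe$shape
  cdf <- stats::pgamma(grid$edges, shape = dfe$shape, scale = sc)
  list(w_below = cdf[1L], w_nodes = diff(cdf),
       w_above = 1 - cdf[length(cdf)])
}

#' Node spectra for DFE integration (cached by demography)
#'
#' @return list with the quadrature `grid`, a matrix `seg` of
#'   `floor(n/2)+1` rows by `n_quadrature + 2` columns (neutral node, the
#'   interior nodes, lethal node) of per-influx segregating spectra, and
#'   `pop_total` for the neutral node.
#' @keywords internal
dfe_node_spectra <- function(demog, n, n_quadrature) {
  nw <- weighted_recent_n(demog)
  grid <- dfe_quadrature_grid(n_quadrature, gamma_max = 0.98 * nw)
  neu <- expected_folded_sfs_selected(demog, 0, n)
  seg <- matrix(0, nrow = length(neu$seg_per_influx),
                ncol = n_quadrature + 2L)
  seg[, 1L] <- neu$seg_per_influx
  for (i in seq_along(grid$nodes))
    seg[, i + 1L] <-
      expected_folded_sfs_selected(demog, -grid$nodes[i], n)$seg_per_influx
  # lethal node: no polymorphism at all
  list(grid = grid, seg = seg, pop_total_neutral = neu$pop_total)
}

#' Expected folded SFS integrated over a gamma DFE
#'
#' Quadrature is a fixed log-spaced grid over gamma = Ne*s with
#' gamma-CDF bin masses as weights, plus an effectively neutral node for
#' lower-tail mass and an effectively lethal node for mass beyond the
#' grid's representable maximum (0.98 * Nw).
#'
#' @param demog a [demographic_model()].
#' @param dfe a [gamma_dfe()].
#' @param n sample size in alleles.
#' @param n_quadrature number of quadrature nodes (>= 16, default 24).
#' @return list as in [expected_folded_sfs_neutral()].
#' @export
integrate_over_dfe <- function(demog, dfe, n, n_quadrature = 24L) {
  if (dfe$mean_S == 0) return(expected_folded_sfs_neutral(demog, n))
  spectra <- dfe_node_spectra(demog, n, n_quadrature)
  w <- dfe_quadrature_weights(spectra$grid, dfe)
  wt <- c(w$w_below, w$w_nodes, 0)        # lethal node contributes nothing
  seg <- as.vector(spectra$seg %*% wt)
  tot <- sum(seg)
  list(n = n, seg_per_influx = seg,
       props = if (tot > 0) seg / tot else seg,
       pop_total = spectra$pop_total_neutral)
}

# --- likelihood -------------------------------------------------------------

#' Multinomial log-likelihood up to the multinomial coefficient
#'
#' `sum(obs * log(p))`; the data-dependent multinomial coefficient is
#' dropped (it cancels in all comparisons).  A zero expected probability
#' with a nonzero observed count gives `-Inf`.
#'
#' @param obs non-negative counts.
#' @param probs probabilities of the same length.
#' @export
multinomial_loglik <- function(obs, probs) {
  stopifnot(length(obs) == length(probs))
  use <- obs > 0
  if (any(probs[use] <= 0)) return(-Inf)
  sum(obs[use] * log(probs[use]))
}

#' @keywords internal
group_sample_sizes <- function(sfs) as.integer(names(sfs$spectra))

#' Expected class probabilities (monomorphic + folded segregating cells)
#'
#' Converts a per-influx segregating spectrum into sample-class
#' probabilities using the shared mutational influx implied by f0:
#' lambda = (1 - f0) / V_neutral, where V_neutral is the total neutral
#' segregating density.  f0 is the fraction of sites carrying no
#' (currently segregating) mutation; sampled-monomorphic segregating sites
#' fold into the monomorphic cell.
#' @keywords internal
expected_cell_probs <- function(seg_per_influx, lambda) {
  p_seg <- lambda * seg_per_influx[-1L]
  p0 <- 1 - sum(p_seg)
  if (p0 <= 0) return(NULL)
  c(p0, p_seg)
}

#' Log-likelihood of a neutral/selected folded SFS pair
#'
#' Multinomial log-likelihood per allele-number group (monomorphic class
#' included via the f0-implied mutational influx), summed over groups and
#' over the neutral and selected classes.
#'
#' @param sfs_neutral,sfs_selected [grouped_folded_sfs()] objects.
#' @param demog a [demographic_model()].
#' @param dfe a [gamma_dfe()].
#' @param f0 fraction of unmutated sites, in (0, 1).
#' @param n_quadrature quadrature nodes for the DFE integral.
#' @return scalar log-likelihood (`-Inf` for inadmissible parameters).
#' @export
sfs_loglik <- function(sfs_neutral, sfs_selected, demog, dfe, f0,
                       n_quadrature = 24L) {
  if (f0 <= 0 || f0 >= 1) return(-Inf)
  ll <- 0
  lambda <- NULL
  for (n in group_sample_sizes(sfs_neutral)) {
    exp_neu <- expected_folded_sfs_neutral(demog, n)
    if (is.null(lambda)) lambda <- (1 - f0) / exp_neu$pop_total
    p <- expected_cell_probs(exp_neu$seg_per_influx, lambda)
    if (is.null(p)) return(-Inf)
    ll <- ll + multinomial_loglik(sfs_neutral$spectra[[as.character(n)]], p)
  }
  if (is.null(lambda)) {                     # neutral SFS empty
    v <- expected_folded_sfs_neutral(demog, 2L)$pop_total
    lambda <- (1 - f0) / v
  }
  for (n in group_sample_sizes(sfs_selected)) {
    exp_sel <- integrate_over_dfe(demog, dfe, n, n_quadrature)
    p <- expected_cell_probs(exp_sel$seg_per_influx, lambda)
    if (is.null(p)) return(-Inf)
    ll <- ll + multinomial_loglik(sfs_selected$spectra[[as.character(n)]], p)
  }
  ll
}
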