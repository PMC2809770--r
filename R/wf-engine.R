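# ---------------------------------------------------------------------------
# Wright-Fisher machinery shared by the synthetic-data generator and the
# likelihood code.  Selection follows the semidominant scheme in which the
# wild-type homozygote, heterozygote and mutant homozygote have fitnesses
# 1, 1 - s/2 and 1 - s: positive s is deleterious to the mutant allele.
# Scaled selection is gamma = N*s (diploid N); the diffusion-limit relative
# fixation rate of a new semidominant mutation is S/(1 - exp(-S)) with
# S = -2*N*s = -2*gamma.
# ---------------------------------------------------------------------------

#' Deterministic allele-frequency change under semidominant selection
#'
#' @param p mutant allele frequency in `[0, 1]`.
#' @param s selection coefficient against the mutant homozygote; the
#'   heterozygote has fitness `1 - s/2`. `s > 0` is deleterious.
#' @return expected mutant frequency after selection.
#' @keywords internal
wf_freq_after_selection <- function(p, s) {
  if (s == 0) return(p)
  w_mut <- p * (1 - s) + (1 - p) * (1 - s / 2)
  wbar <- p^2 * (1 - s) + 2 * p * (1 - p) * (1 - s / 2) + (1 - p)^2
  p * w_mut / wbar
}

#' Wright-Fisher transition matrix
#'
#' Row i+1, column j+1 holds P(count j next generation | count i now) for a
#' population of `pop2N` chromosomes under binomial reproduction with
#' semidominant selection `s`.  States 0 and `pop2N` are absorbing.
#'
#' @param pop2N number of chromosomes (2N); at least 4.
#' @param s selection coefficient (see [wf_freq_after_selection()]).
#' @return a `(pop2N + 1) x (pop2N + 1)` dense matrix.
#' @export
wf_transition_matrix <- function(pop2N, s = 0) {
  stopifnot(is.numeric(pop2N), length(pop2N) == 1L, pop2N >= 4,
            is.finite(s), abs(s) < 1)
  pop2N <- as.integer(pop2N)
  p <- wf_freq_after_selection((0:pop2N) / pop2N, s)
  m <- t(vapply(p, function(pp) stats::dbinom(0:pop2N, pop2N, pp),
                numeric(pop2N + 1L)))
  # enforce absorption exactly (guards tiny numerical drift at the edges)
  m[1L, ] <- 0; m[1L, 1L] <- 1
  m[pop2N + 1L, ] <- 0; m[pop2N + 1L, pop2N + 1L] <- 1
  m
}

#' Exact fixation probability from the discrete chain
#'
#' Absorption probability at count `pop2N` for a mutation starting at
#' `init_count` copies, from the fundamental-matrix decomposition of the
#' finite Markov chain.  Used as the brute-force oracle for diffusion
#' approximations and the forward simulator.
#'
#' @inheritParams wf_transition_matrix
#' @param init_count starting copy number (default 1, a new mutation).
#' @return fixation probability in `[0, 1]`.
#' @export
wf_fixation_prob_exact <- function(pop2N, s = 0, init_count = 1L) {
  m <- wf_transition_matrix(pop2N, s)
  tr <- 2:pop2N                           # transient states 1..2N-1
  q <- m[tr, tr, drop = FALSE]
  r_fix <- m[tr, pop2N + 1L]
  b <- solve(diag(length(tr)) - q, r_fix)
  b[[init_count]]
}

#' Equilibrium density of segregating sites per unit mutational influx
#'
#' Expected number of sites at derived count j (j = 1..2N-1) at
#' mutation-selection-drift equilibrium when one new mutation enters the
#' population (at count 1) per generation.
#'
#' @inheritParams wf_transition_matrix
#' @return numeric vector of length `pop2N - 1`.
#' @export
wf_equilibrium_density <- function(pop2N, s = 0) {
  m <- wf_transition_matrix(pop2N, s)
  tr <- 2:pop2N
  tt <- t(m[tr, tr, drop = FALSE])        # maps density forward one generation
  e1 <- numeric(length(tr)); e1[1L] <- 1
  solve(diag(length(tr)) - tt, e1)
}

#' Map a segregating-site density onto a different population-size grid
#'
#' Each count j out of `from2N` is redistributed binomially over counts of
#' `to2N` chromosomes (mass landing on 0 or `to2N` is dropped as absorbed).
#'
#' @keywords internal
wf_regrid_density <- function(x, from2N, to2N) {
  stopifnot(length(x) == from2N - 1L)
  if (from2N == to2N) return(x)
  q <- (1:(from2N - 1L)) / from2N
  out <- numeric(to2N - 1L)
  for (j in seq_along(q)) {
    if (x[j] == 0) next
    out <- out + x[j] * stats::dbinom(1:(to2N - 1L), to2N, q[j])
  }
  out
}

#' Non-equilibrium segregating-site density under a step change in size
#'
#' Starts from equilibrium at `pop2N1` chromosomes, switches to `pop2N2`,
#' and iterates the size-`pop2N2` transition (with one new mutation per
#' generation entering at count 1) for `t_gens` generations.  `t_gens` is
#' measured in generations on the model grid.  Beyond `8 * pop2N2`
#' generations the density is numerically indistinguishable from the new
#' equilibrium and the iteration is truncated there.
#'
#' @param pop2N1,pop2N2 chromosome counts before/after the change.
#' @param t_gens generations since the change (>= 0).  At `t_gens = 0` the
#'   change has not yet acted: the ancestral equilibrium on the `pop2N1`
#'   grid is returned for any `pop2N2`.
#' @param s selection coefficient.
#' @return density over counts `1..pop2N - 1` per unit influx, with
#'   attribute `pop2N` giving the grid it lives on.
#' @export
wf_stepchange_density <- function(pop2N1, pop2N2, t_gens, s = 0) {
  stopifnot(t_gens >= 0)
  t_gens <- as.integer(round(t_gens))
  x0 <- wf_equilibrium_density(pop2N1, s)
  if (t_gens == 0L || pop2N1 == pop2N2)
    return(structure(x0, pop2N = pop2N1))
  x <- wf_regrid_density(x0, pop2N1, pop2N2)
  t_eff <- min(t_gens, as.integer(ceiling(8 * pop2N2)))
  if (t_gens > t_eff)
    return(structure(wf_equilibrium_density(pop2N2, s), pop2N = pop2N2))
  m <- wf_transition_matrix(pop2N2, s)
  tr <- 2:pop2N2
  tt <- t(m[tr, tr, drop = FALSE])
  e1 <- numeric(length(tr)); e1[1L] <- 1
  for (g in seq_len(t_eff)) x <- as.vector(tt %*% x) + e1
  structure(x, pop2N = pop2N2)
}

#' Folded binomial sampling matrix
#'
#' `F[k + 1, j]` is the probability that a sample of `n` alleles drawn
#' binomially from population frequency `j / pop2N` shows minor-allele count
#' `k` (k = 0..floor(n/2); k = 0 collects monomorphic samples).  The exact
#' 50/50 cell at even `n` is counted once.
#'
#' @keywords internal
wf_folded_sampling_matrix <- function(pop2N, n) {
  stopifnot(n >= 2)
  q <- (1:(pop2N - 1L)) / pop2N
  kmax <- n %/% 2L
  f <- matrix(0, nrow = kmax + 1L, ncol = pop2N - 1L)
  for (k in 0:kmax) {
    pr <- stats::dbinom(k, n, q)
    if (k != n - k) pr <- pr + stats::dbinom(n - k, n, q)
    f[k + 1L, ] <- pr
  }
  f
}

#' Expected folded sample spectrum per unit mutational influx
#'
#' Combines a population density from [wf_stepchange_density()] with folded
#' binomial sampling to `n` alleles.  Entry k+1 (k = 0..floor(n/2)) is the
#' expected number of sites with minor-allele count k among currently
#' segregating sites, per unit influx; index 1 (k = 0) holds segregating
#' sites that appear monomorphic in the sample.
#'
#' @param density population density over counts `1..pop2N-1`.
#' @param pop2N chromosomes in the population grid.
#' @param n sample size (alleles).
#' @return numeric vector of length `floor(n/2) + 1`.
#' @keywords internal
wf_sample_folded <- function(density, pop2N, n) {
  as.vector(wf_folded_sampling_matrix(pop2N, n) %*% density)
}

#' Forward Wright-Fisher simulation
#'
#' Vectorised binomial-reproduction simulator used as the brute-force oracle
#' for the transition-matrix computations.  All replicates evolve in
#' lockstep; absorbing states 0 and 2N are sticky.  An optional step change
#' in population size rescales counts binomially at the change generation.
#'
#' @param pop2N chromosomes (>= 4).
#' @param s selection coefficient, `|s| < 1` (positive = deleterious).
#' @param n_generations generations to simulate.
#' @param n_reps number of independent replicate populations.
#' @param init_count starting copy number for every replicate.
#' @param demog optional `list(pop2N2 =, t_change =)`: at generation
#'   `t_change` the population size switches to `pop2N2`.
#' @param seed integer seed (mandatory, for reproducibility).
#' @param record if `"trajectory"`, returns the full count matrix
#'   (generations x replicates); if `"final"` (default), only the final
#'   counts and absorption summary.
#' @return list with `final_counts`, `pop2N_final`, `fixed`, `lost`, and for
#'   `record = "trajectory"` a `trajectory` matrix.
#' @export
forward_wf_simulate <- function(pop2N, s, n_generations, n_reps = 1L,
                                init_count = 1L, demog = NULL, seed,
                                record = c("final", "trajectory")) {
  record <- match.arg(record)
  stopifnot(pop2N >= 4, is.finite(s), abs(s) < 1, n_generations >= 1,
            init_count >= 0, init_count <= pop2N)
  set.seed(as.integer(seed))
  pop2N <- as.integer(pop2N)
  counts <- rep.int(as.integer(init_count), n_reps)
  cur2N <- pop2N
  traj <- if (record == "trajectory")
    matrix(NA_integer_, nrow = n_generations + 1L, ncol = n_reps) else NULL
  if (!is.null(traj)) traj[1L, ] <- counts
  for (g in seq_len(n_generations)) {
    if (!is.null(demog) && g == demog$t_change) {
      new2N <- as.integer(demog$pop2N2)
      counts <- stats::rbinom(n_reps, new2N, counts / cur2N)
      cur2N <- new2N
    }
    live <- counts > 0L & counts < cur2N
    if (any(live)) {
      p <- wf_freq_after_selection(counts[live] / cur2N, s)
      counts[live] <- stats::rbinom(sum(live), cur2N, p)
    }
    if (!is.null(traj)) traj[g + 1L, ] <- counts
  }
  out <- list(final_counts = counts, pop2N_final = cur2N,
              fixed = counts == cur2N, lost = counts == 0L)
  if (!is.null(traj)) out$trajectory <- traj
  out
}
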