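# ---------------------------------------------------------------------------
# Staged maximum-likelihood fitting.  Stage 1 fits the step-change
# demography (N2/N1 ratio, t) plus f0 to the neutral folded SFS; stage 2
# fits the gamma DFE (shape, mean Ne*s) plus f0 to the joint
# neutral + selected likelihood with the demography held fixed, reusing
# cached node spectra so that DFE-parameter optimisation and per-locus
# bootstrap refits are cheap.  Multi-start Nelder-Mead is used throughout
# because the (t, N2/N1) surface is ragged.
# ---------------------------------------------------------------------------

#' Candidate demographies for grid searches
#'
#' The coarse (N2/N1, t) grid used to seed the stage-1 fit and to
#' propagate demographic uncertainty through bootstrap refits.
#' @param grid_2N ancestral grid chromosomes.
#' @param t_max upper bound on t (grid generations).
#' @return list of [demographic_model()].
#' @export
demog_candidate_grid <- function(grid_2N, t_max = 5L * grid_2N) {
  n1 <- grid_2N / 2
  r_grid <- c(0.25, 0.5, 1, 1.5, 2, 3, 4)
  t_grid <- unique(pmin(c(0, 12, 25, 50, 100, 200, 400), t_max))
  out <- list()
  for (r in r_grid) for (t in t_grid)
    out[[length(out) + 1L]] <- demographic_model(n1, n1 * r, t)
  out
}

#' @keywords internal
observed_f0_start <- function(sfs) {
  mono <- sum(unlist(lapply(sfs$spectra, `[[`, 1L)))
  tot <- sfs$total_sites
  min(max(mono / max(tot, 1), 0.5), 0.999)
}

#' @keywords internal
neutral_group_loglik <- function(sfs_neutral, demog, f0) {
  lambda <- NULL
  ll <- 0
  for (n in group_sample_sizes(sfs_neutral)) {
    ex <- expected_folded_sfs_neutral(demog, n)
    if (is.null(lambda)) lambda <- (1 - f0) / ex$pop_total
    p <- expected_cell_probs(ex$seg_per_influx, lambda)
    if (is.null(p)) return(list(ll = -Inf, lambda = NA_real_))
    ll <- ll + multinomial_loglik(sfs_neutral$spectra[[as.character(n)]], p)
  }
  list(ll = ll, lambda = lambda)
}

#' Fit demography and gamma DFE by maximum likelihood
#'
#' @param sfs_neutral,sfs_selected [grouped_folded_sfs()] objects for the
#'   neutral reference and the selected (0-fold) class.
#' @param grid_2N chromosomes of the ancestral model grid (default 200).
#'   Only the size ratio and scaled time are identifiable; the grid sets
#'   the resolution of the transition-matrix computation.
#' @param n_quadrature DFE quadrature nodes (default 24).
#' @param n_starts optimisation starts per stage (default 5).
#' @param t_max upper bound for the time since the size change, in grid
#'   generations (default `5 * grid_2N`).
#' @param seed integer seed (start-point jitter).
#' @return object of class `dfe_fit` with elements `dfe`, `demog`, `f0`,
#'   `loglik`, `weighted_n`, `nes_class_props`, `lambda`, `convergence`,
#'   plus the grid settings needed for refits.
#' @export
fit_dfe_ml <- function(sfs_neutral, sfs_selected, grid_2N = 200L,
                       n_quadrature = 24L, n_starts = 5L,
                       t_max = 5L * grid_2N, seed = 1L) {
  stopifnot(sfs_neutral$total_sites > 0, sfs_selected$total_sites > 0)
  set.seed(substream_seed(seed, "fit_dfe_ml"))
  n1 <- grid_2N / 2

  # ---- stage 1: demography + f0 from the neutral SFS ----
  # The folded neutral SFS carries limited demographic information, so the
  # size ratio is searched on a bounded range (beyond ~4-fold the folded
  # spectrum at these sample sizes is essentially flat in r, and the grid
  # cost grows as (2N2)^2); f0 is profiled out in 1-D for each (r, t) and
  # the best grid point is refined locally.
  f0_init <- observed_f0_start(sfs_neutral)
  profile_f0 <- function(demog) {
    f <- function(q) {
      ll <- neutral_group_loglik(sfs_neutral, demog, stats::plogis(q))$ll
      if (!is.finite(ll)) 1e12 else -ll
    }
    op <- stats::optimize(f, interval = stats::qlogis(c(0.2, 0.9995)))
    list(f0 = stats::plogis(op$minimum), nll = op$objective)
  }
  candidates <- demog_candidate_grid(grid_2N, t_max)
  stage1 <- data.frame(r = vapply(candidates, function(d) d$n2 / d$n1,
                                  numeric(1)),
                       t = vapply(candidates, `[[`, numeric(1), "t"),
                       nll = Inf, f0 = NA_real_)
  for (i in seq_along(candidates)) {
    pf <- profile_f0(candidates[[i]])
    stage1$nll[i] <- pf$nll; stage1$f0[i] <- pf$f0
  }
  best_row <- stage1[which.min(stage1$nll), ]
  obj1 <- function(par) {
    r <- exp(par[1L]); t <- exp(par[2L]) - 1; f0 <- stats::plogis(par[3L])
    if (r < 0.1 || r > 5 || t < 0 || t > t_max) return(1e12)
    demog <- demographic_model(n1, n1 * r, 4 * round(t / 4))
    ll <- neutral_group_loglik(sfs_neutral, demog, f0)$ll
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best1 <- stats::optim(c(log(best_row$r), log(best_row$t + 1),
                          stats::qlogis(best_row$f0)), obj1,
                        method = "Nelder-Mead",
                        control = list(maxit = 120, reltol = 1e-8))
  if (best1$value > best_row$nll) {          # refinement went astray
    best1 <- list(par = c(log(best_row$r), log(best_row$t + 1),
                          stats::qlogis(best_row$f0)),
                  value = best_row$nll, convergence = 0L)
  }
  r_hat <- min(max(exp(best1$par[1L]), 0.1), 5)
  t_hat <- 4 * round((exp(best1$par[2L]) - 1) / 4)
  demog_hat <- demographic_model(n1, n1 * r_hat, t_hat)

  # ---- stage 2: DFE + f0 with demography fixed ----
  fit2 <- dfe_stage2_fit(sfs_neutral, sfs_selected, demog_hat,
                         n_quadrature = n_quadrature, n_starts = n_starts,
                         f0_init = stats::plogis(best1$par[3L]))

  dfe_hat <- fit2$dfe
  f0_hat <- fit2$f0
  ll_joint <- sfs_loglik(sfs_neutral, sfs_selected, demog_hat, dfe_hat,
                         f0_hat, n_quadrature)
  structure(list(
    dfe = dfe_hat, demog = demog_hat, f0 = f0_hat, loglik = ll_joint,
    weighted_n = weighted_recent_n(demog_hat),
    nes_class_props = nes_class_proportions(dfe_hat),
    lambda = (1 - f0_hat) /
      expected_folded_sfs_neutral(demog_hat,
                                  group_sample_sizes(sfs_neutral)[1L])$pop_total,
    grid_2N = grid_2N, n_quadrature = n_quadrature, t_max = t_max,
    convergence = list(stage1 = best1$convergence %||% 0L,
                       stage2 = fit2$convergence,
                       stage1_grid_nll = best_row$nll,
                       stage1_nll = best1$value)),
    class = "dfe_fit")
}

#' Stage-2 refit: gamma DFE and f0 with the demography held fixed
#'
#' Used internally by [fit_dfe_ml()] and for fast per-locus bootstrap
#' refits (node spectra for a fixed demography are cached).
#'
#' @param sfs_neutral,sfs_selected observed grouped folded SFSs.
#' @param demog fixed [demographic_model()].
#' @param n_quadrature quadrature nodes.
#' @param n_starts optimisation starts.
#' @param f0_init starting value for f0.
#' @return list with `dfe`, `f0`, `loglik`, `convergence`.
#' @export
dfe_stage2_fit <- function(sfs_neutral, sfs_selected, demog,
                           n_quadrature = 24L, n_starts = 5L,
                           f0_init = NULL) {
  if (is.null(f0_init)) f0_init <- observed_f0_start(sfs_neutral)
  ns_sel <- group_sample_sizes(sfs_selected)
  ns_neu <- group_sample_sizes(sfs_neutral)
  node_list <- lapply(ns_sel, function(n)
    dfe_node_spectra(demog, n, n_quadrature))
  names(node_list) <- as.character(ns_sel)
  exp_neu <- lapply(ns_neu, function(n) expected_folded_sfs_neutral(demog, n))
  names(exp_neu) <- as.character(ns_neu)
  v_neu <- exp_neu[[1L]]$pop_total
  grid <- node_list[[1L]]$grid

  obj2 <- function(par) {
    shape <- exp(par[1L]); mean_s <- exp(par[2L])
    f0 <- stats::plogis(par[3L])
    if (shape < 0.02 || shape > 20 || mean_s > 1e7) return(1e12)
    lambda <- (1 - f0) / v_neu
    ll <- 0
    for (nm in names(exp_neu)) {
      p <- expected_cell_probs(exp_neu[[nm]]$seg_per_influx, lambda)
      if (is.null(p)) return(1e12)
      ll <- ll + multinomial_loglik(sfs_neutral$spectra[[nm]], p)
    }
    w <- dfe_quadrature_weights(grid, gamma_dfe(shape, mean_s))
    wt <- c(w$w_below, w$w_nodes, 0)
    for (nm in names(node_list)) {
      seg <- as.vector(node_list[[nm]]$seg %*% wt)
      p <- expected_cell_probs(seg, lambda)
      if (is.null(p)) return(1e12)
      ll <- ll + multinomial_loglik(sfs_selected$spectra[[nm]], p)
    }
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  q0 <- stats::qlogis(f0_init)
  starts2 <- list(c(log(0.3), log(1000), q0),
                  c(log(0.15), log(100), q0),
                  c(log(0.6), log(10000), q0),
                  c(log(1), log(10), q0),
                  c(log(0.4), log(30), q0))
  starts2 <- starts2[seq_len(min(n_starts, length(starts2)))]
  fits <- lapply(starts2, function(st)
    tryCatch(stats::optim(st, obj2, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-9)),
             error = function(e) list(value = Inf)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(!is.finite(vals))) stop("stage-2 DFE fit failed at all starts")
  best <- fits[[which.min(vals)]]
  list(dfe = gamma_dfe(exp(best$par[1L]), exp(best$par[2L])),
       f0 = stats::plogis(best$par[3L]),
       loglik = -best$value, convergence = best$convergence)
}

#' Per-locus bootstrap intervals for fitted DFE quantities
#'
#' Resamples loci with replacement, rebuilds both grouped folded SFSs and
#' refits the DFE (stage 2, with the demography re-selected from the
#' candidate grid per replicate; reduced multi-starts).  Returns percentile
#' CIs and the raw replicate vectors, which can be fed to
#' [contrast_alpha()] for between-dataset contrasts of the shape or of the
#' Ne*s class proportions.
#'
#' @param loci list of `annotated_locus`.
#' @param fit a [fit_dfe_ml()] result.
#' @param neutral_ref neutral site class used in the fit.
#' @param cpg_filter as used in the fit.
#' @param n_boot bootstrap replicates (default 200; the full-scale analysis
#'   uses 1000).
#' @param seed integer seed.
#' @return list with `ci` (rows: shape, nes_lt1, nes_1to10, nes_gt10) and
#'   `replicates` (matrix, one column per quantity).
#' @export
dfe_fit_bootstrap <- function(loci, fit, neutral_ref = c("4fold", "intron"),
                              cpg_filter = FALSE, n_boot = 200L, seed = 1L) {
  neutral_ref <- match.arg(neutral_ref)
  candidates <- demog_candidate_grid(fit$grid_2N, fit$t_max)
  set.seed(substream_seed(seed, "dfe_fit_boot"))
  reps <- matrix(NA_real_, nrow = n_boot, ncol = 4L,
                 dimnames = list(NULL, c("shape", "nes_lt1", "nes_1to10",
                                         "nes_gt10")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(loci), replace = TRUE)
    lset <- loci[idx]
    neu <- build_grouped_folded_sfs(lset, neutral_ref, cpg_filter)
    sel <- build_grouped_folded_sfs(lset, "0fold", cpg_filter)
    if (sfs_segregating(neu) == 0 || sel$total_sites == 0) next
    lls <- vapply(candidates, function(d)
      neutral_group_loglik(neu, d, fit$f0)$ll, numeric(1))
    demog_b <- if (any(is.finite(lls))) candidates[[which.max(lls)]]
               else fit$demog
    refit <- tryCatch(
      dfe_stage2_fit(neu, sel, demog_b, n_quadrature = fit$n_quadrature,
                     n_starts = 2L, f0_init = fit$f0),
      error = function(e) NULL)
    if (is.null(refit)) next
    reps[b, ] <- c(refit$dfe$shape, nes_class_proportions(refit$dfe))
  }
  ok <- stats::complete.cases(reps)
  ci <- t(apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975)))
  list(ci = ci, replicates = reps, n_failed = sum(!ok))
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat("<dfe_fit>\n")
  cat("  gamma DFE: shape =", signif(x$dfe$shape, 3),
      ", mean Ne*s =", signif(x$dfe$mean_S, 4), "\n")
  cat("  demography: N2/N1 =", signif(x$demog$n2 / x$demog$n1, 3),
      ", t =", x$demog$t, "grid generations; weighted N =",
      round(x$weighted_n, 1), "\n")
  cat("  f0 =", signif(x$f0, 4), "; log-likelihood =",
      signif(x$loglik, 8), "\n")
  pr <- round(100 * x$nes_class_props)
  cat("  Ne*s classes: 0-1:", pr[1L], "%  1-10:", pr[2L], "%  >10:",
      pr[3L], "%\n")
  invisible(x)
}
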