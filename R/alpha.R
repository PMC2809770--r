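# ---------------------------------------------------------------------------
# Estimating the fraction of adaptive substitutions, alpha.
#
# Model-based route: the expected nonsynonymous divergence due to fixation
# of deleterious mutations is d_S times the mean relative fixation rate
# under the fitted DFE; alpha is the excess of observed over expected,
# scaled by observed.  MK-table route: the Fay-Wyckoff-Wu estimator
# alpha = 1 - (D_S * sum(P_N)) / (D_N * sum(P_S)), optionally excluding
# variants at frequency <= 10% after downsampling to a fixed 20 alleles.
# ---------------------------------------------------------------------------

#' Relative fixation rate of a semidominant mutation
#'
#' Diffusion-limit fixation probability of a new mutation relative to a
#' neutral one: `R(S) = S / (1 - exp(-S))`, continuous at 0 with
#' `R(0) = 1`.  `S` is the scaled additive selection coefficient
#' (the diffusion exponent); under the fitness scheme 1, 1 - s/2, 1 - s a
#' mutation with Ne*s = gamma has `S = -2 * gamma` (negative =
#' deleterious).
#'
#' @param S scaled selection (finite; may be a vector).
#' @return relative fixation rate(s).
#' @export
relative_fixation_rate <- function(S) {
  stopifnot(all(is.finite(S)))
  out <- numeric(length(S))
  big <- S > 700
  small <- S < -700
  mid <- !big & !small
  out[big] <- S[big]                       # exp(-S) underflows; R ~ S
  out[small] <- 0                          # S * exp(S) underflows to 0
  z <- S[mid]
  out[mid] <- ifelse(abs(z) < 1e-8, 1 + z / 2, z / (1 - exp(-z)))
  out
}

#' Mean relative fixation rate under a gamma DFE
#'
#' `E[R(-2 gamma)]` with gamma ~ Gamma(shape, mean_S / shape), evaluated by
#' probability-integral-transform quadrature (smooth and bounded for any
#' shape, including shape < 1 where the density is singular at 0).
#'
#' @param dfe a [gamma_dfe()].
#' @return mean fixation rate relative to neutral, in `[0, 1]`.
#' @export
dfe_mean_fixation_ratio <- function(dfe) {
  if (dfe$mean_S == 0) return(1)
  sc <- dfe$mean_S / dfe$shape
  f <- function(u) relative_fixation_rate(
    -2 * stats::qgamma(u, shape = dfe$shape, scale = sc))
  stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Expected selected-site divergence from deleterious fixations
#'
#' `d_N^del = d_neutral * E[R(S)]` under the fitted DFE, with Ne*s on the
#' weighted-N scale (N equated with Ne).
#'
#' @param dfe a [gamma_dfe()] (typically from a [fit_dfe_ml()] object).
#' @param d_neutral observed neutral divergence (>= 0).
#' @return expected divergence at selected sites due to deleterious
#'   fixations.
#' @export
expected_deleterious_divergence <- function(dfe, d_neutral) {
  stopifnot(d_neutral >= 0)
  d_neutral * dfe_mean_fixation_ratio(dfe)
}

#' Model-based alpha from observed and expected divergence
#'
#' `alpha = (d_N - d_N_del) / d_N`; negative values are reported, not
#' truncated.
#'
#' @param d_n observed selected-site divergence (> 0).
#' @param d_n_del expected divergence from deleterious fixations.
#' @export
alpha_from_divergence <- function(d_n, d_n_del) {
  if (!is.finite(d_n) || d_n <= 0)
    stop("observed selected divergence must be positive")
  (d_n - d_n_del) / d_n
}

#' Per-locus McDonald-Kreitman table
#'
#' For every locus, counts of divergent (D) and polymorphic (P) sites for
#' the selected (0-fold) and neutral reference classes, after downsampling
#' every site to exactly `fixed_n` alleles (sites with lower coverage or
#' without a called orthologous outgroup base are ignored).  A site whose
#' outgroup base differs from all `fixed_n` sampled alleles counts once as
#' divergent; otherwise, if two bases segregate in the subsample it counts
#' as polymorphic, recorded both unfiltered and with the minor variant at
#' frequency strictly above 10%.
#'
#' @param loci list of `annotated_locus`.
#' @param outgroup "close" or "far".
#' @param neutral_ref neutral site class, "4fold" or "intron".
#' @param cpg_filter if TRUE, use only non-CpG-prone sites.
#' @param fixed_n alleles per site after downsampling (default 20).
#' @param seed integer seed for the downsampling.
#' @return data.frame of class `mk_table` with one row per locus: D_N, D_S,
#'   P_N, P_S, P_N_gt10, P_S_gt10, L_N, L_S.
#' @export
build_mk_table <- function(loci, outgroup = c("close", "far"),
                           neutral_ref = c("4fold", "intron"),
                           cpg_filter = FALSE, fixed_n = 20L, seed = 1L) {
  outgroup <- match.arg(outgroup)
  neutral_ref <- match.arg(neutral_ref)
  field <- paste0("outgroup_", outgroup)
  set.seed(substream_seed(seed, paste("mk", outgroup, neutral_ref)))
  thresh_count <- floor(0.10 * fixed_n)     # strictly > 10%: minor count > this
  one_class <- function(locus, cls) {
    keep <- which(class_site_filter(locus, cls, cpg_filter) &
                    locus$coverage >= fixed_n)
    og <- locus[[field]][keep]
    keep <- keep[og %in% DNA_BASES]
    if (!length(keep)) return(c(D = 0L, P = 0L, P_gt = 0L, L = 0L))
    og <- locus[[field]][keep]
    counts <- site_base_counts(locus)[, keep, drop = FALSE]
    sub <- downsample_counts_matrix(counts, fixed_n)
    og_in_sub <- sub[cbind(match(og, DNA_BASES), seq_along(keep))]
    div <- og_in_sub == 0L
    seg <- colSums(sub > 0L) >= 2L
    poly <- !div & seg
    minor <- fixed_n - pmax(sub[1L, ], sub[2L, ], sub[3L, ], sub[4L, ])
    c(D = sum(div), P = sum(poly),
      P_gt = sum(poly & minor > thresh_count), L = length(keep))
  }
  rows <- lapply(loci, function(locus) {
    sel <- one_class(locus, "0fold")
    neu <- one_class(locus, neutral_ref)
    data.frame(locus = locus$locus_id,
               D_N = sel[["D"]], D_S = neu[["D"]],
               P_N = sel[["P"]], P_S = neu[["P"]],
               P_N_gt10 = sel[["P_gt"]], P_S_gt10 = neu[["P_gt"]],
               L_N = sel[["L"]], L_S = neu[["L"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "outgroup") <- outgroup
  attr(out, "neutral_ref") <- neutral_ref
  class(out) <- c("mk_table", class(out))
  out
}

#' Fay-Wyckoff-Wu alpha from an MK table
#'
#' `alpha_FWW = 1 - (D_S * sum(P_N)) / (D_N * sum(P_S))`, counts summed
#' over genes.  With `freq_threshold = 0.10`, polymorphisms whose minor
#' variant is at frequency 10% or less (after the fixed-n downsampling)
#' are excluded.
#'
#' @param mk an [build_mk_table()] result (or any data.frame with the same
#'   columns).
#' @param freq_threshold 0 (all variants) or 0.10.
#' @return list with `alpha`, `method`, and the pooled counts; `alpha` is
#'   `NA` with a `reason` when a denominator is zero.
#' @export
alpha_fww <- function(mk, freq_threshold = 0) {
  stopifnot(freq_threshold %in% c(0, 0.10))
  d_n <- sum(mk$D_N); d_s <- sum(mk$D_S)
  if (freq_threshold == 0) {
    p_n <- sum(mk$P_N); p_s <- sum(mk$P_S)
  } else {
    p_n <- sum(mk$P_N_gt10); p_s <- sum(mk$P_S_gt10)
  }
  method <- if (freq_threshold == 0) "fww_all" else "fww_gt10"
  if (d_n == 0 || p_s == 0)
    return(list(alpha = NA_real_, method = method,
                reason = "zero denominator (D_N or sum P_S)",
                counts = c(D_N = d_n, D_S = d_s, P_N = p_n, P_S = p_s)))
  list(alpha = 1 - (d_s * p_n) / (d_n * p_s), method = method,
       counts = c(D_N = d_n, D_S = d_s, P_N = p_n, P_S = p_s))
}

#' Demographic bias relation between true and estimated alpha
#'
#' For a gamma DFE with shape `b` and a ratio `lambda` of current to
#' ancestral Ne: `alpha_est = 1 - (1 - alpha_true) * lambda^(-b)`, and its
#' inversion `alpha_true = 1 - (1 - alpha_est) * lambda^b`.  A contraction
#' (`lambda < 1`) makes the estimate an underestimate; an expansion an
#' overestimate.
#'
#' @param alpha known value (`alpha_true` when solving for `alpha_est`,
#'   `alpha_est` when solving for `alpha_true`).
#' @param shape_b gamma shape parameter (> 0).
#' @param lambda ratio of current to ancestral Ne (> 0).
#' @param solve_for which side to compute.
#' @return the implied alpha.
#' @export
alpha_bias_relation <- function(alpha, shape_b, lambda,
                                solve_for = c("alpha_true", "alpha_est")) {
  solve_for <- match.arg(solve_for)
  stopifnot(lambda > 0, shape_b > 0)
  if (solve_for == "alpha_true") 1 - (1 - alpha) * lambda^shape_b
  else 1 - (1 - alpha) * lambda^(-shape_b)
}

#' Two-sided bootstrap contrast between two alpha estimates
#'
#' Combines two bootstrap distributions (paired by replicate) into a
#' two-sided p-value for the difference, with +1 continuity correction:
#' `p = 2 * min(Pr(delta <= 0), Pr(delta >= 0))`, capped at 1.
#'
#' @param boot_a,boot_b bootstrap replicate vectors for the two datasets.
#' @return list with `p`, `delta` (point difference of means), `n_reps`.
#' @export
contrast_alpha <- function(boot_a, boot_b) {
  ok_a <- boot_a[is.finite(boot_a)]
  ok_b <- boot_b[is.finite(boot_b)]
  b <- min(length(ok_a), length(ok_b))
  if (b < 100) warning("fewer than 100 bootstrap replicates; p-value coarse")
  if (b < 2) stop("not enough bootstrap replicates for a contrast")
  delta <- ok_a[seq_len(b)] - ok_b[seq_len(b)]
  p_lo <- (1 + sum(delta <= 0)) / (b + 1)
  p_hi <- (1 + sum(delta >= 0)) / (b + 1)
  list(p = min(1, 2 * min(p_lo, p_hi)),
       delta = mean(ok_a) - mean(ok_b), n_reps = b)
}

#' Model-based alpha for a locus set, with full-chain bootstrap
#'
#' Computes observed divergences for the selected and neutral classes,
#' takes the expected deleterious divergence from a fitted DFE, and
#' reports `alpha = (d_N - d_N^del) / d_N`.  The bootstrap resamples loci
#' with replacement and re-runs the whole chain - SFS construction,
#' stage-2 DFE refit (demography fixed at the point estimate for
#' tractability), divergences - per replicate.
#'
#' @param loci list of `annotated_locus`.
#' @param fit a [fit_dfe_ml()] result for the same class pair.
#' @param outgroup "close" or "far".
#' @param neutral_ref "4fold" or "intron".
#' @param cpg_filter if TRUE, restrict to non-CpG-prone sites.
#' @param n_boot bootstrap replicates (0 disables the CI).
#' @param seed integer seed.
#' @param refit_demography if `"grid"`, every bootstrap replicate re-selects
#'   the demography from the coarse candidate grid (ranked by the
#'   replicate's neutral likelihood at the point-estimate f0) before the
#'   DFE refit, so the interval reflects demographic as well as DFE
#'   uncertainty; `"none"` keeps the point-estimate demography throughout.
#' @return object of class `alpha_estimate`: list with `alpha`, `method`,
#'   `ci`, `se`, `d_n`, `d_s`, `mean_fixation_ratio`, `replicates`.
#' @export
estimate_alpha_model <- function(loci, fit, outgroup = c("close", "far"),
                                 neutral_ref = c("4fold", "intron"),
                                 cpg_filter = FALSE, n_boot = 0L, seed = 1L,
                                 refit_demography = c("grid", "none")) {
  outgroup <- match.arg(outgroup)
  neutral_ref <- match.arg(neutral_ref)
  refit_demography <- match.arg(refit_demography)
  candidates <- if (refit_demography == "grid")
    demog_candidate_grid(fit$grid_2N, fit$t_max) else NULL
  point <- function(lset, dfe) {
    d_n <- jc_divergence(lset, outgroup, "0fold", cpg_filter)$d
    d_s <- jc_divergence(lset, outgroup, neutral_ref, cpg_filter)$d
    if (!is.finite(d_n) || d_n <= 0) return(c(NA_real_, d_n, d_s))
    del <- expected_deleterious_divergence(dfe, d_s)
    c(alpha_from_divergence(d_n, del), d_n, d_s)
  }
  pt <- point(loci, fit$dfe)
  reps <- NULL
  if (n_boot > 0L) {
    set.seed(substream_seed(seed, paste("alpha_boot", outgroup, neutral_ref)))
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(loci), replace = TRUE)
      lset <- loci[idx]
      neu <- build_grouped_folded_sfs(lset, neutral_ref, cpg_filter)
      sel <- build_grouped_folded_sfs(lset, "0fold", cpg_filter)
      if (sfs_segregating(neu) == 0 || sel$total_sites == 0)
        return(NA_real_)
      demog_b <- fit$demog
      if (!is.null(candidates)) {
        lls <- vapply(candidates, function(d)
          neutral_group_loglik(neu, d, fit$f0)$ll, numeric(1))
        if (any(is.finite(lls)))
          demog_b <- candidates[[which.max(lls)]]
      }
      refit <- tryCatch(
        dfe_stage2_fit(neu, sel, demog_b,
                       n_quadrature = fit$n_quadrature, n_starts = 2L,
                       f0_init = fit$f0),
        error = function(e) NULL)
      if (is.null(refit)) return(NA_real_)
      point(lset, refit$dfe)[1L]
    }, numeric(1))
  }
  ok <- reps[is.finite(reps)]
  structure(list(
    alpha = pt[1L], method = "model_based",
    ci = if (length(ok) >= 2) unname(stats::quantile(ok, c(0.025, 0.975)))
         else c(NA_real_, NA_real_),
    se = if (length(ok) >= 2) stats::sd(ok) else NA_real_,
    d_n = pt[2L], d_s = pt[3L],
    mean_fixation_ratio = dfe_mean_fixation_ratio(fit$dfe),
    outgroup = outgroup, neutral_ref = neutral_ref,
    replicates = reps), class = "alpha_estimate")
}

#' Fay-Wyckoff-Wu alpha for a locus set with per-locus bootstrap
#'
#' @inheritParams estimate_alpha_model
#' @param freq_threshold 0 or 0.10 (exclude minor variants at <= 10%).
#' @param fixed_n alleles per site after downsampling.
#' @return object of class `alpha_estimate`.
#' @export
estimate_alpha_fww <- function(loci, outgroup = c("close", "far"),
                               neutral_ref = c("4fold", "intron"),
                               freq_threshold = 0, cpg_filter = FALSE,
                               fixed_n = 20L, n_boot = 0L, seed = 1L) {
  outgroup <- match.arg(outgroup)
  neutral_ref <- match.arg(neutral_ref)
  mk <- build_mk_table(loci, outgroup, neutral_ref, cpg_filter, fixed_n, seed)
  pt <- alpha_fww(mk, freq_threshold)
  reps <- NULL
  if (n_boot > 0L) {
    set.seed(substream_seed(seed, paste("fww_boot", outgroup, neutral_ref,
                                        freq_threshold)))
    n_loci <- nrow(mk)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_loci, replace = TRUE)
      alpha_fww(mk[idx, , drop = FALSE], freq_threshold)$alpha
    }, numeric(1))
  }
  ok <- reps[is.finite(reps)]
  structure(list(
    alpha = pt$alpha, method = pt$method, counts = pt$counts,
    ci = if (length(ok) >= 2) unname(stats::quantile(ok, c(0.025, 0.975)))
         else c(NA_real_, NA_real_),
    se = if (length(ok) >= 2) stats::sd(ok) else NA_real_,
    outgroup = outgroup, neutral_ref = neutral_ref,
    replicates = reps), class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat("<alpha_estimate> method =", x$method, " outgroup =", x$outgroup,
      " neutral =", x$neutral_ref, "\n")
  cat("  alpha =", signif(x$alpha, 4))
  if (is.finite(x$ci[1L]))
    cat("  [95% CI ", signif(x$ci[1L], 3), "/", signif(x$ci[2L], 3), "]",
        sep = "")
  cat("\n")
  invisible(x)
}
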