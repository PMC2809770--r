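# Small shared helpers.

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the package flows from one top-level seed; each stage
#' (simulation, downsampling, bootstrap, ...) draws from its own substream
#' so that, e.g., changing the number of bootstrap replicates does not
#' perturb the simulated data.  The derived seed stays below 2^31.
#'
#' @param seed integer master seed.
#' @param label stage name.
#' @return integer seed.
#' @export
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Folded minor-allele count from an unfolded count
#' @keywords internal
fold_count <- function(i, n) pmin(i, n - i)

#' Harmonic number a_n = sum_{i=1}^{n-1} 1/i used by Watterson's estimator
#' @keywords internal
watterson_a <- function(n) {
  vapply(n, function(nn) if (nn < 2) NA_real_ else sum(1 / seq_len(nn - 1L)),
         numeric(1))
}

DNA_BASES <- c("A", "C", "G", "T")
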