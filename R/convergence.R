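#' Geweke convergence diagnostic
#'
#' Compares the mean of the first 10% of a chain with the mean of the last
#' 50% using a two-sample z statistic. The variance of each window mean is
#' adjusted for autocorrelation by inflating the sample variance with the
#' window's `n / ESS` ratio (a spectral-density estimate at frequency zero by
#' way of the ESS, rather than a windowed periodogram). For a stationary
#' chain the statistic is asymptotically standard normal, so `|z| > 1.96`
#' flags non-stationarity at the 5% level.
#'
#' @param x Numeric vector of at least 100 samples; `NA`s removed first.
#' @return The z statistic. If both windows have zero variance the numerator
#'   and denominator both vanish and 0 is returned.
#' @export
geweke_z <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 100L) stop("geweke_z requires at least 100 samples")
  a <- x[seq_len(max(2L, floor(0.1 * n)))]
  b <- x[seq.int(n - floor(0.5 * n) + 1L, n)]
  va <- window_mean_var(a)
  vb <- window_mean_var(b)
  num <- mean(a) - mean(b)
  den <- sqrt(va + vb)
  if (den == 0) return(0)
  num / den
}

# Autocorrelation-adjusted variance of a window mean: (s^2 * n/ESS) / n.
window_mean_var <- function(w) {
  s2 <- var(w)
  if (s2 == 0) return(0)
  e <- if (length(w) >= 10L) ess(w) else length(w)
  s2 / e
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the PSRF from two or more length-matched chains:
#' `sqrt(((n - 1)/n * W + B/n) / W)` where `W` is the mean within-chain
#' variance and `B/n` the variance of the chain means. Values near 1 indicate
#' that between-chain and within-chain variability agree; values above about
#' 1.1 are commonly read as non-convergence. Given a single numeric vector,
#' it is split into first and second halves as two pseudo-chains (a standard
#' trick for applying a multi-chain diagnostic to one trace; documented
#' choice).
#'
#' @param chains A list of two or more equal-length numeric vectors, or a
#'   single numeric vector (half-split).
#' @return The PSRF. Degenerate cases: all chains constant and identical
#'   means gives 1 by convention; zero within-chain variance but distinct
#'   means gives `Inf`.
#' @export
gelman_rubin <- function(chains) {
  if (is.numeric(chains)) {
    n <- length(chains)
    half <- n %/% 2L
    chains <- list(chains[seq_len(half)], chains[seq.int(half + 1L, 2L * half)])
  }
  stopifnot(is.list(chains), length(chains) >= 2L)
  lens <- lengths(chains)
  if (length(unique(lens)) != 1L) stop("chains must have a common length")
  n <- lens[1L]
  if (n < 10L) stop("gelman_rubin requires chains of length >= 10")
  W <- mean(vapply(chains, var, numeric(1L)))
  B_over_n <- var(vapply(chains, mean, numeric(1L)))
  if (W == 0) {
    return(if (B_over_n == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

burnin_grid <- function(n, grid_step, max_frac) {
  unique(as.integer(floor(seq(0, max_frac, by = grid_step) * n)))
}

#' ESS-maximizing burn-in estimate
#'
#' Evaluates candidate burn-ins on a grid of fractions of the chain length
#' and returns the one whose post-burn-in ESS is largest (ties broken toward
#' the smaller burn-in). The rationale: discarding a non-stationary prefix
#' removes the long-range trend that inflates autocorrelation, so the ESS of
#' the remainder jumps up; for an already-stationary chain no candidate
#' systematically dominates and the smallest wins. The search is fully
#' deterministic given the series.
#'
#' @param x Numeric vector of at least 200 samples.
#' @param grid_step Grid resolution as a fraction of `n` (default 0.01).
#' @param max_frac Largest burn-in fraction considered (default 0.5).
#' @return The burn-in as a sample count (0-based; samples `[0, burnin)` are
#'   discarded).
#' @export
estimate_burnin_ess <- function(x, grid_step = 0.01, max_frac = 0.5) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 200L) stop("estimate_burnin_ess requires at least 200 samples")
  bs <- burnin_grid(n, grid_step, max_frac)
  bs <- bs[n - bs >= 10L]
  esses <- vapply(bs, function(b) ess(x[seq.int(b + 1L, n)]), numeric(1L))
  bs[which.max(esses)]
}

#' Geweke-based burn-in estimate
#'
#' Walks the same burn-in grid as [estimate_burnin_ess()] and returns the
#' smallest burn-in at which the Geweke statistic of the remaining chain
#' drops below 1.96 in absolute value. If no candidate passes, the maximal
#' grid burn-in is returned and the result flagged as non-converged.
#'
#' @inheritParams estimate_burnin_ess
#' @return A list with `burnin` (sample count), `z` (the Geweke statistic at
#'   that burn-in) and `converged` (whether any candidate passed).
#' @export
estimate_burnin_geweke <- function(x, grid_step = 0.01, max_frac = 0.5) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 200L) stop("estimate_burnin_geweke requires at least 200 samples")
  bs <- burnin_grid(n, grid_step, max_frac)
  bs <- bs[n - bs >= 100L]
  for (b in bs) {
    z <- geweke_z(x[seq.int(b + 1L, n)])
    if (abs(z) < 1.96) {
      return(list(burnin = b, z = z, converged = TRUE))
    }
  }
  b <- as.integer(floor(max_frac * n))
  list(burnin = b, z = geweke_z(x[seq.int(b + 1L, n)]), converged = FALSE)
}

#' Per-parameter convergence verdict
#'
#' Runs the full diagnostic battery on one numeric parameter trace: both
#' burn-in estimators, the Geweke statistic and the half-split Gelman-Rubin
#' PSRF on the post-burn-in chain, and the post-burn-in ESS. The suggested
#' burn-in is the maximum of the individual estimates (conservative), and the
#' chain is declared converged when all three criteria hold at that burn-in:
#' `|z| < 1.96`, `PSRF < 1.1` and `ESS >= ess_min`.
#'
#' The default `ess_min = 200` mirrors the heuristic popularised by Tracer;
#' note that this floor has no theoretical justification -- 200 effective
#' samples correspond to a computational uncertainty of roughly 28% of the
#' posterior standard deviation (see [ess_uncertainty()]) -- so stricter
#' values are often appropriate and all components are reported so callers
#' can apply their own rule.
#'
#' @param x Numeric vector of at least 200 samples.
#' @param ess_min Minimum post-burn-in ESS required for convergence.
#' @param grid_step Burn-in grid resolution (fraction of `n`).
#' @param name Optional parameter name carried into the report.
#' @return An `mcmc_diagnostics` list: `parameter`, `geweke_z`, `psrf`,
#'   `burnin_geweke`, `burnin_ess`, `burnin_suggested`, `ess_at_suggested`,
#'   `converged`, `thresholds`.
#' @export
diagnose_series <- function(x, ess_min = 200, grid_step = 0.01,
                            name = "parameter") {
  x <- x[!is.na(x)]
  n <- length(x)
  gw <- estimate_burnin_geweke(x, grid_step = grid_step)
  be <- estimate_burnin_ess(x, grid_step = grid_step)
  b <- max(gw$burnin, be)
  post <- x[seq.int(b + 1L, n)]
  z <- geweke_z(post)
  psrf <- gelman_rubin(post)
  e <- ess(post)
  structure(list(parameter = name,
                 geweke_z = z,
                 psrf = psrf,
                 burnin_geweke = gw$burnin,
                 burnin_ess = be,
                 burnin_suggested = b,
                 ess_at_suggested = e,
                 converged = gw$converged && abs(z) < 1.96 &&
                   psrf < 1.1 && e >= ess_min,
                 thresholds = list(z_crit = 1.96, psrf_max = 1.1,
                                   ess_min = ess_min)),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat(sprintf("Convergence diagnostics for '%s'\n", x$parameter))
  cat(sprintf("  suggested burn-in: %d (Geweke %d, ESS-based %d)\n",
              x$burnin_suggested, x$burnin_geweke, x$burnin_ess))
  cat(sprintf("  Geweke z %.3f (|z| < %.2f)  PSRF %.4f (< %.2f)  ESS %.1f (>= %d)\n",
              x$geweke_z, x$thresholds$z_crit, x$psrf, x$thresholds$psrf_max,
              x$ess_at_suggested, x$thresholds$ess_min))
  cat(sprintf("  verdict: %s\n",
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
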