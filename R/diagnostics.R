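#' Gelman-Rubin potential scale reduction factor
#'
#' The original (non-split) PSRF: with m chains of length n, between-chain
#' variance `B = n * var(chain means)` and mean within-chain variance `W`,
#' the statistic is `sqrt((n-1)/n + B/(n*W))`. A split variant (each chain
#' halved before the computation) is available behind `split`.
#'
#' @param chains list of >= 2 equal-length numeric vectors (one per chain).
#' @param split halve each chain first (split-Rhat)? Default FALSE.
#' @return the PSRF; `Inf` when the chains are internally constant but
#'   disagree, 1 when all draws are identical.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need >= 2 chains", call. = FALSE)
  }
  if (split) {
    chains <- unlist(lapply(chains, function(x) {
      h <- floor(length(x) / 2)
      list(x[seq_len(h)], x[h + seq_len(h)])
    }), recursive = FALSE)
  }
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length", call. = FALSE)
  if (n < 4L) stop("chains must have length >= 4", call. = FALSE)
  means <- vapply(chains, mean, numeric(1L))
  W <- mean(vapply(chains, var, numeric(1L)))
  B <- n * var(means)
  if (W == 0) {
    return(if (B == 0) 1 else Inf)
  }
  sqrt((n - 1) / n + B / (n * W))
}

#' Effective sample size of one chain
#'
#' `ESS = n / tau` with the integrated autocorrelation time `tau`
#' estimated by Geyer's initial-positive-sequence rule: consecutive
#' autocorrelation pairs are accumulated until the first non-positive
#' pair sum. A constant chain reports `ESS = n` with a `zero_variance`
#' flag; an antithetic chain (negative lag-1 autocorrelation) may report
#' `ESS > n` and carries an `antithetic` flag.
#'
#' @param draws numeric vector, length >= 10.
#' @param lag_max maximum lag examined (default `min(n - 1, 1000)`).
#' @return the ESS, with logical attributes `zero_variance` and
#'   `antithetic`.
#' @export
effective_sample_size <- function(draws, lag_max = NULL) {
  n <- length(draws)
  if (n < 10L) stop("need >= 10 draws", call. = FALSE)
  if (var(draws) == 0) {
    return(structure(as.numeric(n), zero_variance = TRUE, antithetic = FALSE))
  }
  lag_max <- lag_max %||% min(n - 1L, 1000L)
  rho <- drop(stats::acf(draws, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)[-1L]
  # pair sums P_0 = 1 + rho_1, P_k = rho_2k + rho_2k+1; accumulate while
  # positive (always admitting P_0)
  tau <- -1 + 2 * (1 + rho[1L])
  k <- 2L
  while (k + 1L <= length(rho)) {
    P <- rho[k] + rho[k + 1L]
    if (P <= 0) break
    tau <- tau + 2 * P
    k <- k + 2L
  }
  tau <- max(tau, 2 / n)   # keep ESS finite for strongly antithetic chains
  structure(n / tau, zero_variance = FALSE, antithetic = rho[1L] < 0)
}

#' Convergence diagnostics for a fitted model
#'
#' Computes, for every labelled parameter, the Gelman-Rubin PSRF across
#' chains (on the retained, pre-thinning draws) and the effective sample
#' size per chain and combined (summed over chains). Convergence is
#' declared when every PSRF is at or below `threshold`; `psrf_rounded`
#' reports the statistic at one decimal.
#'
#' @param samples an `mwm_samples` from [run_chains()].
#' @param threshold PSRF cutoff (default 1.1).
#' @return data.frame of class `mwm_diagnostics` with columns `parameter`,
#'   `psrf`, `psrf_rounded`, `ess_mean_chain`, `ess_combined`, `flagged`;
#'   attribute `converged`.
#' @export
diagnose <- function(samples, threshold = 1.1) {
  stopifnot(inherits(samples, "mwm_samples"))
  if (length(samples$chains) < 2L) {
    stop("need >= 2 chains for convergence diagnostics", call. = FALSE)
  }
  pars <- samples$par_labels
  psrf <- ess_chain <- ess_comb <- numeric(length(pars))
  for (j in seq_along(pars)) {
    cols <- lapply(samples$chains, function(m) m[, j])
    psrf[j] <- gelman_rubin(cols)
    ess <- vapply(cols, function(x) as.numeric(effective_sample_size(x)),
                  numeric(1L))
    ess_chain[j] <- mean(ess)
    ess_comb[j] <- sum(ess)
  }
  out <- data.frame(parameter = pars,
                    psrf = psrf,
                    psrf_rounded = round(psrf, 1L),
                    ess_mean_chain = ess_chain,
                    ess_combined = ess_comb,
                    flagged = psrf > threshold)
  attr(out, "converged") <- !any(out$flagged)
  attr(out, "threshold") <- threshold
  class(out) <- c("mwm_diagnostics", "data.frame")
  out
}

#' @export
print.mwm_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics:", nrow(x), "parameters; max PSRF =",
      signif(max(x$psrf), 4), "| converged:", attr(x, "converged"), "\n")
  if (any(x$flagged)) {
    cat("  flagged (PSRF >", attr(x, "threshold"), "):",
        paste(x$parameter[x$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}
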