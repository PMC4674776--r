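#' Sampler configuration
#'
#' Defaults mirror the fitting protocol used throughout: three chains
#' started from overdispersed initial values, 2,500 burn-in sweeps, 2,500
#' retained sweeps per chain, and the combined 7,500 draws thinned to
#' 5,000 for inference.
#'
#' @param n_chains number of chains (default 3).
#' @param burn_in burn-in sweeps per chain (default 2500).
#' @param draws_per_chain retained sweeps per chain (default 2500).
#' @param thin_target combined retained draw count after thinning
#'   (default 5000); if the combined draws do not exceed it, no thinning.
#' @param seed base seed; each chain derives its own deterministic stream.
#' @param overdispersion multiplicative jitter factors applied to the
#'   least-squares initial values, recycled over chains (default 0.5, 1, 2).
#' @param store_ranef keep per-mouse random-effect draws (default FALSE).
#' @param debug assert the censoring invariant after every sweep.
#' @return object of class `mwm_sampler_config`.
#' @export
sampler_config <- function(n_chains = 3L, burn_in = 2500L,
                           draws_per_chain = 2500L, thin_target = 5000L,
                           seed = 1L, overdispersion = c(0.5, 1, 2),
                           store_ranef = FALSE, debug = FALSE) {
  stopifnot(n_chains >= 1L, burn_in >= 1L, draws_per_chain >= 1L,
            thin_target >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 draws_per_chain = as.integer(draws_per_chain),
                 thin_target = as.integer(thin_target),
                 seed = as.integer(seed),
                 overdispersion = overdispersion,
                 store_ranef = isTRUE(store_ranef),
                 debug = isTRUE(debug)),
            class = "mwm_sampler_config")
}

chain_seed <- function(base_seed, chain) {
  as.integer((as.numeric(base_seed) + 104729 * (chain - 1)) %%
               (.Machine$integer.max - 1)) + 1L
}

# Cross-products reused every sweep: X'X and its Cholesky factor, row
# indices per mouse, Z_i'Z_i per mouse, and a fast path for balanced
# cohorts where every mouse shares the same Z block.
prepare_design <- function(design) {
  if (!is.null(design$cache)) return(design)
  X <- design$X
  XtX <- crossprod(X)
  cholXtX <- tryCatch(chol(XtX), error = function(e)
    stop("design matrix is rank deficient; inspect the design ",
         "(collinear columns or empty groups)", call. = FALSE))
  rows <- split(seq_along(design$y), design$mouse)
  ZtZ <- lapply(rows, function(r) crossprod(design$Zrow[r, , drop = FALSE]))
  npm <- lengths(rows)
  balanced <- length(unique(npm)) == 1L &&
    all(vapply(ZtZ, function(m) isTRUE(all.equal(m, ZtZ[[1L]])),
               logical(1L)))
  cache <- list(XtX = XtX, cholXtX = cholXtX, rows = rows, ZtZ = ZtZ,
                balanced = balanced,
                row_mat = if (balanced) matrix(unlist(rows), ncol = length(rows))
                          else NULL,
                Zt = if (balanced) t(design$Zrow[rows[[1L]], , drop = FALSE])
                     else NULL)
  design$cache <- cache
  design
}

ranef_contribution <- function(state, design) {
  rowSums(design$Zrow * state$u[as.integer(design$mouse), , drop = FALSE])
}

#' Initialize one chain
#'
#' Fixed effects start at the least-squares solution (censored rows taken
#' at the cutoff) scaled by a chain-indexed overdispersion factor; random
#' effects start at zero; standard deviations start at residual-scale
#' heuristics scaled by the same factor; latent responses start at the
#' observed latency (uncensored) or one second above the cutoff (censored).
#'
#' @param design an `mwm_design`.
#' @param config an [sampler_config()].
#' @param chain 1-based chain index.
#' @return object of class `mwm_chain_state`: list with `beta`, `u`
#'   (mice x (1+df) matrix), `ystar`, `sds` (random-effect s.d.s,
#'   intercept first), `sd_resid`.
#' @export
init_chain <- function(design, config, chain = 1L) {
  design <- prepare_design(design)
  f <- rep_len(config$overdispersion, config$n_chains)[chain]
  beta_ls <- qr.coef(qr(design$X), design$y)
  if (anyNA(beta_ls)) {
    stop("design matrix is rank deficient; inspect the design ",
         "(collinear columns or empty groups)", call. = FALSE)
  }
  resid <- design$y - drop(design$X %*% beta_ls)
  s <- max(sd(resid), 1e-3)
  M <- nlevels(design$mouse)
  q <- ncol(design$Zrow)
  ystar <- design$y
  ystar[design$censored] <- design$censor_limit + 1
  structure(list(beta = beta_ls * f,
                 u = matrix(0, M, q,
                            dimnames = list(levels(design$mouse), NULL)),
                 ystar = ystar,
                 sds = rep(s / 2, q) * f,
                 sd_resid = s * f,
                 chain = chain),
            class = "mwm_chain_state")
}

#' Latent-response update (censoring augmentation)
#'
#' For every censored observation the latent uncensored latency is redrawn
#' from its full conditional: a normal with mean equal to the current
#' fitted value and s.d. equal to the residual s.d., truncated to lie at or
#' above the censor limit. Uncensored responses are untouched.
#'
#' @param state an `mwm_chain_state`.
#' @param design an `mwm_design`.
#' @return the updated state.
#' @export
update_latent <- function(state, design) {
  cens <- design$censored
  if (!any(cens)) return(state)
  mu <- drop(design$X %*% state$beta) + ranef_contribution(state, design)
  state$ystar[cens] <- rtnorm_lower(sum(cens), mu[cens], state$sd_resid,
                                    design$censor_limit)
  state
}

#' Fixed-effect block update
#'
#' With flat priors the full conditional of the fixed effects given the
#' latent responses minus the random-effect contribution is multivariate
#' normal with mean the least-squares solution and covariance
#' `sd_resid^2 (X'X)^-1`.
#'
#' @inheritParams update_latent
#' @return the updated state.
#' @export
update_fixed_effects <- function(state, design) {
  design <- prepare_design(design)
  r <- state$ystar - ranef_contribution(state, design)
  R <- design$cache$cholXtX
  mean_beta <- backsolve(R, forwardsolve(R, crossprod(design$X, r),
                                         upper.tri = TRUE, transpose = TRUE))
  state$beta <- drop(mean_beta) + state$sd_resid *
    backsolve(R, rnorm(length(state$beta)))
  names(state$beta) <- design$labels
  state
}

#' Random-effect block update
#'
#' Per mouse, the (1+df)-vector of random intercept and spline deviations
#' is redrawn jointly from its multivariate-normal full conditional; mice
#' are conditionally independent. On balanced cohorts (all mice share one
#' Z block) the update is vectorized across mice and consumes the same
#' normal deviates in the same order as the per-mouse loop.
#'
#' @inheritParams update_latent
#' @return the updated state.
#' @export
update_random_effects <- function(state, design) {
  design <- prepare_design(design)
  cache <- design$cache
  q <- ncol(design$Zrow)
  resid <- state$ystar - drop(design$X %*% state$beta)
  Dinv <- diag(1 / pmax(state$sds, 1e-12)^2, q)
  s2 <- state$sd_resid^2
  M <- nrow(state$u)
  if (cache$balanced) {
    A <- cache$ZtZ[[1L]] / s2 + Dinv
    Ra <- chol(A)
    Rmat <- matrix(resid[cache$row_mat], nrow = nrow(cache$row_mat))
    b <- (cache$Zt %*% Rmat) / s2
    mean_u <- backsolve(Ra, forwardsolve(Ra, b, upper.tri = TRUE,
                                         transpose = TRUE))
    draw <- mean_u + backsolve(Ra, matrix(rnorm(q * M), q, M))
    state$u <- t(draw)
    rownames(state$u) <- levels(design$mouse)
  } else {
    for (i in seq_len(M)) {
      ri <- cache$rows[[i]]
      A <- cache$ZtZ[[i]] / s2 + Dinv
      Ra <- chol(A)
      b <- crossprod(design$Zrow[ri, , drop = FALSE], resid[ri]) / s2
      mean_u <- backsolve(Ra, forwardsolve(Ra, b, upper.tri = TRUE,
                                           transpose = TRUE))
      state$u[i, ] <- drop(mean_u) + backsolve(Ra, rnorm(q))
    }
  }
  state
}

#' Variance-component update
#'
#' A flat prior on a standard deviation implies an inverse-gamma full
#' conditional for the variance: shape `(M - 1)/2` and rate `S/2`, where
#' `M` is the number of mice and `S` the sum of squared effects. Each of
#' the four random-effect s.d.s is updated from its own conditional; the
#' residual s.d. is updated analogously from all residuals (flat-on-s.d.
#' default, vague inverse-gamma IG(0.001, 0.001) alternative). Sums of
#' squares are floored at 1e-12 to survive all-zero states early in
#' burn-in.
#'
#' @inheritParams update_latent
#' @return the updated state.
#' @export
update_variance_components <- function(state, design) {
  M <- nrow(state$u)
  if (M < 3L) {
    stop("refusing the variance-component update with fewer than 3 mice: ",
         "the flat prior on the s.d. scale risks an improper posterior",
         call. = FALSE)
  }
  for (k in seq_along(state$sds)) {
    S <- max(sum(state$u[, k]^2), 1e-12)
    state$sds[k] <- sqrt(rinvgamma1((M - 1) / 2, S / 2))
  }
  resid <- state$ystar - drop(design$X %*% state$beta) -
    ranef_contribution(state, design)
  n <- length(resid)
  S <- max(sum(resid^2), 1e-12)
  if (design$spec$residual_prior == "inv_gamma") {
    state$sd_resid <- sqrt(rinvgamma1(n / 2 + 0.001, S / 2 + 0.001))
  } else {
    state$sd_resid <- sqrt(rinvgamma1((n - 1) / 2, S / 2))
  }
  state
}

# Interweaving (non-centered) rescale of each random-effect family:
# substituting u_k = sigma_k * w_k makes sigma_k a regression coefficient
# with a Gaussian full conditional (flat prior on (0, Inf) -> truncated
# normal). Sampling it there and mapping back is a valid extra Gibbs step
# that leaves the posterior invariant while breaking the slow mixing of
# variance components near zero under the centered updates.
interweave_scales <- function(state, design) {
  midx <- as.integer(design$mouse)
  r_base <- state$ystar - drop(design$X %*% state$beta) -
    ranef_contribution(state, design)
  s2 <- state$sd_resid^2
  for (k in seq_along(state$sds)) {
    sk <- state$sds[k]
    if (sk < 1e-10) next
    w <- state$u[, k] / sk
    zcol <- design$Zrow[, k] * w[midx]
    d <- sum(zcol^2) / s2
    if (d < 1e-12) next
    rk <- r_base + sk * zcol
    m <- sum(zcol * rk) / s2 / d
    sk_new <- rtnorm_lower(1L, m, 1 / sqrt(d), 0)
    state$u[, k] <- sk_new * w
    state$sds[k] <- sk_new
    r_base <- rk - sk_new * zcol
  }
  state
}

one_sweep <- function(state, design) {
  state <- update_latent(state, design)
  state <- update_fixed_effects(state, design)
  state <- update_random_effects(state, design)
  state <- update_variance_components(state, design)
  interweave_scales(state, design)
}

#' Deterministic thinning indices
#'
#' Reduces `n_combined` chained draws to `target` by keeping evenly spaced
#' indices (`round(seq(1, n_combined, length.out = target))`); for the
#' default 7,500 to 5,000 reduction this keeps indices not divisible by 3,
#' i.e. drops every third draw of the chain-concatenated sequence.
#'
#' @param n_combined combined draw count across chains.
#' @param target retained count.
#' @return integer vector of kept indices.
#' @export
thin_indices <- function(n_combined, target) {
  if (n_combined <= target) return(seq_len(n_combined))
  idx <- unique(round(seq(1, n_combined, length.out = target)))
  while (length(idx) < target) {   # fill rounding collisions, if any
    gaps <- setdiff(seq_len(n_combined), idx)
    idx <- sort(c(idx, gaps[seq_len(target - length(idx))]))
  }
  as.integer(idx)
}

#' Run the blocked Gibbs sampler
#'
#' Each sweep updates, in order: latent censored responses, fixed effects,
#' per-mouse random effects, variance components. Chains are independent
#' and own deterministic RNG streams derived from the base seed, so runs
#' are fully reproducible.
#'
#' @param design an `mwm_design`.
#' @param config an [sampler_config()].
#' @return object of class `mwm_samples`: per-chain draw matrices
#'   (`chains`, rows = retained sweeps, columns = labelled parameters),
#'   the thinned combined draw matrix (`draws`) with `chain_id` and
#'   `iteration` vectors, plus labels, config, basis and design metadata.
#' @export
run_chains <- function(design, config = sampler_config()) {
  stopifnot(inherits(design, "mwm_design"),
            inherits(config, "mwm_sampler_config"))
  if (nlevels(design$mouse) < 3L) {
    stop("refusing to sample with fewer than 3 mice: the flat prior on ",
         "the s.d. scale risks an improper posterior", call. = FALSE)
  }
  design <- prepare_design(design)
  p <- length(design$labels)
  q <- ncol(design$Zrow)
  par_labels <- c(design$labels, "sd_intercept",
                  paste0("sd_spline", seq_len(q - 1L)), "sd_residual")
  chains <- vector("list", config$n_chains)
  ranef <- if (config$store_ranef) vector("list", config$n_chains) else NULL
  seeds <- integer(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    seeds[ch] <- chain_seed(config$seed, ch)
    set.seed(seeds[ch])
    state <- init_chain(design, config, ch)
    total <- config$burn_in + config$draws_per_chain
    draws <- matrix(NA_real_, config$draws_per_chain, p + q + 1L,
                    dimnames = list(NULL, par_labels))
    udraws <- if (config$store_ranef)
      array(NA_real_, c(config$draws_per_chain, dim(state$u))) else NULL
    for (sweep in seq_len(total)) {
      state <- one_sweep(state, design)
      if (!all(is.finite(state$beta)) || !all(is.finite(state$sds)) ||
          !is.finite(state$sd_resid)) {
        stop("non-finite sampler state in chain ", ch, " at sweep ", sweep,
             call. = FALSE)
      }
      if (config$debug) {
        stopifnot(all(state$ystar[design$censored] >= design$censor_limit),
                  all(state$ystar[!design$censored] ==
                        design$y[!design$censored]))
      }
      if (sweep > config$burn_in) {
        i <- sweep - config$burn_in
        draws[i, ] <- c(state$beta, state$sds, state$sd_resid)
        if (config$store_ranef) udraws[i, , ] <- state$u
      }
    }
    chains[[ch]] <- draws
    if (config$store_ranef) ranef[[ch]] <- udraws
  }
  combined <- do.call(rbind, chains)
  chain_id <- rep(seq_len(config$n_chains), each = config$draws_per_chain)
  iteration <- rep(seq_len(config$draws_per_chain), config$n_chains)
  keep <- thin_indices(nrow(combined), config$thin_target)
  structure(list(chains = chains,
                 draws = combined[keep, , drop = FALSE],
                 chain_id = chain_id[keep],
                 iteration = iteration[keep],
                 labels = design$labels,
                 par_labels = par_labels,
                 config = config,
                 seeds = seeds,
                 basis = design$basis,
                 spec = design$spec,
                 groups = design$groups,
                 group_of_mouse = design$group_of_mouse,
                 n_days = design$n_days,
                 trials_per_day = design$trials_per_day,
                 censor_limit = design$censor_limit,
                 day_center = design$day_center,
                 n_obs = length(design$y),
                 ranef = ranef),
            class = "mwm_samples")
}

#' @export
print.mwm_samples <- function(x, ...) {
  cat("Posterior samples:", length(x$chains), "chain(s) x",
      nrow(x$chains[[1L]]), "retained sweeps;", nrow(x$draws),
      "draws after thinning;", length(x$par_labels), "parameters\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}
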