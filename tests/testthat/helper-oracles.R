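# Independent oracles used across the suite. Everything here is written
# against first principles (truncated power functions, grid integration,
# closed forms), never by calling the code paths under test.

# Natural cubic spline via truncated power functions with explicitly
# imposed linear-tail constraints: knots xi_1 < ... < xi_K (boundary knots
# included), basis {1, x, N_1..N_{K-2}} with
#   d_k(x) = [(x - xi_k)_+^3 - (x - xi_K)_+^3] / (xi_K - xi_k)
#   N_k(x) = d_k(x) - d_{K-1}(x)
# (the standard reduction that zeroes the quadratic/cubic tails).
tp_natural_basis <- function(x, knots) {
  K <- length(knots)
  stopifnot(K >= 3L)
  dk <- function(k, x) {
    (pmax(x - knots[k], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[k])
  }
  cols <- lapply(seq_len(K - 2L), function(k) dk(k, x) - dk(K - 1L, x))
  cbind(1, x, do.call(cbind, cols))
}

# Residual of regressing y on the columns of M (span membership check).
span_residual <- function(y, M) {
  fit <- qr(M)
  max(abs(y - M %*% qr.coef(fit, y)))
}

# Grid-integration posterior for an intercept-only censored Gaussian model
# with known sigma and a flat prior: returns normalized density on a grid.
tobit_grid_posterior <- function(y, censored, sigma, limit,
                                 grid = seq(-50, 150, length.out = 40001)) {
  nc <- sum(censored)
  loglik <- vapply(grid, function(b) {
    sum(dnorm(y[!censored], b, sigma, log = TRUE)) +
      nc * pnorm((limit - b) / sigma, lower.tail = FALSE, log.p = TRUE)
  }, numeric(1))
  w <- exp(loglik - max(loglik))
  w <- w / sum(w)
  list(grid = grid, weight = w,
       mean = sum(grid * w),
       sd = sqrt(sum(grid^2 * w) - sum(grid * w)^2),
       quantile = function(p) grid[which.min(abs(cumsum(w) - p))])
}

# Grid quantiles of the flat-prior-on-sd full conditional of a random
# effect s.d. given M effects with sum of squares S:
#   p(sigma | u) propto sigma^-M exp(-S / (2 sigma^2))
sd_conditional_grid_quantiles <- function(M, S, probs,
                                          grid = seq(1e-3, 60, length.out = 200001)) {
  logd <- -M * log(grid) - S / (2 * grid^2)
  w <- exp(logd - max(logd))
  cdf <- cumsum(w) / sum(w)
  vapply(probs, function(p) grid[which.min(abs(cdf - p))], numeric(1))
}

# Small deterministic cohort: m mice, all days/trials, latencies from a
# fixed linear curve plus tiny deterministic perturbations (no RNG).
toy_cohort <- function(m = 4L, n_days = 6L, trials_per_day = 4L,
                       start = 40, rate = 1, censor_limit = 60) {
  rec <- expand.grid(trial = seq_len(trials_per_day), day = seq_len(n_days),
                     mouse = seq_len(m))
  idx <- (rec$day - 1) * trials_per_day + (rec$trial - 1)
  lat <- start - rate * idx + 0.5 * sin(seq_len(nrow(rec)))
  lat <- pmin(pmax(lat, 1), censor_limit)
  mwm_cohort(data.frame(mouse_id = paste0("m", rec$mouse),
                        genotype = "WT", treatment = "scr",
                        day = rec$day, trial = rec$trial,
                        latency = lat, censored = lat == censor_limit),
             trials_per_day = trials_per_day, censor_limit = censor_limit)
}

# GLS posterior mean of beta for y = X beta + Z u + e with known variance
# components and flat prior on beta (marginalizing the random effects).
gls_posterior_mean <- function(X, Zrow, mouse, y, sds, sd_resid) {
  n <- length(y)
  V <- diag(sd_resid^2, n)
  D <- diag(sds^2, ncol(Zrow))
  for (ids in split(seq_len(n), mouse)) {
    Zi <- Zrow[ids, , drop = FALSE]
    V[ids, ids] <- V[ids, ids] + Zi %*% D %*% t(Zi)
  }
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}
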