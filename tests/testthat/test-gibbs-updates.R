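# Direct full-conditional checks of the individual sampler blocks against
# closed forms and grid-integration oracles.

intercept_only_design <- function(y, censored = rep(FALSE, length(y)),
                                  limit = 60, mouse = NULL) {
  # minimal hand-built design for oracle math: intercept-only fixed
  # effects, one random block per mouse (identity Zrow column structure)
  n <- length(y)
  mouse <- mouse %||% factor(rep("m1", n))
  structure(list(X = matrix(1, n, 1, dimnames = list(NULL, "mu")),
                 Zrow = matrix(1, n, 1),
                 mouse = mouse,
                 y = y, censored = censored,
                 labels = "mu",
                 censor_limit = limit,
                 spec = model_spec(df = 1),
                 n_days = 1L, trials_per_day = n,
                 day = rep(1L, n), trial = seq_len(n),
                 day_center = 0),
            class = "mwm_design")
}

blank_state <- function(design, beta = 0, sds = 1, sd_resid = 1) {
  M <- nlevels(design$mouse)
  ystar <- design$y
  ystar[design$censored] <- design$censor_limit + 1
  structure(list(beta = rep(beta, ncol(design$X)),
                 u = matrix(0, M, ncol(design$Zrow)),
                 ystar = ystar,
                 sds = rep(sds, ncol(design$Zrow)),
                 sd_resid = sd_resid),
            class = "mwm_chain_state")
}

test_that("latent update leaves uncensored data untouched and respects the bound", {
  design <- intercept_only_design(c(10, 20, 30))
  state <- blank_state(design, beta = 20, sd_resid = 5)
  set.seed(1)
  expect_identical(update_latent(state, design)$ystar, design$y)

  design2 <- intercept_only_design(c(10, 60, 60),
                                   censored = c(FALSE, TRUE, TRUE))
  state2 <- blank_state(design2, beta = 55, sd_resid = 10)
  set.seed(2)
  draws <- replicate(2000, update_latent(state2, design2)$ystar[2:3])
  expect_true(all(draws >= 60))
  expect_equal(update_latent(state2, design2)$ystar[1], 10)
})

test_that("latent update matches the closed-form truncated-normal mean", {
  # mu = 55, sd = 10, bound 60: E = mu + sd * phi(a)/(1 - Phi(a)), a = 0.5
  design <- intercept_only_design(rep(60, 1), censored = TRUE)
  state <- blank_state(design, beta = 55, sd_resid = 10)
  n <- 1e5
  set.seed(3)
  draws <- vapply(seq_len(n),
                  function(i) update_latent(state, design)$ystar[1],
                  numeric(1))
  a <- (60 - 55) / 10
  truth_mean <- 55 + 10 * dnorm(a) / pnorm(a, lower.tail = FALSE)
  truth_sd <- 10 * sqrt(1 + a * dnorm(a) / pnorm(a, lower.tail = FALSE) -
                          (dnorm(a) / pnorm(a, lower.tail = FALSE))^2)
  expect_lt(abs(mean(draws) - truth_mean), 3 * truth_sd / sqrt(n))
})

test_that("extreme-tail truncated normal sampling stays exact (rejection path)", {
  set.seed(4)
  d <- rtnorm_lower(5000, mean = 0, sd = 1, lower = 8)
  expect_true(all(d >= 8))
  # E[X | X > 8] for standard normal = phi(8)/(1-Phi(8)) ~ 8.1219
  truth <- dnorm(8) / pnorm(8, lower.tail = FALSE)
  expect_lt(abs(mean(d) - truth), 0.01)
})

test_that("fixed-effect update reproduces the conjugate posterior on {1,2,3}", {
  design <- intercept_only_design(c(1, 2, 3))
  state <- blank_state(design, sd_resid = 2)
  n <- 1e5
  set.seed(5)
  draws <- vapply(seq_len(n),
                  function(i) update_fixed_effects(state, design)$beta[1],
                  numeric(1))
  # posterior is Normal(2, sigma^2 / 3)
  expect_lt(abs(mean(draws) - 2), 3 * (2 / sqrt(3)) / sqrt(n))
  expect_lt(abs(sd(draws) - 2 / sqrt(3)), 3 * (2 / sqrt(3)) / sqrt(2 * n))
})

test_that("fixed-effect draws concentrate at least squares as sd_resid -> 0", {
  cohort <- toy_cohort(4L)
  design <- build_design(cohort, model_spec())
  state <- init_chain(design, sampler_config(seed = 1), 1)
  state$beta <- qr.coef(qr(design$X), design$y)
  state$u[] <- 0
  state$sd_resid <- 1e-8
  set.seed(6)
  out <- update_fixed_effects(state, design)
  expect_equal(unname(out$beta), unname(qr.coef(qr(design$X), design$y)),
               tolerance = 1e-5)
})

test_that("two-parameter Gibbs posterior mean matches grid integration", {
  # intercept + slope on a 5-row fixture, known sigma, flat priors:
  # posterior is exactly N(beta_ls, sigma^2 (X'X)^-1); check the update's
  # empirical mean against a dense 2-D grid integration of the likelihood
  X <- cbind(1, c(-2, -1, 0, 1, 2))
  y <- c(5.1, 4.0, 3.2, 2.1, 1.3)
  sigma <- 0.5
  design <- intercept_only_design(y)
  design$X <- X
  design$labels <- c("b0", "b1")
  state <- blank_state(design, sd_resid = sigma)
  state$beta <- c(0, 0)
  g0 <- seq(2, 4, length.out = 401)
  g1 <- seq(-2, 0, length.out = 401)
  ll <- outer(g0, g1, function(a, b) {
    vapply(seq_along(a), function(i)
      sum(dnorm(y, a[i] + b[i] * X[, 2], sigma, log = TRUE)), numeric(1))
  })
  w <- exp(ll - max(ll)); w <- w / sum(w)
  grid_mean <- c(sum(rowSums(w) * g0), sum(colSums(w) * g1))
  n <- 2e4
  set.seed(7)
  draws <- t(vapply(seq_len(n),
                    function(i) update_fixed_effects(state, design)$beta,
                    numeric(2)))
  expect_lt(max(abs(colMeans(draws) - grid_mean)), 0.01)
})

test_that("random-effect update matches the 1-D shrinkage formula", {
  # single mouse, intercept-only random structure: full conditional is
  # N(b / (n/s2 + 1/tau2), 1 / (n/s2 + 1/tau2)) with b = sum(resid)/s2
  y <- c(3, 5, 4)
  design <- intercept_only_design(y)
  state <- blank_state(design, beta = 2, sds = 1.5, sd_resid = 2)
  prec <- length(y) / 4 + 1 / 1.5^2
  mu_true <- sum(y - 2) / 4 / prec
  sd_true <- 1 / sqrt(prec)
  n <- 1e5
  set.seed(8)
  draws <- vapply(seq_len(n),
                  function(i) update_random_effects(state, design)$u[1, 1],
                  numeric(1))
  expect_lt(abs(mean(draws) - mu_true), 3 * sd_true / sqrt(n))
  expect_lt(abs(sd(draws) - sd_true), 3 * sd_true / sqrt(2 * n))
})

test_that("random effects shrink to zero as their prior s.d.s -> 0", {
  cohort <- toy_cohort(4L)
  design <- build_design(cohort, model_spec())
  state <- init_chain(design, sampler_config(seed = 1), 1)
  state$sds <- rep(1e-8, 4)
  set.seed(9)
  out <- update_random_effects(state, design)
  expect_lt(max(abs(out$u)), 1e-5)
})

test_that("balanced vectorized and per-mouse random-effect paths are bit-identical", {
  cohort <- toy_cohort(5L)
  design <- build_design(cohort, model_spec())
  design <- mwmbayes:::prepare_design(design)
  expect_true(design$cache$balanced)
  state <- init_chain(design, sampler_config(seed = 1), 1)
  state$sd_resid <- 8
  set.seed(10)
  fast <- update_random_effects(state, design)
  design_loop <- design
  design_loop$cache$balanced <- FALSE
  set.seed(10)
  slow <- update_random_effects(state, design_loop)
  # identical normal deviates in identical order; only BLAS rounding differs
  expect_equal(unname(fast$u), unname(slow$u), tolerance = 1e-12)
})

test_that("variance update matches the grid of the flat-on-sd conditional", {
  # u = (1, -1, 2, 0): M = 4 mice, S = 6
  design <- intercept_only_design(rep(10, 8),
                                  mouse = factor(rep(paste0("m", 1:4), 2)))
  state <- blank_state(design, beta = 10, sd_resid = 1)
  state$u[, 1] <- c(1, -1, 2, 0)
  n <- 2e5
  set.seed(11)
  draws <- vapply(seq_len(n),
                  function(i) update_variance_components(state, design)$sds[1],
                  numeric(1))
  probs <- seq(0.1, 0.9, by = 0.1)
  grid_q <- sd_conditional_grid_quantiles(M = 4, S = 6, probs)
  emp_q <- unname(quantile(draws, probs))
  expect_lt(max(abs(emp_q / grid_q - 1)), 0.01 + 3 / sqrt(n))
})

test_that("variance update survives all-zero effects via the positive floor", {
  design <- intercept_only_design(rep(10, 8),
                                  mouse = factor(rep(paste0("m", 1:4), 2)))
  state <- blank_state(design, beta = 10, sd_resid = 1)
  set.seed(12)
  out <- update_variance_components(state, design)
  expect_true(all(out$sds > 0) && all(is.finite(out$sds)))
})

test_that("doubling the effects doubles the conditional median s.d. (scale equivariance)", {
  design <- intercept_only_design(rep(10, 8),
                                  mouse = factor(rep(paste0("m", 1:4), 2)))
  state1 <- blank_state(design, beta = 10, sd_resid = 1)
  state1$u[, 1] <- c(1, -1, 2, 0)
  state2 <- state1
  state2$u[, 1] <- 2 * state1$u[, 1]
  n <- 4e4
  set.seed(13)
  m1 <- median(vapply(seq_len(n), function(i)
    update_variance_components(state1, design)$sds[1], numeric(1)))
  set.seed(13)
  m2 <- median(vapply(seq_len(n), function(i)
    update_variance_components(state2, design)$sds[1], numeric(1)))
  expect_equal(m2 / m1, 2, tolerance = 0.03)
})

test_that("the variance update refuses fewer than 3 mice", {
  design <- intercept_only_design(c(10, 12),
                                  mouse = factor(c("m1", "m2")))
  state <- blank_state(design, beta = 10)
  expect_error(update_variance_components(state, design), "improper")
})

test_that("permuting mouse order leaves each mouse's conditional unchanged", {
  y <- c(3, 5, 4, 6, 2, 7)
  mouse1 <- factor(rep(c("a", "b", "c"), each = 2), levels = c("a", "b", "c"))
  mouse2 <- factor(mouse1, levels = c("c", "a", "b"))
  d1 <- intercept_only_design(y, mouse = mouse1)
  d2 <- intercept_only_design(y, mouse = mouse2)
  state1 <- blank_state(d1, beta = 4, sds = 2, sd_resid = 1)
  state2 <- blank_state(d2, beta = 4, sds = 2, sd_resid = 1)
  n <- 4e4
  set.seed(14)
  u1 <- vapply(seq_len(n), function(i)
    update_random_effects(state1, d1)$u[1, 1], numeric(1))  # mouse "a"
  set.seed(15)
  u2 <- vapply(seq_len(n), function(i)
    update_random_effects(state2, d2)$u[2, 1], numeric(1))  # mouse "a"
  expect_lt(abs(mean(u1) - mean(u2)), 4 * sd(u1) / sqrt(n))
  expect_lt(abs(sd(u1) - sd(u2)), 4 * sd(u1) / sqrt(2 * n))
})
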