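# A hand-made mwm_samples object with controlled draws, for exact
# arithmetic checks of the curve and rate computations.
fake_samples <- function(beta_draws, groups = "WT:scr", n_days = 6L,
                         trials_per_day = 4L, df = 3L) {
  basis <- build_basis(seq_len(n_days), df = df)
  spec <- model_spec(df = df, trials_per_day = trials_per_day)
  labels <- mwmbayes:::fixed_labels(groups, spec)
  colnames(beta_draws) <- labels
  structure(list(draws = beta_draws, labels = labels,
                 par_labels = c(labels, "sd_intercept",
                                paste0("sd_spline", seq_len(df)),
                                "sd_residual"),
                 basis = basis, spec = spec, groups = groups,
                 n_days = n_days, trials_per_day = trials_per_day,
                 day_center = 0,
                 chains = list(beta_draws), chain_id = rep(1L, nrow(beta_draws)),
                 iteration = seq_len(nrow(beta_draws))),
            class = "mwm_samples")
}

test_that("curve grid covers all cells and reduces to the spline when dummies are off", {
  beta <- matrix(0, 200, 10)
  beta[, 1] <- 30                       # intercept only
  s <- fake_samples(beta)
  cd <- fitted_curve_draws(s, "WT:scr")
  expect_equal(ncol(cd), 6L * 4L)
  expect_true(all(cd == 30))
  expect_error(fitted_curve_draws(s, "nope"), "available")

  # non-zero spline, zero dummies: within-day cells share the day value
  beta2 <- matrix(0, 200, 10)
  beta2[, 1] <- 40; beta2[, 2] <- 2; beta2[, 3] <- -1; beta2[, 4] <- 0.5
  s2 <- fake_samples(beta2)
  cd2 <- fitted_curve_draws(s2, "WT:scr")
  grid <- attr(cd2, "grid")
  for (d in 1:6) {
    cells <- which(grid$day == d)
    expect_true(all(apply(cd2[1:5, cells], 1, function(r) diff(range(r)) == 0)))
  }
})

test_that("a single hand-set draw matches hand computation on a 2-day spec", {
  # day covariate with df=1 keeps hand arithmetic simple
  basis <- build_basis(1:4, df = 1)
  spec <- model_spec(df = 1, trials_per_day = 2)
  labels <- mwmbayes:::fixed_labels("g:a", spec)
  beta <- matrix(c(20, 3, -2, 0.5), 1, 4, dimnames = list(NULL, labels))
  s <- structure(list(draws = beta, labels = labels, basis = basis,
                      spec = spec, groups = "g:a", n_days = 2L,
                      trials_per_day = 2L, day_center = 0),
                 class = "mwm_samples")
  cd <- fitted_curve_draws(s, "g:a")
  grid <- attr(cd, "grid")
  B <- function(d) evaluate_basis(basis, d)
  hand <- 20 + 3 * B(grid$day) + (-2 + 0.5 * grid$day) * (grid$trial == 2)
  expect_equal(as.numeric(cd), as.numeric(hand))
})

test_that("summarize_curve reproduces normal quantiles and keeps ordering", {
  set.seed(71)
  draws <- matrix(rnorm(24 * 5000, 10, 1), 5000, 24)
  attr(draws, "grid") <- expand.grid(trial = 1:4, day = 1:6)[, c("day", "trial")]
  sm <- summarize_curve(draws, "g")
  expect_true(all(abs(sm$lower - qnorm(0.025, 10, 1)) < 0.15))
  expect_true(all(abs(sm$upper - qnorm(0.975, 10, 1)) < 0.15))
  expect_true(all(sm$lower <= sm$mean & sm$mean <= sm$upper))

  const <- matrix(5, 200, 24)
  attr(const, "grid") <- attr(draws, "grid")
  smc <- summarize_curve(const, "g")
  expect_true(all(smc$upper - smc$lower == 0))
  expect_error(summarize_curve(draws[1:50, ], "g"), ">= 100 draws")
})

test_that("learning rate is the endpoint difference over 23 trials", {
  # deterministic draw: latency 50 at (1,1) and 27 at (6,4) -> rate 1
  beta <- matrix(0, 150, 10)
  beta[, 1] <- 50
  s <- fake_samples(beta)
  cd <- fitted_curve_draws(s, "WT:scr")
  grid <- attr(cd, "grid")
  # construct a linear-in-index curve via intercept + spline (day part)
  # and trial-4 dummy: simplest exact check uses the flat curve -> rate 0
  expect_true(all(learning_rate(s, "WT:scr") == 0))

  # now an exactly linear curve dropping 1 s per trial from 50
  basis <- s$basis
  X <- cbind(1, evaluate_basis(basis, 1:6))
  day_mean <- 50 - 1 * (4 * (1:6 - 1))        # trial-1 latency per day
  coefs <- qr.coef(qr(X), day_mean)           # exact: linear in span
  beta2 <- matrix(0, 150, 10)
  beta2[, 1] <- coefs[1]; beta2[, 2:4] <- matrix(coefs[2:4], 150, 3, byrow = TRUE)
  beta2[, 5] <- -1; beta2[, 6] <- -2; beta2[, 7] <- -3   # trial dummies
  s2 <- fake_samples(beta2)
  expect_equal(unname(learning_rate(s2, "WT:scr")), rep(1, 150),
               tolerance = 1e-10)
})

test_that("within-day improvement is the trial-4 dummy plus its drift", {
  beta <- matrix(0, 120, 10)
  beta[, 7] <- -6     # trial-4 offset
  beta[, 10] <- 0.5   # trial-4 drift per day
  s <- fake_samples(beta)
  expect_equal(unname(within_day_improvement(s, "WT:scr", 4)),
               rep(-6 + 0.5 * 4, 120))
  expect_error(within_day_improvement(s, "WT:scr", 9), "within 1")
})

test_that("inter-day setbacks reduce to spline increments on a linear curve", {
  # linear day curve, zero dummies: setback d->d+1 equals the day slope
  basis <- build_basis(1:6, df = 3)
  X <- cbind(1, evaluate_basis(basis, 1:6))
  coefs <- qr.coef(qr(X), 40 - 3 * (1:6))
  beta <- matrix(0, 120, 10)
  beta[, 1] <- coefs[1]; beta[, 2:4] <- matrix(coefs[2:4], 120, 3, byrow = TRUE)
  s <- fake_samples(beta)
  expect_equal(unname(interday_setbacks(s, "WT:scr")), rep(-3, 120),
               tolerance = 1e-10)
  # hand-set toy draw: add a trial-4 dummy of -5 -> jump rises by 5
  beta2 <- beta; beta2[, 7] <- -5
  s2 <- fake_samples(beta2)
  expect_equal(unname(interday_setbacks(s2, "WT:scr", days = 4:6)),
               rep(-3 + 5, 120), tolerance = 1e-10)
  expect_error(interday_setbacks(s, "WT:scr", days = c(2, 4)), "consecutive")
})

test_that("contrast inverts credible intervals consistently", {
  set.seed(72)
  sym <- rnorm(20000)
  r <- contrast(sym, 0, "sym")
  expect_gt(r$p_value, 0.9)

  allpos <- abs(rnorm(5000)) + 0.01
  r2 <- contrast(allpos, 0, "pos")
  expect_true(r2$p_is_floor)
  expect_equal(r2$p_value, 2 / 5000)

  shifted <- rnorm(1e5, 1, 1)
  r3 <- contrast(shifted, 0, "shift")
  expect_equal(r3$p_value, 2 * pnorm(-1), tolerance = 0.05)

  expect_error(contrast(rnorm(10), rnorm(9)), "mismatched")

  # CI/P consistency on random fixtures
  for (mu in c(-0.5, 0, 0.3, 2)) {
    d <- rnorm(4000, mu, 1)
    r <- contrast(d, 0, "x")
    excludes <- r$lower > 0 || r$upper < 0
    expect_equal(r$p_value < 0.05, excludes)
  }
})

test_that("curve summaries are invariant to draw order", {
  set.seed(73)
  beta <- matrix(rnorm(300 * 10, 30, 2), 300, 10)
  s <- fake_samples(beta)
  perm <- sample(300)
  s2 <- s; s2$draws <- s$draws[perm, , drop = FALSE]
  sm1 <- summarize_curve(fitted_curve_draws(s, "WT:scr"))
  sm2 <- summarize_curve(fitted_curve_draws(s2, "WT:scr"))
  expect_equal(sm1, sm2)
})
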