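#' Ground-truth parameters for a synthetic cohort
#'
#' The generative model mirrors the analysis model: each group's mean
#' latency declines linearly in cumulative trial index from
#' `start_latency` at `rate_per_trial` seconds per trial (a curve the
#' spline-plus-dummy mean structure represents exactly), optionally with
#' additional trial-of-day offsets and linear-in-day drifts; each mouse
#' adds a Gaussian random intercept and three Gaussian random spline
#' deviations; trials add Gaussian residual noise; latencies at or above
#' the censor limit are recorded at the limit and flagged censored.
#'
#' @param genotypes,treatments character vectors (recycled against each
#'   other) defining the groups in order.
#' @param n_mice mice per group (scalar or per-group vector).
#' @param n_days training days (default 6).
#' @param trials_per_day trials per day (default 4).
#' @param start_latency per-group mean latency at day 1 trial 1, seconds.
#' @param rate_per_trial per-group constant improvement, seconds per trial.
#' @param trial_offsets optional (trials_per_day - 1) x groups matrix of
#'   trial-of-day offsets (seconds, trial 1 is reference); default 0.
#' @param trial_drifts optional matching matrix of linear-in-day drifts of
#'   the offsets (seconds per day); default 0.
#' @param sd_intercept s.d. of per-mouse random intercepts (default 5 s).
#' @param sd_spline length-3 s.d.s of per-mouse random spline coefficients
#'   (default 2 s each).
#' @param sd_residual residual s.d. (default 10 s).
#' @param censor_limit trial cutoff (default 60 s).
#' @param latency_floor smallest recordable latency; Gaussian latents
#'   below it are clamped up to keep latencies positive (default 0.1 s).
#' @param seed RNG seed for [simulate_cohort()].
#' @return object of class `mwm_true_parameters`.
#' @export
true_parameters <- function(genotypes = "WT", treatments = "scr",
                            n_mice = 20L, n_days = 6L, trials_per_day = 4L,
                            start_latency = 45, rate_per_trial = 1,
                            trial_offsets = NULL, trial_drifts = NULL,
                            sd_intercept = 5, sd_spline = c(2, 2, 2),
                            sd_residual = 10, censor_limit = 60,
                            latency_floor = 0.1, seed = 1L) {
  k <- max(length(genotypes), length(treatments))
  genotypes <- rep_len(genotypes, k)
  treatments <- rep_len(treatments, k)
  n_mice <- rep_len(as.integer(n_mice), k)
  start_latency <- rep_len(start_latency, k)
  rate_per_trial <- rep_len(rate_per_trial, k)
  nd <- trials_per_day - 1L
  trial_offsets <- trial_offsets %||% matrix(0, nd, k)
  trial_drifts <- trial_drifts %||% matrix(0, nd, k)
  stopifnot(all(n_mice >= 1L), n_days >= 1L, trials_per_day >= 1L,
            all(start_latency > 0), all(start_latency <= censor_limit),
            sd_intercept >= 0, all(sd_spline >= 0), sd_residual >= 0,
            nrow(trial_offsets) == nd, ncol(trial_offsets) == k,
            nrow(trial_drifts) == nd, ncol(trial_drifts) == k)
  structure(list(genotypes = genotypes, treatments = treatments,
                 n_mice = n_mice, n_days = as.integer(n_days),
                 trials_per_day = as.integer(trials_per_day),
                 start_latency = start_latency,
                 rate_per_trial = rate_per_trial,
                 trial_offsets = trial_offsets,
                 trial_drifts = trial_drifts,
                 sd_intercept = sd_intercept, sd_spline = sd_spline,
                 sd_residual = sd_residual, censor_limit = censor_limit,
                 latency_floor = latency_floor,
                 seed = as.integer(seed)),
            class = "mwm_true_parameters")
}

# Noise-free group mean at (day, trial), group g (1-based).
true_cell_mean <- function(truth, g, day, trial) {
  idx <- (day - 1) * truth$trials_per_day + (trial - 1)
  m <- truth$start_latency[g] - truth$rate_per_trial[g] * idx
  off <- trial > 1L
  m + ifelse(off,
             truth$trial_offsets[pmax(trial - 1L, 1L), g] +
               truth$trial_drifts[pmax(trial - 1L, 1L), g] * day,
             0)
}

#' Simulate a cohort with known ground truth
#'
#' @param truth an [true_parameters()].
#' @return list with `cohort` (an [mwm_cohort()]) and `truth` (the input,
#'   echoed). Fully reproducible from `truth$seed`.
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "mwm_true_parameters"))
  set.seed(truth$seed)
  basis <- build_basis(seq_len(max(truth$n_days, 4L)), df = length(truth$sd_spline))
  days <- seq_len(truth$n_days)
  trials <- seq_len(truth$trials_per_day)
  B <- evaluate_basis(basis, days)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1L)
  recs <- vector("list", length(truth$genotypes))
  for (g in seq_along(truth$genotypes)) {
    glab <- paste0("g", g)
    mice <- sprintf("%s_%s_%s_m%02d", truth$genotypes[g], truth$treatments[g],
                    glab, seq_len(truth$n_mice[g]))
    u0 <- rnorm(truth$n_mice[g], 0, truth$sd_intercept)
    v <- matrix(rnorm(truth$n_mice[g] * length(truth$sd_spline), 0,
                      rep(truth$sd_spline, each = truth$n_mice[g])),
                truth$n_mice[g], length(truth$sd_spline))
    cell <- expand.grid(trial = trials, day = days)
    mu_cell <- true_cell_mean(truth, g, cell$day, cell$trial)
    per_mouse <- lapply(seq_along(mice), function(i) {
      ran <- u0[i] + drop(B %*% v[i, ])[cell$day]
      latent <- mu_cell + ran +
        rnorm(nrow(cell), 0, truth$sd_residual)
      censored <- latent >= truth$censor_limit
      latency <- pmin(latent, truth$censor_limit)
      latency <- pmax(latency, truth$latency_floor)
      data.frame(mouse_id = mice[i],
                 genotype = truth$genotypes[g],
                 treatment = truth$treatments[g],
                 day = cell$day, trial = cell$trial,
                 latency = latency, censored = censored)
    })
    recs[[g]] <- do.call(rbind, per_mouse)
  }
  records <- do.call(rbind, recs)
  cohort <- mwm_cohort(records, trials_per_day = truth$trials_per_day,
                       censor_limit = truth$censor_limit)
  list(cohort = cohort, truth = truth)
}

#' Packaged simulation scenarios
#'
#' * `"fig4b-like"` — four genotype-by-treatment groups (WT:scr, WT:sh1,
#'   hAPPlow:scr, hAPPlow:sh1), 20 mice/group, 6 days x 4 trials, start
#'   latency 45 s, per-trial improvements 1.6, 0.9, 1.6 and 0.4 s/trial,
#'   default noise scales, censoring at 60 s.
#' * `"null"` — same shape, all four groups share one curve
#'   (1.0 s/trial from 45 s); contrasts between groups are truly zero.
#' * `"tiny"` — one group of 2 mice, 6 days x 4 trials; below the
#'   sampler's 3-mouse propriety guard, intended for oracle-scale math
#'   only.
#'
#' The noise scales (residual 10 s, intercept 5 s, spline 2 s) produce
#' realistic early-training censoring; they are package choices, not
#' published estimates.
#'
#' @param name scenario name.
#' @param seed RNG seed stored in the returned truth (default 7).
#' @param n_mice optional override of mice per group.
#' @return an [true_parameters()].
#' @export
scenario <- function(name, seed = 7L, n_mice = NULL) {
  known <- c("fig4b-like", "null", "tiny")
  if (!name %in% known) {
    stop("unknown scenario \"", name, "\"; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  switch(name,
    "fig4b-like" = true_parameters(
      genotypes = c("WT", "WT", "hAPPlow", "hAPPlow"),
      treatments = c("scr", "sh1", "scr", "sh1"),
      n_mice = n_mice %||% 20L, start_latency = 45,
      rate_per_trial = c(1.6, 0.9, 1.6, 0.4), seed = seed),
    "null" = true_parameters(
      genotypes = c("WT", "WT", "hAPPlow", "hAPPlow"),
      treatments = c("scr", "sh1", "scr", "sh1"),
      n_mice = n_mice %||% 20L, start_latency = 45,
      rate_per_trial = 1.0, seed = seed),
    "tiny" = true_parameters(
      genotypes = "WT", treatments = "scr", n_mice = n_mice %||% 2L,
      start_latency = 40, rate_per_trial = 1.0, sd_intercept = 2,
      sd_spline = c(1, 1, 1), sd_residual = 5, seed = seed))
}

#' Write / read a ground-truth sidecar file
#'
#' YAML-format serialization of [true_parameters()] used by recovery
#' reports.
#'
#' @param truth an `mwm_true_parameters`.
#' @param path file path.
#' @return `path` (write) or an `mwm_true_parameters` (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "mwm_true_parameters"))
  obj <- unclass(truth)
  obj$trial_offsets <- as.vector(obj$trial_offsets)
  obj$trial_drifts <- as.vector(obj$trial_drifts)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  k <- length(obj$genotypes)
  nd <- obj$trials_per_day - 1L
  true_parameters(genotypes = obj$genotypes, treatments = obj$treatments,
                  n_mice = obj$n_mice, n_days = obj$n_days,
                  trials_per_day = obj$trials_per_day,
                  start_latency = obj$start_latency,
                  rate_per_trial = obj$rate_per_trial,
                  trial_offsets = matrix(obj$trial_offsets, nd, k),
                  trial_drifts = matrix(obj$trial_drifts, nd, k),
                  sd_intercept = obj$sd_intercept,
                  sd_spline = obj$sd_spline,
                  sd_residual = obj$sd_residual,
                  censor_limit = obj$censor_limit,
                  latency_floor = obj$latency_floor,
                  seed = obj$seed)
}
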