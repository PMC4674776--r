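#' Fit the hierarchical learning-curve model to a cohort
#'
#' End-to-end convenience wrapper: builds the spline basis from the
#' cohort's training days, assembles design matrices, runs the Gibbs
#' sampler, computes convergence diagnostics and summarizes every group's
#' population learning curve with 95% credible bands.
#'
#' @param cohort an [mwm_cohort()].
#' @param spec an [model_spec()]; its censor limit and trials/day are
#'   taken from the cohort.
#' @param config an [sampler_config()].
#' @param psrf_threshold convergence cutoff passed to [diagnose()].
#' @return object of class `mwm_fit`: list with `samples`, `diagnostics`,
#'   `curves` (all groups stacked), `rates` (per-group learning-rate
#'   contrast rows), `basis`, `spec`, `config`.
#' @export
fit_learning_curves <- function(cohort, spec = NULL,
                                config = sampler_config(),
                                psrf_threshold = 1.1) {
  stopifnot(inherits(cohort, "mwm_cohort"))
  spec <- spec %||% model_spec(trials_per_day = cohort$trials_per_day,
                               censor_limit = cohort$censor_limit)
  basis <- build_basis(cohort$records$day, df = spec$df)
  design <- build_design(cohort, spec, basis)
  samples <- run_chains(design, config)
  diagnostics <- diagnose(samples, threshold = psrf_threshold)
  curves <- do.call(rbind, lapply(samples$groups, function(g) {
    summarize_curve(fitted_curve_draws(samples, g), g)
  }))
  class(curves) <- c("mwm_curves", "data.frame")
  rates <- do.call(rbind, lapply(samples$groups, function(g) {
    contrast(learning_rate(samples, g), 0,
             label = paste0("learning_rate[", g, "]"))
  }))
  structure(list(samples = samples, diagnostics = diagnostics,
                 curves = curves, rates = rates, basis = basis,
                 spec = spec, config = config),
            class = "mwm_fit")
}

#' @export
print.mwm_fit <- function(x, ...) {
  cat("Hierarchical learning-curve fit\n")
  print(x$samples)
  print(x$diagnostics)
  cat("Per-trial learning rates (s/trial, positive = improvement):\n")
  for (i in seq_len(nrow(x$rates))) print(x$rates[i, ])
  invisible(x)
}

#' Genotype contrasts of learning quantities within each treatment
#'
#' For every treatment present with both genotypes, contrasts the two
#' genotypes' learning rates (and, when requested, inter-day setbacks over
#' `setback_days`) draw-for-draw, with credible-interval-inversion P
#' values.
#'
#' @param samples an `mwm_samples`.
#' @param setback_days optional day vector for setback contrasts.
#' @return data.frame of stacked `mwm_contrast` rows.
#' @export
group_contrasts <- function(samples, setback_days = NULL) {
  parts <- do.call(rbind, strsplit(samples$groups, ":", fixed = TRUE))
  out <- list()
  for (tr in unique(parts[, 2L])) {
    gs <- samples$groups[parts[, 2L] == tr]
    if (length(gs) < 2L) next
    combs <- utils::combn(gs, 2L)
    for (j in seq_len(ncol(combs))) {
      a <- combs[1L, j]; b <- combs[2L, j]
      out[[length(out) + 1L]] <- contrast(
        learning_rate(samples, a), learning_rate(samples, b),
        label = paste0("learning_rate[", a, " - ", b, "]"))
      if (!is.null(setback_days)) {
        out[[length(out) + 1L]] <- contrast(
          interday_setbacks(samples, a, setback_days),
          interday_setbacks(samples, b, setback_days),
          label = paste0("setback[", a, " - ", b, "]"))
      }
    }
  }
  do.call(rbind, out)
}

fit_metadata <- function(fit) {
  s <- fit$samples
  list(package = "mwmbayes",
       parameter_order = s$par_labels,
       groups = as.list(s$groups),
       n_days = s$n_days,
       trials_per_day = s$trials_per_day,
       censor_limit = s$censor_limit,
       spline = list(df = fit$basis$df,
                     boundary_knots = fit$basis$boundary_knots,
                     internal_knots = fit$basis$internal_knots,
                     knot_rule = "quantiles of observed days"),
       priors = list(fixed_effects = "flat",
                     random_effect_sds = "flat on (0, Inf)",
                     residual_sd = fit$spec$residual_prior),
       day_centering = fit$spec$center_day,
       group_specific_dummies = fit$spec$group_dummies,
       learning_rate_definition =
         "(fitted day1 trial1 - fitted last day last trial)/(total trials - 1)",
       setback_definition =
         "fitted(day d+1, trial 1) - fitted(day d, last trial), averaged over transitions",
       ess_method = "Geyer initial positive sequence",
       psrf_method = "original (non-split) Gelman-Rubin",
       thin_rule = "evenly spaced retention of combined chained draws",
       sampler = list(n_chains = fit$config$n_chains,
                      burn_in = fit$config$burn_in,
                      draws_per_chain = fit$config$draws_per_chain,
                      thin_target = fit$config$thin_target,
                      retained_after_thinning = nrow(s$draws),
                      base_seed = fit$config$seed,
                      chain_seeds = s$seeds,
                      overdispersion = fit$config$overdispersion),
       converged = attr(fit$diagnostics, "converged"),
       max_psrf = max(fit$diagnostics$psrf))
}

#' Serialize a fit to a results directory
#'
#' Writes `draws.csv` (chain, iteration, one column per labelled
#' parameter), `metadata.yaml` (seeds, config, knots, parameter order,
#' prior choices, diagnostics summary), `diagnostics.csv`, `curves.csv`
#' and `contrasts.csv`.
#'
#' @param fit an `mwm_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "mwm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- fit$samples
  draws <- data.frame(chain = s$chain_id, iteration = s$iteration,
                      s$draws, check.names = FALSE)
  utils::write.csv(draws, file.path(dir, "draws.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$diagnostics),
                   file.path(dir, "diagnostics.csv"), row.names = FALSE)
  curves <- fit$curves
  names(curves) <- c("group", "day", "trial", "mean", "lo2.5", "hi97.5")
  utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
  contr <- rbind(fit$rates, group_contrasts(s, setback_days =
                                              max(1L, s$n_days - 2L):s$n_days))
  utils::write.csv(as.data.frame(contr), file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  yaml::write_yaml(fit_metadata(fit), file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Simulate a scenario cohort and write it with its truth sidecar
#'
#' @param name scenario name (see [scenario()]).
#' @param out_dir output directory; receives `cohort.csv` and `truth.yaml`.
#' @param seed simulation seed.
#' @param n_mice optional mice-per-group override.
#' @return named character vector of the two file paths, invisibly.
#' @export
run_simulate <- function(name, out_dir, seed = 7L, n_mice = NULL) {
  truth <- scenario(name, seed = seed, n_mice = n_mice)
  sim <- simulate_cohort(truth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(out_dir, "cohort.csv")
  truth_path <- file.path(out_dir, "truth.yaml")
  write_trials(sim$cohort, cohort_path)
  write_truth(truth, truth_path)
  invisible(c(cohort = cohort_path, truth = truth_path))
}

#' Fit a cohort CSV and write all result files
#'
#' @param input_csv cohort CSV in the [load_trials()] schema.
#' @param out_dir results directory.
#' @param config an [sampler_config()].
#' @param censor_limit,trials_per_day cohort schema parameters.
#' @return the `mwm_fit`, invisibly.
#' @export
run_fit <- function(input_csv, out_dir, config = sampler_config(),
                    censor_limit = 60, trials_per_day = 4L) {
  cohort <- load_trials(input_csv, censor_limit = censor_limit,
                        trials_per_day = trials_per_day)
  fit <- fit_learning_curves(cohort, config = config)
  write_results(fit, out_dir)
  invisible(fit)
}

#' Recovery report against a ground-truth sidecar
#'
#' Refits the cohort and compares, per group, the posterior learning rate
#' against the generating per-trial improvement: posterior mean, 95% CI,
#' truth-in-CI indicator and a posterior z-score
#' `(mean - truth)/posterior sd`.
#'
#' @param input_csv cohort CSV produced by [run_simulate()].
#' @param truth_path matching `truth.yaml` sidecar.
#' @param out_dir optional directory for `recovery.csv`.
#' @param config an [sampler_config()].
#' @return data.frame with one row per group plus attribute `coverage`
#'   (fraction of truths inside their CIs).
#' @export
run_recover <- function(input_csv, truth_path, out_dir = NULL,
                        config = sampler_config()) {
  if (!file.exists(truth_path)) {
    stop("truth sidecar not found: ", truth_path, call. = FALSE)
  }
  truth <- read_truth(truth_path)
  cohort <- load_trials(input_csv, censor_limit = truth$censor_limit,
                        trials_per_day = truth$trials_per_day)
  truth_groups <- group_label(truth$genotypes, truth$treatments)
  if (!setequal(truth_groups, cohort_groups(cohort)) ||
      cohort$n_days != truth$n_days) {
    stop("truth sidecar does not match the cohort ",
         "(different groups or day count)", call. = FALSE)
  }
  fit <- fit_learning_curves(cohort, config = config)
  rows <- lapply(seq_along(truth_groups), function(g) {
    draws <- learning_rate(fit$samples, truth_groups[g])
    data.frame(group = truth_groups[g],
               true_rate = truth$rate_per_trial[g],
               posterior_mean = mean(draws),
               lower = unname(quantile(draws, 0.025)),
               upper = unname(quantile(draws, 0.975)),
               z = (mean(draws) - truth$rate_per_trial[g]) / sd(draws))
  })
  out <- do.call(rbind, rows)
  out$in_ci <- out$true_rate >= out$lower & out$true_rate <= out$upper
  attr(out, "coverage") <- mean(out$in_ci)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
  }
  out
}

#' Plot posterior learning curves with credible bands
#'
#' Base-graphics plot of group population curves over cumulative trial
#' index, broken into per-day segments, with shaded 95% credible bands.
#'
#' @param x an `mwm_curves` data.frame (e.g. `fit$curves`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mwm_curves <- function(x, ...) {
  groups <- unique(x$group)
  cols <- grDevices::hcl.colors(max(2L, length(groups)), "Dark 3")
  tpd <- max(x$trial)
  x$index <- (x$day - 1L) * tpd + x$trial
  graphics::plot(NA, xlim = range(x$index), ylim = c(0, max(x$upper) * 1.05),
                 xlab = "cumulative trial", ylab = "escape latency (s)", ...)
  for (gi in seq_along(groups)) {
    gx <- x[x$group == groups[gi], ]
    for (d in unique(gx$day)) {
      seg <- gx[gx$day == d, ]
      graphics::polygon(c(seg$index, rev(seg$index)),
                        c(seg$lower, rev(seg$upper)),
                        col = grDevices::adjustcolor(cols[gi], alpha.f = 0.2),
                        border = NA)
      graphics::lines(seg$index, seg$mean, col = cols[gi], lwd = 2)
    }
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n")
  invisible(x)
}
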