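#' Model specification
#'
#' Collects the structural choices of the hierarchical latency model: the
#' spline degrees of freedom over training day, the trial-of-day dummy
#' structure (indicators for trials 2..T with effects drifting linearly in
#' day), whether those dummies are group-specific (default, one independent
#' 10-parameter mean structure per genotype-by-treatment group when T = 4)
#' or shared across groups, and the prior for the residual s.d.
#'
#' Fixed effects always carry flat priors; the four random-effect standard
#' deviations (intercept + three spline terms) always carry flat priors on
#' the s.d. scale. The residual s.d. prior defaults to flat on the s.d.
#' scale as well (`"flat_sd"`), with a vague inverse-gamma alternative.
#'
#' @param df spline degrees of freedom (default 3).
#' @param trials_per_day trials per training day (default 4).
#' @param censor_limit right-censoring cutoff in seconds (default 60).
#' @param group_dummies logical; group-specific trial dummies (default TRUE).
#' @param center_day logical; center day in the dummy-by-day interactions
#'   (default FALSE: raw day).
#' @param residual_prior `"flat_sd"` or `"inv_gamma"`.
#' @return object of class `mwm_model_spec`.
#' @export
model_spec <- function(df = 3L, trials_per_day = 4L, censor_limit = 60,
                       group_dummies = TRUE, center_day = FALSE,
                       residual_prior = c("flat_sd", "inv_gamma")) {
  residual_prior <- match.arg(residual_prior)
  stopifnot(df >= 1L, trials_per_day >= 1L, censor_limit > 0)
  structure(list(df = as.integer(df),
                 trials_per_day = as.integer(trials_per_day),
                 censor_limit = censor_limit,
                 group_dummies = isTRUE(group_dummies),
                 center_day = isTRUE(center_day),
                 residual_prior = residual_prior),
            class = "mwm_model_spec")
}

# One fixed-effect row for a (group, day, trial) cell: group-blocked
# [1, B1(d), B2(d), B3(d), 1[t=2..T], 1[t=2..T]*d] or the shared-dummy
# variant. `day_center` is subtracted inside the interactions only.
fixed_row <- function(g, day, trial, basis, spec, n_groups, day_center = 0) {
  B <- evaluate_basis(basis, day)
  dums <- as.numeric(trial == seq(2L, spec$trials_per_day))
  dc <- day - day_center
  if (spec$group_dummies) {
    block <- c(1, B, dums, dums * dc)
    row <- numeric(n_groups * length(block))
    row[(g - 1L) * length(block) + seq_along(block)] <- block
  } else {
    block <- c(1, B)
    row <- numeric(n_groups * length(block) + 2L * length(dums))
    row[(g - 1L) * length(block) + seq_along(block)] <- block
    row[n_groups * length(block) + seq_along(c(dums, dums * dc))] <-
      c(dums, dums * dc)
  }
  row
}

fixed_labels <- function(group_labels, spec) {
  tt <- seq(2L, spec$trials_per_day)
  spl <- paste0("spline", seq_len(spec$df))
  if (spec$group_dummies) {
    block <- c("intercept", spl, paste0("trial", tt), paste0("trial", tt, ":day"))
    as.vector(vapply(group_labels, function(g) paste(g, block, sep = "::"),
                     character(length(block))))
  } else {
    block <- c("intercept", spl)
    c(as.vector(vapply(group_labels, function(g) paste(g, block, sep = "::"),
                       character(length(block)))),
      paste0("trial", tt), paste0("trial", tt, ":day"))
  }
}

#' Assemble design matrices for the hierarchical latency model
#'
#' Builds the fixed-effect matrix X (group-blocked: per group an intercept,
#' `df` spline columns, trial-of-day dummies and their linear-in-day
#' drifts), the per-observation random-effect covariate rows
#' `[1, B1(d), ..., Bdf(d)]` shared by the animal's random intercept and
#' spline deviations, the response vector and the censoring indicator.
#'
#' @param cohort an [mwm_cohort()].
#' @param spec an [model_spec()].
#' @param basis an [build_basis()] result built from the cohort's days.
#' @return object of class `mwm_design`: list with `X`, `Zrow`, `mouse`
#'   (factor, one level per animal), `y`, `censored`, `labels` (fixed-effect
#'   column labels), `groups`, `group_of_mouse`, `day`, `trial`, `n_days`,
#'   `trials_per_day`, `censor_limit`, `basis`, `spec`.
#' @export
build_design <- function(cohort, spec = model_spec(), basis = NULL) {
  stopifnot(inherits(cohort, "mwm_cohort"), inherits(spec, "mwm_model_spec"))
  rec <- cohort$records
  if (nrow(rec) == 0L) stop("empty cohort", call. = FALSE)
  if (is.null(basis)) basis <- build_basis(rec$day, df = spec$df)
  groups <- cohort_groups(cohort)
  gidx <- match(group_label(rec$genotype, rec$treatment), groups)
  day_center <- if (spec$center_day) mean(unique(rec$day)) else 0

  n <- nrow(rec)
  B <- evaluate_basis(basis, rec$day)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1L)
  tt <- seq(2L, spec$trials_per_day)
  dums <- outer(rec$trial, tt, `==`) * 1
  dc <- rec$day - day_center
  block <- cbind(1, B, dums, dums * dc)
  if (spec$group_dummies) {
    pb <- ncol(block)
    X <- matrix(0, n, pb * length(groups))
    for (g in seq_along(groups)) {
      rows <- gidx == g
      X[rows, (g - 1L) * pb + seq_len(pb)] <- block[rows, , drop = FALSE]
    }
  } else {
    pb <- 1L + spec$df
    X <- matrix(0, n, pb * length(groups) + 2L * length(tt))
    for (g in seq_along(groups)) {
      rows <- gidx == g
      X[rows, (g - 1L) * pb + seq_len(pb)] <- block[rows, seq_len(pb), drop = FALSE]
    }
    X[, pb * length(groups) + seq_len(2L * length(tt))] <-
      block[, -seq_len(pb), drop = FALSE]
  }
  labels <- fixed_labels(groups, spec)
  colnames(X) <- labels

  mouse <- factor(rec$mouse_id, levels = unique(rec$mouse_id))
  group_of_mouse <- gidx[match(levels(mouse), rec$mouse_id)]
  names(group_of_mouse) <- levels(mouse)

  structure(list(X = X,
                 Zrow = cbind(1, B),
                 mouse = mouse,
                 y = rec$latency,
                 censored = rec$censored,
                 labels = labels,
                 groups = groups,
                 group_of_mouse = group_of_mouse,
                 day = rec$day,
                 trial = rec$trial,
                 day_center = day_center,
                 n_days = cohort$n_days,
                 trials_per_day = spec$trials_per_day,
                 censor_limit = cohort$censor_limit,
                 basis = basis,
                 spec = spec),
            class = "mwm_design")
}

#' Ordered parameter labels
#'
#' The stable parameter ordering used by the sampler, draw storage and all
#' reports: the fixed-effect labels (group blocks in group order, within a
#' block intercept, spline terms, trial dummies, dummy-by-day drifts)
#' followed by `sd_intercept`, `sd_spline1..df`, `sd_residual`.
#'
#' @param design an `mwm_design` (or `mwm_samples`).
#' @return character vector of parameter labels.
#' @export
describe_parameters <- function(design) {
  labels <- if (inherits(design, "mwm_samples")) design$labels else design$labels
  spl <- paste0("sd_spline", seq_len(design$spec$df))
  c(labels, "sd_intercept", spl, "sd_residual")
}
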