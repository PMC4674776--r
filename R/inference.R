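# Fixed-effect design rows for every (day, trial) cell of one group's
# population curve (random effects at zero).
curve_grid_rows <- function(samples, group) {
  groups <- samples$groups
  g <- match(group, groups)
  if (is.na(g)) {
    stop("unknown group \"", group, "\"; available: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(trial = seq_len(samples$trials_per_day),
                      day = seq_len(samples$n_days))[, c("day", "trial")]
  rows <- t(vapply(seq_len(nrow(grid)), function(i) {
    fixed_row(g, grid$day[i], grid$trial[i], samples$basis, samples$spec,
              length(groups), samples$day_center)
  }, numeric(length(samples$labels))))
  list(grid = grid, rows = rows)
}

#' Per-draw fitted population learning curve
#'
#' Evaluates, for every retained (thinned) draw, the fixed-effects-only
#' fitted latency of one group over the complete day x trial grid (random
#' effects at zero: the population curve).
#'
#' @param samples an `mwm_samples`.
#' @param group group label ("genotype:treatment").
#' @return draws x cells numeric matrix with attribute `grid` (data.frame
#'   of `day`, `trial` per column).
#' @export
fitted_curve_draws <- function(samples, group) {
  gr <- curve_grid_rows(samples, group)
  beta <- samples$draws[, seq_along(samples$labels), drop = FALSE]
  out <- beta %*% t(gr$rows)
  attr(out, "grid") <- gr$grid
  attr(out, "group") <- group
  out
}

#' Summarize curve draws into a learning-curve table
#'
#' @param curve_draws matrix from [fitted_curve_draws()] (>= 100 draws).
#' @param group optional group label override.
#' @return data.frame of class `mwm_curves`: `group`, `day`, `trial`,
#'   `mean`, `lower` (2.5%), `upper` (97.5%).
#' @export
summarize_curve <- function(curve_draws, group = NULL) {
  if (nrow(curve_draws) < 100L) {
    stop("need >= 100 draws to summarize credible bands", call. = FALSE)
  }
  grid <- attr(curve_draws, "grid")
  qs <- apply(curve_draws, 2L, quantile, probs = c(0.025, 0.975))
  out <- data.frame(group = group %||% attr(curve_draws, "group"),
                    day = grid$day, trial = grid$trial,
                    mean = colMeans(curve_draws),
                    lower = qs[1L, ], upper = qs[2L, ])
  rownames(out) <- NULL
  class(out) <- c("mwm_curves", "data.frame")
  out
}

#' Posterior draws of the per-trial learning rate
#'
#' Rate = (fitted latency at day 1 trial 1 minus fitted latency at the
#' last day's last trial) / (total trial count - 1), in seconds per trial;
#' positive values mean improvement.
#'
#' @param samples an `mwm_samples`.
#' @param group group label.
#' @return numeric vector, one rate per retained draw.
#' @export
learning_rate <- function(samples, group) {
  cd <- fitted_curve_draws(samples, group)
  grid <- attr(cd, "grid")
  first <- which(grid$day == 1L & grid$trial == 1L)
  last <- which(grid$day == max(grid$day) & grid$trial == max(grid$trial))
  total <- nrow(grid)
  (cd[, first] - cd[, last]) / (total - 1L)
}

#' Posterior draws of within-day improvement
#'
#' Fitted latency at the last trial of `day` minus the first trial of
#' `day` (population curve); negative values mean the group got faster
#' across the day's trials.
#'
#' @param samples an `mwm_samples`.
#' @param group group label.
#' @param day training day within the observed range.
#' @return numeric vector, one value per retained draw.
#' @export
within_day_improvement <- function(samples, group, day) {
  if (day < 1L || day > samples$n_days) {
    stop("day must be within 1..", samples$n_days, call. = FALSE)
  }
  cd <- fitted_curve_draws(samples, group)
  grid <- attr(cd, "grid")
  a <- which(grid$day == day & grid$trial == samples$trials_per_day)
  b <- which(grid$day == day & grid$trial == 1L)
  cd[, a] - cd[, b]
}

#' Posterior draws of mean inter-day setback
#'
#' The overnight setback from day d to d+1 is the rise of the fitted
#' population curve from the last trial of day d to the first trial of day
#' d+1; positive values mean performance regressed overnight. The result
#' averages over the consecutive-day transitions inside `days` (e.g. the
#' last 3 training days contribute the two final transitions).
#'
#' @param samples an `mwm_samples`.
#' @param group group label.
#' @param days integer vector of consecutive training days (length >= 2);
#'   default all days.
#' @return numeric vector, one mean setback per retained draw.
#' @export
interday_setbacks <- function(samples, group, days = NULL) {
  days <- days %||% seq_len(samples$n_days)
  days <- sort(as.integer(days))
  if (length(days) < 2L || any(days < 1L) || any(days > samples$n_days) ||
      any(diff(days) != 1L)) {
    stop("days must be >= 2 consecutive training days within 1..",
         samples$n_days, call. = FALSE)
  }
  cd <- fitted_curve_draws(samples, group)
  grid <- attr(cd, "grid")
  trans <- vapply(days[-length(days)], function(d) {
    a <- which(grid$day == d + 1L & grid$trial == 1L)
    b <- which(grid$day == d & grid$trial == samples$trials_per_day)
    cd[, a] - cd[, b]
  }, numeric(nrow(cd)))
  if (is.null(dim(trans))) trans <- matrix(trans, ncol = 1L)
  rowMeans(trans)
}

#' Posterior contrast with credible-interval-inversion P value
#'
#' Differences are taken draw-for-draw (`a - b`); the approximate P value
#' is twice the smaller posterior tail probability relative to zero, so
#' P < 0.05 exactly when the 95% equal-tailed credible interval of the
#' difference excludes zero. When one tail is empty the P value is
#' reported as the resolution floor `2/N` with `p_is_floor = TRUE`.
#'
#' @param a,b numeric vectors of matched posterior draws (equal length);
#'   `b` may be 0 to test a single quantity against zero.
#' @param label contrast label for reports.
#' @return one-row data.frame of class `mwm_contrast`: `label`, `mean`,
#'   `lower`, `upper`, `p_value`, `p_is_floor`, `n_draws`.
#' @export
contrast <- function(a, b = 0, label = "contrast") {
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) {
    stop("mismatched draw counts: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  d <- a - b
  N <- length(d)
  p_hi <- mean(d > 0)
  p_lo <- mean(d < 0)
  p <- 2 * min(p_hi, p_lo)
  floor_hit <- p < 2 / N
  if (floor_hit) p <- 2 / N
  p <- min(p, 1)
  out <- data.frame(label = label,
                    mean = mean(d),
                    lower = unname(quantile(d, 0.025)),
                    upper = unname(quantile(d, 0.975)),
                    p_value = p,
                    p_is_floor = floor_hit,
                    n_draws = N)
  class(out) <- c("mwm_contrast", "data.frame")
  out
}

#' @export
print.mwm_contrast <- function(x, digits = 3, ...) {
  for (i in seq_len(nrow(x))) {
    p <- if (x$p_is_floor[i]) paste("<", signif(x$p_value[i], 2)) else
      paste("=", signif(x$p_value[i], 2))
    cat(sprintf("%s: %.2f s (95%% CI %.2f to %.2f), P %s (N = %d draws)\n",
                x$label[i], x$mean[i], x$lower[i], x$upper[i], p,
                x$n_draws[i]))
  }
  invisible(x)
}
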