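#' Natural cubic spline basis over training day
#'
#' Builds the 3-degrees-of-freedom (by default) natural cubic spline basis
#' used for the day-level learning curve. Boundary knots sit at the
#' extremes of the observed days; the `df - 1` internal knots sit at evenly
#' spaced quantiles of the supplied day values (for `df = 3`, the 33.3% and
#' 66.7% quantiles). Natural (linear-tail) constraints make every basis
#' function linear at and beyond the boundary knots, so evaluation
#' extrapolates linearly.
#'
#' @param days day values observed in the cohort (need not be unique).
#' @param df spline degrees of freedom, excluding the intercept (default 3).
#' @return object of class `mwm_spline_basis` with fields `df`,
#'   `boundary_knots` and `internal_knots`.
#' @export
build_basis <- function(days, df = 3L) {
  days <- as.numeric(days)
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  if (length(unique(days)) < df + 1L) {
    stop("configuration error: need at least df + 1 = ", df + 1L,
         " distinct day values to place knots, got ",
         length(unique(days)), call. = FALSE)
  }
  boundary <- range(days)
  internal <- if (df > 1L) {
    unname(stats::quantile(days, probs = seq_len(df - 1L) / df))
  } else numeric(0)
  structure(list(df = as.integer(df),
                 boundary_knots = boundary,
                 internal_knots = internal),
            class = "mwm_spline_basis")
}

#' Evaluate the spline basis
#'
#' @param basis an `mwm_spline_basis`.
#' @param day day value(s); any real is accepted (linear extrapolation
#'   beyond the boundary knots).
#' @return for a single day, a length-`df` numeric vector; otherwise a
#'   `length(day) x df` matrix with one row per day.
#' @export
evaluate_basis <- function(basis, day) {
  stopifnot(inherits(basis, "mwm_spline_basis"))
  b <- splines::ns(as.numeric(day), knots = basis$internal_knots,
                   Boundary.knots = basis$boundary_knots, intercept = FALSE)
  b <- unclass(b)[, seq_len(basis$df), drop = FALSE]
  dimnames(b) <- list(NULL, paste0("spline", seq_len(basis$df)))
  if (length(day) == 1L) drop(b) else b
}

#' @export
print.mwm_spline_basis <- function(x, ...) {
  cat("Natural cubic spline basis: df =", x$df,
      "| boundary knots at", paste(signif(x$boundary_knots, 6), collapse = ", "),
      "| internal knots at", paste(signif(x$internal_knots, 6), collapse = ", "),
      "\n")
  invisible(x)
}
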