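#' Trial-level water-maze cohort
#'
#' Container for hidden-platform training data: one row per animal x
#' training day x trial-of-day, holding the escape latency in seconds and a
#' right-censoring flag (latency capped at the trial cutoff, 60 s by
#' default). Every animal belongs to exactly one genotype-by-treatment
#' group. Unbalanced designs (missing trials) are permitted.
#'
#' @param records data.frame with columns `mouse_id`, `genotype`,
#'   `treatment`, `day` (1-based integer), `trial` (1-based integer),
#'   `latency` (seconds), `censored` (logical or 0/1).
#' @param trials_per_day number of trials per training day (default 4).
#' @param censor_limit trial cutoff in seconds (default 60).
#' @return object of class `mwm_cohort`: list with elements `records`
#'   (validated data.frame), `groups` (data.frame of genotype/treatment in
#'   order of first appearance), `n_days`, `trials_per_day`, `censor_limit`.
#' @export
mwm_cohort <- function(records, trials_per_day = 4L, censor_limit = 60) {
  required <- c("mouse_id", "genotype", "treatment", "day", "trial",
                "latency", "censored")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s) ",
         paste0('"', missing_cols, '"', collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$mouse_id <- as.character(records$mouse_id)
  records$genotype <- as.character(records$genotype)
  records$treatment <- as.character(records$treatment)
  records$day <- as.integer(records$day)
  records$trial <- as.integer(records$trial)
  records$latency <- as.numeric(records$latency)
  cens <- records$censored
  if (is.character(cens)) cens <- as.numeric(cens)
  records$censored <- as.logical(cens)
  if (anyNA(records$censored)) {
    stop("validation error: censored flag not interpretable as 0/1 at row(s) ",
         paste(which(is.na(records$censored)), collapse = ", "), call. = FALSE)
  }

  n <- nrow(records)
  if (n > 0L) {
    bad <- which(records$day < 1L)
    if (length(bad)) stop("validation error: day < 1 at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    bad <- which(records$trial < 1L | records$trial > trials_per_day)
    if (length(bad)) stop("validation error: trial outside 1..",
                          trials_per_day, " at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    bad <- which(!is.finite(records$latency) | records$latency <= 0 |
                   records$latency > censor_limit)
    if (length(bad)) stop("validation error: latency outside (0, ",
                          censor_limit, "] at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    # a trial recorded exactly at the cutoff is a timeout: coerce the flag
    coerce <- which(records$latency == censor_limit & !records$censored)
    if (length(coerce)) {
      warning(length(coerce), " record(s) at the censor limit with censored=0",
              " coerced to censored=1 (row(s) ",
              paste(utils::head(coerce, 10L), collapse = ", "), ")",
              call. = FALSE)
      records$censored[coerce] <- TRUE
    }
    bad <- which(records$censored & records$latency != censor_limit)
    if (length(bad)) stop("validation error: censored record with latency != ",
                          censor_limit, " at row(s) ",
                          paste(bad, collapse = ", "), call. = FALSE)
    key <- paste(records$mouse_id, records$day, records$trial, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) stop("validation error: duplicate (mouse, day, trial) at row(s) ",
                          paste(dup, collapse = ", "), call. = FALSE)
    gp <- unique(records[c("mouse_id", "genotype", "treatment")])
    if (anyDuplicated(gp$mouse_id)) {
      off <- gp$mouse_id[duplicated(gp$mouse_id)]
      stop("validation error: mouse assigned to more than one group: ",
           paste(unique(off), collapse = ", "), call. = FALSE)
    }
  }
  groups <- unique(records[c("genotype", "treatment")])
  rownames(groups) <- NULL
  structure(list(records = records,
                 groups = groups,
                 n_days = if (n > 0L) max(records$day) else 0L,
                 trials_per_day = as.integer(trials_per_day),
                 censor_limit = censor_limit),
            class = "mwm_cohort")
}

#' @export
print.mwm_cohort <- function(x, ...) {
  cat("Water-maze cohort:", nrow(x$records), "trial records,",
      length(unique(x$records$mouse_id)), "mice,",
      nrow(x$groups), "group(s)\n")
  cat("  ", x$n_days, "training day(s) x", x$trials_per_day,
      "trials/day; censored at", x$censor_limit, "s (",
      sum(x$records$censored), "censored records )\n")
  invisible(x)
}

#' Group labels of a cohort
#' @param cohort an `mwm_cohort`.
#' @return character vector "genotype:treatment" in group order.
#' @export
cohort_groups <- function(cohort) {
  if (nrow(cohort$groups) == 0L) return(character(0))
  group_label(cohort$groups$genotype, cohort$groups$treatment)
}

#' Read trial records from CSV
#'
#' Expects the schema
#' `mouse_id,genotype,treatment,day,trial,latency_s,censored` with
#' `censored` coded 0/1. Rows whose latency equals the censor limit but
#' carry `censored = 0` are coerced to censored (with a warning), since a
#' timed-out trial is recorded at the cutoff.
#'
#' @param path CSV file path.
#' @param censor_limit trial cutoff in seconds (default 60).
#' @param trials_per_day trials per day (default 4).
#' @return an [mwm_cohort()].
#' @export
load_trials <- function(path, censor_limit = 60, trials_per_day = 4L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = c(mouse_id = "character"),
                         check.names = TRUE)
  required <- c("mouse_id", "genotype", "treatment", "day", "trial",
                "latency_s", "censored")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
         paste0('"', missing_cols, '"', collapse = ", "), call. = FALSE)
  }
  names(raw)[names(raw) == "latency_s"] <- "latency"
  mwm_cohort(raw, trials_per_day = trials_per_day,
             censor_limit = censor_limit)
}

#' Write trial records to CSV
#'
#' Inverse of [load_trials()]: `load_trials(write_trials(c))` reproduces the
#' cohort field-for-field. An empty cohort yields a header-only file.
#'
#' @param cohort an `mwm_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  stopifnot(inherits(cohort, "mwm_cohort"))
  out <- cohort$records
  names(out)[names(out) == "latency"] <- "latency_s"
  out$censored <- as.integer(out$censored)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
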