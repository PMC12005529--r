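#' Least-squares annual eGFR slope
#'
#' Ordinary least-squares slope of eGFR (mL/min/1.73m2) on time (years).
#' Returns `NA` with no error when fewer than two points are available; the
#' classification step decides what to do with such patients.
#'
#' @param times years since first measurement (strictly increasing).
#' @param values eGFR measurements, positive, same length as `times`.
#' @return slope in mL/min/1.73m2 per year, or `NA_real_` when `length < 2`.
#' @export
fit_egfr_slope <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (any(values <= 0)) stop("eGFR values must be positive")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (length(times) < 2L) return(NA_real_)
  unname(stats::cov(times, values) / stats::var(times))
}

#' Classify renal progression from the annual eGFR slope
#'
#' Decline (positive eGFR loss, `-slope`) of at least `fast_cutoff`
#' (default 10 mL/min/1.73m2/yr) is fast progression; decline between
#' `stable_epsilon` and the cutoff is moderate; decline of at most
#' `stable_epsilon` (stable renal function) is slow. Fast maps to the FAST
#' extreme-phenotype group, moderate and slow to noFAST. Patients with a
#' single measurement cannot be regressed and are classified only through
#' an explicit override.
#'
#' @param slope fitted slope (`NA` allowed when `n_points == 1`).
#' @param n_points number of eGFR measurements.
#' @param fast_cutoff annual decline defining fast progression.
#' @param stable_epsilon decline at or below which renal function is called
#'   stable.
#' @param override optional class (`"fast"`, `"moderate"`, `"slow"`) for
#'   single-measurement patients.
#' @return list with `slope`, `decline_rate`, `class`, `group`, `n_points`;
#'   `class` is `"unclassifiable"` (group `NA`) when no slope and no
#'   override exist.
#' @export
classify_progression <- function(slope, n_points, fast_cutoff = 10,
                                 stable_epsilon = 1, override = NULL) {
  if (n_points < 0) stop("n_points must be non-negative")
  if (is.na(slope)) {
    if (!is.null(override) && !is.na(override)) {
      cls <- match.arg(override, c("fast", "moderate", "slow"))
      return(list(slope = NA_real_, decline_rate = NA_real_, class = cls,
                  group = if (cls == "fast") "FAST" else "noFAST",
                  n_points = n_points))
    }
    return(list(slope = NA_real_, decline_rate = NA_real_,
                class = "unclassifiable", group = NA_character_,
                n_points = n_points))
  }
  decline <- -slope
  cls <- if (decline >= fast_cutoff) "fast"
         else if (decline > stable_epsilon) "moderate"
         else "slow"
  list(slope = slope, decline_rate = decline, class = cls,
       group = if (cls == "fast") "FAST" else "noFAST", n_points = n_points)
}

#' Stratify a cohort into FAST vs noFAST extreme phenotypes
#'
#' Fits the per-patient eGFR slope and classifies progression for every
#' patient of a long-format eGFR table. Single-measurement patients are
#' classified through the optional override table and otherwise excluded
#' with a warning.
#'
#' @param egfr data frame with columns `patient_id`, `time` (years) and
#'   `egfr`; zero rows give an empty call table.
#' @param overrides optional data frame with columns `patient_id`, `class`.
#' @param fast_cutoff,stable_epsilon see [classify_progression()].
#' @return data frame of progression calls (one row per patient) with
#'   columns `patient_id`, `n_points`, `slope`, `decline_rate`, `class`,
#'   `group`; unclassifiable patients are dropped from the table.
#' @export
assign_groups <- function(egfr, overrides = NULL, fast_cutoff = 10,
                          stable_epsilon = 1) {
  stopifnot(all(c("patient_id", "time", "egfr") %in% names(egfr)))
  ids <- unique(egfr$patient_id)
  ov <- if (!is.null(overrides)) {
    stats::setNames(as.character(overrides$class), overrides$patient_id)
  } else character()
  rows <- lapply(ids, function(id) {
    d <- egfr[egfr$patient_id == id, , drop = FALSE]
    d <- d[order(d$time), ]
    if (anyDuplicated(d$time)) {
      stop("duplicate measurement times for patient ", id)
    }
    slope <- fit_egfr_slope(d$time, d$egfr)
    call <- classify_progression(slope, nrow(d), fast_cutoff, stable_epsilon,
                                 override = if (id %in% names(ov)) ov[[id]] else NULL)
    data.frame(patient_id = id, n_points = call$n_points, slope = call$slope,
               decline_rate = call$decline_rate, class = call$class,
               group = call$group, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), n_points = integer(),
               slope = numeric(), decline_rate = numeric(),
               class = character(), group = character())
  if (anyDuplicated(out$patient_id)) stop("duplicate patient ids")
  n_excl <- sum(out$class == "unclassifiable")
  if (n_excl > 0L) {
    warning(n_excl, " patient(s) with a single eGFR value and no class ",
            "override excluded from stratification")
  }
  out[out$class != "unclassifiable", , drop = FALSE]
}
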