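# Orchestration of the time-cohort analyses: univariate and multivariate
# Cox models per time window, the continuous-score interaction model,
# and per-group landmark KM / kernel hazard curves.

#' Declare an analysis plan
#'
#' @param windows list of 2-vectors `c(t0, t1)` in years.  The default
#'   covers the full decade, the two clinical halves, and the early
#'   split at 2.5 years: (0,10), (0,5), (5,10), (0,2.5), (2.5,5).
#' @param univariate covariate names analysed one at a time.
#' @param multivariate covariate names fitted jointly.
#' @param mv_windows windows for the multivariate model (default the
#'   early window (0,2.5) and the late window (5,10)).
#' @param strata optional stratification variable (e.g. `"nodal"`): the
#'   whole suite is repeated within each stratum level.
#' @param group_var name of the four-group factor column (default `"group"`).
#' @return an `analysis_plan`.
#' @export
analysis_plan <- function(windows = list(c(0, 10), c(0, 5), c(5, 10), c(0, 2.5), c(2.5, 5)),
                          univariate = "group",
                          multivariate = c("age", "stage", "nodal", "grade2", "her2", "group"),
                          mv_windows = list(c(0, 2.5), c(5, 10)),
                          strata = NULL, group_var = "group") {
  windows <- lapply(windows, function(w) time_window(w[1], w[2]))
  mv_windows <- lapply(mv_windows, function(w) time_window(w[1], w[2]))
  structure(list(windows = windows, univariate = univariate,
                 multivariate = multivariate, mv_windows = mv_windows,
                 strata = strata, group_var = group_var),
            class = "analysis_plan")
}

# one Cox fit summarized as report rows; failures become flagged NA rows
#' @noRd
fit_rows <- function(records, covariates, window, model_label) {
  out <- tryCatch({
    fit <- cox_fit(records, covariates, window)
    ph <- if (fit$n_event >= 3L) schoenfeld_ph_test(fit) else NULL
    tab <- fit$coefficients
    data.frame(model = model_label, window = format(window), term = tab$term,
               hr = tab$hr, ci_lo = tab$ci_lo, ci_hi = tab$ci_hi, p = tab$p,
               ph_p = if (is.null(ph)) NA_real_ else ph$table$p[match(tab$term, ph$table$term)],
               ph_global_p = if (is.null(ph)) NA_real_ else ph$global_p,
               n = fit$n, n_event = fit$n_event,
               note = if (isTRUE(fit$diverged)) "diverged" else "",
               stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(model = model_label, window = format(window), term = NA_character_,
               hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
               ph_p = NA_real_, ph_global_p = NA_real_, n = NA_integer_,
               n_event = NA_integer_, note = conditionMessage(e),
               stringsAsFactors = FALSE)
  })
  out
}

#' Univariate Cox analysis of one variable across time windows
#'
#' @param records clinical table ([survival_records()]).
#' @param variable covariate column name; factors are contrasted against
#'   their first (reference) level.
#' @param windows list of [time_window()]s or 2-vectors.
#' @return data.frame of report rows (one per contrast per window);
#'   windows where the model cannot be fitted (e.g. no events) carry NA
#'   estimates and the failure message in `note`.
#' @export
run_univariate <- function(records, variable,
                           windows = list(c(0, 10), c(0, 5), c(5, 10))) {
  windows <- lapply(windows, function(w) if (inherits(w, "time_window")) w else time_window(w[1], w[2]))
  do.call(rbind, lapply(windows, function(w)
    fit_rows(records, variable, w, paste0("univariate:", variable))))
}

#' Multivariate Cox analysis over one window
#'
#' Joint model of the clinical covariates and the biomarker group with
#' complete-case handling; constant covariates (e.g. nodal status in a
#' node-negative stratum) are dropped with a log entry.
#'
#' @inheritParams run_univariate
#' @param covariates character vector of covariate columns.
#' @param window a [time_window()] or 2-vector.
#' @export
run_multivariate <- function(records, covariates, window) {
  if (!inherits(window, "time_window")) window <- time_window(window[1], window[2])
  fit_rows(records, covariates, window, "multivariate")
}

#' Continuous-score interaction model
#'
#' Fits `a + b + a:b` over a window with both scores centered at their
#' medians over the full cohort before the product is formed, so the
#' main effects are interpretable at typical score values and the
#' product term is insensitive to the centering choice.
#'
#' @inheritParams run_univariate
#' @param score_a,score_b names of continuous score columns
#'   (default `"mks"`, `"ers"`).
#' @param window a [time_window()] or 2-vector.
#' @return a [cox_fit()] result with terms `a`, `b`, `a_x_b`.
#' @export
run_interaction <- function(records, score_a = "mks", score_b = "ers", window) {
  if (!inherits(window, "time_window")) window <- time_window(window[1], window[2])
  records <- survival_records(records)
  a <- records[[score_a]] - stats::median(records[[score_a]], na.rm = TRUE)
  b <- records[[score_b]] - stats::median(records[[score_b]], na.rm = TRUE)
  records[[score_a]] <- a
  records[[score_b]] <- b
  records[[paste0(score_a, "_x_", score_b)]] <- a * b
  cox_fit(records, c(score_a, score_b, paste0(score_a, "_x_", score_b)), window)
}

#' Run the full time-cohort analysis suite
#'
#' Executes, for every window of the plan, the univariate models and the
#' four-group model; the multivariate model over the plan's multivariate
#' windows; per-group landmark KM curves for every window; and per-group
#' kernel hazard curves over the full follow-up.  Deterministic given
#' `(records, plan)`; model failures are carried as flagged rows, never
#' silently dropped.
#'
#' @param records clinical table including the biomarker `group` column.
#' @param plan an [analysis_plan()].
#' @return an `analysis_report`: list with `cox` (all report rows),
#'   `km` (per window x group curves), `hazard` (per group curves), and
#'   `strata` (named sub-reports when the plan stratifies).
#' @export
run_time_cohort_suite <- function(records, plan = analysis_plan()) {
  stopifnot(inherits(plan, "analysis_plan"))
  records <- survival_records(records)

  if (!is.null(plan$strata)) {
    lev <- unique(stats::na.omit(records[[plan$strata]]))
    sub <- lapply(lev, function(l) {
      run_time_cohort_suite(records[!is.na(records[[plan$strata]]) &
                                      records[[plan$strata]] == l, , drop = FALSE],
                            analysis_plan(windows = lapply(plan$windows, function(w) c(w$t0, w$t1)),
                                          univariate = plan$univariate,
                                          multivariate = plan$multivariate,
                                          mv_windows = lapply(plan$mv_windows, function(w) c(w$t0, w$t1)),
                                          strata = NULL, group_var = plan$group_var))
    })
    names(sub) <- as.character(lev)
  } else sub <- NULL

  vars <- unique(c(plan$univariate, plan$group_var))
  cox_rows <- do.call(rbind, c(
    lapply(vars, function(v) run_univariate(records, v, plan$windows)),
    lapply(plan$mv_windows, function(w) run_multivariate(records, plan$multivariate, w))))

  gv <- records[[plan$group_var]]
  groups <- levels(factor(gv))
  km <- lapply(plan$windows, function(w) {
    curves <- lapply(groups, function(g) {
      r <- records[!is.na(gv) & gv == g, , drop = FALSE]
      tryCatch(km_estimate(landmark_restrict(r, w)), error = function(e) NULL)
    })
    names(curves) <- groups
    curves
  })
  names(km) <- vapply(plan$windows, format, "")

  hazard <- lapply(groups, function(g) {
    r <- records[!is.na(gv) & gv == g, , drop = FALSE]
    if (sum(r$event) == 0L) NULL else kernel_hazard(r)
  })
  names(hazard) <- groups

  structure(list(cox = cox_rows, km = km, hazard = hazard, strata = sub,
                 n = nrow(records), n_event = sum(records$event)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> n = %d, events = %d, %d model rows, %d window(s)\n",
              x$n, x$n_event, nrow(x$cox), length(x$km)))
  if (!is.null(x$strata)) cat("  strata:", paste(names(x$strata), collapse = ", "), "\n")
  invisible(x)
}
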