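#' Build a survival record table
#'
#' Validates the minimal clinical contract used across the package:
#' a `sample_id`, a positive follow-up time in years, and a 0/1 distant
#' event indicator.  Additional covariate columns pass through untouched;
#' missing covariate values stay `NA` and are handled per model
#' (complete-case with logged exclusion counts).
#'
#' @param data data.frame with at least `sample_id`, `time_years`, `event`.
#' @return the validated data.frame.
#' @export
survival_records <- function(data) {
  data <- as.data.frame(data)
  need <- c("sample_id", "time_years", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) lb_stop("clinical table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(data$sample_id)) lb_stop("duplicated sample_id in clinical table")
  if (!is.numeric(data$time_years) || anyNA(data$time_years) || any(data$time_years <= 0))
    lb_stop("time_years must be positive and non-missing")
  if (!all(data$event %in% c(0, 1)))
    lb_stop("event must be 0 (censored) or 1 (distant event)")
  data
}

#' Product-limit (Kaplan-Meier) estimate
#'
#' @param time,event numeric vectors (years; 1 = event, 0 = censored), or
#'   a data.frame accepted by [survival_records()] as first argument.
#' @return a `km_curve`: distinct observed times with at-risk counts,
#'   event counts, survival estimates and Greenwood standard errors.
#'   Censoring at a time equal to an event time is handled after the
#'   events (the usual right-continuous convention).
#' @export
km_estimate <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    d <- survival_records(time); event <- d$event; time <- d$time_years
  }
  stopifnot(length(time) == length(event), length(time) >= 1L)
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * sum d/(n(n-d))
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  se <- surv * sqrt(gw)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 surv = surv, std_err = se, n = length(time),
                 events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, S(max) = %.3f\n",
              x$n, x$events, utils::tail(x$surv, 1)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step function; S(t) = 1 before the first observed time.
#' @param km a [km_estimate()] result.
#' @param t times (years).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    k <- which(km$time <= ti)
    if (length(k) == 0L) 1 else km$surv[max(k)]
  }, 0)
}

#' Define a landmark time window
#'
#' @param t0 landmark (years, >= 0); only patients still event-free
#'   after `t0` enter the window.
#' @param t1 end of window (years, may be `Inf`); follow-up beyond `t1`
#'   is administratively censored at `t1`.
#' @export
time_window <- function(t0, t1) {
  stopifnot(is.numeric(t0), is.numeric(t1), length(t0) == 1, length(t1) == 1)
  if (!(t0 >= 0 && t0 < t1)) lb_stop("need 0 <= t0 < t1")
  structure(list(t0 = t0, t1 = t1), class = "time_window")
}

#' @export
format.time_window <- function(x, ...) {
  sprintf("%g-%s yr", x$t0, if (is.finite(x$t1)) sprintf("%g", x$t1) else "Inf")
}

#' @export
print.time_window <- function(x, ...) { cat("<time_window>", format(x), "\n"); invisible(x) }

#' Restrict records to a landmark window
#'
#' Keeps only patients with follow-up strictly beyond the landmark `t0`
#' (event-free at the landmark), re-origins time to `t - t0`, and
#' administratively censors at `t1`.  Events exactly at `t1` count inside
#' the window (half-open `(t0, t1]`).
#'
#' @param records a [survival_records()] table.
#' @param window a [time_window()].
#' @return the restricted records with transformed `time_years`/`event`.
#' @export
landmark_restrict <- function(records, window) {
  records <- survival_records(records)
  stopifnot(inherits(window, "time_window"))
  keep <- records$time_years > window$t0
  if (!any(keep)) lb_stop("empty risk set at landmark t0 = %g", window$t0)
  out <- records[keep, , drop = FALSE]
  t <- out$time_years - window$t0
  w <- window$t1 - window$t0
  over <- t > w
  out$event[over] <- 0
  t[over] <- w
  out$time_years <- t
  rownames(out) <- NULL
  out
}
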