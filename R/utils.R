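# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
lb_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
lb_warn <- function(...) warning(sprintf(...), call. = FALSE)

# message-level run log used by readers/orchestrators; collected via
# withCallingHandlers() in the CLI so exclusion accounting ends up in the log
#' @noRd
lb_log <- function(...) message(sprintf(...))

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# quantile type 7 (linear interpolation) is R's default; used for medians
# and tertiles so that cutpoints are reproducible across platforms
#' @noRd
lb_quantile <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
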