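# Cox proportional-hazards fitting by Newton-Raphson on the Efron
# partial likelihood.  The implementation keeps the per-event risk-set
# sums it computes, so the proportional-hazards diagnostic can reuse them.

# log partial likelihood, score and observed information at beta.
# X, time, status must be sorted by decreasing time.
#' @noRd
cox_derivs <- function(beta, X, time, status) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                       # guard overflow; cancels in ratios
  w <- exp(eta)
  cw <- cumsum(w)
  cwx <- apply(X * w, 2, cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)
  # upper-triangle cross-product cumulative sums
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, ut[, 1], drop = FALSE] * X[, ut[, 2], drop = FALSE]
  cwxx <- apply(XX * w, 2, cumsum)
  if (nrow(ut) == 1L) cwxx <- matrix(cwxx, ncol = 1L)

  ev_times <- unique(time[status == 1])
  ll <- 0; U <- numeric(p); H <- matrix(0, p, p)
  unpack <- function(v) { m <- matrix(0, p, p); m[cbind(ut[,1], ut[,2])] <- v
                          m[cbind(ut[,2], ut[,1])] <- v; m }
  for (tk in ev_times) {
    m_k <- max(which(time == tk))             # prefix = risk set {time >= tk}
    D <- which(time == tk & status == 1)
    d <- length(D)
    S0 <- cw[m_k]; S1 <- cwx[m_k, ]; S2 <- unpack(cwxx[m_k, ])
    wd <- w[D]
    s0d <- sum(wd)
    s1d <- drop(crossprod(X[D, , drop = FALSE], wd))
    s2d <- unpack(colSums(XX[D, , drop = FALSE] * wd))
    ll <- ll + sum(eta[D])
    U <- U + colSums(X[D, , drop = FALSE])
    for (l in seq_len(d) - 1) {
      f <- l / d
      den <- S0 - f * s0d
      mu <- (S1 - f * s1d) / den
      ll <- ll - log(den)
      U <- U - mu
      H <- H + (S2 - f * s2d) / den - tcrossprod(mu)
    }
  }
  list(loglik = ll, score = U, imat = H)
}

# expand covariates to a numeric design matrix; factors against their
# first (reference) level; constant columns dropped with a log line
#' @noRd
cox_design <- function(records, covariates) {
  miss <- setdiff(covariates, names(records))
  if (length(miss)) lb_stop("covariate(s) not in records: %s", paste(miss, collapse = ", "))
  dat <- records[, covariates, drop = FALSE]
  cc <- stats::complete.cases(dat)
  if (any(!cc)) lb_log("complete-case exclusion: %d record(s) with missing covariates dropped", sum(!cc))
  dat <- droplevels(dat[cc, , drop = FALSE])
  single <- vapply(dat, function(v)
    (is.factor(v) && nlevels(v) < 2L) || length(unique(v)) == 1L, TRUE)
  if (any(single)) {
    lb_log("constant covariate column(s) dropped: %s",
           paste(names(dat)[single], collapse = ", "))
    dat <- dat[, !single, drop = FALSE]
  }
  if (ncol(dat) == 0L) lb_stop("no usable covariate columns after expansion")
  X <- stats::model.matrix(~ ., data = dat)[, -1, drop = FALSE]
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    lb_log("constant covariate column(s) dropped: %s",
           paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0L) lb_stop("no usable covariate columns after expansion")
  list(X = X, keep = cc)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron-corrected partial likelihood by Newton-Raphson
#' (up to 50 iterations, step-halving, convergence when the largest
#' information-scaled step falls below 1e-8).  Standard errors come from
#' the inverse observed information; confidence intervals are Wald
#' `exp(beta +/- 1.96 se)` and p-values are two-sided Wald tests.
#'
#' @param records a [survival_records()] table.
#' @param covariates character vector of covariate column names; factor
#'   columns are expanded against their first level, which is the
#'   reference category.
#' @param window optional [time_window()]; records are passed through
#'   [landmark_restrict()] first.
#' @return a `cox_result` with a coefficient table (`beta`, `se`, `hr`,
#'   95% CI, Wald `z`, `p`), the log partial likelihood, counts, and the
#'   fitted internals reused by [schoenfeld_ph_test()].  A monotone
#'   likelihood (complete separation) is flagged via `diverged = TRUE`
#'   and a warning rather than an error.
#' @export
cox_fit <- function(records, covariates, window = NULL) {
  records <- survival_records(records)
  if (!is.null(window)) records <- landmark_restrict(records, window)
  des <- cox_design(records, covariates)
  records <- records[des$keep, , drop = FALSE]
  X <- des$X
  if (sum(records$event) == 0L) lb_stop("no events in the fitted window")

  ord <- order(records$time_years, decreasing = TRUE)
  Xs <- X[ord, , drop = FALSE]
  ts <- records$time_years[ord]
  ds <- records$event[ord]
  xbar <- colMeans(Xs)
  Xc <- sweep(Xs, 2, xbar)                    # centering stabilizes exp(eta)
  p <- ncol(Xc)
  beta <- numeric(p)
  dv <- cox_derivs(beta, Xc, ts, ds)
  diverged <- FALSE
  for (it in seq_len(50L)) {
    step <- tryCatch(solve(dv$imat, dv$score), error = function(e)
      lb_stop("singular information matrix (collinear covariates?)"))
    beta_new <- beta + step
    dv_new <- cox_derivs(beta_new, Xc, ts, ds)
    halved <- 0L
    while (dv_new$loglik < dv$loglik - 1e-10 && halved < 20L) {
      step <- step / 2
      beta_new <- beta + step
      dv_new <- cox_derivs(beta_new, Xc, ts, ds)
      halved <- halved + 1L
    }
    beta <- beta_new; dv <- dv_new
    if (max(abs(step)) < 1e-8) break
    if (it == 50L || max(abs(beta)) > 20) {
      diverged <- max(abs(beta)) > 20
      if (diverged) {
        lb_warn("monotone partial likelihood: coefficient diverging (complete separation?)")
        break
      }
    }
  }
  var <- solve(dv$imat)
  se <- sqrt(diag(var))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  coef_tab <- data.frame(term = colnames(X), beta = beta, se = se,
                         hr = exp(beta),
                         ci_lo = exp(beta - 1.959964 * se),
                         ci_hi = exp(beta + 1.959964 * se),
                         z = z, p = pval, row.names = NULL,
                         stringsAsFactors = FALSE)
  structure(list(coefficients = coef_tab, loglik = dv$loglik,
                 n = nrow(X), n_event = sum(records$event),
                 window = window, diverged = diverged,
                 var = var, imat = dv$imat, beta = beta,
                 X = Xc, time = ts, status = ds),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d%s%s\n", x$n, x$n_event,
              if (!is.null(x$window)) paste0(", window ", format(x$window)) else "",
              if (isTRUE(x$diverged)) ", DIVERGED" else ""))
  tab <- x$coefficients
  tab$hr <- signif(tab$hr, digits); tab$ci_lo <- signif(tab$ci_lo, digits)
  tab$ci_hi <- signif(tab$ci_hi, digits); tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "hr", "ci_lo", "ci_hi", "p")], row.names = FALSE)
  invisible(x)
}
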