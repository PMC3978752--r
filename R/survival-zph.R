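# Proportional-hazards diagnostic based on scaled Schoenfeld residuals
# (Grambsch-Therneau correlation-with-time score test).

#' Test the proportional-hazards assumption
#'
#' Computes per-event Schoenfeld residuals from a fitted Cox model,
#' scales them by the inverse information, and tests their correlation
#' with transformed time.  A trend of the scaled residuals in time means
#' the covariate's log hazard ratio is not constant.  Reported are a
#' chi-square statistic and p-value per covariate plus a global test
#' across all covariates.
#'
#' @param fit a [cox_fit()] result.
#' @param transform time transform for the correlation: `"km"` (left-
#'   continuous Kaplan-Meier transform, the conventional default),
#'   `"identity"`, or `"rank"`.
#' @return a `ph_test` with a per-covariate table and `global_p`.
#' @export
schoenfeld_ph_test <- function(fit, transform = c("km", "identity", "rank")) {
  stopifnot(inherits(fit, "cox_result"))
  transform <- match.arg(transform)
  d <- fit$n_event
  if (d < 3L) lb_stop("proportional-hazards test needs at least 3 events (got %d)", d)

  X <- fit$X; time <- fit$time; status <- fit$status   # sorted by decreasing time
  p <- ncol(X)
  eta <- drop(X %*% fit$beta); eta <- eta - max(eta)
  w <- exp(eta)
  cw <- cumsum(w)
  cwx <- apply(X * w, 2, cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)

  ev_times <- unique(time[status == 1])
  res <- matrix(0, d, p, dimnames = list(NULL, colnames(X)))
  gt <- numeric(d)
  row <- 1L
  for (tk in ev_times) {
    m_k <- max(which(time == tk))
    D <- which(time == tk & status == 1)
    dk <- length(D)
    S0 <- cw[m_k]; S1 <- cwx[m_k, ]
    wd <- w[D]
    s0d <- sum(wd); s1d <- drop(crossprod(X[D, , drop = FALSE], wd))
    # Efron: average the l-adjusted risk-set means over the tie group
    mu <- Reduce(`+`, lapply(seq_len(dk) - 1, function(l)
      (S1 - (l / dk) * s1d) / (S0 - (l / dk) * s0d))) / dk
    for (i in D) {
      res[row, ] <- X[i, ] - mu
      gt[row] <- tk
      row <- row + 1L
    }
  }

  g <- switch(transform,
    identity = gt,
    rank = rank(gt),
    km = {
      km <- km_estimate(time, status)
      # left-continuous: survival just before each event time
      1 - vapply(gt, function(t) {
        k <- which(km$time < t)
        if (length(k) == 0L) 1 else km$surv[max(k)]
      }, 0)
    })
  g <- g - mean(g)
  sg2 <- sum(g^2)

  u <- drop(crossprod(res, g))                      # p-vector
  vu <- drop(fit$var %*% u)
  chisq <- d * vu^2 / (diag(fit$var) * sg2)
  pval <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  global_chisq <- d * drop(crossprod(u, vu)) / sg2
  global_p <- stats::pchisq(global_chisq, df = p, lower.tail = FALSE)

  structure(list(table = data.frame(term = colnames(X), chisq = chisq,
                                    df = 1, p = pval, row.names = NULL,
                                    stringsAsFactors = FALSE),
                 global_chisq = global_chisq, global_df = p,
                 global_p = global_p, transform = transform,
                 residuals = res, g_time = gt),
            class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat(sprintf("<ph_test> transform = %s\n", x$transform))
  tab <- x$table; tab$chisq <- signif(tab$chisq, 4); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("GLOBAL chisq = %.4g, df = %d, p = %.3g\n",
              x$global_chisq, x$global_df, x$global_p))
  invisible(x)
}
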