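# fixtures and independent oracles used across test files

# small expression matrix with named genes/samples
make_expr <- function(genes = 5, samples = 4, seed = 1, gene_ids = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples), genes, samples,
              dimnames = list(gene_ids %||% sprintf("G%02d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  expression_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal clinical table
make_records <- function(time, event, ...) {
  data.frame(sample_id = sprintf("r%03d", seq_along(time)),
             time_years = time, event = event, ...,
             stringsAsFactors = FALSE)
}

# two-group exponential survival data with true hazard ratio `hr`
sim_exp_two_group <- function(n, base_rate = 0.1, hr = 1, cens_max = 20) {
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, base_rate * hr^x)
  cens <- runif(n, 0, cens_max)
  make_records(pmin(t, cens), as.integer(t <= cens), x = x)
}

# independent Efron partial log-likelihood for one binary covariate,
# computed straight from the definition (risk/death sets by brute force)
efron_loglik_binary <- function(beta_grid, time, event, x) {
  ev <- sort(unique(time[event == 1]))
  ll <- numeric(length(beta_grid))
  for (tk in ev) {
    R <- which(time >= tk)
    D <- which(time == tk & event == 1)
    d <- length(D)
    n1R <- sum(x[R] == 1); n0R <- sum(x[R] == 0)
    n1D <- sum(x[D] == 1); n0D <- sum(x[D] == 0)
    ll <- ll + beta_grid * n1D
    for (l in seq_len(d) - 1) {
      SR <- n0R + n1R * exp(beta_grid)
      SD <- n0D + n1D * exp(beta_grid)
      ll <- ll - log(SR - (l / d) * SD)
    }
  }
  ll
}

# order-statistic quantile oracle (type 7): sort and interpolate
quantile7_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  unname(xs[lo] + (h - lo) * (xs[pmin(lo + 1, length(xs))] - xs[lo]))
}

# the fixed 12-record Cox fixture used by the oracle-equivalence checks
cox_fixture_12 <- function() {
  make_records(time = c(1, 1, 2, 3, 3, 3, 4, 5, 6, 7, 8, 9),
               event = c(1, 0, 1, 1, 1, 0, 1, 0, 1, 1, 0, 1),
               x = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1, 0))
}

# letrozole-like response records with the paper's printed counts:
# high-MKS baseline, 15 low-ERS (7 responders), 11 high-ERS (11 responders)
paper_response_records <- function() {
  data.frame(
    sample_id = sprintf("L%02d", 1:26),
    mks_level = "high",
    ers_level = rep(c("low", "high"), c(15, 11)),
    clinical_response = factor(
      c(rep("responder", 7), rep("non-responder", 8), rep("responder", 11)),
      levels = c("non-responder", "responder", "unknown")),
    mks_14 = NA_real_, mks_90 = NA_real_,
    delta_14 = NA_real_, delta_90 = NA_real_,
    stringsAsFactors = FALSE)
}
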