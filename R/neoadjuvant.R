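# Neoadjuvant letrozole arm: clinical response labelling, molecular
# response (proliferation-score change on treatment), and the
# association between baseline estrogen-related score and response.

#' Classify clinical response from tumor volume change
#'
#' A volume reduction strictly greater than 50% over the treatment
#' period is a responder; at or below 50% a non-responder; missing
#' volume data gives `unknown`.
#'
#' @param volume_change_percent signed percent volume reduction
#'   (reduction positive).
#' @return factor with levels `non-responder`, `responder`, `unknown`.
#' @export
classify_clinical_response <- function(volume_change_percent) {
  lab <- ifelse(is.na(volume_change_percent), "unknown",
                ifelse(volume_change_percent > 50, "responder", "non-responder"))
  factor(lab, levels = c("non-responder", "responder", "unknown"))
}

#' Molecular response: proliferation-score change on treatment
#'
#' Molecular response is downregulation of the proliferation score
#' under therapy: `delta_t = MKS(day t) - MKS(day 0)`, negative values
#' meaning downregulation.  A sample missing the day-0 matrix cannot be
#' assessed; a sample missing a later timepoint gets `NA` for that
#' delta (logged).
#'
#' @param expr_by_day named list of [expression_matrix()] objects with
#'   names `"0"`, `"14"`, `"90"` (day 0 mandatory, at least one later
#'   day present).  Samples are matched by id across timepoints.
#' @param mks_set the proliferation [gene_set()]
#'   (default `default_gene_sets("mks")`).
#' @return data.frame `sample_id`, `mks_0`, `mks_14`, `mks_90`,
#'   `delta_14`, `delta_90` over the day-0 samples.
#' @export
molecular_response <- function(expr_by_day, mks_set = default_gene_sets("mks")) {
  if (!"0" %in% names(expr_by_day)) lb_stop("day-0 expression is required")
  later <- intersect(c("14", "90"), names(expr_by_day))
  if (length(later) == 0L) lb_stop("need expression at day 14 and/or day 90")
  s0 <- compute_score(expr_by_day[["0"]], mks_set)
  out <- data.frame(sample_id = names(s0), mks_0 = as.numeric(s0),
                    mks_14 = NA_real_, mks_90 = NA_real_,
                    stringsAsFactors = FALSE)
  for (day in later) {
    st <- compute_score(expr_by_day[[day]], mks_set)
    idx <- match(out$sample_id, names(st))
    if (anyNA(idx))
      lb_log("day %s: %d sample(s) missing, delta set NA", day, sum(is.na(idx)))
    out[[paste0("mks_", day)]] <- as.numeric(st)[idx]
  }
  out$delta_14 <- out$mks_14 - out$mks_0
  out$delta_90 <- out$mks_90 - out$mks_0
  out
}

#' Response rates and score dynamics by estrogen-related level
#'
#' Restricted (by default) to tumors with high baseline proliferation,
#' compares clinical response rates between baseline low- and high-ERS
#' tumors (association tested on the 2x2 of responder/non-responder by
#' ERS level, unknowns excluded from denominators) and compares the
#' absolute proliferation score at day 14 and day 90 between the two
#' ERS levels by Wilcoxon rank-sum (the baseline-adjusted deltas are
#' reported as a secondary comparison).
#'
#' @param records data.frame with columns `sample_id`, `clinical_response`
#'   (as from [classify_clinical_response()]), `mks_level`, `ers_level`
#'   (baseline levels), `mks_14`, `mks_90`, `delta_14`, `delta_90`.
#' @param high_mks_only restrict to baseline high-MKS tumors (default TRUE).
#' @param method association test passed to [contingency_test()].
#' @return list with per-level counts and rates, `p_association`
#'   (requested method), `p_fisher` (always reported alongside),
#'   `p_wilcoxon_14`, `p_wilcoxon_90` on absolute scores, and
#'   `p_wilcoxon_delta_14`, `p_wilcoxon_delta_90` on deltas.
#' @export
compare_response_by_ers <- function(records, high_mks_only = TRUE,
                                    method = c("chi2_cc", "fisher")) {
  method <- match.arg(method)
  need <- c("clinical_response", "mks_level", "ers_level")
  miss <- setdiff(need, names(records))
  if (length(miss)) lb_stop("records lack column(s): %s", paste(miss, collapse = ", "))
  r <- records
  if (high_mks_only) r <- r[!is.na(r$mks_level) & r$mks_level == "high", , drop = FALSE]
  for (lev in c("low", "high"))
    if (!any(r$ers_level == lev, na.rm = TRUE))
      lb_stop("no samples with ERS level '%s' in the analysis set", lev)

  known <- !is.na(r$clinical_response) & r$clinical_response != "unknown"
  if (any(!known))
    lb_log("response denominators exclude %d sample(s) with unknown clinical response", sum(!known))
  k <- r[known, , drop = FALSE]
  cnt <- function(lev, resp) sum(k$ers_level == lev & k$clinical_response == resp)
  n_low <- sum(k$ers_level == "low"); n_high <- sum(k$ers_level == "high")
  resp_low <- cnt("low", "responder"); resp_high <- cnt("high", "responder")
  tab <- matrix(c(resp_low, n_low - resp_low, resp_high, n_high - resp_high),
                nrow = 2, byrow = TRUE,
                dimnames = list(ers = c("low", "high"),
                                response = c("responder", "non-responder")))
  wil <- function(col) {
    x <- r[[col]][r$ers_level == "low"]; y <- r[[col]][r$ers_level == "high"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) NA_real_ else wilcoxon_ranksum(x, y)$p
  }
  list(table = tab,
       rate_low_ers = resp_low / n_low,
       rate_high_ers = resp_high / n_high,
       n_low_ers = n_low, n_high_ers = n_high,
       p_association = contingency_test(tab, method)$p,
       p_fisher = contingency_test(tab, "fisher")$p,
       p_wilcoxon_14 = wil("mks_14"),
       p_wilcoxon_90 = wil("mks_90"),
       p_wilcoxon_delta_14 = wil("delta_14"),
       p_wilcoxon_delta_90 = wil("delta_90"))
}
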