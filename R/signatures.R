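#' Compute a gene-set signature score
#'
#' The score of a sample is the arithmetic mean of the expression values
#' of the signature genes present in the matrix, on the same (log) scale
#' as the input.  Rows sharing a gene id are averaged before scoring
#' (probe-set collapsing).  Genes absent from the matrix are dropped with
#' a warning; if no signature gene is present this is an error.
#'
#' @param expr an [expression_matrix()] (or coercible matrix).
#' @param set a [gene_set()].
#' @return named numeric vector of per-sample scores with attributes
#'   `signature` (the set name) and `n_genes` (genes actually used).
#' @export
compute_score <- function(expr, set) {
  expr <- expression_matrix(unclass(expr))
  stopifnot(inherits(set, "gene_set"))
  hit <- set$gene_ids %in% rownames(expr)
  if (!any(hit))
    lb_stop("no gene of set '%s' found in expression matrix (missing: %s)",
            set$name, paste(set$gene_ids, collapse = ", "))
  if (!all(hit))
    lb_warn("gene set '%s': %d/%d genes absent from matrix, dropped (%s)",
            set$name, sum(!hit), length(hit),
            paste(set$gene_ids[!hit], collapse = ", "))
  sub <- expr[set$gene_ids[hit], , drop = FALSE]
  s <- colMeans(sub)
  attr(s, "signature") <- set$name
  attr(s, "n_genes") <- sum(hit)
  s
}

#' Compute a score threshold on a reference cohort
#'
#' Cutpoints are computed once on a declared set of reference samples and
#' can then be applied to any cohort.  The median uses linear
#' interpolation for even n; tertile cutpoints are the 33.33rd and
#' 66.67th percentiles.
#'
#' @param scores named per-sample score vector from [compute_score()].
#' @param reference_samples sample ids defining the cutpoint(s); default
#'   all scored samples.
#' @param kind `"median"` or `"tertile"`.
#' @return a `score_threshold` object.
#' @export
compute_threshold <- function(scores, reference_samples = names(scores),
                              kind = c("median", "tertile")) {
  kind <- match.arg(kind)
  if (length(reference_samples) == 0L) lb_stop("empty reference sample set")
  if (!all(reference_samples %in% names(scores)))
    lb_stop("reference samples absent from scores: %s",
            paste(setdiff(reference_samples, names(scores)), collapse = ", "))
  x <- scores[reference_samples]
  need <- if (kind == "median") 2L else 3L
  if (length(x) < need)
    lb_stop("need at least %d reference samples for %s threshold", need, kind)
  cut <- if (kind == "median") lb_quantile(x, 0.5) else
    lb_quantile(x, c(1, 2) / 3)
  structure(list(signature = attr(scores, "signature") %||% "score",
                 kind = kind, cutpoints = cut,
                 reference_samples = reference_samples),
            class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("<score_threshold> %s %s at %s (n ref = %d)\n", x$signature,
              x$kind, paste(signif(x$cutpoints, 5), collapse = ", "),
              length(x$reference_samples)))
  invisible(x)
}

#' Median-split scores into low/high levels
#'
#' Scores strictly above the cutpoint are `high`; scores at or below it
#' are `low` (the convention is that "high" means above the median, so a
#' tie at the cutpoint is low).
#'
#' @param scores per-sample score vector.
#' @param threshold a median [compute_threshold()].
#' @return factor with levels `low`, `high`, named by sample.
#' @export
dichotomize <- function(scores, threshold) {
  stopifnot(inherits(threshold, "score_threshold"))
  if (threshold$kind != "median") lb_stop("dichotomize needs a median threshold")
  lev <- ifelse(scores > threshold$cutpoints[1], "high", "low")
  out <- factor(lev, levels = c("low", "high"))
  names(out) <- names(scores)
  out
}

#' Assign scores to tertiles
#'
#' T1 is the lowest tertile; values exactly at a cutpoint go to the lower
#' tertile.  If all reference scores coincide the cutpoints collapse and
#' every sample lands in T1 (degenerate, warned).
#'
#' @inheritParams dichotomize
#' @return factor with levels `T1`, `T2`, `T3`, named by sample.
#' @export
tertile_assign <- function(scores, threshold) {
  stopifnot(inherits(threshold, "score_threshold"))
  if (threshold$kind != "tertile") lb_stop("tertile_assign needs a tertile threshold")
  cut <- threshold$cutpoints
  if (cut[1] >= cut[2]) lb_warn("degenerate tertile cutpoints (all scores equal?)")
  lev <- ifelse(scores <= cut[1], "T1", ifelse(scores <= cut[2], "T2", "T3"))
  out <- factor(lev, levels = c("T1", "T2", "T3"))
  names(out) <- names(scores)
  out
}

#' Combine proliferation and estrogen levels into the four biomarker groups
#'
#' The 2x2 combination of median-split MKS and ERS levels gives the four
#' groups `lowMKS/highERS` (reference for modelling), `lowMKS/lowERS`,
#' `highMKS/highERS`, `highMKS/lowERS`.
#'
#' @param mks_level,ers_level factors or characters with values
#'   `low`/`high` (vectors of equal length).
#' @return factor with the reference group `lowMKS/highERS` first.
#' @export
assign_group <- function(mks_level, ers_level) {
  mks <- as.character(mks_level); ers <- as.character(ers_level)
  if (length(mks) != length(ers)) lb_stop("level vectors differ in length")
  ok <- function(v) all(v %in% c("low", "high") | is.na(v))
  if (!ok(mks) || !ok(ers)) lb_stop("levels must be 'low' or 'high'")
  lab <- paste0(mks, "MKS/", ers, "ERS")
  lab[is.na(mks) | is.na(ers)] <- NA
  out <- factor(lab, levels = biomarker_group_levels())
  names(out) <- names(mks_level) %||% names(ers_level)
  out
}

#' Biomarker group labels in modelling order (reference first)
#' @export
biomarker_group_levels <- function() {
  c("lowMKS/highERS", "lowMKS/lowERS", "highMKS/highERS", "highMKS/lowERS")
}

#' Score a cohort and assign biomarker groups
#'
#' Convenience wrapper: computes MKS and ERS scores, derives median
#' thresholds on a reference cohort (default: all samples), and returns a
#' per-sample table of scores, levels and the four-group label.
#'
#' @param expr an [expression_matrix()].
#' @param sets named list with `gene_set`s `MKS` and `ERS`
#'   (default [default_gene_sets()]).
#' @param reference_samples samples on which the medians are computed.
#' @return data.frame with columns `sample_id`, `mks`, `ers`,
#'   `mks_level`, `ers_level`, `group`; thresholds in attribute
#'   `"thresholds"`.
#' @export
score_cohort <- function(expr, sets = default_gene_sets(),
                         reference_samples = NULL) {
  mks <- compute_score(expr, sets$MKS)
  ers <- compute_score(expr, sets$ERS)
  reference_samples <- reference_samples %||% names(mks)
  th_m <- compute_threshold(mks, reference_samples, "median")
  th_e <- compute_threshold(ers, reference_samples, "median")
  ml <- dichotomize(mks, th_m)
  el <- dichotomize(ers, th_e)
  out <- data.frame(sample_id = names(mks), mks = as.numeric(mks),
                    ers = as.numeric(ers), mks_level = ml, ers_level = el,
                    group = assign_group(ml, el), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- list(MKS = th_m, ERS = th_e)
  out
}
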