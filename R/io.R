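# Readers/writers for the delimited formats the pipeline consumes.

# sniff tab vs comma from the header line
#' @noRd
detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' First column gene id, header row of sample ids, tab- or
#' comma-delimited (auto-detected).  Rows sharing a gene id are
#' collapsed by their mean with a warning.  Any non-numeric or missing
#' cell is an error naming its location.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) lb_stop("no such file: %s", path)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    lb_stop("non-numeric or missing expression value at gene '%s', sample '%s' ('%s')",
            gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]], vals[bad[1, , drop = FALSE]])
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    lb_warn("collapsing %d duplicated gene id(s) by mean: %s",
            length(dups), paste(dups, collapse = ", "))
    num <- rowsum(num, gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- unique(raw[[1]])
  }
  rownames(num) <- gene_ids
  expression_matrix(num)
}

#' Write an expression matrix as tab-delimited text
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Delimited text with mandatory columns `sample_id`, `time_years` (or
#' `time_months` with `time_unit = "months"`), `event`; optional
#' covariates pass through.  The missing-value token is `NA`.
#'
#' @param path file path.
#' @param time_unit `"years"` or `"months"`; months are divided by 12 on
#'   read.
#' @return a [survival_records()] table.
#' @export
read_clinical <- function(path, time_unit = c("years", "months")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) lb_stop("no such file: %s", path)
  sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (time_unit == "months") {
    src <- if ("time_months" %in% names(d)) "time_months" else "time_years"
    d$time_years <- d[[src]] / 12
    d[[setdiff(src, "time_years")]] <- NULL
  }
  for (v in intersect(c("stage", "nodal", "grade", "grade2", "her2", "group",
                        "mks_level", "ers_level"), names(d)))
    d[[v]] <- factor(d[[v]])
  if ("group" %in% names(d) &&
      all(levels(d$group) %in% biomarker_group_levels()))
    d$group <- factor(d$group, levels = biomarker_group_levels())
  survival_records(d)
}

#' Read gene sets from a JSON config
#'
#' The file maps signature names to gene-id arrays, e.g.
#' `{"MKS": ["AURKA", ...], "ERS": ["ESR1", "PGR", "BCL2", "SCUBE2"]}`.
#'
#' @param path JSON file path.
#' @return named list of [gene_set()]s.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) lb_stop("no such file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) gene_set(nm, raw[[nm]]))
  names(out) <- names(raw)
  out
}

#' Write per-sample scores/levels as delimited text
#'
#' Long format with columns `sample_id`, `signature`, `score`, `level`,
#' `group`, as produced by [score_cohort()].
#'
#' @param scored a [score_cohort()] result.
#' @param path output path.
#' @export
write_scores <- function(scored, path) {
  long <- rbind(
    data.frame(sample_id = scored$sample_id, signature = "MKS",
               score = scored$mks, level = as.character(scored$mks_level),
               group = as.character(scored$group), stringsAsFactors = FALSE),
    data.frame(sample_id = scored$sample_id, signature = "ERS",
               score = scored$ers, level = as.character(scored$ers_level),
               group = as.character(scored$group), stringsAsFactors = FALSE))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-tabulate two clinical variables
#'
#' Counts with column percentages; missing values form their own
#' `Unknown` row (reported, but excluded from the association test, and
#' percentages are computed on the full column including unknowns, the
#' convention of clinical characteristics tables).  The association
#' p-value is chi-square on the known categories, with continuity
#' correction when the known table is 2x2; degenerate tables (a single
#' populated row or column) get `p = NA`.
#'
#' @param clinical data.frame.
#' @param row_var,col_var column names.
#' @return a `crosstab` with `counts`, `col_percent`, `p`.
#' @export
crosstab <- function(clinical, row_var, col_var) {
  for (v in c(row_var, col_var))
    if (!v %in% names(clinical)) lb_stop("variable '%s' not in table", v)
  r <- as.character(clinical[[row_var]]); r[is.na(r)] <- "Unknown"
  cl <- as.character(clinical[[col_var]]); cl[is.na(cl)] <- "Unknown"
  counts <- table(r, cl, dnn = c(row_var, col_var))
  cs <- colSums(counts)
  pct <- 100 * sweep(unclass(counts), 2, pmax(cs, 1L), "/")
  pct[, cs == 0] <- 0
  known <- counts[rownames(counts) != "Unknown", colnames(counts) != "Unknown",
                  drop = FALSE]
  known <- known[rowSums(known) > 0, colSums(known) > 0, drop = FALSE]
  p <- if (nrow(known) < 2L || ncol(known) < 2L) NA_real_
       else if (all(dim(known) == 2L)) contingency_test(known, "chi2_cc")$p
       else suppressWarnings(stats::chisq.test(known, correct = FALSE)$p.value)
  structure(list(counts = counts, col_percent = pct, p = p,
                 row_var = row_var, col_var = col_var),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("<crosstab> %s x %s (p = %s)\n", x$row_var, x$col_var,
              if (is.na(x$p)) "NA" else signif(x$p, 3)))
  print(x$counts)
  invisible(x)
}

#' Serialize an analysis report's model table
#'
#' Writes the Cox rows (variable, HR, CI, p, PH p, window) as
#' tab-delimited text plus per-curve coordinate files.
#'
#' @param report an [run_time_cohort_suite()] result.
#' @param dir output directory (created if absent).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$cox, file.path(dir, "cox_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  km_rows <- do.call(rbind, lapply(names(report$km), function(w)
    do.call(rbind, lapply(names(report$km[[w]]), function(g) {
      cv <- report$km[[w]][[g]]
      if (is.null(cv)) return(NULL)
      data.frame(window = w, group = g, time = cv$time, surv = cv$surv,
                 n_risk = cv$n_risk, n_event = cv$n_event,
                 stringsAsFactors = FALSE)
    }))))
  utils::write.table(km_rows, file.path(dir, "km_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hz_rows <- do.call(rbind, lapply(names(report$hazard), function(g) {
    hc <- report$hazard[[g]]
    if (is.null(hc)) return(NULL)
    data.frame(group = g, time = hc$time, hazard = hc$hazard,
               bandwidth = hc$bandwidth, stringsAsFactors = FALSE)
  }))
  utils::write.table(hz_rows, file.path(dir, "hazard_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
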