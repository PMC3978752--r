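#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of continuous log-scale
#' (log2 assumed) expression values with genes in rows and samples in
#' columns.  Row names are gene identifiers, column names are sample
#' identifiers.  Values are assumed already normalized across samples;
#' no normalization is performed anywhere in this package.
#'
#' @param values numeric matrix (genes x samples) with dimnames, or an
#'   object coercible to one.
#' @return the validated matrix, invisibly classed `"expression_matrix"`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) lb_stop("expression values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L)
    lb_stop("expression matrix needs at least 1 gene and 1 sample")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    lb_stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    lb_stop("duplicated gene ids: %s",
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    lb_stop("duplicated sample ids: %s",
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    lb_stop("expression matrix contains %d non-finite values", sum(!is.finite(values)))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Define a gene set
#'
#' @param name non-empty signature name.
#' @param gene_ids non-empty character vector of unique gene identifiers.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, gene_ids) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    lb_stop("gene set name must be a non-empty string")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) lb_stop("gene set '%s' is empty", name)
  if (anyDuplicated(gene_ids))
    lb_stop("gene set '%s' has duplicated ids", name)
  structure(list(name = name, gene_ids = gene_ids), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}

#' Default signature gene sets
#'
#' The proliferation signature (`mks`) is the mean expression of 12
#' mitotic kinases; the estrogen-related signature (`ers`) is the mean of
#' the four ER-associated genes of the Oncotype DX panel (ESR1, PGR,
#' BCL2, SCUBE2).  The mitotic-kinase list ships as a documented default
#' and both lists are overridable through [read_gene_sets()] because the
#' exact probe sets of the originating study are platform-specific.
#'
#' @param which `"mks"`, `"ers"`, or `"all"` (a named list of both).
#' @return a [gene_set()] or list of them.
#' @export
default_gene_sets <- function(which = c("all", "mks", "ers")) {
  which <- match.arg(which)
  mks <- gene_set("MKS", c("AURKA", "AURKB", "BUB1", "BUB1B", "CDK1", "CHEK1",
                           "MELK", "NEK2", "PBK", "PLK1", "PLK4", "TTK"))
  ers <- gene_set("ERS", c("ESR1", "PGR", "BCL2", "SCUBE2"))
  switch(which, mks = mks, ers = ers, all = list(MKS = mks, ERS = ers))
}
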