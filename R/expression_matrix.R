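#' Gene-by-sample expression matrix with unit and layer tags
#'
#' The central container of the package: a numeric gene x sample matrix of
#' non-negative abundances, tagged with the measurement unit and the omics
#' layer. Missing measurements are explicit `NA`s, never silent zeros; all
#' statistics downstream use pairwise-complete samples.
#'
#' @param values Numeric matrix, genes in rows (rownames required), samples
#'   in columns (colnames required). Values must be finite and >= 0 or `NA`.
#' @param unit One of `"FPKM"`, `"iBAQ"`, `"mmol_per_gDW"`, `"fraction"`.
#' @param layer One of `"mRNA"`, `"protein"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `unit`, `layer`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' em <- expression_matrix(m, unit = "FPKM", layer = "mRNA")
#' em
#' @export
expression_matrix <- function(values, unit, layer) {
  unit <- match.arg(unit, em_units())
  layer <- match.arg(layer, em_layers())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(values) & (!is.finite(values) | values < 0),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "negative or non-finite abundance at gene '%s', sample '%s'",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
      call. = FALSE)
  }
  structure(list(values = values, unit = unit, layer = layer),
            class = "ExpressionMatrix")
}

em_units <- function() c("FPKM", "iBAQ", "mmol_per_gDW", "fraction")
em_layers <- function() c("mRNA", "protein")

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$layer, x$unit))
  n_na <- sum(is.na(x$values))
  if (n_na) cat(sprintf("  %d missing value(s)\n", n_na))
  show_n <- min(4L, nrow(x$values))
  show_m <- min(4L, ncol(x$values))
  print(x$values[seq_len(show_n), seq_len(show_m), drop = FALSE])
  invisible(x)
}

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
em_genes <- function(x) rownames(x$values)

#' @rdname em_genes
#' @export
em_samples <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x An `ExpressionMatrix`.
#' @param genes,samples Character vectors (or indices) selecting rows/columns;
#'   `NULL` keeps all.
#' @return An `ExpressionMatrix`.
#' @export
em_subset <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) {
    if (is.character(genes) && !all(genes %in% rownames(v))) {
      stop("unknown gene identifier(s): ",
           paste(setdiff(genes, rownames(v)), collapse = ", "), call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples) && !all(samples %in% colnames(v))) {
      stop("unknown sample identifier(s): ",
           paste(setdiff(samples, colnames(v)), collapse = ", "), call. = FALSE)
    }
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, x$unit, x$layer)
}

#' Pair the mRNA and protein layers on their shared genes
#'
#' Intersects the gene sets of an mRNA and a protein matrix (exact,
#' case-sensitive identifier matching) over an identical sample set, and
#' reorders both layers identically. This is the operation that defines the
#' paired transcript-protein core on which translation rates and gene-wise
#' correlations are computed.
#'
#' @param mrna `ExpressionMatrix` with `layer = "mRNA"`.
#' @param protein `ExpressionMatrix` with `layer = "protein"`.
#' @return An object of class `PairedOmics`: list with elements `mrna`,
#'   `protein` (both reordered to the common gene set) and `n_genes`.
#' @export
pair_layers <- function(mrna, protein) {
  stopifnot(inherits(mrna, "ExpressionMatrix"),
            inherits(protein, "ExpressionMatrix"))
  if (mrna$layer != "mRNA" || protein$layer != "protein") {
    stop("pair_layers() expects an mRNA matrix and a protein matrix",
         call. = FALSE)
  }
  if (!identical(sort(em_samples(mrna)), sort(em_samples(protein)))) {
    stop("mRNA and protein matrices must share an identical sample set",
         call. = FALSE)
  }
  common <- intersect(em_genes(mrna), em_genes(protein))
  if (!length(common)) stop("gene sets are disjoint", call. = FALSE)
  out <- list(
    mrna = em_subset(mrna, genes = common, samples = em_samples(mrna)),
    protein = em_subset(protein, genes = common, samples = em_samples(mrna)),
    n_genes = length(common)
  )
  class(out) <- "PairedOmics"
  out
}

#' @export
print.PairedOmics <- function(x, ...) {
  cat(sprintf("PairedOmics: %d transcript-protein pairs across %d samples\n",
              x$n_genes, ncol(x$mrna$values)))
  invisible(x)
}
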