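#' Collapse replicate samples to condition means
#'
#' Averages replicate columns (pairwise-complete) into one column per
#' condition. Gene-wise correlation analyses across a condition series are
#' computed on condition means, one value per steady state.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param design `ConditionDesign` covering every sample.
#' @return An `ExpressionMatrix` with one column per condition.
#' @export
collapse_replicates <- function(matrix, design) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  expression_matrix(condition_means(matrix$values, design),
                    unit = matrix$unit, layer = matrix$layer)
}

# gene x condition means over replicate samples (pairwise-complete)
condition_means <- function(values, design) {
  check_design_covers(design, colnames(values))
  d <- design[match(colnames(values), design$sample), ]
  conds <- unique(d$condition)
  out <- vapply(conds, function(cc) {
    rowMeans(values[, d$condition == cc, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(values)))
  out[is.nan(out)] <- NA_real_
  if (is.null(dim(out))) out <- matrix(out, ncol = length(conds))
  dimnames(out) <- list(rownames(values), conds)
  out
}

# mu per condition, checked for consistency across the condition's samples
condition_mu <- function(design, conditions) {
  mu <- vapply(conditions, function(cc) {
    v <- unique(design$mu[design$condition == cc])
    if (length(v) != 1L) {
      stop("inconsistent growth rate within condition '", cc, "'",
           call. = FALSE)
    }
    v
  }, numeric(1))
  if (any(is.na(mu))) stop("growth rate missing for a condition", call. = FALSE)
  mu
}

#' Impute missing protein degradation rates with the dataset median
#'
#' Genes without a measured first-order protein degradation rate are
#' assigned the median of all measured rates in the dataset, and flagged.
#'
#' @param rates Named numeric vector of measured `k_dP` values (1/h); genes
#'   absent from `rates` (or `NA` in it) are imputed.
#' @param universe Character vector of all gene identifiers to cover.
#' @return A `DegradationRates` data frame with columns `gene`, `kdp`,
#'   `imputed`, and attribute `"median"` (median of measured rates).
#' @export
impute_degradation_rates <- function(rates, universe) {
  measured <- rates[is.finite(rates) & rates > 0]
  if (!length(measured)) {
    stop("no measured degradation rates to impute from", call. = FALSE)
  }
  if (any(is.finite(rates) & rates <= 0)) {
    stop("degradation rates must be > 0", call. = FALSE)
  }
  med <- stats::median(measured)
  kdp <- measured[universe]
  imputed <- !universe %in% names(measured)
  kdp[imputed] <- med
  out <- data.frame(gene = universe, kdp = unname(kdp), imputed = imputed,
                    stringsAsFactors = FALSE)
  attr(out, "median") <- med
  class(out) <- c("DegradationRates", "data.frame")
  out
}

#' Per-gene, per-condition protein translation rates
#'
#' Computes the apparent translation (synthesis) rate per mRNA,
#' `k_sP = C_prot * (k_dP + mu) / C_mRNA` (protein/mRNA/h), from paired
#' absolute protein and mRNA abundances. Replicates are collapsed to
#' condition means first (ratio of means, not mean of ratios), giving one
#' `k_sP` per gene and condition. Conditions where the mRNA mean is zero or
#' missing propagate as missing.
#'
#' @param protein,mrna `ExpressionMatrix` objects in `mmol_per_gDW` over the
#'   same samples; their gene sets are intersected.
#' @param kdp A [impute_degradation_rates()] result covering the paired
#'   genes.
#' @param design `ConditionDesign` covering every sample.
#' @return A `TranslationRateMatrix`: list with `values` (gene x condition),
#'   `mu` (named per-condition growth rates) and `unit`.
#' @export
compute_translation_rates <- function(protein, mrna, kdp, design) {
  stopifnot(inherits(protein, "ExpressionMatrix"),
            inherits(mrna, "ExpressionMatrix"),
            inherits(kdp, "DegradationRates"))
  paired <- pair_layers(mrna, protein)
  pm <- condition_means(paired$protein$values, design)
  mm <- condition_means(paired$mrna$values, design)
  mu <- condition_mu(design, colnames(pm))
  genes <- rownames(pm)
  miss <- setdiff(genes, kdp$gene)
  if (length(miss)) {
    stop("degradation rate missing for gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         "; run impute_degradation_rates() over the paired universe",
         call. = FALSE)
  }
  kd <- stats::setNames(kdp$kdp, kdp$gene)[genes]
  mm[!is.na(mm) & mm == 0] <- NA_real_
  ksp <- pm * outer(kd, mu, `+`) / mm
  structure(list(values = ksp, mu = mu, unit = "protein/mRNA/h"),
            class = "TranslationRateMatrix")
}

#' @export
print.TranslationRateMatrix <- function(x, ...) {
  cat(sprintf("TranslationRateMatrix: %d genes x %d conditions [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Ribosomal fraction of the proteome
#'
#' Per sample, the summed abundance of ribosomal proteins divided by the
#' summed abundance of all detected proteins (mol/mol).
#'
#' @param protein `ExpressionMatrix` of protein abundances.
#' @param ribosomal_genes Character vector of ribosomal gene identifiers;
#'   its intersection with the matrix genes must be non-empty.
#' @return Named numeric vector, sample -> fraction in \[0, 1).
#' @export
ribosome_fraction <- function(protein, ribosomal_genes) {
  stopifnot(inherits(protein, "ExpressionMatrix"))
  ribo <- intersect(ribosomal_genes, em_genes(protein))
  if (!length(ribo)) {
    stop("no ribosomal genes present in the protein matrix", call. = FALSE)
  }
  tot <- colSums(protein$values, na.rm = TRUE)
  rib <- colSums(protein$values[ribo, , drop = FALSE], na.rm = TRUE)
  rib / tot
}

#' @rdname impute_degradation_rates
#' @param path Path to a two-column (`gene`, `kdp`) TSV/CSV of measured
#'   rates.
#' @return For `load_degradation_rates`: a named numeric vector.
#' @export
load_degradation_rates <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("gene", "kdp") %in% names(df))) {
    stop("degradation-rate table needs columns 'gene' and 'kdp'",
         call. = FALSE)
  }
  stats::setNames(as.numeric(df$kdp), as.character(df$gene))
}
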