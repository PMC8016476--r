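#' Scale a growth-rate series by the per-gene regression intercept
#'
#' For each gene, condition means are regressed on the growth rate by
#' ordinary least squares; the gene's values are divided by the fitted
#' y-intercept and log2-transformed. The scaled profile reads as the
#' fold-change relative to a theoretical growth rate of zero. Genes with a
#' non-positive fitted intercept (or an incomplete condition profile) are
#' excluded, with the reason recorded.
#'
#' @param matrix `ExpressionMatrix` (samples are collapsed to condition
#'   means first).
#' @param design `ConditionDesign`; needs >= 3 distinct growth rates.
#' @return A `ScaledMatrix`: list with `values` (gene x condition, log2),
#'   `mode = "GR_intercept"`, `constants` (named per-gene intercepts),
#'   `excluded` (data frame `gene`, `reason`).
#' @export
scale_by_growth_intercept <- function(matrix, design) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  cm <- condition_means(matrix$values, design)
  mu <- condition_mu(design, colnames(cm))
  if (length(unique(mu)) < 3L) {
    stop("need >= 3 distinct growth rates for intercept scaling",
         call. = FALSE)
  }
  complete <- stats::complete.cases(cm)
  excluded <- data.frame(gene = rownames(cm)[!complete],
                         reason = rep("incomplete profile", sum(!complete)),
                         stringsAsFactors = FALSE)
  cmc <- cm[complete, , drop = FALSE]
  fit <- stats::lm(t(cmc) ~ mu)
  intercepts <- stats::coef(fit)[1L, ]
  names(intercepts) <- rownames(cmc)
  bad <- intercepts <= 0
  if (any(bad)) {
    excluded <- rbind(excluded, data.frame(
      gene = names(intercepts)[bad],
      reason = rep("nonpositive intercept", sum(bad)),
      stringsAsFactors = FALSE))
  }
  keep <- cmc[!bad, , drop = FALSE]
  vals <- log2(keep / intercepts[!bad])
  structure(list(values = vals, mode = "GR_intercept",
                 constants = intercepts[!bad], excluded = excluded),
            class = "ScaledMatrix")
}

#' Scale by the mean over a reference sample set
#'
#' For each gene, values are divided by the mean of that gene over the
#' reference samples and log2-transformed. With the severe-nitrogen-
#' restriction reference (the nitrogen-limited Phe and Ile conditions), the
#' scaled profile reads as the fold-change from the most nitrogen-restricted
#' state.
#'
#' @param matrix `ExpressionMatrix` (gene x sample).
#' @param reference_samples Non-empty character vector of reference sample
#'   identifiers, all present in `matrix`.
#' @return A `ScaledMatrix` with `mode = "NM_reference"`; columns are the
#'   samples of `matrix`. Genes with a non-positive reference mean are
#'   excluded with a reason.
#' @export
scale_by_reference_mean <- function(matrix, reference_samples) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!length(reference_samples)) {
    stop("reference sample set is empty", call. = FALSE)
  }
  miss <- setdiff(reference_samples, em_samples(matrix))
  if (length(miss)) {
    stop("reference sample(s) not in matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  v <- matrix$values
  ref_mean <- rowMeans(v[, reference_samples, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(ref_mean) | ref_mean <= 0
  excluded <- data.frame(gene = rownames(v)[bad],
                         reason = rep("nonpositive reference mean", sum(bad)),
                         stringsAsFactors = FALSE)
  keep <- v[!bad, , drop = FALSE]
  structure(list(values = log2(keep / ref_mean[!bad]),
                 mode = "NM_reference",
                 constants = ref_mean[!bad], excluded = excluded),
            class = "ScaledMatrix")
}

#' @export
print.ScaledMatrix <- function(x, ...) {
  cat(sprintf("ScaledMatrix (%s): %d genes x %d columns, %d excluded\n",
              x$mode, nrow(x$values), ncol(x$values), nrow(x$excluded)))
  invisible(x)
}
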