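#' Count theoretically observable tryptic peptides
#'
#' Digests a protein sequence fully tryptically (cleavage C-terminal to K or
#' R, suppressed before P, zero missed cleavages) and counts the peptides
#' whose length falls within the observable window. This is the denominator
#' of the iBAQ quantity.
#'
#' @param sequence Protein sequence (single string over the amino-acid
#'   alphabet, `X` allowed).
#' @param min_len,max_len Observable length window in residues (default
#'   7-30, the standard iBAQ convention).
#' @return Integer count of observable peptides.
#' @examples
#' count_observable_peptides("AAAKAAAAAAR")  # peptides AAAK, AAAAAAR -> 1
#' @export
count_observable_peptides <- function(sequence, min_len = 7L, max_len = 30L) {
  peps <- tryptic_peptides(sequence)
  sum(nchar(peps) >= min_len & nchar(peps) <= max_len)
}

# fully tryptic digest, KP/RP rule, zero missed cleavages
tryptic_peptides <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop("empty protein sequence", call. = FALSE)
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- !chars %in% c(aa_alphabet(), "X")
  if (any(bad)) {
    stop(sprintf("invalid residue '%s' at position %d",
                 chars[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  n <- length(chars)
  cut <- which(chars %in% c("K", "R"))
  cut <- cut[cut < n & chars[cut + 1L] != "P"]
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  substring(sequence, starts, ends)
}

#' Compute iBAQ values from precursor intensities
#'
#' Averages technical-replicate columns (if a grouping is given) and divides
#' each gene's mean intensity by its number of theoretically observable
#' tryptic peptides. Genes with a zero observable count are excluded with a
#' warning rather than divided.
#'
#' @param intensity `ExpressionMatrix` of summed precursor intensities
#'   (unit `"iBAQ"`).
#' @param observable_counts Named integer vector, gene -> observable peptide
#'   count (see [count_observable_peptides()]). Every gene of `intensity`
#'   must be present.
#' @param tech_groups Optional character vector (one entry per column of
#'   `intensity`) assigning columns to technical-replicate groups; columns
#'   in the same group are averaged and the output column carries the group
#'   name. `NULL` keeps columns as they are.
#' @return `ExpressionMatrix` of iBAQ values.
#' @export
compute_ibaq <- function(intensity, observable_counts, tech_groups = NULL) {
  stopifnot(inherits(intensity, "ExpressionMatrix"))
  v <- intensity$values
  if (!is.null(tech_groups)) {
    if (length(tech_groups) != ncol(v)) {
      stop("'tech_groups' must have one entry per column", call. = FALSE)
    }
    groups <- unique(tech_groups)
    v <- matrix(vapply(groups, function(g) {
      rowMeans(v[, tech_groups == g, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(v))), nrow = nrow(v),
    dimnames = list(rownames(v), groups))
    v[is.nan(v)] <- NA_real_
  }
  miss <- setdiff(rownames(v), names(observable_counts))
  if (length(miss)) {
    stop("no observable-peptide count for gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  cnt <- observable_counts[rownames(v)]
  zero <- cnt == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero observable peptides excluded: ",
            paste(utils::head(rownames(v)[zero], 5), collapse = ", "),
            call. = FALSE)
    v <- v[!zero, , drop = FALSE]
    cnt <- cnt[!zero]
  }
  expression_matrix(v / cnt, unit = "iBAQ", layer = intensity$layer)
}

new_calibration_fit <- function(slope, intercept, r2, n, space, signal_unit) {
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n = n, space = space, signal_unit = signal_unit),
            class = "CalibrationFit")
}

#' @export
print.CalibrationFit <- function(x, ...) {
  cat(sprintf(
    "CalibrationFit (%s, %s space): slope %.6g, intercept %.6g, R2 %.4f, n = %d\n",
    x$signal_unit, x$space, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

fit_spikein_core <- function(spikes, space, signal_unit, min_points) {
  keep <- spikes$signal > 0 & spikes$amount > 0
  spikes <- spikes[keep, , drop = FALSE]
  if (nrow(spikes) < min_points) {
    stop("calibration needs >= ", min_points,
         " usable standards, got ", nrow(spikes), call. = FALSE)
  }
  if (space == "log10") {
    fit <- stats::lm(log10(amount) ~ log10(signal), data = spikes)
  } else {
    fit <- stats::lm(amount ~ signal, data = spikes)
  }
  cf <- stats::coef(fit)
  # summary() warns on exact fits (noise-free standards); R2 is still valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (any(!is.finite(cf))) stop("calibration fit is degenerate", call. = FALSE)
  new_calibration_fit(slope = unname(cf[2]), intercept = unname(cf[1]),
                      r2 = r2, n = nrow(spikes), space = space,
                      signal_unit = signal_unit)
}

#' Fit the UPS2 protein calibration
#'
#' Ordinary least squares of log10(known amount) on log10(iBAQ signal),
#' using only standards identified with at least two unique peptides.
#'
#' @param ups2 `SpikeInTable` of UPS2-like standards; the
#'   `n_unique_peptides` column, if present, gates inclusion.
#' @param min_unique_peptides Inclusion threshold (default 2).
#' @return A `CalibrationFit` (slope, intercept, R^2, n, in log10 space).
#' @export
fit_protein_calibration <- function(ups2, min_unique_peptides = 2L) {
  stopifnot(inherits(ups2, "SpikeInTable"))
  if (!is.null(ups2$n_unique_peptides)) {
    ups2 <- ups2[!is.na(ups2$n_unique_peptides) &
                   ups2$n_unique_peptides >= min_unique_peptides, ,
                 drop = FALSE]
  }
  fit_spikein_core(ups2, space = "log10", signal_unit = "iBAQ",
                   min_points = 3L)
}

#' Fit the mRNA spike-in calibration
#'
#' Regression between known absolute concentrations of mRNA standards and
#' their measured FPKM. The default fit space is log10-log10, consistent
#' with the protein procedure and the multi-decade dynamic range of the
#' standards; `space = "linear"` fits on the natural scale instead (such a
#' fit is dominated by the most abundant standards).
#'
#' @param spikes `SpikeInTable` of mRNA standards; needs >= 3 standards
#'   spanning >= 2 decades of known amount.
#' @param space `"log10"` (default) or `"linear"`.
#' @return A `CalibrationFit`.
#' @export
fit_mrna_calibration <- function(spikes, space = c("log10", "linear")) {
  stopifnot(inherits(spikes, "SpikeInTable"))
  space <- match.arg(space)
  usable <- spikes[spikes$signal > 0, , drop = FALSE]
  if (nrow(usable) >= 2L) {
    span <- log10(max(usable$amount) / min(usable$amount))
    if (span < 2) {
      stop("mRNA standards must span >= 2 decades of concentration",
           call. = FALSE)
    }
  }
  fit_spikein_core(spikes, space = space, signal_unit = "FPKM",
                   min_points = 3L)
}

#' Convert a relative-unit matrix to absolute concentrations
#'
#' Applies a spike-in calibration to every value:
#' `10^(slope * log10(signal) + intercept)` for a log10-space fit, or
#' `slope * signal + intercept` for a linear-space fit. Zero signals (and
#' linear-space estimates <= 0) map to missing, never to -Inf or negative
#' concentrations.
#'
#' @param matrix `ExpressionMatrix` whose unit matches the fit's signal
#'   type (`"FPKM"` or `"iBAQ"`).
#' @param fit A `CalibrationFit`.
#' @return `ExpressionMatrix` in `mmol_per_gDW`.
#' @export
apply_calibration <- function(matrix, fit) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(fit, "CalibrationFit"))
  if (matrix$unit != fit$signal_unit) {
    stop(sprintf("unit mismatch: matrix is %s but the fit is for %s",
                 matrix$unit, fit$signal_unit), call. = FALSE)
  }
  v <- matrix$values
  out <- v
  zero <- !is.na(v) & v == 0
  if (fit$space == "log10") {
    out[!zero] <- 10^(fit$slope * log10(v[!zero]) + fit$intercept)
  } else {
    out[!zero] <- fit$slope * v[!zero] + fit$intercept
    out[!is.na(out) & out <= 0] <- NA_real_
  }
  out[zero] <- NA_real_
  expression_matrix(out, unit = "mmol_per_gDW", layer = matrix$layer)
}

#' Scale calibrated mRNA abundances to measured total RNA content
#'
#' Per sample, abundances are multiplied by a factor proportional to
#' (measured total RNA fraction of dry weight) / (summed calibrated mRNA of
#' that sample), normalised so the factor equals 1 for the reference sample
#' (the first column by default, i.e. the first GR condition). This
#' preserves the cross-sample relative totals implied by the bulk RNA
#' measurement without asserting an absolute mRNA:total-RNA ratio.
#'
#' @param calibrated `ExpressionMatrix` in `mmol_per_gDW` (mRNA layer).
#' @param content A [total_content()] table with an `rna_fraction` for every
#'   sample of `calibrated`.
#' @param reference Reference sample id (default: first column).
#' @return `ExpressionMatrix` with rescaled columns.
#' @export
scale_to_total_rna <- function(calibrated, content, reference = NULL) {
  stopifnot(inherits(calibrated, "ExpressionMatrix"),
            inherits(content, "TotalContent"))
  if (is.null(content$rna_fraction)) {
    stop("content table has no 'rna_fraction' column", call. = FALSE)
  }
  samples <- em_samples(calibrated)
  miss <- setdiff(samples, content$sample)
  if (length(miss)) {
    stop("missing total RNA content for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(reference)) reference <- samples[1L]
  frac <- stats::setNames(content$rna_fraction, content$sample)[samples]
  sums <- colSums(calibrated$values, na.rm = TRUE)
  if (any(sums == 0)) {
    stop("sample(s) with zero summed abundance cannot be scaled",
         call. = FALSE)
  }
  raw <- frac / sums
  factor <- raw / raw[[reference]]
  expression_matrix(sweep(calibrated$values, 2, factor, `*`),
                    unit = calibrated$unit, layer = calibrated$layer)
}
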