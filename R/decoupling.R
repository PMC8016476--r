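#' Null-model factors for growth + nitrogen control of gene expression
#'
#' Bundles the multiplicative factors of the physiological null model: under
#' growth-rate control alone, non-CCM transcript abundance and translation
#' rates scale with the growth-rate ratio (transcription tracks RNA
#' polymerase II and translation tracks ribosome content, both proportional
#' to growth rate); nitrogen-state changes multiply mRNA by one global
#' factor and the translation rate by an independent one. CCM genes are
#' exempt from both controls: their factor is exactly 1 in both layers.
#'
#' @param nitrogen_mrna Scalar > 0: mRNA fold-change from the baseline to
#'   the target nitrogen state.
#' @param nitrogen_ksp Scalar > 0: translation-rate fold-change, independent
#'   of the mRNA factor.
#' @param ccm_genes Character vector of CCM gene identifiers (held constant).
#' @return A `NullModelFactors` list.
#' @export
null_model_factors <- function(nitrogen_mrna = 1, nitrogen_ksp = 1,
                               ccm_genes = character(0)) {
  if (nitrogen_mrna <= 0 || nitrogen_ksp <= 0) {
    stop("nitrogen factors must be > 0", call. = FALSE)
  }
  structure(list(nitrogen_mrna = nitrogen_mrna, nitrogen_ksp = nitrogen_ksp,
                 ccm_genes = unique(as.character(ccm_genes))),
            class = "NullModelFactors")
}

#' Derive nitrogen factors from a reference nitrogen-metabolism dataset
#'
#' Estimates the global mRNA and translation-rate fold-changes between two
#' nitrogen states from a reference dataset in which only the nitrogen state
#' varies (growth rate fixed). The mRNA factor is the median, over the
#' majority-cluster (nitrogen-responsive) genes, of mean abundance in the
#' target state divided by mean abundance in the source state; the k_sP
#' factor is computed identically on translation rates.
#'
#' @param paired A [pair_layers()] reference dataset.
#' @param design `ConditionDesign` of the reference samples.
#' @param kdp [impute_degradation_rates()] covering the paired genes.
#' @param majority_genes Character vector of nitrogen-responsive genes (for
#'   example the largest NM cluster).
#' @param from,to Logical: preferred-source status of the source and target
#'   states; conditions are grouped by `design$preferred`.
#' @return List with `mrna_factor` and `ksp_factor`.
#' @export
derive_nitrogen_factors <- function(paired, design, kdp, majority_genes,
                                    from = FALSE, to = TRUE) {
  stopifnot(inherits(paired, "PairedOmics"))
  mm <- condition_means(paired$mrna$values, design)
  state_of <- function(cond) {
    unique(design$preferred[design$condition == cond])
  }
  pref <- vapply(colnames(mm), state_of, logical(1))
  if (!any(pref == from) || !any(pref == to)) {
    stop("reference dataset lacks one of the requested nitrogen states",
         call. = FALSE)
  }
  ksp <- compute_translation_rates(paired$protein, paired$mrna, kdp, design)
  genes <- intersect(majority_genes, rownames(mm))
  if (!length(genes)) stop("no majority-cluster genes in the dataset",
                           call. = FALSE)
  state_mean <- function(m, state) {
    rowMeans(m[genes, pref == state, drop = FALSE], na.rm = TRUE)
  }
  mrna_factor <- stats::median(state_mean(mm, to) / state_mean(mm, from),
                               na.rm = TRUE)
  kv <- ksp$values
  ksp_factor <- stats::median(state_mean(kv, to) / state_mean(kv, from),
                              na.rm = TRUE)
  list(mrna_factor = mrna_factor, ksp_factor = ksp_factor)
}

#' Predict expression and translation rates under the null model
#'
#' Given baseline per-gene values, computes the "calculated" (theoretical)
#' values expected if the growth-rate change and the nitrogen-state change
#' were the only regulatory signals: non-CCM genes are multiplied by
#' `mu_target / mu_baseline` and the respective nitrogen factor in each
#' layer; CCM genes are returned unchanged.
#'
#' @param baseline_mrna,baseline_ksp Named numeric vectors of baseline
#'   condition means (gene -> value); either may be `NULL` to skip a layer.
#' @param factors A [null_model_factors()].
#' @param mu_baseline,mu_target Growth rates (> 0) of the two states.
#' @return List with `mrna` and `ksp` (named vectors, `NULL` where the
#'   input was `NULL`).
#' @export
predict_null_expression <- function(baseline_mrna, baseline_ksp, factors,
                                    mu_baseline, mu_target) {
  stopifnot(inherits(factors, "NullModelFactors"))
  if (mu_baseline <= 0 || mu_target <= 0) {
    stop("growth rates must be > 0", call. = FALSE)
  }
  ratio <- mu_target / mu_baseline
  scale_layer <- function(x, nf) {
    if (is.null(x)) return(NULL)
    if (is.null(names(x))) stop("baseline vectors must be named by gene",
                                call. = FALSE)
    fac <- rep(ratio * nf, length(x))
    fac[names(x) %in% factors$ccm_genes] <- 1
    x * fac
  }
  list(mrna = scale_layer(baseline_mrna, factors$nitrogen_mrna),
       ksp = scale_layer(baseline_ksp, factors$nitrogen_ksp))
}

#' Classify perturbation-specific regulation against the null model
#'
#' Per gene, the deviation `log2(measured / calculated)` is computed; genes
#' within the agreement band (|log2| <= threshold, i.e. 2-fold by default)
#' are `accounted` for by the physiological null model, the rest are called
#' `specific_up` or `specific_down`. Genes with non-positive or missing
#' values in either vector are excluded with a reason.
#'
#' @param measured,calculated Named numeric vectors over a shared gene
#'   universe.
#' @param threshold Agreement half-width on the log2 scale (default 1).
#' @return A `DecouplingResult`: list with `table` (data frame `gene`,
#'   `measured`, `calculated`, `log2_deviation`, `class`), `excluded`
#'   (data frame `gene`, `reason`), `summary` (counts and percentages per
#'   class) and `threshold`.
#' @export
classify_specific_regulation <- function(measured, calculated, threshold = 1) {
  if (is.null(names(measured)) || is.null(names(calculated))) {
    stop("'measured' and 'calculated' must be named by gene", call. = FALSE)
  }
  genes <- intersect(names(measured), names(calculated))
  if (!length(genes)) stop("no shared genes", call. = FALSE)
  m <- measured[genes]
  cc <- calculated[genes]
  bad <- !is.finite(m) | !is.finite(cc) | m <= 0 | cc <= 0
  excluded <- data.frame(gene = genes[bad],
                         reason = rep("nonpositive or missing value", sum(bad)),
                         stringsAsFactors = FALSE)
  genes <- genes[!bad]
  dev <- log2(m[!bad] / cc[!bad])
  cls <- ifelse(dev > threshold, "specific_up",
                ifelse(dev < -threshold, "specific_down", "accounted"))
  counts <- vapply(c("accounted", "specific_up", "specific_down"),
                   function(k) sum(cls == k), integer(1))
  out <- list(
    table = data.frame(gene = genes, measured = unname(m[!bad]),
                       calculated = unname(cc[!bad]),
                       log2_deviation = unname(dev), class = cls,
                       stringsAsFactors = FALSE),
    excluded = excluded,
    summary = data.frame(class = names(counts), n = unname(counts),
                         percent = unname(100 * counts / sum(counts)),
                         stringsAsFactors = FALSE),
    threshold = threshold
  )
  class(out) <- "DecouplingResult"
  out
}

#' @export
print.DecouplingResult <- function(x, ...) {
  cat(sprintf("DecouplingResult (|log2| threshold %.2g): %d genes\n",
              x$threshold, nrow(x$table)))
  print(x$summary, row.names = FALSE)
  if (nrow(x$excluded)) {
    cat(sprintf("%d gene(s) excluded\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' Run the decoupling analysis on a baseline/target dataset pair
#'
#' Convenience wrapper over the full engine: collapses both datasets to
#' condition means, computes baseline and target translation rates from the
#' paired layers, predicts the target under the growth + nitrogen null
#' model, and classifies specific regulation per layer.
#'
#' @param baseline,target Lists with elements `mrna`, `protein`
#'   (`ExpressionMatrix`) and `design` (`ConditionDesign`), each a single
#'   condition (as produced by [simulate_perturbation_pair()]).
#' @param kdp [impute_degradation_rates()] covering the paired genes.
#' @param factors A [null_model_factors()].
#' @param threshold Agreement band half-width on the log2 scale.
#' @return List with `mrna` and `ksp` (`DecouplingResult` each).
#' @export
decouple_datasets <- function(baseline, target, kdp, factors, threshold = 1) {
  one_state <- function(st) {
    paired <- pair_layers(st$mrna, st$protein)
    mrna <- condition_means(paired$mrna$values, st$design)[, 1L]
    ksp <- compute_translation_rates(st$protein, st$mrna, kdp,
                                     st$design)$values[, 1L]
    mu <- condition_mu(st$design, unique(st$design$condition))
    list(mrna = mrna, ksp = ksp, mu = unname(mu))
  }
  b <- one_state(baseline)
  t <- one_state(target)
  pred <- predict_null_expression(b$mrna, b$ksp, factors,
                                  mu_baseline = b$mu, mu_target = t$mu)
  list(
    mrna = classify_specific_regulation(t$mrna, pred$mrna, threshold),
    ksp = classify_specific_regulation(t$ksp, pred$ksp, threshold)
  )
}
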