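#' One-way ANOVA differential-expression screen
#'
#' Per gene, a one-way ANOVA across conditions on log10-transformed
#' abundances (abundances are lognormal-like across several decades, so the
#' log transform stabilises variances), followed by Benjamini-Hochberg
#' adjustment across genes. The fold-change reported is the ratio of the
#' largest to the smallest condition mean (natural scale).
#'
#' @param matrix An `ExpressionMatrix`.
#' @param design `ConditionDesign` covering every sample; every condition
#'   needs >= 2 replicates.
#' @param alpha FDR level used for the `de` flag (default 0.01).
#' @param log_transform Log10-transform before the ANOVA (default `TRUE`);
#'   zeros become missing under the transform.
#' @return A `DEResult` data frame: `gene`, `f_stat`, `p`, `q`,
#'   `fold_change`, `de` (logical, `q < alpha`), with attribute `"alpha"`.
#' @export
anova_de <- function(matrix, design, alpha = 0.01, log_transform = TRUE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  check_design_covers(design, colnames(v))
  d <- design[match(colnames(v), design$sample), ]
  fac <- factor(d$condition)
  if (nlevels(fac) < 2L) stop("need >= 2 conditions", call. = FALSE)
  reps <- table(fac)
  if (any(reps < 2L)) {
    stop("condition(s) with a single replicate: ",
         paste(names(reps)[reps < 2], collapse = ", "), call. = FALSE)
  }
  y <- v
  if (log_transform) {
    y[!is.na(y) & y <= 0] <- NA_real_
    y <- log10(y)
  }
  grp <- as.integer(fac)
  res <- t(apply(y, 1L, function(row) {
    ok <- !is.na(row)
    ni <- tabulate(grp[ok], nlevels(fac))
    use <- ok & ni[grp] >= 2L
    if (length(unique(grp[use])) < 2L) return(c(NA_real_, NA_real_))
    tst <- tryCatch(
      stats::oneway.test(row[use] ~ factor(grp[use]), var.equal = TRUE),
      error = function(e) NULL)
    if (is.null(tst) || !is.finite(tst$statistic)) {
      # degenerate within-group variance: means differ => F unbounded
      gm <- tapply(row[use], grp[use], mean)
      if (max(gm) - min(gm) < 1e-12) return(c(0, 1))
      return(c(Inf, 0))
    }
    c(unname(tst$statistic), tst$p.value)
  }))
  cm <- condition_means(v, design)
  fc <- apply(cm, 1L, function(m) {
    m <- m[!is.na(m)]
    if (!length(m) || min(m) <= 0) return(NA_real_)
    max(m) / min(m)
  })
  out <- data.frame(gene = rownames(v), f_stat = res[, 1], p = res[, 2],
                    q = stats::p.adjust(res[, 2], method = "BH"),
                    fold_change = fc, stringsAsFactors = FALSE)
  out$de <- !is.na(out$q) & out$q < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Gene-wise correlation between the mRNA and protein layers
#'
#' For every paired gene, the Spearman rank correlation (average ranks for
#' ties) and Pearson correlation of its mRNA and protein abundances across a
#' sample set, with a Shapiro-Wilk normality p-value per layer. Pairs are
#' pairwise-complete; genes with fewer than 3 complete pairs, or with a
#' constant layer, report missing correlations rather than 0.
#'
#' @param paired A [pair_layers()] result.
#' @param samples Optional character vector restricting the sample set.
#' @return A `GeneCorrelation` data frame: `gene`, `rho`, `r`,
#'   `shapiro_p_mrna`, `shapiro_p_protein`, `n`.
#' @export
gene_wise_correlation <- function(paired, samples = NULL) {
  stopifnot(inherits(paired, "PairedOmics"))
  m <- paired$mrna$values
  p <- paired$protein$values
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(m))
    if (length(miss)) {
      stop("unknown sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    m <- m[, samples, drop = FALSE]
    p <- p[, samples, drop = FALSE]
  }
  if (ncol(m) < 3L) stop("need >= 3 shared samples", call. = FALSE)
  shapiro_p <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || length(unique(x)) == 1L) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  safe_cor <- function(x, y, method) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok], method = method)
  }
  genes <- rownames(m)
  out <- data.frame(
    gene = genes,
    rho = vapply(genes, function(g) safe_cor(m[g, ], p[g, ], "spearman"),
                 numeric(1)),
    r = vapply(genes, function(g) safe_cor(m[g, ], p[g, ], "pearson"),
               numeric(1)),
    shapiro_p_mrna = vapply(genes, function(g) shapiro_p(m[g, ]), numeric(1)),
    shapiro_p_protein = vapply(genes, function(g) shapiro_p(p[g, ]),
                               numeric(1)),
    n = vapply(genes, function(g) sum(!is.na(m[g, ]) & !is.na(p[g, ])),
               numeric(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("GeneCorrelation", "data.frame")
  out
}

#' Median correlation per differential-expression quartile
#'
#' Ranks genes by fold-change (ties broken by gene identifier), cuts the
#' ranking into four consecutive groups (remainder genes go to the earliest
#' quartiles), and reports the median gene-wise Spearman rho per quartile
#' together with the quartile's minimum fold-change. Used to test whether
#' poor protein-mRNA correlations are explained by a narrow range of
#' differential expression.
#'
#' @param corr A [gene_wise_correlation()] result.
#' @param fold_change Named numeric vector (gene -> fold-change), e.g. the
#'   `fold_change` column of [anova_de()].
#' @return Data frame with one row per quartile: `quartile`, `n`,
#'   `min_fold_change`, `median_rho`.
#' @export
quartile_correlation_summary <- function(corr, fold_change) {
  stopifnot(inherits(corr, "GeneCorrelation"))
  if (is.null(names(fold_change))) {
    stop("'fold_change' must be named by gene", call. = FALSE)
  }
  genes <- intersect(corr$gene, names(fold_change))
  genes <- genes[!is.na(fold_change[genes])]
  if (length(genes) < 4L) stop("need >= 4 genes", call. = FALSE)
  fc <- fold_change[genes]
  ord <- genes[order(fc, genes)]
  n <- length(ord)
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  extra <- n - 4L * base
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  qt <- rep(1:4, times = sizes)
  rho <- stats::setNames(corr$rho, corr$gene)[ord]
  data.frame(
    quartile = 1:4,
    n = sizes,
    min_fold_change = vapply(1:4, function(k) min(fc[ord[qt == k]]),
                             numeric(1)),
    median_rho = vapply(1:4, function(k)
      stats::median(rho[qt == k], na.rm = TRUE), numeric(1))
  )
}

#' Relative abundance (fraction of the per-sample total)
#'
#' Divides each value by its sample's column total, turning abundances into
#' mol/mol fractions of total mRNA (or total protein). Columns sum to 1 over
#' their non-missing entries.
#'
#' @param matrix An `ExpressionMatrix` with non-negative values.
#' @return `ExpressionMatrix` with unit `"fraction"`.
#' @export
relative_abundance <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  tot <- colSums(v, na.rm = TRUE)
  if (any(tot == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(v)[tot == 0], collapse = ", "), call. = FALSE)
  }
  expression_matrix(sweep(v, 2, tot, `/`), unit = "fraction",
                    layer = matrix$layer)
}

#' Pooled and sample-wise protein-mRNA correlations
#'
#' Pooled statistics are computed over the flattened gene x sample pairs:
#' Pearson r on log10 values (abundances span decades, and the customary
#' presentation of total protein-RNA correlation is on the log scale) and
#' Spearman rho (rank-based, scale-free). Sample-wise statistics are the
#' same quantities per sample across genes, summarised by their medians.
#'
#' @param paired A [pair_layers()] result.
#' @return List with `pooled_r`, `pooled_rho`, `per_sample` (data frame with
#'   `sample`, `r`, `rho`), `median_sample_r`, `median_sample_rho`, and `n`
#'   (number of pooled pairs).
#' @export
global_and_samplewise_correlation <- function(paired) {
  stopifnot(inherits(paired, "PairedOmics"))
  m <- paired$mrna$values
  p <- paired$protein$values
  ok <- !is.na(m) & !is.na(p) & m > 0 & p > 0
  if (sum(ok) < 3L) stop("too few complete positive pairs", call. = FALSE)
  pooled_r <- stats::cor(log10(m[ok]), log10(p[ok]))
  pooled_rho <- stats::cor(m[ok], p[ok], method = "spearman")
  per_sample <- data.frame(
    sample = colnames(m),
    r = vapply(seq_len(ncol(m)), function(j) {
      okj <- ok[, j]
      if (sum(okj) < 3L) return(NA_real_)
      stats::cor(log10(m[okj, j]), log10(p[okj, j]))
    }, numeric(1)),
    rho = vapply(seq_len(ncol(m)), function(j) {
      okj <- !is.na(m[, j]) & !is.na(p[, j])
      if (sum(okj) < 3L) return(NA_real_)
      stats::cor(m[okj, j], p[okj, j], method = "spearman")
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(pooled_r = pooled_r, pooled_rho = pooled_rho,
       per_sample = per_sample,
       median_sample_r = stats::median(per_sample$r, na.rm = TRUE),
       median_sample_rho = stats::median(per_sample$rho, na.rm = TRUE),
       n = sum(ok))
}
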