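#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value computed by summing, over all tables with the
#' observed margins, the hypergeometric probabilities that do not exceed the
#' probability of the observed table (with a relative tolerance of 1e-7 for
#' ties, the usual convention). The odds ratio is the sample odds ratio
#' `(a*d)/(b*c)`; when `b*c == 0` it is `Inf` if `a*d > 0` and `NA` if the
#' table is doubly degenerate.
#'
#' The table layout is `a` = in set & in term, `b` = in set & not term,
#' `c` = not set & in term, `d` = neither.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return List with `p` and `odds_ratio`.
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  white <- a + c          # genes carrying the term
  black <- b + d
  drawn <- a + b          # size of the query set
  support <- max(0L, drawn - black):min(drawn, white)
  probs <- stats::dhyper(support, white, black, drawn)
  p_obs <- stats::dhyper(a, white, black, drawn)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  list(p = p, odds_ratio = or)
}

#' GO-slim over-representation of a gene set
#'
#' For every term annotated in the background, builds the 2x2 contingency
#' table of set membership against term membership and applies
#' [fisher_two_tailed()], with Benjamini-Hochberg adjustment across terms.
#' The background is the gene universe entering the analysis (for example
#' the paired transcript-protein core), not the genome.
#'
#' @param gene_set Character vector, a subset of `background`.
#' @param background Character vector of all genes in the analysis universe.
#' @param annotation A [go_annotation()].
#' @return An `EnrichmentTable` data frame: `term`, `name`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p`, `q`, sorted by `p`.
#' @export
go_set_enrichment <- function(gene_set, background, annotation) {
  stopifnot(inherits(annotation, "GOAnnotation"))
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  out <- setdiff(gene_set, background)
  if (length(out)) {
    stop("gene set is not a subset of the background: ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  }
  gene_set <- unique(gene_set)
  background <- unique(background)
  g2t <- annotation$gene2term[intersect(names(annotation$gene2term),
                                        background)]
  if (!length(g2t)) {
    return(empty_enrichment_table())
  }
  term_genes <- split(rep(names(g2t), lengths(g2t)), unlist(g2t, use.names = FALSE))
  n_bg <- length(background)
  n_set <- length(gene_set)
  rows <- lapply(names(term_genes), function(tt) {
    tg <- term_genes[[tt]]
    a <- length(intersect(tg, gene_set))
    b <- n_set - a
    cc <- length(tg) - a
    d <- n_bg - a - b - cc
    ft <- fisher_two_tailed(a, b, cc, d)
    data.frame(term = tt,
               name = if (tt %in% names(annotation$term_names))
                 annotation$term_names[[tt]] else NA_character_,
               a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$term), ]
  rownames(tab) <- NULL
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

empty_enrichment_table <- function() {
  tab <- data.frame(term = character(0), name = character(0),
                    a = integer(0), b = integer(0), c = integer(0),
                    d = integer(0), odds_ratio = numeric(0),
                    p = numeric(0), q = numeric(0),
                    stringsAsFactors = FALSE)
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Term enrichment in sliding windows along the correlation ranking
#'
#' Sorts genes by their protein-mRNA Spearman rho (ascending, ties broken
#' by gene identifier) and tests every `window`-gene sliding window (moved
#' by `step`) for term over-representation against the full ranked universe.
#' Windows at the low end of the ranking probe genes whose protein levels
#' decouple from their transcripts; high-rho windows probe tightly coupled
#' genes.
#'
#' @param corr A [gene_wise_correlation()] result; genes with missing rho
#'   are dropped.
#' @param annotation A [go_annotation()].
#' @param window Window size in genes (default 200).
#' @param step Step between window starts (default 1).
#' @return An `EnrichmentTable` with additional columns `window` (index),
#'   `start` (first rank) and `median_rho`.
#' @export
sliding_window_enrichment <- function(corr, annotation, window = 200L,
                                      step = 1L) {
  stopifnot(inherits(corr, "GeneCorrelation"))
  ok <- !is.na(corr$rho)
  genes <- corr$gene[ok]
  rho <- corr$rho[ok]
  ord <- order(rho, genes)
  genes <- genes[ord]
  rho <- rho[ord]
  n <- length(genes)
  if (window > n) stop("window exceeds the number of ranked genes", call. = FALSE)
  starts <- seq.int(1L, n - window + 1L, by = step)
  res <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    idx <- seq.int(s, s + window - 1L)
    tab <- go_set_enrichment(genes[idx], genes, annotation)
    if (!nrow(tab)) return(NULL)
    tab$window <- i
    tab$start <- s
    tab$median_rho <- stats::median(rho[idx])
    tab
  })
  tab <- do.call(rbind, res)
  if (is.null(tab)) tab <- empty_enrichment_table()
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Term enrichment among the most abundant genes
#'
#' Ranks genes by their overall median abundance and tests the top fraction
#' (default 10%) for term over-representation against all genes of the
#' matrix.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param annotation A [go_annotation()].
#' @param fraction Top fraction in (0, 1); the set size is
#'   `ceiling(fraction * n)`.
#' @return An `EnrichmentTable`.
#' @export
top_fraction_enrichment <- function(matrix, annotation, fraction = 0.10) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  med <- apply(matrix$values, 1L, stats::median, na.rm = TRUE)
  genes <- names(sort(med, decreasing = TRUE))
  top <- genes[seq_len(ceiling(fraction * length(genes)))]
  go_set_enrichment(top, em_genes(matrix), annotation)
}
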