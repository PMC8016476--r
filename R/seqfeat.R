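# standard genetic code, DNA alphabet; stops are "*"
genetic_code <- function() Biostrings::GENETIC_CODE

#' Amino-acid composition per gene
#'
#' Counts each of the 20 amino acids in every protein sequence and divides
#' by the sequence length; `X` residues are excluded from both the counts
#' and the denominator, so proportions always sum to 1.
#'
#' @param seqs A [sequence_set()] of kind `"protein"`.
#' @return Numeric matrix, genes x 20 amino acids, rows summing to 1.
#' @export
amino_acid_proportions <- function(seqs) {
  stopifnot(inherits(seqs, "SequenceSet"))
  if (seqs$kind != "protein") stop("expected protein sequences", call. = FALSE)
  aas <- aa_alphabet()
  counts <- t(vapply(seqs$seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch <- ch[ch != "X"]
    tabulate(factor(ch, levels = aas), nbins = length(aas))
  }, numeric(length(aas))))
  colnames(counts) <- aas
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("sequence(s) consisting only of X: ",
         paste(names(seqs$seqs)[tot == 0], collapse = ", "), call. = FALSE)
  }
  counts / tot
}

#' Codon usage per gene
#'
#' For each gene, codon frequencies are computed over the coding sequence
#' (a terminal stop codon is allowed and ignored; an internal stop is an
#' error). With `mode = "family"` (default) the value for a codon is its
#' fraction within its synonymous family (the codons of one amino acid),
#' families absent from a gene being missing rather than zero; with
#' `mode = "global"` it is the fraction over all sense codons of the gene.
#'
#' @param seqs A [sequence_set()] of kind `"CDS"`.
#' @param mode `"family"` or `"global"`.
#' @return Numeric matrix, genes x 61 sense codons; attribute
#'   `"codon_family"` maps codons to amino acids.
#' @export
codon_usage <- function(seqs, mode = c("family", "global")) {
  stopifnot(inherits(seqs, "SequenceSet"))
  if (seqs$kind != "CDS") stop("expected CDS sequences", call. = FALSE)
  mode <- match.arg(mode)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  fam <- code[sense]
  counts <- t(vapply(names(seqs$seqs), function(g) {
    s <- seqs$seqs[[g]]
    cods <- substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
    is_stop <- cods %in% names(code)[code == "*"]
    if (any(is_stop)) {
      pos <- which(is_stop)
      if (any(pos != length(cods))) {
        stop(sprintf("internal stop codon in gene '%s' at codon %d",
                     g, pos[pos != length(cods)][1]), call. = FALSE)
      }
      cods <- cods[-length(cods)]
    }
    cods <- cods[!grepl("N", cods)]
    tabulate(factor(cods, levels = sense), nbins = length(sense))
  }, numeric(length(sense))))
  colnames(counts) <- sense
  out <- if (mode == "global") {
    counts / rowSums(counts)
  } else {
    res <- matrix(NA_real_, nrow(counts), ncol(counts),
                  dimnames = dimnames(counts))
    for (a in unique(fam)) {
      idx <- which(fam == a)
      fam_tot <- rowSums(counts[, idx, drop = FALSE])
      frac <- counts[, idx, drop = FALSE] / fam_tot
      frac[fam_tot == 0, ] <- NA_real_   # family absent: missing, not zero
      res[, idx] <- frac
    }
    res
  }
  attr(out, "codon_family") <- fam
  out
}

#' Purine content of codons
#'
#' @param codons Character vector of codons.
#' @return Integer vector: number of A/G letters among the 3 positions.
#' @export
codon_purine_count <- function(codons) {
  vapply(strsplit(toupper(codons), ""), function(x) sum(x %in% c("A", "G")),
         integer(1))
}

#' Sequence-feature profile across correlation brackets
#'
#' Sorts genes by their protein-mRNA Spearman rho (ascending, ties broken
#' by gene identifier) and cuts the ranking into consecutive,
#' non-overlapping brackets of `bracket` genes (a final partial bracket is
#' kept and flagged). For each bracket the mean of every feature is taken
#' and reported as log2(bracket mean / all-gene mean), so a value of 0 means
#' the bracket matches the overall composition.
#'
#' @param corr A [gene_wise_correlation()] result.
#' @param features Numeric matrix, genes x features (e.g. the output of
#'   [amino_acid_proportions()] or [codon_usage()]).
#' @param bracket Bracket size in genes (default 200, minimum 10).
#' @return A `CompositionProfile`: list with `log2_ratio` (bracket x
#'   feature), `median_rho`, `size`, `partial` (logical per bracket),
#'   `bracket_mean`, `overall_mean`, `genes` (list of per-bracket gene ids).
#' @export
bracket_profile <- function(corr, features, bracket = 200L) {
  stopifnot(inherits(corr, "GeneCorrelation"))
  if (bracket < 10L) stop("bracket must be >= 10 genes", call. = FALSE)
  if (is.null(rownames(features))) {
    stop("'features' must have gene rownames", call. = FALSE)
  }
  ok <- !is.na(corr$rho) & corr$gene %in% rownames(features)
  genes <- corr$gene[ok]
  rho <- corr$rho[ok]
  if (length(genes) < bracket) {
    stop("fewer genes with features and rho than one bracket", call. = FALSE)
  }
  ord <- order(rho, genes)
  genes <- genes[ord]
  rho <- rho[ord]
  n <- length(genes)
  bid <- ceiling(seq_len(n) / bracket)
  nb <- max(bid)
  feat <- features[genes, , drop = FALSE]
  overall <- colMeans(feat, na.rm = TRUE)
  bracket_mean <- matrix(vapply(seq_len(nb), function(b) {
    colMeans(feat[bid == b, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(feat))), nrow = nb, byrow = TRUE,
  dimnames = list(NULL, colnames(feat)))
  structure(list(
    log2_ratio = log2(sweep(bracket_mean, 2, overall, `/`)),
    median_rho = vapply(seq_len(nb), function(b)
      stats::median(rho[bid == b]), numeric(1)),
    size = as.integer(table(bid)),
    partial = vapply(seq_len(nb), function(b) sum(bid == b) < bracket,
                     logical(1)),
    bracket_mean = bracket_mean,
    overall_mean = overall,
    genes = split(genes, bid)
  ), class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf("CompositionProfile: %d brackets x %d features (rho %.2f .. %.2f)\n",
              nrow(x$log2_ratio), ncol(x$log2_ratio),
              min(x$median_rho), max(x$median_rho)))
  invisible(x)
}
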