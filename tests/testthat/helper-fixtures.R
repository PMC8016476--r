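# small constructors shared across test files

tiny_em <- function(values, genes = NULL, samples = NULL,
                    unit = "mmol_per_gDW", layer = "mRNA") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(samples)) colnames(values) <- samples
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, unit = unit, layer = layer)
}

# a design of length(mu) conditions x reps replicates; sample names c1_r1 ...
make_design <- function(mu, reps = 3L, limitation = "carbon",
                        n_source = "NH4", preferred = TRUE,
                        condition = NULL) {
  if (is.null(condition)) condition <- sprintf("c%d", seq_along(mu))
  limitation <- rep_len(limitation, length(mu))
  n_source <- rep_len(n_source, length(mu))
  preferred <- rep_len(preferred, length(mu))
  df <- do.call(rbind, lapply(seq_along(mu), function(i) {
    data.frame(sample = sprintf("%s_r%d", condition[i], seq_len(reps)),
               condition = condition[i], mu = mu[i],
               limitation = limitation[i],
               n_source = n_source[i], preferred = preferred[i],
               replicate = seq_len(reps), stringsAsFactors = FALSE)
  }))
  condition_design(df)
}

# matrix whose columns follow the design: per gene a function of (mu, sample)
design_matrix_em <- function(design, gene_values, unit = "mmol_per_gDW",
                             layer = "mRNA") {
  m <- t(vapply(gene_values, function(f) vapply(seq_len(nrow(design)),
        function(i) f(design$mu[i], i), numeric(1)),
        numeric(nrow(design))))
  rownames(m) <- names(gene_values)
  colnames(m) <- design$sample
  expression_matrix(m, unit = unit, layer = layer)
}

# brute-force two-sided Fisher p by explicit enumeration over all feasible
# tables with the observed margins, using factorial arithmetic only
fisher_enumeration_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  table_prob <- function(x) {
    # hypergeometric via log factorials
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(r1 - x) - lfactorial(c1 - x) -
          lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, table_prob, numeric(1))
  p_obs <- table_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
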