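#' Read a gene x sample abundance table
#'
#' Reads a tab- or comma-delimited file (first column gene identifiers,
#' header row sample identifiers) into a validated [expression_matrix()].
#' Loaders reject rather than coerce: duplicated gene rows, negative values
#' and non-numeric cells raise descriptive errors instead of producing `NA`s
#' silently. Empty cells and the literal `NA` are treated as explicitly
#' missing measurements.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param unit,layer Unit and layer tags, see [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
load_expression_matrix <- function(path, unit, layer) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) {
    stop("malformed header in '", path,
         "': expected a gene column plus >= 1 sample column", call. = FALSE)
  }
  genes <- as.character(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicated gene row(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      col[!nzchar(trimws(col))] <- NA_character_
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & toupper(trimws(col)) != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1]], genes[bad[1]], names(vals)[j]),
             call. = FALSE)
      }
      num[!is.na(col) & toupper(trimws(col)) == "NA"] <- NA_real_
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative entry at gene '%s', sample '%s' in '%s'",
                 genes[neg[1, 1]], colnames(m)[neg[1, 2]], path),
         call. = FALSE)
  }
  expression_matrix(m, unit = unit, layer = layer)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", na.strings = c("NA", ""))
}

#' Per-sample culture physiology table
#'
#' Describes each sample of a chemostat series: condition label, specific
#' growth rate (the dilution rate at steady state), limiting nutrient,
#' nitrogen source, whether the nitrogen source is preferred, and replicate
#' index.
#'
#' @param df Data frame with columns `sample`, `condition`, `mu`,
#'   `limitation` (`"carbon"` or `"nitrogen"`), `n_source`, `preferred`
#'   (logical), `replicate` (integer).
#' @return A `ConditionDesign` (a validated data frame).
#' @export
condition_design <- function(df) {
  req <- c("sample", "condition", "mu", "limitation", "n_source",
           "preferred", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("design table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df[req], stringsAsFactors = FALSE)
  df$sample <- as.character(df$sample)
  df$condition <- as.character(df$condition)
  df$n_source <- as.character(df$n_source)
  df$preferred <- as.logical(df$preferred)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample identifier(s) in design", call. = FALSE)
  }
  if (any(!is.finite(df$mu) | df$mu <= 0)) {
    stop("all growth rates 'mu' must be finite and > 0", call. = FALSE)
  }
  bad_lim <- setdiff(unique(df$limitation), design_limitations())
  if (length(bad_lim)) {
    stop("unknown limitation value(s): ", paste(bad_lim, collapse = ", "),
         "; allowed: ", paste(design_limitations(), collapse = ", "),
         call. = FALSE)
  }
  bad_src <- setdiff(unique(df$n_source), design_n_sources())
  if (length(bad_src)) {
    stop("unknown nitrogen source(s): ", paste(bad_src, collapse = ", "),
         "; allowed: ", paste(design_n_sources(), collapse = ", "),
         call. = FALSE)
  }
  rep_dup <- stats::aggregate(df$replicate, by = list(df$condition),
                              FUN = anyDuplicated)
  if (any(rep_dup$x > 0)) {
    stop("replicate indices must be unique within condition(s): ",
         paste(rep_dup$Group.1[rep_dup$x > 0], collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("ConditionDesign", "data.frame")
  df
}

design_limitations <- function() c("carbon", "nitrogen")
design_n_sources <- function() c("NH4", "Gln", "Gln*", "Glu", "Phe", "Ile")

#' @rdname condition_design
#' @param path Path to a TSV/CSV file with the design columns.
#' @export
load_condition_design <- function(path) {
  condition_design(read_delim_auto(path))
}

# every sample of the matrix must be described in the design
check_design_covers <- function(design, samples) {
  miss <- setdiff(samples, design$sample)
  if (length(miss)) {
    stop("sample(s) absent from the condition design: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Spike-in standard table
#'
#' Rows of (standard id, known amount, measured signal, and for protein
#' standards the number of identified unique peptides).
#'
#' @param df Data frame with columns `id`, `amount`, `signal` and optionally
#'   `n_unique_peptides`.
#' @return A `SpikeInTable` (validated data frame).
#' @export
spikein_table <- function(df) {
  req <- c("id", "amount", "signal")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("spike-in table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate spike-in id(s)", call. = FALSE)
  if (any(!is.finite(df$amount) | df$amount <= 0)) {
    stop("spike-in known amounts must be > 0", call. = FALSE)
  }
  if (any(!is.finite(df$signal) | df$signal < 0)) {
    stop("spike-in signals must be >= 0", call. = FALSE)
  }
  class(df) <- c("SpikeInTable", "data.frame")
  df
}

#' @rdname spikein_table
#' @param path Path to a TSV/CSV spike-in table.
#' @export
load_spikein_table <- function(path) spikein_table(read_delim_auto(path))

#' Gene to GO-slim term annotation
#'
#' @param mapping Data frame with columns `gene`, `term`, and optionally
#'   `name` (human-readable term name).
#' @return A `GOAnnotation`: list with `gene2term` (named list of character
#'   term vectors) and `term_names` (named character).
#' @export
go_annotation <- function(mapping) {
  req <- c("gene", "term")
  miss <- setdiff(req, names(mapping))
  if (length(miss)) {
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  gene <- as.character(mapping$gene)
  term <- as.character(mapping$term)
  keep <- nzchar(gene) & nzchar(term)
  gene <- gene[keep]; term <- term[keep]
  if (!length(gene)) stop("annotation contains no gene-term pairs", call. = FALSE)
  gene2term <- lapply(split(term, gene), unique)
  term_names <- character(0)
  if (!is.null(mapping$name)) {
    nm <- as.character(mapping$name)[keep]
    ok <- !is.na(nm) & nzchar(nm)
    term_names <- nm[ok][!duplicated(term[ok])]
    names(term_names) <- term[ok][!duplicated(term[ok])]
  }
  structure(list(gene2term = gene2term, term_names = term_names),
            class = "GOAnnotation")
}

#' @rdname go_annotation
#' @param path Path to a two-column (`gene`, `term`[, `name`]) TSV, or a GAF
#'   2.x file (lines starting with `!` are comments; gene = DB Object ID,
#'   column 2; term = GO ID, column 5).
#' @param format `"auto"` (GAF if the first non-comment line has >= 15
#'   tab-separated fields or the file starts with `!gaf-version`),
#'   `"tsv"`, or `"gaf"`.
#' @export
load_go_annotation <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 25L, warn = FALSE)
    is_gaf <- any(grepl("^!gaf-version", first)) ||
      {
        body <- first[!startsWith(first, "!")]
        length(body) > 0 && length(strsplit(body[1], "\t", fixed = TRUE)[[1]]) >= 15
      }
    format <- if (is_gaf) "gaf" else "tsv"
  }
  if (format == "gaf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    gene <- vapply(fields, `[`, "", 2L)
    term <- vapply(fields, `[`, "", 5L)
    go_annotation(data.frame(gene = gene, term = term,
                             stringsAsFactors = FALSE))
  } else {
    go_annotation(read_delim_auto(path))
  }
}

#' Named sequence collection (protein or CDS)
#'
#' @param seqs Named character vector of sequences.
#' @param kind `"protein"` (20-letter alphabet plus `X`) or `"CDS"`
#'   (`A/C/G/T/N`, length divisible by 3).
#' @return A `SequenceSet`: list with `seqs` and `kind`.
#' @export
sequence_set <- function(seqs, kind = c("protein", "CDS")) {
  kind <- match.arg(kind)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by gene identifier", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence identifier(s)", call. = FALSE)
  }
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- nm
  if (any(!nzchar(seqs))) stop("empty sequence(s) present", call. = FALSE)
  if (kind == "protein") {
    bad <- grepl(sprintf("[^%sX]", paste(aa_alphabet(), collapse = "")), seqs)
    if (any(bad)) {
      g <- names(seqs)[which(bad)[1]]
      pos <- regexpr(sprintf("[^%sX]", paste(aa_alphabet(), collapse = "")),
                     seqs[[which(bad)[1]]])
      stop(sprintf("invalid residue in gene '%s' at position %d", g, pos),
           call. = FALSE)
    }
  } else {
    badlen <- nchar(seqs) %% 3L != 0L
    if (any(badlen)) {
      stop("CDS length not divisible by 3 for gene(s): ",
           paste(names(seqs)[badlen], collapse = ", "), call. = FALSE)
    }
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      g <- names(seqs)[which(bad)[1]]
      stop(sprintf("invalid nucleotide in gene '%s'", g), call. = FALSE)
    }
  }
  structure(list(seqs = seqs, kind = kind), class = "SequenceSet")
}

aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname sequence_set
#' @param path Path to a FASTA file.
#' @export
load_sequences <- function(path, kind = c("protein", "CDS")) {
  kind <- match.arg(kind)
  set <- if (kind == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  seqs <- as.character(set)
  # FASTA headers: identifier is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sequence_set(seqs, kind = kind)
}

#' Per-sample total RNA and protein content
#'
#' Fractions of cell dry weight, as measured by bulk assays (Qubit for RNA,
#' BCA for protein). Used to scale calibrated per-gene abundances so that
#' per-sample totals follow the measured contents.
#'
#' @param df Data frame with columns `sample`, and `rna_fraction` and/or
#'   `protein_fraction`, both in (0, 1).
#' @return A `TotalContent` (validated data frame).
#' @export
total_content <- function(df) {
  if (!"sample" %in% names(df)) stop("missing 'sample' column", call. = FALSE)
  fr_cols <- intersect(c("rna_fraction", "protein_fraction"), names(df))
  if (!length(fr_cols)) {
    stop("need 'rna_fraction' and/or 'protein_fraction' column", call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample(s)", call. = FALSE)
  for (cl in fr_cols) {
    v <- df[[cl]]
    if (any(!is.finite(v) | v <= 0 | v >= 1)) {
      stop("'", cl, "' values must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  class(df) <- c("TotalContent", "data.frame")
  df
}

#' @rdname total_content
#' @param path Path to a TSV/CSV content table.
#' @export
load_total_content <- function(path) total_content(read_delim_auto(path))

#' Write a table to disk (single serialization point)
#'
#' All tabular outputs of the package funnel through this function: TSV,
#' UTF-8, `.` decimal separator, no quoting, no row names. An
#' `ExpressionMatrix` is written with its genes as a leading `gene` column;
#' `TranslationRateMatrix` and `ScaledMatrix` likewise.
#'
#' @param x Data frame, matrix, `ExpressionMatrix`, `TranslationRateMatrix`
#'   or `ScaledMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- if (inherits(x, "ExpressionMatrix")) {
    data.frame(gene = em_genes(x), x$values, check.names = FALSE,
               stringsAsFactors = FALSE)
  } else if (inherits(x, c("TranslationRateMatrix", "ScaledMatrix"))) {
    data.frame(gene = rownames(x$values), x$values, check.names = FALSE,
               stringsAsFactors = FALSE)
  } else if (is.matrix(x)) {
    data.frame(gene = rownames(x), x, check.names = FALSE,
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
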