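#' Read coding sequences from a FASTA file
#'
#' Reads a FASTA file of coding sequences (CDS) into a transcript table.
#' Sequences are uppercased and must contain only A, C, G, T or N; `N` is
#' tolerated (reference-assembly imperfections) and flagged per record.
#' Length checks (divisibility by 3, internal stops) are deferred to
#' [translate_cds()] so that a reader round-trip is lossless.
#'
#' @param path Path to an existing FASTA file.
#' @return A data.frame with columns `gene_id`, `cds` and `has_ambiguous`
#'   (logical, TRUE when the sequence contains `N`), one row per FASTA
#'   record in file order. An empty file yields a zero-row data.frame.
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(gene_id = character(), cds = character(),
                      has_ambiguous = logical(), stringsAsFactors = FALSE))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  cds <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", cds)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in FASTA: ", ids[duplicated(ids)][1L])
  }
  data.frame(gene_id = ids, cds = unname(cds),
             has_ambiguous = unname(grepl("N", cds, fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Write coding sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` recovers the
#' `gene_id` and `cds` columns exactly.
#'
#' @param transcripts data.frame with columns `gene_id` and `cds`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  stopifnot(is.data.frame(transcripts),
            all(c("gene_id", "cds") %in% names(transcripts)))
  x <- Biostrings::DNAStringSet(transcripts$cds)
  names(x) <- transcripts$gene_id
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translates an in-frame CDS. A terminal stop codon is dropped; an internal
#' stop codon is an error reporting its codon position. Codons containing `N`
#' translate to `X` (unknown residue), so ambiguous bases never invent an
#' amino acid.
#'
#' @param cds A single DNA string over A/C/G/T/N whose length is a multiple
#'   of 3.
#' @return The amino-acid string (one-letter code, possibly containing `X`).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds)) stop("CDS contains characters outside {A,C,G,T,N}")
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[grepl("N", codons, fixed = TRUE)] <- "X"
  stops <- which(aa == "*")
  n_codons <- length(codons)
  if (length(stops) > 0L) {
    internal <- stops[stops < n_codons]
    if (length(internal) > 0L) {
      stop("internal stop codon at codon position ", internal[1L])
    }
    aa <- aa[-n_codons]
  }
  paste(aa, collapse = "")
}

#' Add protein sequences to a transcript table
#'
#' @param transcripts data.frame from [read_fasta()] or
#'   [simulate_transcriptome()].
#' @return The same data.frame with a `protein` column appended.
#' @export
add_proteins <- function(transcripts) {
  transcripts$protein <- vapply(transcripts$cds, translate_cds, character(1L),
                                USE.NAMES = FALSE)
  transcripts
}

#' Construct a per-fraction sample table
#'
#' The unit of differential testing: a genes-by-samples integer count matrix
#' for one polysome fraction, with a two-group design (KO vs CTL).
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param group Character or factor of per-sample labels, values in
#'   `"KO"`/`"CTL"`, one per column.
#' @param fraction One of `"total"`, `"light"`, `"heavy"` (or another label
#'   such as `"brain"` when reusing the engine outside polysome profiling).
#' @return An object of class `sample_table`: a list with elements `counts`,
#'   `group` (factor with levels CTL, KO) and `fraction`.
#' @export
sample_table <- function(counts, group, fraction) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (length(group) != ncol(counts)) stop("one group label per sample required")
  if (!all(group %in% c("KO", "CTL"))) {
    stop("group labels must be 'KO' or 'CTL'")
  }
  group <- factor(as.character(group), levels = c("CTL", "KO"))
  if (any(table(group) < 2L)) {
    stop("each group needs at least 2 samples for differential testing")
  }
  structure(list(counts = counts, group = group,
                 fraction = as.character(fraction)),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: %d genes x %d samples, fraction '%s' (%s)\n",
              nrow(x$counts), ncol(x$counts), x$fraction,
              paste(sprintf("%s n=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a gene-level count table from TSV
#'
#' Expects a tab-separated file (UTF-8; lines starting with `#` are
#' comments) whose header row names the samples and whose first column holds
#' gene ids. Cells must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @param fraction Fraction label attached to the resulting table.
#' @param groups Named character vector mapping every sample id to `"KO"` or
#'   `"CTL"`.
#' @return A [sample_table()].
#' @export
read_counts <- function(path, fraction, groups) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene-id column and >=1 sample")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != floor(m)) || any(m < 0)) {
    stop("count table contains non-integer or negative cells")
  }
  rownames(m) <- gene_ids
  samples <- colnames(m)
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0L) {
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  }
  sample_table(m, group = unname(groups[samples]), fraction = fraction)
}

#' Write a sample table back to TSV
#'
#' @param table A [sample_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  df <- data.frame(gene_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
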