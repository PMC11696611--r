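#' Wobble-uridine (U34) codon set
#'
#' The A-ending codons decoded by the U34-modified tRNAs: AAA (Lys, read by
#' tRNA-Lys-UUU), GAA (Glu, tRNA-Glu-UUC) and CAA (Gln, tRNA-Gln-UUG).
#' Optionally extended with the G-ending codons of the same boxes (AAG, GAG,
#' CAG), which the same tRNAs can read by U:G wobble.
#'
#' @param include_wobble_g Include AAG/GAG/CAG (default FALSE).
#' @return Character vector of codons.
#' @export
u34_codons <- function(include_wobble_g = FALSE) {
  set <- c("AAA", "GAA", "CAA")
  if (include_wobble_g) set <- c(set, "AAG", "GAG", "CAG")
  set
}

#' Flag codons belonging to the U34 set
#'
#' @param codons Character vector of codon strings.
#' @param set The U34 codon set (see [u34_codons()]).
#' @return Logical vector, one flag per codon.
#' @export
u34_annotate <- function(codons, set = u34_codons()) {
  known <- names(Biostrings::GENETIC_CODE)
  bad <- !(codons %in% known)
  if (any(bad)) stop("unknown codon: ", codons[bad][1L])
  codons %in% set
}

#' Count sense codons of a coding sequence
#'
#' In-frame, non-overlapping triplets from position 1. Stop codons (so in
#' particular a terminal stop) and codons containing `N` are excluded.
#'
#' @param cds A single in-frame DNA string.
#' @return Named integer vector over the 61 sense codons; `sum()` of it is
#'   the number of counted codons.
#' @export
count_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not divisible by 3")
  codons <- sense_codons()
  out <- stats::setNames(integer(length(codons)), codons)
  if (n == 0L) return(out)
  trip <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  trip <- trip[trip %in% codons]   # drops stops and N-containing codons
  tab <- table(factor(trip, levels = codons))
  out[] <- as.integer(tab)
  out
}

#' Pooled codon counts of a gene set
#'
#' Sums [count_codons()] over the members, i.e. codon frequencies are pooled
#' across genes rather than averaged per gene.
#'
#' @param transcripts Transcript data.frame with `gene_id` and `cds`.
#' @param gene_ids Genes to include (default: all).
#' @return Named integer vector over the 61 sense codons.
#' @export
codon_usage <- function(transcripts, gene_ids = NULL) {
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, transcripts$gene_id)
    if (length(missing) > 0L) {
      stop("gene ids absent from transcript table: ",
           paste(utils::head(missing, 3L), collapse = ", "))
    }
    transcripts <- transcripts[transcripts$gene_id %in% gene_ids, ,
                               drop = FALSE]
  }
  Reduce(`+`, lapply(transcripts$cds, count_codons))
}

#' Per-codon chi-squared enrichment of a gene set against a background
#'
#' For each of the 61 sense codons, a 2x2 contingency table (codon vs all
#' other codons; set vs background) is tested by Pearson's chi-squared
#' statistic (1 df, no continuity correction), with BH adjustment across the
#' 61 codons. A codon is flagged enriched when its set frequency exceeds the
#' background frequency at `fdr < fdr_cutoff`, depleted for the opposite
#' direction. An omnibus 61-cell goodness-of-fit chi-squared of the set
#' counts against the background proportions is also reported; background
#' codons with zero expected count are merged into a single "other" cell for
#' that statistic.
#'
#' The background is the whole transcriptome, by default including the test
#' set itself; pass background counts with the set subtracted for an
#' exclusive comparison.
#'
#' @param set_counts,background_counts Named integer vectors over the 61
#'   sense codons (see [codon_usage()]).
#' @param u34_set Codons flagged in the `u34` column.
#' @param fdr_cutoff FDR threshold for the enriched/depleted flags
#'   (default 0.05).
#' @return List with `table` (data.frame: codon, obs_set, obs_background,
#'   freq_set, freq_background, chi2, p, fdr, enriched, depleted, u34),
#'   `global_chi2`, `global_df`, `global_p`, and `merged_codons` (codons
#'   folded into the "other" cell of the global test).
#' @export
codon_chi2 <- function(set_counts, background_counts,
                       u34_set = u34_codons(), fdr_cutoff = 0.05) {
  codons <- sense_codons()
  stopifnot(setequal(names(set_counts), codons),
            setequal(names(background_counts), codons))
  a <- as.numeric(set_counts[codons])
  c_ <- as.numeric(background_counts[codons])
  n_set <- sum(a)
  n_bg <- sum(c_)
  if (n_set <= 0 || n_bg <= 0) stop("set and background must be nonempty")
  b <- n_set - a
  d <- n_bg - c_
  n <- n_set + n_bg
  num <- n * (a * d - b * c_)^2
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(den > 0, num / den, 0)
  p <- ifelse(den > 0, stats::pchisq(chi2, df = 1L, lower.tail = FALSE), 1)
  fdr <- bh_adjust(p)
  freq_set <- a / n_set
  freq_bg <- c_ / n_bg
  tab <- data.frame(codon = codons,
                    obs_set = as.integer(a),
                    obs_background = as.integer(c_),
                    freq_set = freq_set,
                    freq_background = freq_bg,
                    chi2 = chi2,
                    p = p,
                    fdr = fdr,
                    enriched = freq_set > freq_bg & fdr < fdr_cutoff,
                    depleted = freq_set < freq_bg & fdr < fdr_cutoff,
                    u34 = u34_annotate(codons, u34_set),
                    stringsAsFactors = FALSE)

  prop_bg <- c_ / n_bg
  merged <- codons[prop_bg == 0]
  keep <- prop_bg > 0
  obs <- a[keep]
  exp_ <- n_set * prop_bg[keep]
  if (length(merged) > 0L) {
    obs <- c(obs, sum(a[!keep]))
    exp_ <- c(exp_, 0)
    # an "other" cell with zero expectation contributes only if observed
    global_chi2 <- sum((obs[exp_ > 0] - exp_[exp_ > 0])^2 / exp_[exp_ > 0]) +
      if (obs[length(obs)] > 0) Inf else 0
    global_df <- sum(keep) - 1L
  } else {
    global_chi2 <- sum((obs - exp_)^2 / exp_)
    global_df <- length(obs) - 1L
  }
  global_p <- stats::pchisq(global_chi2, df = global_df, lower.tail = FALSE)
  list(table = tab, global_chi2 = global_chi2, global_df = global_df,
       global_p = global_p, merged_codons = merged)
}
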