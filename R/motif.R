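#' Configuration of the hydrophilic-run motif scanner
#'
#' The motif is a run of at least `min_run` consecutive hydrophilic residues
#' (penta-hydrophilic with the default `min_run = 5`), previously linked to
#' protein aggregation when wobble-uridine-dependent decoding fails. The
#' default alphabet is the charged plus polar-uncharged side chains
#' (D, E, K, R, H, N, Q, S, T); it is configurable because the precise
#' residue set is a modelling choice.
#'
#' @param hydrophilic_residues Character vector of one-letter residue codes.
#' @param min_run Minimum run length (>= 2; default 5).
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(hydrophilic_residues = default_hydrophilic_residues(),
                         min_run = 5L) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  stopifnot(min_run >= 2L, all(hydrophilic_residues %in% aa20))
  structure(list(hydrophilic_residues = unique(hydrophilic_residues),
                 min_run = as.integer(min_run)),
            class = "motif_config")
}

#' Default hydrophilic residue alphabet
#'
#' @return Character vector: D, E, K, R, H, N, Q, S, T.
#' @export
default_hydrophilic_residues <- function() {
  c("D", "E", "K", "R", "H", "N", "Q", "S", "T")
}

#' Scan a protein for hydrophilic runs
#'
#' Finds the maximal runs of at least `cfg$min_run` consecutive hydrophilic
#' residues, left to right. Runs are maximal: a run of 7 hydrophilic
#' residues is one motif, not three overlapping windows. `X` (unknown
#' residue) is accepted and is never hydrophilic.
#'
#' @param protein A single amino-acid string over the 20 standard one-letter
#'   codes plus `X`.
#' @param cfg A [motif_config()].
#' @return List: `n_motifs`, `has_motif`, and `positions`, a data.frame with
#'   1-based inclusive `start`/`end` columns (one row per maximal run).
#' @export
scan_motifs <- function(protein, cfg = motif_config()) {
  stopifnot(is.character(protein), length(protein) == 1L,
            inherits(cfg, "motif_config"))
  chars <- strsplit(protein, "")[[1L]]
  legal <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X")
  bad <- !(chars %in% legal)
  if (any(bad)) {
    stop("illegal residue '", chars[bad][1L], "' at position ",
         which(bad)[1L])
  }
  is_hydro <- chars %in% cfg$hydrophilic_residues
  r <- rle(is_hydro)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= cfg$min_run
  positions <- data.frame(start = starts[hit], end = ends[hit])
  list(n_motifs = nrow(positions),
       has_motif = nrow(positions) >= 1L,
       positions = positions)
}

#' Scan a table of proteins for hydrophilic runs
#'
#' @param transcripts data.frame with `gene_id` and `protein` columns (see
#'   [add_proteins()]).
#' @param cfg A [motif_config()].
#' @return data.frame: gene_id, n_motifs, has_motif.
#' @export
scan_motif_table <- function(transcripts, cfg = motif_config()) {
  stopifnot(is.data.frame(transcripts),
            all(c("gene_id", "protein") %in% names(transcripts)))
  n <- vapply(transcripts$protein,
              function(p) scan_motifs(p, cfg)$n_motifs, integer(1L),
              USE.NAMES = FALSE)
  data.frame(gene_id = transcripts$gene_id, n_motifs = n,
             has_motif = n >= 1L, stringsAsFactors = FALSE)
}

#' Motif prevalence in a gene set
#'
#' Fraction of proteins carrying at least one motif, as an unrounded
#' percentage plus the nearest-integer display value (the form in which such
#' prevalences are usually quoted, e.g. 282 of 2288 displays as 12%).
#'
#' @param x Either a data.frame with a logical `has_motif` column, or the
#'   number of motif-positive proteins.
#' @param n_total Total number of proteins (only when `x` is a count).
#' @return List: n_positive, n_total, percent (unrounded), display_percent
#'   (nearest integer).
#' @export
motif_prevalence <- function(x, n_total = NULL) {
  if (is.data.frame(x)) {
    stopifnot("has_motif" %in% names(x))
    if (nrow(x) == 0L) stop("empty motif table")
    n_pos <- sum(x$has_motif)
    n_tot <- nrow(x)
  } else {
    stopifnot(is.numeric(x), length(x) == 1L, !is.null(n_total), n_total > 0)
    n_pos <- x
    n_tot <- n_total
  }
  pct <- 100 * n_pos / n_tot
  list(n_positive = n_pos, n_total = n_tot, percent = pct,
       display_percent = round(pct))
}

#' Exact test of motif enrichment against a background proteome
#'
#' Two-sided Fisher exact test on the 2x2 presence/absence table of a gene
#' set versus a background proteome (e.g. motif occurrence in the full
#' proteome as the reference).
#'
#' @param set_results,background_results data.frames with logical
#'   `has_motif` columns, or logical vectors.
#' @return List: odds_ratio (conditional MLE), p (two-sided), and the 2x2
#'   `table` (rows set/background, columns positive/negative).
#' @export
motif_fisher <- function(set_results, background_results) {
  get_flags <- function(x) {
    if (is.data.frame(x)) x$has_motif else as.logical(x)
  }
  s <- get_flags(set_results)
  b <- get_flags(background_results)
  if (length(s) == 0L || length(b) == 0L) stop("empty motif table")
  tab <- matrix(c(sum(s), sum(!s), sum(b), sum(!b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("set", "background"),
                                c("positive", "negative")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
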