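#' Run the full translatome analysis
#'
#' Orchestrates the whole chain on either simulated or supplied data:
#' per-fraction NB-LRT differential abundance (total, light, heavy), BH
#' adjustment and threshold calls; integration into regulation categories;
#' codon-usage chi-squared enrichment of the post-transcriptionally
#' regulated set against the whole-transcriptome background with U34
#' annotation; and penta-hydrophilic motif prevalence plus exact enrichment
#' of the corresponding proteins against the whole proteome. Identical
#' inputs and seed give identical outputs.
#'
#' @param counts Named list of three [sample_table()]s (`total`, `light`,
#'   `heavy`), or NULL to simulate from `sim`.
#' @param transcripts Transcript data.frame with `gene_id`, `cds` (and
#'   optionally `protein`), or NULL to simulate.
#' @param sim A [sim_config()] used when `counts`/`transcripts` are NULL.
#' @param thresholds [de_thresholds()] applied to every fraction.
#' @param motif_cfg [motif_config()] for the run scanner.
#' @param u34_set U34 codon set for annotation (see [u34_codons()]).
#' @param min_cpm Low-expression filter threshold (see [filter_low()]).
#' @param out_dir Optional output directory: writes de_total/light/heavy.tsv,
#'   regulation_calls.tsv, codon_enrichment.tsv, motif_results.tsv and
#'   summary.json there.
#' @return (Invisibly) a list: `de` (per-fraction `de_result`s), `regulation`,
#'   `codon` (see [codon_chi2()]), `motif` (scan table, prevalence, fisher),
#'   `truth` (when simulated), and `summary` (category counts, enriched
#'   codons, motif prevalence).
#' @export
run_pipeline <- function(counts = NULL, transcripts = NULL,
                         sim = sim_config(),
                         thresholds = de_thresholds(),
                         motif_cfg = motif_config(),
                         u34_set = u34_codons(),
                         min_cpm = 1, out_dir = NULL) {
  truth <- NULL
  if (is.null(counts) || is.null(transcripts)) {
    ds <- simulate_dataset(sim)
    if (is.null(counts)) counts <- ds$counts
    if (is.null(transcripts)) transcripts <- ds$transcripts
    truth <- ds$truth
  }
  stopifnot(all(c("total", "light", "heavy") %in% names(counts)))
  if (!("protein" %in% names(transcripts))) {
    transcripts <- add_proteins(transcripts)
  }

  de <- lapply(counts[c("total", "light", "heavy")], function(st) {
    de_test(filter_low(st, min_cpm = min_cpm), thresholds)
  })
  regulation <- classify_regulation(de$total, de$light, de$heavy)

  post_genes <- regulation$gene_id[
    regulation$category == "post_transcriptional"]
  post_in_tx <- intersect(post_genes, transcripts$gene_id)
  codon <- NULL
  if (length(post_in_tx) > 0L) {
    codon <- codon_chi2(codon_usage(transcripts, post_in_tx),
                        codon_usage(transcripts), u34_set = u34_set)
  }

  motif_all <- scan_motif_table(transcripts, motif_cfg)
  motif_set <- motif_all[motif_all$gene_id %in% post_in_tx, , drop = FALSE]
  motif <- list(scan = motif_all)
  if (nrow(motif_set) > 0L) {
    motif$prevalence <- motif_prevalence(motif_set)
    motif$fisher <- motif_fisher(motif_set, motif_all)
  }

  enriched_codons <- if (is.null(codon)) character() else {
    codon$table$codon[codon$table$enriched]
  }
  summary <- list(
    n_genes_tested = nrow(regulation),
    category_counts = as.list(table(regulation$category)),
    n_nonconverged = sum(vapply(de, function(d) {
      nc <- attr(d, "n_nonconverged")
      if (is.null(nc)) 0L else nc
    }, integer(1L))),
    enriched_codons = as.list(enriched_codons),
    enriched_u34_codons = as.list(intersect(enriched_codons, u34_set)),
    motif_prevalence_percent = if (is.null(motif$prevalence)) NULL else
      motif$prevalence$percent,
    motif_fisher_p = if (is.null(motif$fisher)) NULL else motif$fisher$p)

  result <- list(de = de, regulation = regulation, codon = codon,
                 motif = motif, truth = truth, summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (f in names(result$de)) wt(result$de[[f]], paste0("de_", f, ".tsv"))
  wt(result$regulation, "regulation_calls.tsv")
  if (!is.null(result$codon)) wt(result$codon$table, "codon_enrichment.tsv")
  wt(result$motif$scan, "motif_results.tsv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load a pipeline configuration from YAML
#'
#' Supports either a `simulate:` block (fields of [sim_config()]) or a
#' `counts:` block with per-fraction TSV paths, a `groups:` map and a
#' `fasta:` path; plus optional `thresholds:` (fc_threshold, fdr_threshold)
#' and `motif:` (hydrophilic_residues, min_run) blocks.
#'
#' @param path Path to the YAML file.
#' @return List with elements ready to pass to [run_pipeline()]: `counts`,
#'   `transcripts`, `sim`, `thresholds`, `motif_cfg`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list(counts = NULL, transcripts = NULL, sim = sim_config(),
              thresholds = de_thresholds(), motif_cfg = motif_config())
  if (!is.null(y$simulate)) {
    out$sim <- do.call(sim_config, y$simulate)
  } else if (!is.null(y$counts)) {
    groups <- unlist(y$groups)
    out$counts <- lapply(stats::setNames(nm = c("total", "light", "heavy")),
                         function(f) read_counts(y$counts[[f]], f, groups))
    out$transcripts <- read_fasta(y$fasta)
  } else {
    stop("config needs either a 'simulate' or a 'counts' block")
  }
  if (!is.null(y$thresholds)) out$thresholds <- do.call(de_thresholds,
                                                        y$thresholds)
  if (!is.null(y$motif)) out$motif_cfg <- do.call(motif_config, y$motif)
  out
}
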