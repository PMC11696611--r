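#' Simulation configuration for the synthetic polysome-profiling fixture
#'
#' Bundles and validates the parameters of the synthetic study: a
#' transcriptome with controlled codon usage and planted hydrophilic runs,
#' and negative-binomial count tables for the total, light and heavy
#' fractions with planted transcriptional / post-transcriptional effects.
#' Defaults describe the study conditions the downstream analyses are
#' validated against: 5 replicates per group, a 2-fold effect
#' (`effect_log2fc = 1`), mean dispersion 0.1, and a 3-fold boost of the
#' wobble-uridine codons AAA/GAA/CAA in post-transcriptionally regulated
#' genes.
#'
#' @param n_genes Number of genes.
#' @param n_reps_per_group Replicates per group (KO and CTL); at least 2.
#' @param frac_post,frac_transcriptional,frac_mix Proportions of genes
#'   regulated post-transcriptionally, transcriptionally, and at both levels;
#'   the remainder is unchanged.
#' @param effect_log2fc Magnitude of every planted log2 fold change
#'   (KO relative to CTL); each regulated gene gets a random sign.
#' @param dispersion_mean Mean of the gene-wise NB dispersion phi
#'   (variance = mu + phi mu^2); gene dispersions are log-normal around it.
#' @param libsize_cv Coefficient of variation of the log-normal per-sample
#'   library-size factors.
#' @param cds_length_range Length-two integer vector, CDS length bounds in
#'   nucleotides (rounded to whole codons).
#' @param u34_codon_boost Multiplier (>= 1) applied to the AAA/GAA/CAA codon
#'   probabilities of U34-enriched genes before renormalisation.
#' @param hydrophilic_run_prob Probability that a post-transcriptionally
#'   regulated gene receives one planted run of 5 hydrophilic residues.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_reps_per_group = 5L,
                       frac_post = 0.10,
                       frac_transcriptional = 0.10,
                       frac_mix = 0.05,
                       effect_log2fc = 1,
                       dispersion_mean = 0.1,
                       libsize_cv = 0.2,
                       cds_length_range = c(300L, 1500L),
                       u34_codon_boost = 3,
                       hydrophilic_run_prob = 0.12,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_reps_per_group = as.integer(n_reps_per_group),
              frac_post = frac_post,
              frac_transcriptional = frac_transcriptional,
              frac_mix = frac_mix,
              effect_log2fc = effect_log2fc,
              dispersion_mean = dispersion_mean,
              libsize_cv = libsize_cv,
              cds_length_range = as.integer(cds_length_range),
              u34_codon_boost = u34_codon_boost,
              hydrophilic_run_prob = hydrophilic_run_prob,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, n_reps_per_group >= 2L,
              frac_post >= 0, frac_transcriptional >= 0, frac_mix >= 0,
              dispersion_mean > 0, libsize_cv >= 0,
              u34_codon_boost >= 1,
              hydrophilic_run_prob >= 0, hydrophilic_run_prob <= 1,
              length(cds_length_range) == 2L)
    if (frac_post + frac_transcriptional + frac_mix > 1 + 1e-12) {
      stop("category proportions must sum to at most 1")
    }
    if (cds_length_range[1L] > cds_length_range[2L] ||
        cds_length_range[1L] < 30L) {
      stop("infeasible cds_length_range: need min <= max and min >= 30 nt")
    }
  })
  structure(cfg, class = "sim_config")
}

# The 61 sense codons of the standard genetic code, and per-codon amino acids.
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Base codon sampling distribution of the synthetic transcriptome. Codons
# coding hydrophilic residues are down-weighted so that the per-residue
# hydrophilic frequency is ~0.20, keeping chance penta-hydrophilic runs rare
# (real-proteome-like prevalence) and planted runs informative.
base_codon_probs <- function(hydrophilic = default_hydrophilic_residues(),
                             hydrophilic_weight = 0.3) {
  codons <- sense_codons()
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  w <- ifelse(aa %in% hydrophilic, hydrophilic_weight, 1)
  stats::setNames(w / sum(w), codons)
}

# Boost the U34 codon set of a probability vector and renormalise:
# p'_c = b p_c / (1 + (b-1) q) for c in the set, q = sum of base set mass.
boost_codon_probs <- function(probs, boost, codon_set = u34_codons()) {
  w <- ifelse(names(probs) %in% codon_set, boost, 1)
  p <- probs * w
  p / sum(p)
}

#' Simulate a transcriptome with controlled codon usage and planted motifs
#'
#' Generates one CDS per gene (sense codons only, terminal TAA stop) and the
#' ground-truth table used to score every downstream stage. Genes flagged
#' `u34_enriched` (the post-transcriptionally regulated set) draw their
#' codons from a distribution whose AAA/GAA/CAA probabilities are multiplied
#' by `u34_codon_boost` and renormalised. Genes flagged `has_planted_motif`
#' receive one run of 5 hydrophilic residues, encoded at CDS level.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `transcripts` (data.frame: gene_id, cds, protein) and
#'   `truth` (data.frame: gene_id, true_category, true_log2fc_total/light/
#'   heavy, u34_enriched, has_planted_motif).
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  n_post <- round(cfg$frac_post * n)
  n_trans <- round(cfg$frac_transcriptional * n)
  n_mix <- round(cfg$frac_mix * n)
  if (n_post + n_trans + n_mix > n) stop("category counts exceed n_genes")
  category <- rep(c("post_transcriptional", "transcriptional", "mix",
                    "unchanged"),
                  times = c(n_post, n_trans, n_mix,
                            n - n_post - n_trans - n_mix))
  gene_id <- sprintf("g%05d", seq_len(n))

  base_p <- base_codon_probs()
  boosted_p <- boost_codon_probs(base_p, cfg$u34_codon_boost)
  hydro <- default_hydrophilic_residues()
  codons <- sense_codons()
  aa_of <- unname(Biostrings::GENETIC_CODE[codons])
  hydro_codons <- codons[aa_of %in% hydro]
  hydro_p <- base_p[hydro_codons] / sum(base_p[hydro_codons])

  withr::with_seed(cfg$seed + 1L, {
    u34_enriched <- category == "post_transcriptional"
    has_motif <- u34_enriched &
      stats::runif(n) < cfg$hydrophilic_run_prob
    len_codons <- sample(seq(cfg$cds_length_range[1L] %/% 3L,
                             cfg$cds_length_range[2L] %/% 3L),
                         n, replace = TRUE)
    cds <- character(n)
    for (i in seq_len(n)) {
      p <- if (u34_enriched[i]) boosted_p else base_p
      cc <- sample(codons, len_codons[i], replace = TRUE, prob = p)
      if (has_motif[i]) {
        # plant one penta-hydrophilic run at a random internal position
        start <- sample.int(len_codons[i] - 5L, 1L)
        cc[start:(start + 4L)] <- sample(hydro_codons, 5L, replace = TRUE,
                                         prob = hydro_p)
      }
      cds[i] <- paste0(paste(cc, collapse = ""), "TAA")
    }
    sign <- sample(c(-1, 1), n, replace = TRUE)
  })

  e <- cfg$effect_log2fc
  lfc_total <- ifelse(category %in% c("transcriptional", "mix"), sign * e, 0)
  lfc_light <- ifelse(category == "post_transcriptional", sign * e, 0)
  lfc_heavy <- ifelse(category %in% c("post_transcriptional", "mix"),
                      sign * e, 0)

  transcripts <- add_proteins(
    data.frame(gene_id = gene_id, cds = cds, stringsAsFactors = FALSE))
  truth <- data.frame(gene_id = gene_id,
                      true_category = category,
                      true_log2fc_total = lfc_total,
                      true_log2fc_light = lfc_light,
                      true_log2fc_heavy = lfc_heavy,
                      u34_enriched = u34_enriched,
                      has_planted_motif = has_motif,
                      stringsAsFactors = FALSE)
  list(transcripts = transcripts, truth = truth)
}

#' Simulate NB count tables for the three polysome fractions
#'
#' Counts follow NB(mean = libsize_j x baseline_i x 2^(x_j true_log2fc_f,i),
#' dispersion phi_i) with x_j = 1 for KO samples. Gene baselines are
#' log-normal; gene dispersions are log-normal with mean
#' `cfg$dispersion_mean`; per-sample library-size factors are log-normal
#' with CV `cfg$libsize_cv`. Fractions are conditionally independent given
#' the gene baseline. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param truth Ground-truth table from [simulate_transcriptome()].
#' @return Named list of three [sample_table()]s: `total`, `light`, `heavy`.
#' @export
simulate_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(truth))
  n <- nrow(truth)
  reps <- cfg$n_reps_per_group
  group <- rep(c("CTL", "KO"), each = reps)
  x <- as.numeric(group == "KO")
  sample_ids <- paste0(group, "_", rep(seq_len(reps), 2L))
  sdlog_lib <- sqrt(log(1 + cfg$libsize_cv^2))
  lfc <- list(total = truth$true_log2fc_total,
              light = truth$true_log2fc_light,
              heavy = truth$true_log2fc_heavy)

  withr::with_seed(cfg$seed + 2L, {
    baseline <- stats::rlnorm(n, meanlog = log(100), sdlog = 1.2)
    phi <- cfg$dispersion_mean *
      stats::rlnorm(n, meanlog = -0.125, sdlog = 0.5)
    out <- lapply(names(lfc), function(f) {
      libsize <- stats::rlnorm(length(group), meanlog = -sdlog_lib^2 / 2,
                               sdlog = sdlog_lib)
      mu <- outer(baseline, libsize) * 2^(lfc[[f]] %o% x)
      counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
                       nrow = n,
                       dimnames = list(truth$gene_id, sample_ids))
      sample_table(counts, group = group, fraction = f)
    })
  })
  stats::setNames(out, names(lfc))
}

#' Simulate the full fixture (transcriptome + counts + truth)
#'
#' @param cfg A [sim_config()].
#' @return List with `transcripts`, `truth`, and `counts` (list of three
#'   [sample_table()]s).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  tx <- simulate_transcriptome(cfg)
  counts <- simulate_counts(cfg, tx$truth)
  list(transcripts = tx$transcripts, truth = tx$truth, counts = counts)
}

#' Write a simulated dataset to disk
#'
#' Writes transcriptome.fasta, counts_total/light/heavy.tsv, truth.tsv and
#' the resolved configuration as config.yaml into `dir`.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param cfg The [sim_config()] that produced it.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$transcripts, file.path(dir, "transcriptome.fasta"))
  for (f in names(dataset$counts)) {
    write_counts(dataset$counts[[f]],
                 file.path(dir, paste0("counts_", f, ".tsv")))
  }
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
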