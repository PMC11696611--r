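test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_genes = 100L, seed = 7L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$truth, b$truth)
  for (f in names(a$counts)) {
    expect_identical(a$counts[[f]]$counts, b$counts[[f]]$counts)
  }
  # a different seed changes the draws
  c <- simulate_dataset(sim_config(n_genes = 100L, seed = 8L))
  expect_false(identical(a$counts$total$counts, c$counts$total$counts))
})

test_that("truth categories are consistent with the planted log2fc pattern", {
  tx <- simulate_transcriptome(sim_config(n_genes = 500L, seed = 3L))
  tr <- tx$truth
  expect_setequal(unique(tr$true_category),
                  c("post_transcriptional", "transcriptional", "mix",
                    "unchanged"))
  post <- tr$true_category == "post_transcriptional"
  expect_true(all(tr$true_log2fc_total[post] == 0))
  expect_true(all(tr$true_log2fc_heavy[post] != 0 |
                    tr$true_log2fc_light[post] != 0))
  trans <- tr$true_category == "transcriptional"
  expect_true(all(tr$true_log2fc_total[trans] != 0))
  expect_true(all(tr$true_log2fc_light[trans] == 0 &
                    tr$true_log2fc_heavy[trans] == 0))
  mix <- tr$true_category == "mix"
  expect_true(all(tr$true_log2fc_total[mix] != 0 &
                    tr$true_log2fc_heavy[mix] != 0))
  unch <- tr$true_category == "unchanged"
  expect_true(all(tr$true_log2fc_total[unch] == 0 &
                    tr$true_log2fc_light[unch] == 0 &
                    tr$true_log2fc_heavy[unch] == 0))
  expect_identical(tr$u34_enriched, post)
})

test_that("all generated CDS satisfy the transcript invariants", {
  tx <- simulate_transcriptome(sim_config(n_genes = 200L, seed = 9L))
  lens <- nchar(tx$transcripts$cds)
  expect_true(all(lens %% 3L == 0L))
  # translate_cds would error on an internal stop; proteins drop the stop
  expect_equal(nchar(tx$transcripts$protein), lens / 3L - 1L)
})

test_that("u34_codon_boost = 1 leaves enriched-gene codon usage at background", {
  cfg <- sim_config(n_genes = 600L, u34_codon_boost = 1,
                    hydrophilic_run_prob = 0, seed = 21L)
  tx <- simulate_transcriptome(cfg)
  u34 <- u34_codons()
  freq_of <- function(ids) {
    cc <- codon_usage(tx$transcripts, ids)
    sum(cc[u34]) / sum(cc)
  }
  f_set <- freq_of(tx$truth$gene_id[tx$truth$u34_enriched])
  f_bg <- freq_of(tx$truth$gene_id[!tx$truth$u34_enriched])
  # binomial error on >30k codons per side is well under 0.01
  expect_lt(abs(f_set - f_bg), 0.01)
})

test_that("boosted U34 frequency matches the renormalisation closed form", {
  boost <- 3
  cfg <- sim_config(n_genes = 1000L, u34_codon_boost = boost,
                    hydrophilic_run_prob = 0, seed = 22L)
  tx <- simulate_transcriptome(cfg)
  base <- translatome:::base_codon_probs()
  q <- sum(base[u34_codons()])
  expected <- boost * q / (1 + (boost - 1) * q)
  cc <- codon_usage(tx$transcripts,
                    tx$truth$gene_id[tx$truth$u34_enriched])
  empirical <- sum(cc[u34_codons()]) / sum(cc)
  expect_lt(abs(empirical - expected), 0.01)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- sim_config(n_genes = 1000L, dispersion_mean = 1e-8,
                    libsize_cv = 0, frac_post = 0, frac_transcriptional = 0,
                    frac_mix = 0, seed = 31L)
  tx <- simulate_transcriptome(cfg)
  counts <- simulate_counts(cfg, tx$truth)$total$counts
  m <- rowMeans(counts)
  v <- apply(counts, 1L, stats::var)
  keep <- m > 5
  expect_lt(abs(mean(v[keep] / m[keep]) - 1), 0.1)
})

test_that("the moment estimator recovers the configured mean dispersion", {
  cfg <- sim_config(n_genes = 500L, n_reps_per_group = 50L,
                    dispersion_mean = 0.2, libsize_cv = 0, frac_post = 0,
                    frac_transcriptional = 0, frac_mix = 0, seed = 32L)
  tx <- simulate_transcriptome(cfg)
  counts <- simulate_counts(cfg, tx$truth)$total$counts
  m <- rowMeans(counts)
  v <- apply(counts, 1L, stats::var)
  phi_hat <- pmax(0, (v - m) / m^2)
  expect_lt(abs(mean(phi_hat) - 0.2) / 0.2, 0.15)
})

test_that("planted heavy-fraction effects are recovered empirically", {
  cfg <- sim_config(n_genes = 300L, n_reps_per_group = 50L,
                    effect_log2fc = 1, libsize_cv = 0, seed = 33L)
  ds <- simulate_dataset(cfg)
  counts <- ds$counts$heavy$counts
  g <- ds$counts$heavy$group
  lfc_emp <- log2(rowMeans(counts[, g == "KO"]) /
                    rowMeans(counts[, g == "CTL"]))
  planted <- ds$truth$true_log2fc_heavy != 0
  expect_gt(sum(planted), 30L)
  err <- lfc_emp[planted] - ds$truth$true_log2fc_heavy[planted]
  expect_lt(abs(mean(err)), 0.1)
})

test_that("every planted-motif gene is motif-positive under the scanner", {
  cfg <- sim_config(n_genes = 800L, hydrophilic_run_prob = 0.5, seed = 41L)
  tx <- simulate_transcriptome(cfg)
  planted <- tx$truth$has_planted_motif
  expect_gt(sum(planted), 20L)
  scan <- scan_motif_table(tx$transcripts[planted, , drop = FALSE])
  expect_true(all(scan$has_motif))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(cds_length_range = c(9L, 6L)), "infeasible")
  expect_error(sim_config(frac_post = 0.6, frac_transcriptional = 0.6),
               "at most 1")
  expect_error(sim_config(n_reps_per_group = 1L))
  expect_error(sim_config(u34_codon_boost = 0.5))
})

test_that("write_dataset produces a loadable, identical fixture", {
  cfg <- sim_config(n_genes = 60L, seed = 12L)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, cfg, dir)
  groups <- stats::setNames(as.character(ds$counts$total$group),
                            colnames(ds$counts$total$counts))
  back <- read_counts(file.path(dir, "counts_heavy.tsv"), "heavy", groups)
  expect_identical(back$counts, ds$counts$heavy$counts)
  tx <- read_fasta(file.path(dir, "transcriptome.fasta"))
  expect_identical(tx$cds, ds$transcripts$cds)
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$n_genes, cfg$n_genes)
})
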