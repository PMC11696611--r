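# Independent oracles the implementation is checked against. Each one takes
# the dumbest correct route (brute force, direct enumeration, an unrelated
# library path) so that agreement is evidence, not tautology.

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, m * ps / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Pearson chi-squared on a 2x2 table via stats::chisq.test (no continuity
# correction), an implementation path independent of the vectorised formula.
chi2_2x2_oracle <- function(a, b, c, d) {
  suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), nrow = 2L,
                                            byrow = TRUE),
                                     correct = FALSE))
}

# Maximal hydrophilic runs by greedy regex matching.
motif_oracle <- function(protein, residues, min_run) {
  pat <- sprintf("[%s]{%d,}", paste(residues, collapse = ""), min_run)
  m <- gregexpr(pat, protein)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Median-of-ratios size factors computed gene-by-gene with explicit loops.
size_factor_oracle <- function(counts) {
  use <- apply(counts, 1L, function(r) all(r > 0))
  ref <- apply(counts[use, , drop = FALSE], 1L,
               function(r) prod(r)^(1 / length(r)))
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    stats::median(counts[use, j] / ref)
  }, numeric(1L))
  sf / prod(sf)^(1 / length(sf))
}

# Poisson two-group LRT by direct 1-D likelihood maximisation (optimize),
# independent of the package's Fisher-scoring path. Valid for phi = 0.
poisson_lrt_oracle <- function(y, group, sf) {
  ll <- function(lambda, yy, ss) sum(stats::dpois(yy, lambda * ss, log = TRUE))
  fit <- function(yy, ss) {
    if (sum(yy) == 0) return(0)
    stats::optimize(ll, c(1e-8, 10 * sum(yy) / sum(ss)), yy = yy, ss = ss,
                    maximum = TRUE, tol = 1e-10)$objective
  }
  l_full <- fit(y[group == "KO"], sf[group == "KO"]) +
    fit(y[group == "CTL"], sf[group == "CTL"])
  l_null <- fit(y, sf)
  lrt <- max(0, 2 * (l_full - l_null))
  list(lrt = lrt, p = stats::pchisq(lrt, df = 1L, lower.tail = FALSE))
}

# Random in-frame CDS over the 61 sense codons (no stops anywhere).
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# Random protein over the 20 standard residues.
random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], len,
               replace = TRUE), collapse = "")
}

# Small NB count sample_table with a two-group design.
make_nb_table <- function(n_genes, reps, mu_fun, phi, fraction = "total",
                          libsize = rep(1, 2 * reps)) {
  group <- rep(c("CTL", "KO"), each = reps)
  mu <- mu_fun(n_genes, group) * rep(libsize, each = n_genes)
  counts <- matrix(stats::rnbinom(n_genes * 2 * reps, mu = mu,
                                  size = 1 / pmax(phi, 1e-12)),
                   nrow = n_genes,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   paste0(group, "_", rep(seq_len(reps), 2L))))
  sample_table(counts, group, fraction)
}
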