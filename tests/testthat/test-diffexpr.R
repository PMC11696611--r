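test_that("size factors are 1 for identical columns and track scaling", {
  m <- matrix(rep(c(10L, 20L, 5L, 40L), 4L), ncol = 4L,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4), tolerance = 1e-12)

  m2 <- m
  m2[, 2L] <- m2[, 2L] * 2L
  sf <- size_factors(m2)
  expect_equal(unname(sf[2L] / sf[1L]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("size factors equal the hand-computed median-of-ratios oracle", {
  set.seed(51)
  m <- matrix(rpois(5 * 6, lambda = 50) + 1L, nrow = 5L,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)), size_factor_oracle(m),
               tolerance = 1e-12)
})

test_that("size factors are proportional to the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(52)
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 5), nrow = 200L,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours / ref), rep(unname(ours[1] / ref[1]), 6L),
               tolerance = 1e-8)
})

test_that("size_factors errors when no gene is expressed everywhere", {
  m <- matrix(c(0L, 5L, 3L, 0L), nrow = 2L,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(m), "filter")
})

test_that("filter_low applies the inclusive CPM-in-enough-samples rule", {
  set.seed(53)
  st <- make_nb_table(200L, 3L, function(n, g) rep(runif(n, 0.1, 200), 6L),
                      phi = 0.1)
  kept <- filter_low(st, min_cpm = 1, min_samples = 3L)
  cpm <- sweep(st$counts, 2L, colSums(st$counts), "/") * 1e6
  oracle <- rownames(st$counts)[rowSums(cpm >= 1) >= 3L]
  expect_identical(rownames(kept$counts), oracle)

  # all-zero gene is always removed
  m <- st$counts
  m[1L, ] <- 0L
  st0 <- sample_table(m, st$group, "total")
  expect_false("g0001" %in% rownames(filter_low(st0)$counts))
})

test_that("a gene exactly at min_cpm in min_samples samples is kept", {
  # column sums 1e6 so counts are CPM directly
  base <- matrix(0L, nrow = 4L, ncol = 4L,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  base[1L, ] <- c(5L, 5L, 0L, 0L)          # cpm 5 in 2 samples
  base[2L, ] <- c(1L, 1L, 0L, 0L)          # cpm exactly 1 in 2 samples
  base[3L, ] <- c(1L, 0L, 0L, 0L)          # cpm 1 in 1 sample only
  base[4L, ] <- 1e6L - colSums(base)
  st <- sample_table(base, c("CTL", "CTL", "KO", "KO"), "total")
  kept <- rownames(filter_low(st, min_cpm = 1, min_samples = 2L)$counts)
  expect_true(all(c("g1", "g2") %in% kept))
  expect_false("g3" %in% kept)
})

test_that("dispersion estimates vanish for Poisson data at large means", {
  set.seed(54)
  st <- make_nb_table(800L, 10L, function(n, g) rep(500, n * length(g)),
                      phi = 0)
  phi <- estimate_dispersion(st, rep(1, 20L))
  expect_lt(mean(phi), 0.01)
})

test_that("dispersion estimates recover phi = 0.1 with 50 replicates", {
  set.seed(55)
  st <- make_nb_table(500L, 50L,
                      function(n, g) rep(rlnorm(n, log(100), 1), length(g)),
                      phi = 0.1)
  phi <- estimate_dispersion(st, size_factors(st))
  expect_lt(abs(mean(phi) - 0.1) / 0.1, 0.2)
})

test_that("a constant gene gets the floor dispersion", {
  m <- matrix(7L, nrow = 2L, ncol = 4L,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  st <- sample_table(m, c("CTL", "CTL", "KO", "KO"), "total")
  phi <- estimate_dispersion(st, rep(1, 4L))
  expect_equal(unname(phi), rep(1e-8, 2L))
})

test_that("identical groups give the exact null result", {
  m <- matrix(rep(c(10L, 25L, 3L), 4L), nrow = 3L,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  st <- sample_table(m, c("CTL", "CTL", "KO", "KO"), "total")
  res <- nb_lrt(st, rep(1, 4L), phi = rep(0.1, 3L))
  expect_equal(res$log2fc, rep(0, 3L), tolerance = 1e-8)
  expect_equal(res$lrt_stat, rep(0, 3L), tolerance = 1e-8)
  expect_equal(res$p_value, rep(1, 3L), tolerance = 1e-8)
})

test_that("the NB LRT at phi = 0 matches a direct Poisson likelihood oracle", {
  set.seed(56)
  group <- rep(c("CTL", "KO"), each = 4L)
  sf <- c(0.8, 1.1, 1.0, 0.9, 1.2, 1.0, 0.7, 1.3)
  for (i in 1:25) {
    y <- rpois(8L, lambda = sample(c(2, 5, 20), 1L) * sf *
                 ifelse(group == "KO", runif(1, 0.5, 2), 1))
    m <- matrix(y, nrow = 1L, dimnames = list("g1", paste0("s", 1:8)))
    st <- sample_table(m, group, "total")
    res <- nb_lrt(st, sf, phi = 0)
    oracle <- poisson_lrt_oracle(y, group, sf)
    expect_equal(res$lrt_stat, oracle$lrt, tolerance = 1e-6)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-6)
  }
})

test_that("the NB LRT agrees with a fixed-theta GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(57)
  group <- rep(c("CTL", "KO"), each = 5L)
  sf <- rep(1, 10L)
  phi <- 0.15
  for (i in 1:10) {
    y <- rnbinom(10L, mu = 60 * ifelse(group == "KO", 1.8, 1), size = 1 / phi)
    m <- matrix(y, nrow = 1L, dimnames = list("g1", paste0("s", 1:10)))
    st <- sample_table(m, group, "total")
    res <- nb_lrt(st, sf, phi = phi)
    fam <- MASS::negative.binomial(theta = 1 / phi)
    full <- stats::glm(y ~ group, family = fam)
    null <- stats::glm(y ~ 1, family = fam)
    lrt_glm <- null$deviance - full$deviance
    expect_equal(res$lrt_stat, lrt_glm, tolerance = 1e-5)
    expect_equal(res$log2fc, unname(coef(full)["groupKO"]) / log(2),
                 tolerance = 1e-5)
  }
})

test_that("the LRT is invariant to sample order and flips sign with labels", {
  set.seed(58)
  st <- make_nb_table(50L, 4L,
                      function(n, g) rep(rlnorm(n, log(50), 1), length(g)) *
                        ifelse(rep(g == "KO", each = n), 1.5, 1),
                      phi = 0.1)
  sf <- size_factors(st)
  phi <- rep(0.1, 50L)
  base <- nb_lrt(st, sf, phi)

  perm <- sample(ncol(st$counts))
  st_perm <- sample_table(st$counts[, perm], as.character(st$group)[perm],
                          "total")
  perm_res <- nb_lrt(st_perm, sf[perm], phi)
  expect_equal(perm_res$lrt_stat, base$lrt_stat, tolerance = 1e-7)

  flipped <- ifelse(as.character(st$group) == "KO", "CTL", "KO")
  st_flip <- sample_table(st$counts, flipped, "total")
  flip_res <- nb_lrt(st_flip, sf, phi)
  expect_equal(flip_res$log2fc, -base$log2fc, tolerance = 1e-7)
  expect_equal(flip_res$lrt_stat, base$lrt_stat, tolerance = 1e-7)
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust equals the brute-force oracle and passes NA through", {
  set.seed(59)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1L))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  p <- c(0.01, NA, 0.04, 0.2)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2L]))
  expect_equal(adj[-2L], bh_oracle(p[-2L]), tolerance = 1e-12)
})

test_that("significance thresholds are inclusive on FC and strict on FDR", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(log2(1.2), 0.5, -2, log2(1.19)),
                    lrt_stat = 1, p_value = 0.01,
                    fdr = c(0.19, 0.2, 0.01, 0.01))
  polysome <- call_de(res, de_thresholds(1.2, 0.2), "heavy")
  expect_true(polysome$significant[1L])    # |FC| = 1.2 exactly, fdr 0.19
  expect_false(polysome$significant[2L])   # fdr = 0.2 is not < 0.2
  expect_false(polysome$significant[4L])   # |FC| just under threshold
  brain <- call_de(res, de_thresholds(2.0, 0.05), "brain")
  expect_true(brain$significant[3L])       # 4-fold down, fdr 0.01
  expect_false(brain$significant[1L])
})

test_that("missing FDR (non-converged fits) is never significant", {
  res <- data.frame(gene_id = "a", log2fc = 3, lrt_stat = 10,
                    p_value = NA_real_, fdr = NA_real_)
  expect_false(call_de(res, de_thresholds())$significant)
})

test_that("the engine detects 2-fold changes with high sensitivity", {
  # 500 genes all carrying a 2-fold effect (random sign); since every gene
  # is shifted, unit size factors are supplied rather than estimated
  set.seed(60)
  n <- 500L
  group <- rep(c("CTL", "KO"), each = 5L)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  mu <- outer(rlnorm(n, log(100), 1), rep(1, 10L)) *
    2^(sgn %o% as.numeric(group == "KO"))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), nrow = n,
                   dimnames = list(sprintf("g%04d", 1:n),
                                   paste0(group, "_", rep(1:5, 2L))))
  st <- sample_table(counts, group, "total")
  phi <- estimate_dispersion(st, rep(1, 10L))
  res <- nb_lrt(st, rep(1, 10L), phi)
  res$fdr <- bh_adjust(res$p_value)
  de <- call_de(res, de_thresholds(1.2, 0.2), "total")
  expect_gte(mean(de$significant), 0.8)
})
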