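#' Significance thresholds for differential-abundance calls
#'
#' Two contexts are used throughout: polysome fractions (absolute fold
#' change >= 1.2 with FDR-adjusted p < 0.2) and whole-brain RNA-seq (fold
#' change > 2 with FDR < 0.05, here encoded as the |FC| >= 2 and FDR < 0.05
#' boundary). The fold-change comparison is inclusive (>=) and the FDR
#' comparison strict (<).
#'
#' @param fc_threshold Linear-scale fold-change threshold, >= 1.
#' @param fdr_threshold FDR cut in (0, 1).
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(fc_threshold = 1.2, fdr_threshold = 0.2) {
  stopifnot(fc_threshold >= 1, fdr_threshold > 0, fdr_threshold < 1)
  structure(list(fc_threshold = fc_threshold, fdr_threshold = fdr_threshold),
            class = "de_thresholds")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: each sample's median ratio to the
#' per-gene geometric-mean reference (genes expressed in all samples),
#' rescaled so the geometric mean of the factors is 1.
#'
#' @param table A [sample_table()] or a count matrix.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(table) {
  counts <- if (inherits(table, "sample_table")) table$counts else table
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    stop("no gene has nonzero counts in every sample; filter the table first")
  }
  logref <- rowMeans(log(counts[use, , drop = FALSE]))
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(col) exp(stats::median(log(col) - logref)))
  sf / exp(mean(log(sf)))
}

#' Filter weakly expressed genes
#'
#' Keeps genes with CPM >= `min_cpm` (counts per million of the raw column
#' totals) in at least `min_samples` samples; both comparisons inclusive.
#'
#' @param table A [sample_table()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Minimum number of samples; defaults to the smaller
#'   group size.
#' @return The filtered [sample_table()].
#' @export
filter_low <- function(table, min_cpm = 1, min_samples = NULL) {
  stopifnot(inherits(table, "sample_table"))
  if (is.null(min_samples)) min_samples <- min(table(table$group))
  cpm <- sweep(table$counts, 2L, colSums(table$counts), "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) stop("filter removed every gene; lower min_cpm")
  sample_table(table$counts[keep, , drop = FALSE], table$group,
               table$fraction)
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per-gene dispersion phi (variance = mu + phi mu^2) estimated on
#' size-factor-scaled counts: the pooled within-group variance s2 and the
#' overall mean m give phi_raw = max(0, (s2 - m) / m^2), which is then
#' shrunk toward a smooth mean-dispersion trend, retaining a fixed weight
#' `gene_weight` (default 0.3) on the per-gene moment estimate and pulling
#' the remainder to the trend, then floored. The trend is a plain local
#' average (lowess without robustness iterations) of phi_raw on log mean:
#' the moment estimator is right-skewed, so robust iterations would bias the
#' trend toward the median and systematically understate the dispersion.
#' With few samples the per-gene estimate is noisy and the strong pull to
#' the trend is what keeps the downstream likelihood-ratio test calibrated.
#'
#' @param table A [sample_table()].
#' @param factors Size factors from [size_factors()].
#' @param gene_weight Weight retained on the per-gene moment estimate
#'   (default 0.3); `1 - gene_weight` goes to the trend.
#' @param floor Lower bound for the returned dispersions (default 1e-8).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(table, factors = size_factors(table),
                                gene_weight = 0.3, floor = 1e-8) {
  stopifnot(inherits(table, "sample_table"))
  counts <- table$counts
  scaled <- sweep(counts, 2L, factors, "/")
  g <- table$group
  n <- ncol(scaled)
  ss <- 0
  for (lev in levels(g)) {
    cols <- scaled[, g == lev, drop = FALSE]
    ss <- ss + rowSums((cols - rowMeans(cols))^2)
  }
  s2 <- ss / (n - nlevels(g))
  m <- rowMeans(scaled)
  phi_raw <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  ok <- m > 0
  phi <- rep(floor, nrow(counts))
  if (sum(ok) >= 10L) {
    lo <- stats::lowess(log(m[ok]), phi_raw[ok], f = 0.5, iter = 0L)
    trend <- pmax(floor, stats::approx(lo$x, lo$y, xout = log(m[ok]),
                                       rule = 2L, ties = mean)$y)
    phi[ok] <- gene_weight * phi_raw[ok] + (1 - gene_weight) * trend
  } else {
    phi[ok] <- phi_raw[ok]
  }
  phi <- pmax(phi, floor)
  names(phi) <- rownames(counts)
  phi
}

# NB log-likelihood at fixed dispersion, Poisson in the phi -> 0 limit.
# y, mu: matrices (genes x samples); phi: per-gene vector.
nb_loglik <- function(y, mu, phi) {
  size <- 1 / pmax(phi, 1e-12)
  ll <- stats::dnbinom(y, mu = mu, size = size, log = TRUE)
  ll[y == 0 & mu == 0] <- 0
  rowSums(ll)
}

# Fisher-scoring fit of a single per-gene rate lambda with offsets sf:
# mu_ij = sf_j * lambda_i under NB(phi_i). Vectorised across genes.
# Returns lambda, the maximised log-likelihood and a convergence flag.
fit_nb_rate <- function(y, sf, phi, max_iter = 50L, tol = 1e-10) {
  n <- nrow(y)
  tot <- rowSums(y)
  lambda <- tot / sum(sf)
  zero <- tot == 0
  eta <- ifelse(zero, 0, log(pmax(lambda, 1e-300)))
  converged <- rep(TRUE, n)
  active <- !zero
  if (any(active)) {
    conv <- rep(FALSE, n)
    for (it in seq_len(max_iter)) {
      idx <- which(active & !conv)
      if (length(idx) == 0L) break
      mu <- exp(eta[idx]) %o% sf
      denom <- 1 + phi[idx] * mu
      score <- rowSums((y[idx, , drop = FALSE] - mu) / denom)
      info <- rowSums(mu / denom)
      step <- pmin(pmax(score / info, -5), 5)
      eta[idx] <- eta[idx] + step
      conv[idx] <- abs(step) < tol
    }
    converged[active] <- conv[active]
  }
  lambda <- ifelse(zero, 0, exp(eta))
  mu <- lambda %o% sf
  list(lambda = lambda, loglik = nb_loglik(y, mu, phi),
       converged = converged | zero)
}

#' Negative-binomial likelihood-ratio test of a two-group effect
#'
#' For each gene, fits mu = s_j exp(beta0 + beta1 1[KO]) at fixed gene-wise
#' dispersion by Fisher scoring, against the null beta1 = 0. The statistic
#' is 2(l_full - l_null) clipped at zero, referred to chi-squared with 1 df;
#' log2fc = beta1 / ln 2 = log2(lambda_KO / lambda_CTL). Non-converged genes
#' get p = NA and are excluded from BH adjustment downstream.
#'
#' @param table A [sample_table()].
#' @param factors Size factors.
#' @param phi Per-gene dispersions.
#' @return data.frame: gene_id, log2fc, lrt_stat, p_value, converged.
#' @export
nb_lrt <- function(table, factors = size_factors(table),
                   phi = estimate_dispersion(table, factors)) {
  stopifnot(inherits(table, "sample_table"))
  y <- table$counts
  g <- table$group
  phi <- rep_len(phi, nrow(y))
  fit_ko <- fit_nb_rate(y[, g == "KO", drop = FALSE], factors[g == "KO"], phi)
  fit_ctl <- fit_nb_rate(y[, g == "CTL", drop = FALSE], factors[g == "CTL"],
                         phi)
  fit_null <- fit_nb_rate(y, factors, phi)
  lrt <- pmax(0, 2 * (fit_ko$loglik + fit_ctl$loglik - fit_null$loglik))
  converged <- fit_ko$converged & fit_ctl$converged & fit_null$converged
  p <- ifelse(converged, stats::pchisq(lrt, df = 1L, lower.tail = FALSE), NA)
  data.frame(gene_id = rownames(y),
             log2fc = log2(fit_ko$lambda / fit_ctl$lambda),
             lrt_stat = lrt,
             p_value = p,
             converged = converged,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment with NA pass-through
#'
#' Step-up FDR adjustment over the non-missing p-values; NA/NaN entries
#' (non-converged fits) pass through unadjusted and do not count toward the
#' family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, possibly with NA.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Apply significance thresholds to LRT results
#'
#' significant <=> |log2fc| >= log2(fc_threshold) AND fdr < fdr_threshold
#' (fold-change boundary inclusive, FDR boundary strict). Genes with missing
#' FDR are never significant.
#'
#' @param results data.frame from [nb_lrt()], with an `fdr` column (see
#'   [bh_adjust()]).
#' @param thresholds A [de_thresholds()].
#' @param fraction Fraction label stored in the output.
#' @return data.frame of class `de_result`: gene_id, log2fc, lrt_stat,
#'   p_value, fdr, significant, fraction.
#' @export
call_de <- function(results, thresholds = de_thresholds(),
                    fraction = "unknown") {
  stopifnot(inherits(thresholds, "de_thresholds"), "fdr" %in% names(results))
  sig <- !is.na(results$fdr) &
    abs(results$log2fc) >= log2(thresholds$fc_threshold) &
    results$fdr < thresholds$fdr_threshold
  out <- data.frame(gene_id = results$gene_id,
                    log2fc = results$log2fc,
                    lrt_stat = results$lrt_stat,
                    p_value = results$p_value,
                    fdr = results$fdr,
                    significant = sig,
                    fraction = fraction,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Full per-fraction differential-abundance test
#'
#' Convenience wrapper: size factors, dispersion estimation, NB LRT, BH
#' adjustment (non-converged genes excluded from the family; their number is
#' reported via the `n_nonconverged` attribute), and threshold calls.
#'
#' @param table A [sample_table()].
#' @param thresholds A [de_thresholds()].
#' @return A `de_result` data.frame (see [call_de()]).
#' @export
de_test <- function(table, thresholds = de_thresholds()) {
  sf <- size_factors(table)
  phi <- estimate_dispersion(table, sf)
  res <- nb_lrt(table, sf, phi)
  res$fdr <- bh_adjust(res$p_value)
  out <- call_de(res, thresholds, fraction = table$fraction)
  attr(out, "n_nonconverged") <- sum(!res$converged)
  out
}
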