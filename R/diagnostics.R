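#' Binomial downsampling of a contact map
#'
#' Replaces every count by a Binomial(count, fraction) draw, emulating
#' sequencing a library to a lower depth.  Independent calls with distinct
#' seeds on the same parent map produce the (conditionally) independent
#' train/test replicates used for held-out scoring.
#'
#' @param o A [contact_map()].
#' @param fraction Retention probability, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return A [contact_map()] at reduced depth.
#' @export
downsample_map <- function(o, fraction, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be strictly between 0 and 1")
  }
  e <- o$entries
  counts <- with_seed(seed,
                      stats::rbinom(nrow(e), as.integer(e$count), fraction))
  contact_map(
    data.table::data.table(i = e$i, j = e$j, count = counts)[counts > 0],
    n_bins = o$n_bins, bin_size = o$bin_size, chrom = o$chrom,
    max_distance_bins = o$max_distance_bins
  )
}

# Observed counts aligned with the pixel table of a posterior_samples
# object (absent pairs = 0).
counts_for_pixels <- function(ps, o) {
  if (o$n_bins != ps$n_bins || o$max_distance_bins < ps$band) {
    stop("contact map grid does not match the posterior samples")
  }
  map_value(o, ps$pixels$i, ps$pixels$j)
}

#' Posterior predictive check with randomized p-values
#'
#' For each pixel the posterior predictive CDF is the average over
#' posterior draws of the Poisson CDF at rate `b_ij * t_ij^(s)`.  Because
#' counts are discrete, the p-value is drawn uniformly between
#' `CDF(o - 1)` and `CDF(o)` (randomized PIT), which is exactly
#' Uniform(0, 1) when the model matches the data-generating process.  The
#' one-sample Kolmogorov-Smirnov statistic against Uniform(0, 1) summarises
#' calibration.
#'
#' @param ps A `posterior_samples` object with at least 50 draws.
#' @param o Observed [contact_map()] on the same grid.
#' @param bias The [bias_vector()] used in the run.
#' @param seed Seed for the randomization.
#' @return List with `p_values` (per pixel), `ks_stat`, and `n_pixels`.
#' @export
ppc_pvalues <- function(ps, o, bias, seed = 1L) {
  if (is.null(ps$draws) || ncol(ps$draws) < 50L) {
    stop("at least 50 posterior draws are required")
  }
  obs <- counts_for_pixels(ps, o)
  b_ij <- bias$values[ps$pixels$i + 1L] * bias$values[ps$pixels$j + 1L]
  rates <- ps$draws * b_ij
  f_hi <- rowMeans(stats::ppois(obs, rates))
  f_lo <- rowMeans(stats::ppois(obs - 1, rates))
  p <- with_seed(seed, f_lo + stats::runif(length(obs)) * (f_hi - f_lo))
  ks <- as.numeric(stats::ks.test(p, "punif")$statistic)
  list(p_values = p, ks_stat = ks, n_pixels = length(p))
}

#' Held-out log-likelihood of a test map
#'
#' Approximates the log-likelihood of an independent test contact map as
#' the mean, over the first `n_draws` posterior draws, of the Poisson
#' log-likelihood `sum_ij log Pois(test_ij; b_ij * t_ij^(s))` (a mean of
#' log-likelihoods, not a log of mean likelihoods).  Pixels on masked bins
#' are excluded.
#'
#' @param ps A `posterior_samples` object with at least `n_draws` draws.
#' @param test A [contact_map()] on the same grid.
#' @param bias The [bias_vector()] shared by train and test.
#' @param n_draws Number of leading draws to average over.
#' @return Scalar mean held-out log-likelihood.
#' @export
test_loglik <- function(ps, test, bias, n_draws = 100L) {
  if (is.null(ps$draws) || ncol(ps$draws) < n_draws) {
    stop("need at least ", n_draws, " posterior draws")
  }
  obs <- counts_for_pixels(ps, test)
  b_ij <- bias$values[ps$pixels$i + 1L] * bias$values[ps$pixels$j + 1L]
  draws <- ps$draws[, seq_len(n_draws), drop = FALSE]
  ll <- vapply(seq_len(n_draws), function(s) {
    sum(stats::dpois(obs, b_ij * draws[, s], log = TRUE))
  }, 0)
  mean(ll)
}

#' Marginal KL divergence versus number of samples
#'
#' Quantifies how well the marginal posterior of each pixel is
#' approximated by the first `size` draws relative to a `gold_size`-draw
#' gold standard.  Both marginals are histogrammed on shared log-scale
#' bins spanning the gold draws (with add-one smoothing) and
#' `KL(subset || gold)` is averaged over pixels.
#'
#' @param ps A `posterior_samples` object.
#' @param sizes Increasing subset sizes, none above `gold_size`.
#' @param gold_size Number of draws defining the gold standard.
#' @param bins Number of shared histogram bins.
#' @return A data.table with columns `size`, `mean_kl`.
#' @export
kl_vs_sample_size <- function(ps, sizes = c(50L, 100L, 250L, 500L),
                              gold_size = ncol(ps$draws), bins = 30L) {
  if (is.null(ps$draws) || ncol(ps$draws) < gold_size) {
    stop("gold_size exceeds the available draws")
  }
  if (any(sizes > gold_size)) stop("sizes cannot exceed gold_size")
  ld <- log(ps$draws[, seq_len(gold_size), drop = FALSE])
  npx <- nrow(ld)
  kl_sum <- numeric(length(sizes))
  for (p in seq_len(npx)) {
    x <- ld[p, ]
    rng <- range(x)
    if (rng[2L] - rng[1L] <= 0) rng <- rng + c(-1e-8, 1e-8)
    brk <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    cut_gold <- pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                          1L), bins)
    gold_counts <- tabulate(cut_gold, bins) + 1
    q <- gold_counts / sum(gold_counts)
    for (k in seq_along(sizes)) {
      sub_counts <- tabulate(cut_gold[seq_len(sizes[k])], bins) + 1
      pk <- sub_counts / sum(sub_counts)
      kl_sum[k] <- kl_sum[k] + sum(pk * log(pk / q))
    }
  }
  data.table::data.table(size = as.integer(sizes), mean_kl = kl_sum / npx)
}
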