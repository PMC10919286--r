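#' Parameters for the synthetic Hi-C generator
#'
#' Defines a ground-truth interaction frequency matrix with power-law
#' distance decay, enriched domain blocks, focal loop bumps and lognormal
#' per-bin biases -- the minimal structure exploited by the model (decay
#' prior, local smoothness, sharp boundaries).  Defaults give a 200-bin map
#' with 3 domains, 2 loops and 5e5 expected read pairs.
#'
#' @param n_bins Number of bins (at least 50).
#' @param decay_exponent Power-law exponent `a` in
#'   `t(d) proportional to (1 + d)^-a`.
#' @param tad_boundaries Sorted 0-based bin indices of domain boundaries;
#'   the `k` boundaries split the chromosome into `k + 1` segments, all of
#'   which are treated as domains.
#' @param tad_enrichment Fold enrichment for pairs within one domain.
#' @param loops List of loop anchors `c(i, j, fold)`; each multiplies a
#'   Gaussian bump of sd `loop_sd` bins and peak height `fold` onto the
#'   truth.
#' @param loop_sd Loop bump width (bins).
#' @param bias_sd Standard deviation of the lognormal per-bin bias
#'   (0 means all biases are exactly 1).
#' @param depth Expected total read pairs when simulating counts.
#' @param max_distance_bins Analysis band width.
#' @param seed Seed for bias generation.
#' @return A named list of generator parameters.
#' @export
synth_params <- function(n_bins = 200L,
                         decay_exponent = 1,
                         tad_boundaries = c(65L, 130L),
                         tad_enrichment = 3,
                         loops = list(c(40L, 90L, 4), c(100L, 170L, 4)),
                         loop_sd = 1.5,
                         bias_sd = 0.3,
                         depth = 5e5,
                         max_distance_bins = n_bins - 1L,
                         seed = 1L) {
  list(n_bins = as.integer(n_bins), decay_exponent = decay_exponent,
       tad_boundaries = as.integer(tad_boundaries),
       tad_enrichment = tad_enrichment, loops = loops, loop_sd = loop_sd,
       bias_sd = bias_sd, depth = depth,
       max_distance_bins = as.integer(max_distance_bins), seed = seed)
}

#' Generate a ground-truth frequency matrix and bias vector
#'
#' `t(i, j) = (1 + d)^-a * tad_factor(i, j) * loop_factor(i, j)` with
#' `d = j - i`; `tad_factor` is `tad_enrichment` when `i` and `j` fall in
#' the same domain segment and 1 otherwise; each loop contributes a factor
#' `1 + (fold - 1) * exp(-((i - a)^2 + (j - b)^2) / (2 * loop_sd^2))`.
#' Biases are i.i.d. lognormal with log-sd `bias_sd`, rescaled to mean 1.
#' Given the same parameters and seed the output is identical.
#'
#' @param params A list from [synth_params()].
#' @return An object of class `synthetic_truth` with fields `t_true`
#'   (a [freq_matrix()]), `bias_true` (a [bias_vector()]) and `params`.
#' @export
make_truth <- function(params) {
  p <- params
  n <- p$n_bins
  if (n < 50L) stop("n_bins must be at least 50")
  bnd <- p$tad_boundaries
  if (is.unsorted(bnd, strictly = TRUE) || any(bnd <= 0L | bnd >= n)) {
    stop("tad_boundaries must be strictly increasing and inside (0, n_bins)")
  }
  for (lp in p$loops) {
    if (lp[1L] < 0 || lp[2L] >= n || abs(lp[2L] - lp[1L]) > p$max_distance_bins) {
      stop("loop anchor outside the matrix or band")
    }
  }
  band <- p$max_distance_bins
  px <- valid_pixel_index(n, band)
  seg <- findInterval(seq_len(n) - 1L, bnd)
  t_val <- (1 + px$d) ^ (-p$decay_exponent)
  t_val <- t_val * ifelse(seg[px$i + 1L] == seg[px$j + 1L],
                          p$tad_enrichment, 1)
  for (lp in p$loops) {
    a <- min(lp[1L], lp[2L])
    b2 <- max(lp[1L], lp[2L])
    bump <- exp(-((px$i - a)^2 + (px$j - b2)^2) / (2 * p$loop_sd^2))
    t_val <- t_val * (1 + (lp[3L] - 1) * bump)
  }
  bias <- if (p$bias_sd > 0) {
    bv <- with_seed(derive_seed(p$seed, "bias"),
                    exp(stats::rnorm(n, 0, p$bias_sd)))
    bv / mean(bv)
  } else {
    rep(1, n)
  }
  structure(
    list(
      t_true = freq_matrix(
        data.table::data.table(i = px$i, j = px$j, value = t_val),
        n_bins = n, max_distance_bins = band
      ),
      bias_true = bias_vector(bias),
      params = p
    ),
    class = "synthetic_truth"
  )
}

# Scale factor making the expected simulated total equal `depth`.
truth_scale <- function(truth, depth) {
  b <- truth$bias_true$values
  e <- truth$t_true$entries
  depth / sum(b[e$i + 1L] * b[e$j + 1L] * e$value)
}

#' Ground truth on the simulated-count scale
#'
#' Returns the latent frequencies rescaled so that
#' `sum(b_i * b_j * t_ij) = depth`, i.e. the exact Poisson rates (divided by
#' the pairwise bias) used by [simulate_counts()] at that depth.
#'
#' @param truth A `synthetic_truth`.
#' @param depth Expected total read pairs.
#' @return A [freq_matrix()].
#' @export
scaled_truth <- function(truth, depth = truth$params$depth) {
  s <- truth_scale(truth, depth)
  e <- data.table::copy(truth$t_true$entries)
  e$value <- e$value * s
  freq_matrix(e, n_bins = truth$t_true$n_bins,
              max_distance_bins = truth$t_true$max_distance_bins)
}

#' Simulate a Poisson contact map from a synthetic truth
#'
#' Rescales the truth so the expected total equals `depth`, then draws
#' each in-band count independently as
#' `o_ij ~ Pois(b_i * b_j * t_ij)`.
#'
#' @param truth A `synthetic_truth` from [make_truth()].
#' @param depth Expected total read pairs.
#' @param seed Integer seed.
#' @return A [contact_map()].
#' @export
simulate_counts <- function(truth, depth = truth$params$depth, seed = 1L) {
  stopifnot(depth > 0)
  s <- truth_scale(truth, depth)
  b <- truth$bias_true$values
  e <- truth$t_true$entries
  lambda <- b[e$i + 1L] * b[e$j + 1L] * e$value * s
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  cm <- contact_map(
    data.table::data.table(i = e$i, j = e$j, count = counts)[counts > 0],
    n_bins = truth$t_true$n_bins,
    max_distance_bins = truth$t_true$max_distance_bins
  )
  attr(cm, "truth_scale") <- s
  cm
}
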