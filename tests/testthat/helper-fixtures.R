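# Shared fixtures, built in code and memoised so expensive objects are
# constructed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small structured map: 60 bins, 2 domains boundaries, 1 loop.
small_map <- function(depth = 6e4, seed = 9L) {
  memo(sprintf("small_%g_%d", depth, seed), {
    p <- synth_params(n_bins = 60L, tad_boundaries = c(20L, 40L),
                      loops = list(c(10L, 30L, 4)), depth = depth,
                      seed = seed)
    truth <- make_truth(p)
    map <- simulate_counts(truth, depth = depth,
                           seed = derive_seed(seed, "counts"))
    list(params = p, truth = truth, map = map)
  })
}

small_balanced <- function() {
  memo("small_balanced", {
    fx <- small_map()
    bal <- ice_balance(fx$map)
    decay <- fit_decay(fx$map, bal$bias, sample_frac = 0.3, seed = 9L)
    c(fx, list(bal = bal, decay = decay))
  })
}

# Flat toy state on a tiny grid for conditional-density oracles.
toy_state <- function(n = 5L, seed = 42L) {
  px <- hicposterior:::valid_pixel_index(n, n - 1L)
  state <- hicposterior:::band_matrix_skeleton(n, n - 1L, NA_real_)
  state[px$idx] <- hicposterior:::with_seed(seed, exp(rnorm(length(px$idx), 0, 0.6)))
  list(n = n, band = n - 1L, px = px, state = state)
}

# Empirical-vs-quadrature KS distance in log space.  ld_fun(u) returns the
# unnormalised log density of u = log t (including the Jacobian term).
ks_vs_quadrature <- function(t_draws, ld_fun, lo, hi, m = 4001L) {
  ug <- seq(lo, hi, length.out = m)
  ld <- ld_fun(ug)
  w <- exp(ld - max(ld))
  cdf <- cumsum(w) / sum(w)
  Fq <- stats::approxfun(ug, cdf, yleft = 0, yright = 1)
  x <- sort(log(t_draws))
  max(abs(Fq(x) - (seq_along(x) - 0.5) / length(x)))
}

# Minimal posterior_samples stand-in for diagnostics that only need draws
# and pixel coordinates.
fake_ps <- function(draws, i, j, n_bins, band = n_bins - 1L) {
  structure(
    list(draws = draws,
         pixels = data.table::data.table(i = i, j = j, d = j - i),
         n_bins = as.integer(n_bins), band = as.integer(band),
         bin_size = 1L, chrom = "chr1",
         mean = rowMeans(draws), variance = NULL, dispersion = NULL,
         mixed = TRUE, burn_in_sweeps = 0L, accept_rate = NA_real_,
         mixing_history = NULL, burn_in_draws = NULL,
         config = NULL, variant = "full", g = NULL),
    class = "posterior_samples"
  )
}

tmp_tsv <- function() tempfile(fileext = ".tsv")
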