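test_that("tile schedules obey the independence contract", {
  s <- tile_schedule(30L, tile_size = 5L)
  expect_length(s$start, 6L)
  expect_equal(sort(unlist(s$phases)), 0:5)
  # a tile larger than the matrix degenerates to a single tile
  s1 <- tile_schedule(30L, tile_size = 200L)
  expect_length(s1$start, 1L)
  # adjacent tiles in one phase violate the blanket-separation contract
  bad <- structure(
    list(start = c(0L, 5L, 10L), end = c(5L, 10L, 15L),
         phases = list(c(0L, 1L), 2L), n_bins = 15L),
    class = "tile_schedule"
  )
  expect_error(validate_tile_schedule(bad), "blanket")
  # tiles must partition the rows
  bad2 <- structure(
    list(start = c(0L, 6L), end = c(5L, 15L), phases = list(0L, 1L),
         n_bins = 15L),
    class = "tile_schedule"
  )
  expect_error(validate_tile_schedule(bad2), "partition")
})

test_that("compiled and reference conditionals agree on a toy state", {
  set.seed(12)
  n <- 8L
  band <- 7L
  px <- hicposterior:::valid_pixel_index(n, band)
  state <- hicposterior:::band_matrix_skeleton(n, band, NA_real_)
  state[px$idx] <- exp(rnorm(length(px$idx), 0, 0.7))
  ob <- hicposterior:::band_matrix_skeleton(n, band)
  ob[px$idx] <- rpois(length(px$idx), 4)
  omega2 <- rep(0.4, band + 1L)
  s2 <- hicposterior:::band_matrix_skeleton(n, band, NA_real_)
  s2[px$idx] <- runif(length(px$idx), 0.1, 0.6)
  fmv <- freq_matrix(data.frame(i = px$i, j = px$j,
                                value = state[px$idx]), n)
  pr <- prune_blanket(fmv, alpha = 0)
  pr$e_row[2, 3] <- TRUE
  pr$e_col[4, 2] <- TRUE
  b <- bias_vector(runif(n, 0.5, 2))
  g <- exp(seq(1, -1, length.out = band + 1L))
  for (variant in c("full", "uniform", "gaussian", "fixed_sigma")) {
    spec <- mrf_spec(omega2, s2, pr, variant = variant, sigma2_fixed = 0.3,
                     n_bins = n, band = band)
    for (k in c(1L, 9L, 20L, length(px$idx))) {
      i <- px$i[k]; j <- px$j[k]; d <- px$d[k]
      for (tc in c(0.3, 1.1, 4)) {
        rr <- log_conditional(tc, i, j, state, ob[i + 1L, d + 1L],
                              b$values[i + 1L] * b$values[j + 1L],
                              g[d + 1L], spec)
        cc <- hicposterior:::cpp_log_conditional(
          tc, i, d, log(state), ob, log(b$values), log(g), omega2, s2,
          pr$e_row, pr$e_col, b$mask,
          hicposterior:::variant_code(variant), 0.3
        )
        expect_equal(rr, cc - lgamma(ob[i + 1L, d + 1L] + 1),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("a vanishing proposal scale accepts almost surely", {
  toy <- toy_state(n = 4L)
  spec <- mrf_spec(rep(0.3, 4L), matrix(0.25, 4L, 4L), NULL,
                   n_bins = 4L, band = 3L)
  set.seed(2)
  acc <- vapply(1:50, function(r) {
    mh_update(u = log(1.5), sd = 1e-9, i = 1L, j = 2L, state = toy$state,
              o_ij = 3, b_ij = 1, g_ij = 1.2, spec = spec)$accepted
  }, NA)
  expect_true(all(acc))
})

test_that("every unmasked pixel is proposed exactly once per sweep", {
  fx <- small_map()
  bal <- small_balanced()$bal
  inputs <- hicposterior:::prepare_inputs(
    fx$map, bal$bias, rep(1, 60L),
    mrf_spec(rep(0.2, 60L),
             hicposterior:::band_matrix_skeleton(60L, 59L, 0.2),
             NULL, variant = "gaussian", n_bins = 60L, band = 59L),
    sampler_config(seed = 1L, tile_size = 16L)
  )
  st <- hicposterior:::new_chain_state(60L, 59L, inputs$px$idx, 5L)
  st <- hicposterior:::run_chunk(st, inputs, n_sweeps = 3L, adapt = FALSE,
                                 sampler_config(seed = 1L, tile_size = 16L),
                                 chain_id = 1L)
  expect_true(all(st$prop[inputs$px$idx] == 3))
  expect_equal(st$proposed, 3 * length(inputs$px$idx))
})

test_that("chains are invariant to tile order within a phase", {
  fx <- small_map()
  bal <- small_balanced()$bal
  cfg <- sampler_config(seed = 3L, tile_size = 10L)
  spec <- mrf_spec(rep(0.2, 60L),
                   hicposterior:::band_matrix_skeleton(60L, 59L, 0.2),
                   NULL, variant = "full", n_bins = 60L, band = 59L)
  inputs <- hicposterior:::prepare_inputs(fx$map, bal$bias, rep(1, 60L),
                                          spec, cfg)
  st0 <- hicposterior:::new_chain_state(60L, 59L, inputs$px$idx, 5L)
  a <- hicposterior:::run_chunk(st0, inputs, 5L, FALSE, cfg, 1L,
                                reverse_within_phase = FALSE)
  b <- hicposterior:::run_chunk(st0, inputs, 5L, FALSE, cfg, 1L,
                                reverse_within_phase = TRUE)
  expect_identical(a$u, b$u)
})

test_that("proposal adaptation pushes rates toward the target and freezes", {
  fx <- small_balanced()
  spec <- suppressWarnings(build_mrf(fx$bal$normalized, alpha = 0))
  cfg <- sampler_config(thin = 10L, n_samples = 20L, max_sweeps = 1500L,
                        seed = 4L)
  ps <- hic_sample(fx$map, fx$bal$bias, fx$decay, spec, cfg)
  expect_true(ps$accept_rate > 0.1 && ps$accept_rate < 0.4)
  # the collection phase runs with frozen proposals: rerunning the
  # identical config reproduces the draws bit for bit
  ps2 <- hic_sample(fx$map, fx$bal$bias, fx$decay, spec, cfg)
  expect_identical(ps$draws, ps2$draws)
  expect_identical(ps$burn_in_sweeps, ps2$burn_in_sweeps)
})

test_that("the mixing rule fires for identical chains and not for split ones", {
  set.seed(9)
  draws <- lapply(1:10, function(k) rnorm(50))
  m <- assess_mixing(draws, draws, tol = 0.1, window = 10L)
  expect_true(m$assessable)
  expect_true(m$mixed)
  expect_equal(m$inter, 0)
  # two chains stuck at different constants: inter >> intra
  a <- lapply(1:10, function(k) rep(0, 50) + rnorm(50, sd = 1e-3))
  b <- lapply(1:10, function(k) rep(5, 50) + rnorm(50, sd = 1e-3))
  m2 <- assess_mixing(a, b, tol = 0.1, window = 10L)
  expect_false(m2$mixed)
  expect_gt(m2$inter, 10 * m2$intra)
  # not yet assessable
  expect_false(assess_mixing(a[1:5], b[1:5], window = 10L)$assessable)
})

test_that("n_samples = 0 still produces burn-in diagnostics", {
  fx <- small_balanced()
  spec <- mrf_spec(rep(0.2, 60L),
                   hicposterior:::band_matrix_skeleton(60L, 59L, 0.2),
                   NULL, variant = "gaussian", n_bins = 60L, band = 59L)
  cfg <- sampler_config(thin = 10L, n_samples = 0L, max_sweeps = 600L,
                        seed = 6L)
  ps <- hic_sample(fx$map, fx$bal$bias, rep(2, 60L), spec, cfg)
  expect_null(ps$draws)
  expect_null(ps$mean)
  expect_true(ps$burn_in_sweeps > 0)
  expect_true(nrow(ps$mixing_history) >= 1L)
})

test_that("summaries are exact sample moments", {
  d <- cbind(c(1, 2, 4), c(3, 2, 8))
  s <- summarize_samples(d)
  expect_equal(s$mean, c(2, 2, 6))
  expect_equal(s$variance, apply(d, 1, var))
  expect_equal(s$dispersion, s$variance / s$mean)
  same <- cbind(c(1, 2), c(1, 2), c(1, 2))
  s2 <- summarize_samples(same)
  expect_equal(s2$variance, c(0, 0))
  expect_equal(s2$dispersion, c(0, 0))
  expect_error(summarize_samples(cbind(c(1, 2))), "2 samples")
})

test_that("posterior means beat the normalized map at recovering truth", {
  # low depth (~250 pairs per bin row): smoothing should pay off
  fx <- small_map(depth = 250 * 60, seed = 23L)
  bal <- ice_balance(fx$map)
  dm <- fit_decay(fx$map, bal$bias, sample_frac = 0.5, seed = 23L)
  spec <- suppressWarnings(build_mrf(bal$normalized))
  cfg <- sampler_config(thin = 10L, n_samples = 60L, max_sweeps = 2000L,
                        seed = 23L)
  ps <- hic_sample(fx$map, bal$bias, dm, spec, cfg)
  tt <- scaled_truth(fx$truth, fx$params$depth)
  tv <- map_value(tt, ps$pixels$i, ps$pixels$j)
  nv <- map_value(bal$normalized, ps$pixels$i, ps$pixels$j)
  ok <- is.finite(nv)
  expect_gt(cor(ps$mean[ok], tv[ok]), cor(nv[ok], tv[ok]))
})

test_that("exported sample containers round-trip", {
  fx <- small_balanced()
  spec <- mrf_spec(rep(0.2, 60L),
                   hicposterior:::band_matrix_skeleton(60L, 59L, 0.2),
                   NULL, variant = "gaussian", n_bins = 60L, band = 59L)
  cfg <- sampler_config(thin = 5L, adapt_interval = 5L, n_samples = 4L,
                        max_sweeps = 2000L, seed = 8L)
  ps <- hic_sample(fx$map, fx$bal$bias, rep(2, 60L), spec, cfg)
  dir <- tempfile()
  export_samples(ps, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ps2 <- read_samples(dir)
  expect_equal(dim(ps2$draws), dim(ps$draws))
  expect_equal(ps2$draws, ps$draws, tolerance = 1e-12)
  expect_equal(ps2$burn_in_sweeps, ps$burn_in_sweeps)
})
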