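test_that("omega2 recovers the log-scale variance per distance stratum", {
  # one populated stratum of lognormal values: var of logs ~ 0.25
  set.seed(31)
  n_pairs <- 10000L
  i <- 0:(n_pairs - 1L)
  fm <- freq_matrix(data.frame(i = i, j = i + 2L,
                               value = exp(rnorm(n_pairs, 0, 0.5))),
                    n_bins = n_pairs + 2L, max_distance_bins = 2L)
  w2 <- suppressWarnings(estimate_omega2(fm))
  expect_length(w2, 3L)              # band + 1 strata
  # SE of a variance estimate: sqrt(2 sigma^4 / n) ~ 0.0035
  expect_equal(w2[3L], 0.25, tolerance = 3 * sqrt(2 * 0.25^2 / n_pairs) / 0.25)
  # under-populated strata borrow the nearest populated value
  expect_equal(w2[1L], w2[3L])
})

test_that("omega2 floors degenerate strata", {
  i <- 0:99
  fm <- freq_matrix(data.frame(i = i, j = i + 1L, value = 2.5),
                    n_bins = 101L, max_distance_bins = 1L)
  w2 <- suppressWarnings(estimate_omega2(fm, variance_floor = 1e-4))
  expect_equal(w2[2L], 1e-4)
})

test_that("sigma2 floors a locally constant field", {
  n <- 40L
  px <- hicposterior:::valid_pixel_index(n, n - 1L)
  fm <- freq_matrix(data.frame(i = px$i, j = px$j, value = 3), n_bins = n)
  s2 <- estimate_sigma2(fm, window = 17L)
  expect_equal(max(s2, na.rm = TRUE), 1e-4)
})

test_that("sigma2 of an i.i.d. lognormal field is twice the log variance", {
  n <- 60L
  s <- 0.4
  px <- hicposterior:::valid_pixel_index(n, n - 1L)
  fm <- freq_matrix(
    data.frame(i = px$i, j = px$j,
               value = hicposterior:::with_seed(8,
                 exp(rnorm(length(px$idx), 1, s)))),
    n_bins = n
  )
  s2 <- estimate_sigma2(fm, window = 17L)
  # adjacent differences of iid N(mu, s^2) logs have variance 2 s^2;
  # average the interior of the field to beat window-level noise
  interior <- s2[15:45, 10:40]
  expect_equal(mean(interior, na.rm = TRUE), 2 * s^2, tolerance = 0.05)
  s2_small <- estimate_sigma2(fm, window = 3L)
  expect_true(all(s2_small >= 1e-4, na.rm = TRUE))
  expect_gt(max(abs(s2_small - s2), na.rm = TRUE), 0)  # window matters
})

test_that("pruning controls the null rate and detects block boundaries", {
  n <- 80L
  px <- hicposterior:::valid_pixel_index(n, n - 1L)
  # homogeneous field: prune rate should not exceed alpha by more than
  # binomial noise (the exact discrete KS test is conservative)
  fm0 <- freq_matrix(
    data.frame(i = px$i, j = px$j,
               value = hicposterior:::with_seed(17,
                 exp(rnorm(length(px$idx), 0, 0.5)))),
    n_bins = n
  )
  alpha <- 0.05
  pr0 <- prune_blanket(fm0, alpha = alpha, flank = 8L)
  tested <- sum(px$j + 1L < n) + sum(px$d >= 1L & px$i + 1L < n)
  rate <- (sum(pr0$e_row) + sum(pr0$e_col)) / tested
  expect_lt(rate, alpha + 3 * sqrt(alpha / tested))
  expect_gt(rate, 0.001)

  # two blocks 4 SD apart: every transition crossing the block boundary
  # at short range must be detected
  bnd <- 40L
  seg <- as.integer(px$i >= bnd) + as.integer(px$j >= bnd)
  fm1 <- freq_matrix(
    data.frame(i = px$i, j = px$j,
               value = hicposterior:::with_seed(18,
                 exp(rnorm(length(px$idx), 2 * seg, 0.5)))),
    n_bins = n
  )
  pr1 <- prune_blanket(fm1, alpha = 0.001, flank = 8L)
  # column transitions between j = 39 and j = 40 for rows near the diagonal
  hit <- vapply(0:30, function(i) pr1$e_col[i + 1L, 39L - i + 1L], NA)
  expect_true(all(hit))

  # switched off
  pr_off <- prune_blanket(fm1, alpha = 0)
  expect_equal(sum(pr_off$e_row) + sum(pr_off$e_col), 0L)
})

test_that("KS machinery agrees with stats::ks.test", {
  set.seed(5)
  for (r in 1:20) {
    x <- rnorm(17)
    y <- rnorm(15, 0.5)
    D <- hicposterior:::ks_d_stat(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y))
    expect_equal(D, unname(ref$statistic), tolerance = 1e-12)
    p <- 1 - stats::psmirnov(D, sizes = c(17L, 15L), exact = TRUE)
    expect_equal(p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("potentials have their closed-form values and symmetries", {
  expect_equal(log_local_potential(2, 2, 0.3), 0)
  w <- 0.35
  expect_equal(log_local_potential(exp(log(4) + sqrt(w)), 4, w), -0.5)
  expect_equal(log_local_potential(0.5, 1, w),
               log_local_potential(2, 1, w))   # sign symmetry
  expect_equal(log_pairwise_potential(3, 3, 0.2), 0)
  expect_equal(log_pairwise_potential(1, 5, 0.2),
               log_pairwise_potential(5, 1, 0.2))
  expect_equal(log_pairwise_potential(2, 6, 0.2),
               log_pairwise_potential(4, 12, 0.2))  # scale invariance
  expect_error(log_local_potential(-1, 2, 0.3), "positive")
  expect_error(log_pairwise_potential(0, 2, 0.3), "positive")
})

test_that("the conditional matches a literal term-by-term transcription", {
  toy <- toy_state(n = 3L)
  n <- toy$n
  band <- toy$band
  state <- toy$state
  omega2 <- c(0.3, 0.5, 0.2)
  s2 <- hicposterior:::band_matrix_skeleton(n, band, NA_real_)
  s2[toy$px$idx] <- hicposterior:::with_seed(2,
    runif(length(toy$px$idx), 0.1, 0.5))
  g <- c(2.0, 1.2, 0.8)
  o_ij <- 4
  b_ij <- 1.3
  i <- 0L; j <- 1L; d <- 1L

  for (variant in c("full", "uniform", "gaussian", "fixed_sigma")) {
    spec <- mrf_spec(omega2, s2, NULL, variant = variant,
                     sigma2_fixed = 0.4, n_bins = n, band = band)
    tg <- seq(0.05, 6, length.out = 100)
    got <- log_conditional(tg, i, j, state, o_ij, b_ij, g[d + 1L], spec)

    # literal transcription: Pois(o; b t) * phi(t) * prod phi(t, t_q)
    want <- dpois(o_ij, b_ij * tg, log = TRUE)
    if (variant != "uniform") {
      want <- want - (log(tg) - log(g[d + 1L]))^2 / (2 * omega2[d + 1L])
    }
    if (variant %in% c("full", "fixed_sigma")) {
      nbrs <- list(c(0L, 0L), c(1L, 1L), c(0L, 2L), c(1L, 2L))  # blanket of (0,1) in 3x3
      for (q in nbrs) {
        tq <- state[q[1L] + 1L, q[2L] - q[1L] + 1L]
        s2e <- if (variant == "fixed_sigma") 0.4 else {
          max(s2[i + 1L, d + 1L], s2[q[1L] + 1L, q[2L] - q[1L] + 1L])
        }
        want <- want - (log(tg) - log(tq))^2 / (2 * s2e)
      }
    }
    expect_equal(got, want, tolerance = 1e-12, label = variant)
  }
})

test_that("pruning an edge removes exactly its pairwise term", {
  toy <- toy_state(n = 4L)
  omega2 <- rep(0.3, 4)
  s2 <- hicposterior:::band_matrix_skeleton(4L, 3L, 0.25)
  spec_full <- mrf_spec(omega2, s2, NULL, variant = "full",
                        n_bins = 4L, band = 3L)
  pr <- spec_full$pruned
  pr$e_col[2, 2] <- TRUE  # prune (1,2)-(1,3): i=1, d=1
  spec_pruned <- mrf_spec(omega2, s2, pr, variant = "full",
                          n_bins = 4L, band = 3L)
  t0 <- 1.7
  a <- log_conditional(t0, 1L, 2L, toy$state, 3, 1, 1.1, spec_full)
  b <- log_conditional(t0, 1L, 2L, toy$state, 3, 1, 1.1, spec_pruned)
  # the flagged column transition prunes the direct edge to (1,3) and, by
  # inheritance, the two diagonal edges of (1,2) crossing it
  dropped <- log_pairwise_potential(t0, toy$state[2, 3], 0.25) +  # (1,3)
    log_pairwise_potential(t0, toy$state[3, 2], 0.25) +           # (2,3)
    log_pairwise_potential(t0, toy$state[1, 4], 0.25)             # (0,3)
  expect_equal(a - b, dropped, tolerance = 1e-12)
  # and the same edge is dropped from the other endpoint's conditional
  a2 <- log_conditional(t0, 1L, 3L, toy$state, 3, 1, 1.1, spec_full)
  b2 <- log_conditional(t0, 1L, 3L, toy$state, 3, 1, 1.1, spec_pruned)
  expect_equal(a2 - b2, log_pairwise_potential(t0, toy$state[2, 2], 0.25),
               tolerance = 1e-12)
})

test_that("conditionals are consistent with the joint density", {
  toy <- toy_state(n = 4L)
  omega2 <- rep(0.3, 4)
  s2 <- hicposterior:::band_matrix_skeleton(4L, 3L, NA_real_)
  s2[toy$px$idx] <- hicposterior:::with_seed(3,
    runif(length(toy$px$idx), 0.15, 0.45))
  g <- c(2, 1.4, 1, 0.8)
  spec <- mrf_spec(omega2, s2, NULL, variant = "full", n_bins = 4L,
                   band = 3L)
  state <- toy$state
  for (k in seq_along(toy$px$idx)) {
    i <- toy$px$i[k]; j <- toy$px$j[k]; d <- toy$px$d[k]
    o_ij <- 3
    t0 <- state[i + 1L, d + 1L]
    t1 <- t0 * 1.8
    lc <- log_conditional(t1, i, j, state, o_ij, 1, g[d + 1L], spec) -
      log_conditional(t0, i, j, state, o_ij, 1, g[d + 1L], spec)
    alt <- state
    alt[i + 1L, d + 1L] <- t1
    jp <- (joint_log_prior(alt, spec, g) + dpois(o_ij, t1, log = TRUE)) -
      (joint_log_prior(state, spec, g) + dpois(o_ij, t0, log = TRUE))
    expect_equal(lc, jp, tolerance = 1e-10)
  }
})

test_that("the joint prior is maximal at the decay curve", {
  n <- 5L
  band <- 4L
  g <- c(3, 2, 1.5, 1.2, 1)
  px <- hicposterior:::valid_pixel_index(n, band)
  state <- hicposterior:::band_matrix_skeleton(n, band, NA_real_)
  state[px$idx] <- 1.4   # all equal: pairwise terms vanish
  omega2 <- rep(0.3, band + 1L)
  s2 <- hicposterior:::band_matrix_skeleton(n, band, 0.2)
  spec <- mrf_spec(omega2, s2, NULL, variant = "full", n_bins = n,
                   band = band)
  flat_g <- rep(1.4, band + 1L)
  expect_equal(joint_log_prior(state, spec, flat_g), 0)
  # moving one pixel away decreases the prior monotonically
  vals <- vapply(c(1.5, 1.8, 2.5, 4), function(tv) {
    alt <- state
    alt[1, 2] <- tv
    joint_log_prior(alt, spec, flat_g)
  }, 0)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals < 0))
})

test_that("edge pruning is symmetric and diagonal edges inherit it", {
  pr <- structure(
    list(e_row = matrix(FALSE, 6, 6), e_col = matrix(FALSE, 6, 6),
         n_bins = 6L, band = 5L, alpha = 0.01, flank = 8L),
    class = "pruned_edges"
  )
  pr$e_row[2, 3] <- TRUE  # transition rows 1|2 at pixel (1,3)
  spec <- mrf_spec(rep(0.2, 6), matrix(0.2, 6, 6), pr, n_bins = 6L,
                   band = 5L)
  expect_true(hicposterior:::edge_is_pruned(pr, 1L, 3L, 2L, 3L))
  expect_true(hicposterior:::edge_is_pruned(pr, 2L, 3L, 1L, 3L))  # both ways
  expect_true(hicposterior:::edge_is_pruned(pr, 1L, 3L, 2L, 4L))  # diagonal
  expect_false(hicposterior:::edge_is_pruned(pr, 1L, 3L, 1L, 4L))
  tab <- pruned_edges(spec)
  expect_true(nrow(tab) >= 2L)
  expect_true(all(tab$i1 < tab$i2 | (tab$i1 == tab$i2 & tab$j1 < tab$j2)))
})
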