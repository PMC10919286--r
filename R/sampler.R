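#' Sampler configuration
#'
#' Tuning knobs of the adaptive Metropolis-Hastings-within-Gibbs run.  One
#' "sweep" updates every unmasked in-band pixel once; draws for mixing
#' assessment and output are collected every `thin` sweeps.  Mixing is
#' declared by the two-chain rule: once at least `min_draws` draws have
#' been collected (i.e. after at least `min_draws * thin` sweeps), the
#' chains are considered mixed when the mean intra-chain RMSE (between
#' consecutive thinned draws) and the mean inter-chain RMSE (between
#' same-index draws) over the last `min_draws` draws agree within
#' `rmse_tol`.  During burn-in, every `adapt_interval` sweeps each pixel's
#' proposal scale is multiplied by `exp(gain0 / round * (rate - target))`
#' (diminishing-gain stochastic approximation); after mixing the scales are
#' frozen.
#'
#' @param n_chains Number of chains (2 required for mixing diagnosis).
#' @param thin Sweeps between collected draws (`k`).
#' @param min_draws Draws required before the first mixing check (the rule
#'   `K >= 10 k`).
#' @param rmse_tol Relative inter/intra RMSE agreement declaring mixing.
#' @param adapt_interval Sweeps between proposal adaptations; must divide
#'   `thin`.
#' @param target_accept Target acceptance rate of the adaptation.
#' @param n_samples Posterior draws collected after burn-in.
#' @param max_sweeps Burn-in cap; if mixing is not declared by then the run
#'   proceeds with `mixed = FALSE` and a warning.
#' @param tile_size Row-block size of the sweep schedule.
#' @param gain0 Initial adaptation gain.
#' @param pool_chains Collect output draws alternately from both chains
#'   instead of chain A only.
#' @param seed Master seed; chain seeds are derived from it.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 2L, thin = 50L, min_draws = 10L,
                           rmse_tol = 0.10, adapt_interval = 10L,
                           target_accept = 0.234, n_samples = 500L,
                           max_sweeps = 10000L, tile_size = 200L,
                           gain0 = 2, pool_chains = FALSE, seed = 1L) {
  stopifnot(thin >= 1L, n_chains >= 2L, min_draws >= 2L,
            target_accept > 0, target_accept < 1,
            thin %% adapt_interval == 0L)
  structure(
    list(n_chains = as.integer(n_chains), thin = as.integer(thin),
         min_draws = as.integer(min_draws), rmse_tol = rmse_tol,
         adapt_interval = as.integer(adapt_interval),
         target_accept = target_accept, n_samples = as.integer(n_samples),
         max_sweeps = as.integer(max_sweeps),
         tile_size = as.integer(tile_size), gain0 = gain0,
         pool_chains = isTRUE(pool_chains), seed = as.integer(seed)),
    class = "sampler_config"
  )
}

#' Tiled sweep schedule
#'
#' Partitions the rows of the band into contiguous blocks of `tile_size`
#' rows executed in two phases (even blocks, then odd blocks).  Pixels in
#' distinct tiles of the same phase are separated by at least one full
#' tile, hence never in each other's second-order Markov blanket, so tiles
#' within a phase may be updated concurrently; each (chain, sweep, tile)
#' gets its own RNG stream, making the chain invariant to the execution
#' order within a phase.
#'
#' @param n_bins Number of rows.
#' @param tile_size Rows per tile (a tile larger than the matrix gives a
#'   single tile).
#' @return An object of class `tile_schedule` with 0-based `start`
#'   (inclusive), `end` (exclusive), and `phases` (list of tile indices).
#' @export
tile_schedule <- function(n_bins, tile_size = 200L) {
  stopifnot(tile_size >= 1L)
  start <- seq.int(0L, n_bins - 1L, by = tile_size)
  end <- pmin(start + tile_size, n_bins)
  idx <- seq_along(start) - 1L
  sched <- structure(
    list(start = as.integer(start), end = as.integer(end),
         phases = list(idx[idx %% 2L == 0L], idx[idx %% 2L == 1L]),
         n_bins = as.integer(n_bins)),
    class = "tile_schedule"
  )
  validate_tile_schedule(sched)
  sched
}

#' Validate a tile schedule against the independence contract
#'
#' Errors unless the tiles exactly partition the rows and no two tiles
#' within one phase are closer than one row (second-order blankets span one
#' row, so adjacent tiles may not run concurrently).
#'
#' @param sched A `tile_schedule` (possibly hand-built).
#' @return `sched`, invisibly.
#' @export
validate_tile_schedule <- function(sched) {
  o <- order(sched$start)
  if (sched$start[o][1L] != 0L ||
      sched$end[o][length(o)] != sched$n_bins ||
      (length(o) > 1L &&
       any(sched$start[o][-1L] != sched$end[o][-length(o)]))) {
    stop("tiles do not partition the rows")
  }
  if (any(sched$end <= sched$start)) stop("empty tile")
  for (ph in sched$phases) {
    if (length(ph) < 2L) next
    s <- sort(sched$start[ph + 1L])
    e <- sched$end[ph + 1L][order(sched$start[ph + 1L])]
    if (any(s[-1L] - e[-length(e)] < 1L)) {
      stop("tiles within one phase are adjacent: concurrent updates would ",
           "share Markov blankets")
    }
  }
  if (!setequal(unlist(sched$phases), seq_along(sched$start) - 1L)) {
    stop("phases must cover every tile exactly once")
  }
  invisible(sched)
}

variant_code <- function(variant) {
  match(variant, c("full", "uniform", "gaussian", "fixed_sigma")) - 1L
}

# Flatten phases to a processing order (within-phase order configurable for
# schedule-invariance tests).
flatten_phases <- function(sched, reverse_within_phase = FALSE) {
  unlist(lapply(sched$phases, function(ph) {
    if (reverse_within_phase) rev(ph) else ph
  }))
}

new_chain_state <- function(n, band, idx, seed) {
  u <- band_matrix_skeleton(n, band, fill = NA_real_)
  u[idx] <- log(with_seed(seed, stats::runif(length(idx))))
  list(
    u = u,
    sd = band_matrix_skeleton(n, band, fill = 1),
    acc = band_matrix_skeleton(n, band, fill = 0),
    prop = band_matrix_skeleton(n, band, fill = 0),
    round = 0L,
    sweep = 0L
  )
}

run_chunk <- function(st, inputs, n_sweeps, adapt, config, chain_id,
                      reverse_within_phase = FALSE) {
  # the compiled kernel updates these in place; copy so callers can hold
  # on to earlier states
  st$u <- st$u + 0
  st$sd <- st$sd + 0
  st$acc <- st$acc + 0
  st$prop <- st$prop + 0
  res <- cpp_run_chunk(
    st$u, st$sd, st$acc, st$prop,
    inputs$o_band, inputs$lb, inputs$lg, inputs$omega2_vec,
    inputs$sigma2, inputs$e_row, inputs$e_col, inputs$maskbin,
    inputs$variant, inputs$sigma2_fixed,
    as.integer(n_sweeps), st$sweep, adapt, config$adapt_interval,
    config$target_accept, config$gain0, st$round,
    inputs$sched$start, inputs$sched$end,
    as.integer(flatten_phases(inputs$sched, reverse_within_phase)),
    as.numeric(inputs$seed), as.integer(chain_id)
  )
  st$round <- res$round
  st$sweep <- res$sweep_end
  st$accepted <- res$accepted
  st$proposed <- res$proposed
  st
}

prepare_inputs <- function(o, bias, decay, spec, config) {
  n <- o$n_bins
  band <- o$max_distance_bins
  stopifnot(length(bias$values) == n, spec$n_bins == n, spec$band == band)
  g <- if (inherits(decay, "decay_model")) {
    predict_g(decay, 0:band)
  } else {
    stopifnot(length(decay) == band + 1L, all(decay > 0))
    as.numeric(decay)
  }
  maskbin <- bias$mask
  lb <- ifelse(maskbin, log(bias$values), 0)
  px <- valid_pixel_index(n, band, maskbin)
  sigma2 <- spec$sigma2
  sigma2[!is.finite(sigma2)] <- spec$variance_floor
  list(
    o_band = sparse_to_band(o$entries, n, band),
    lb = lb, lg = log(g), omega2_vec = spec$omega2, sigma2 = sigma2,
    e_row = spec$pruned$e_row, e_col = spec$pruned$e_col,
    maskbin = maskbin, variant = variant_code(spec$variant),
    sigma2_fixed = if (is.na(spec$sigma2_fixed)) 1 else spec$sigma2_fixed,
    sched = tile_schedule(n, config$tile_size),
    seed = derive_seed(config$seed, "mcmc"),
    px = px, n = n, band = band, g = g
  )
}

#' Two-chain RMSE mixing rule
#'
#' Given the thinned draws of two independently initialised chains,
#' computes over the last `window` draws the mean intra-chain RMSE
#' (root-mean-square element-wise difference between consecutive draws
#' within a chain, averaged over both chains) and the mean inter-chain RMSE
#' (between same-index draws), and declares mixing when the inter-chain
#' RMSE does not exceed the intra-chain RMSE by more than `tol` relative
#' (chains that have not met show inter far above intra; an inter at or
#' below intra cannot indicate non-mixing).
#'
#' @param draws_a,draws_b Lists of numeric draw vectors (unmasked in-band
#'   pixels), same length.
#' @param tol Relative agreement threshold.
#' @param window Number of most recent draws entering the rule.
#' @return A list with `assessable`, `mixed`, `inter`, `intra`.
#' @export
assess_mixing <- function(draws_a, draws_b, tol = 0.10, window = 10L) {
  nd <- min(length(draws_a), length(draws_b))
  if (nd < window) {
    return(list(assessable = FALSE, mixed = FALSE, inter = NA_real_,
                intra = NA_real_))
  }
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  ia <- (nd - window + 1L):nd
  intra <- mean(c(
    vapply(ia[-1L], function(k) rmse(draws_a[[k]], draws_a[[k - 1L]]), 0),
    vapply(ia[-1L], function(k) rmse(draws_b[[k]], draws_b[[k - 1L]]), 0)
  ))
  inter <- mean(vapply(ia, function(k) rmse(draws_a[[k]], draws_b[[k]]), 0))
  # one-sided: unmixed chains show inter >> intra; an inter at or below
  # intra (e.g. literally identical chains) is evidence of mixing
  list(assessable = TRUE, mixed = (inter - intra) / intra <= tol,
       inter = inter, intra = intra)
}

#' Sample the posterior of the interaction frequency matrix
#'
#' Runs two adaptive MH-within-Gibbs chains on the banded matrix, each
#' initialised with i.i.d. Uniform(0, 1) frequencies, with proposal-scale
#' adaptation during burn-in.  Burn-in ends when [assess_mixing()] declares
#' mixing (or at `max_sweeps`, with a warning); proposals are then frozen
#' and `n_samples` thinned draws are collected, by default from chain A.
#'
#' @param o Observed [contact_map()].
#' @param bias A [bias_vector()]; masked bins are excluded everywhere.
#' @param decay A `decay_model`, or a positive vector of per-distance
#'   expectations `g(d)` of length `band + 1`.
#' @param spec An [mrf_spec()].
#' @param config A [sampler_config()].
#' @param verbose Print a log line at each mixing check.
#' @return An object of class `posterior_samples`: `draws` (pixels x
#'   samples matrix of frequencies), `pixels` (their 0-based coordinates),
#'   summaries `mean`/`variance`/`dispersion`, `mixed`, `burn_in_sweeps`,
#'   `accept_rate` (mean MH acceptance over the collection phase),
#'   `mixing_history`, and provenance.
#' @export
hic_sample <- function(o, bias, decay, spec, config = sampler_config(),
                       verbose = FALSE) {
  inputs <- prepare_inputs(o, bias, decay, spec, config)
  idx <- inputs$px$idx
  chains <- lapply(seq_len(config$n_chains), function(c) {
    new_chain_state(inputs$n, inputs$band, idx,
                    derive_seed(config$seed, paste0("chain", c)))
  })

  draws_burn <- rep(list(list()), config$n_chains)
  history <- list()
  mixed <- FALSE
  repeat {
    for (c in seq_along(chains)) {
      chains[[c]] <- run_chunk(chains[[c]], inputs, config$thin,
                               adapt = TRUE, config, chain_id = c)
      draws_burn[[c]][[length(draws_burn[[c]]) + 1L]] <-
        exp(chains[[c]]$u[idx])
    }
    sweep <- chains[[1L]]$sweep
    mx <- assess_mixing(draws_burn[[1L]], draws_burn[[2L]],
                        tol = config$rmse_tol, window = config$min_draws)
    if (mx$assessable) {
      history[[length(history) + 1L]] <- data.table::data.table(
        sweep = sweep, inter = mx$inter, intra = mx$intra,
        mixed = mx$mixed
      )
      if (verbose) {
        message(sprintf("sweep %d: inter-RMSE %.4g intra-RMSE %.4g%s",
                        sweep, mx$inter, mx$intra,
                        if (mx$mixed) " [mixed]" else ""))
      }
      if (mx$mixed) {
        mixed <- TRUE
        break
      }
    }
    if (sweep >= config$max_sweeps) {
      warning("mixing not achieved within max_sweeps = ",
              config$max_sweeps, "; collecting samples anyway")
      break
    }
  }
  burn_in <- chains[[1L]]$sweep

  n_s <- config$n_samples
  draws <- NULL
  accept_rate <- NA_real_
  if (n_s > 0L) {
    draws <- matrix(NA_real_, nrow = length(idx), ncol = n_s)
    acc <- 0
    prp <- 0
    chain_for <- if (config$pool_chains) {
      rep_len(seq_along(chains), n_s)
    } else {
      rep(1L, n_s)
    }
    for (s in seq_len(n_s)) {
      c <- chain_for[s]
      chains[[c]] <- run_chunk(chains[[c]], inputs, config$thin,
                               adapt = FALSE, config, chain_id = c)
      draws[, s] <- exp(chains[[c]]$u[idx])
      acc <- acc + chains[[c]]$accepted
      prp <- prp + chains[[c]]$proposed
    }
    accept_rate <- acc / prp
  }

  ps <- structure(
    list(
      draws = draws,
      pixels = data.table::data.table(i = inputs$px$i, j = inputs$px$j,
                                      d = inputs$px$d),
      n_bins = inputs$n, band = inputs$band, bin_size = o$bin_size,
      chrom = o$chrom,
      mean = NULL, variance = NULL, dispersion = NULL,
      mixed = mixed, burn_in_sweeps = burn_in,
      accept_rate = accept_rate,
      mixing_history = if (length(history)) {
        data.table::rbindlist(history)
      } else {
        data.table::data.table(sweep = integer(), inter = numeric(),
                               intra = numeric(), mixed = logical())
      },
      burn_in_draws = draws_burn,
      config = config,
      variant = spec$variant,
      g = inputs$g
    ),
    class = "posterior_samples"
  )
  if (!is.null(draws) && ncol(draws) >= 2L) {
    sm <- summarize_samples(ps)
    ps$mean <- sm$mean
    ps$variance <- sm$variance
    ps$dispersion <- sm$dispersion
  }
  ps
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "posterior_samples: %d pixels, %d draws, burn-in %d sweeps (mixed: %s), mean acceptance %.3f\n",
    nrow(x$pixels), if (is.null(x$draws)) 0L else ncol(x$draws),
    x$burn_in_sweeps, x$mixed, x$accept_rate))
  invisible(x)
}

#' Posterior summary matrices
#'
#' Element-wise mean, variance and dispersion index (variance / mean) of
#' the stored draws.
#'
#' @param x A `posterior_samples` object or a pixels-by-samples matrix.
#' @return List of numeric vectors `mean`, `variance`, `dispersion`
#'   aligned with the pixel table.
#' @export
summarize_samples <- function(x) {
  draws <- if (inherits(x, "posterior_samples")) x$draws else x
  if (is.null(draws) || ncol(draws) < 2L) {
    stop("at least 2 samples are required to summarise")
  }
  m <- rowMeans(draws)
  v <- rowSums((draws - m)^2) / (ncol(draws) - 1L)
  list(mean = m, variance = v,
       dispersion = ifelse(m > 0, v / m, NA_real_))
}

#' Extract a posterior summary (or one draw) as a frequency matrix
#'
#' @param ps A `posterior_samples` object.
#' @param what `"mean"`, `"variance"`, `"dispersion"`, or `"draw"`.
#' @param index Draw index when `what = "draw"`.
#' @return A [freq_matrix()].
#' @export
as_freq_matrix <- function(ps, what = c("mean", "variance", "dispersion",
                                        "draw"), index = 1L) {
  what <- match.arg(what)
  value <- if (what == "draw") ps$draws[, index] else ps[[what]]
  if (is.null(value)) stop("summary '", what, "' not available")
  freq_matrix(
    data.table::data.table(i = ps$pixels$i, j = ps$pixels$j, value = value),
    n_bins = ps$n_bins, bin_size = ps$bin_size, chrom = ps$chrom,
    max_distance_bins = ps$band
  )
}

#' One Metropolis-Hastings update at a single pixel
#'
#' Reference implementation of the within-Gibbs update: proposes
#' `u* ~ Normal(u, sd^2)` in log space and accepts with probability
#' `min(1, exp(logcond(e^u*) + u* - logcond(e^u) - u))`, the `+u` terms
#' being the change-of-variable correction.  Used for testing; the
#' production path is compiled.
#'
#' @param u Current log frequency.
#' @param sd Proposal standard deviation.
#' @inheritParams log_conditional
#' @param unif,z Optional pre-drawn Uniform(0,1) and Normal(0,1) variates.
#' @return List with `u` (new log value), `accepted`.
#' @export
mh_update <- function(u, sd, i, j, state, o_ij, b_ij, g_ij, spec,
                      unif = stats::runif(1), z = stats::rnorm(1)) {
  cur <- log_conditional(exp(u), i, j, state, o_ij, b_ij, g_ij, spec)
  if (!is.finite(cur)) {
    stop("non-finite conditional at current state, pixel (", i, ", ", j, ")")
  }
  prop <- u + sd * z
  la <- log_conditional(exp(prop), i, j, state, o_ij, b_ij, g_ij, spec) +
    prop - cur - u
  if (la >= 0 || log(unif) < la) {
    list(u = prop, accepted = TRUE)
  } else {
    list(u = u, accepted = FALSE)
  }
}

#' Single-pixel posterior chain with fixed neighbours
#'
#' Runs the compiled MH kernel on one pixel whose Markov blanket is held
#' fixed, returning thinned frequency draws.  Used to compare MCMC
#' marginals against grid-quadrature posteriors.
#'
#' @param o_ij Observed count.
#' @param b_ij Bias product.
#' @param g_ij Distance-decay expectation.
#' @param omega2 Local-potential variance.
#' @param neighbors Fixed neighbour frequencies (possibly empty).
#' @param sigma2_edges Edge variances, one per neighbour.
#' @param variant Prior variant.
#' @param n_draws,thin,proposal_sd,init,seed Chain settings.
#' @return Numeric vector of `n_draws` frequency draws.
#' @export
single_pixel_chain <- function(o_ij, b_ij, g_ij, omega2,
                               neighbors = numeric(), sigma2_edges = numeric(),
                               variant = "full", n_draws = 1000L, thin = 5L,
                               proposal_sd = 1, init = 1, seed = 1L) {
  stopifnot(length(neighbors) == length(sigma2_edges))
  u <- cpp_single_pixel_chain(
    o_ij, log(b_ij), log(g_ij), omega2, log(neighbors), sigma2_edges,
    variant_code(variant), as.integer(n_draws), as.integer(thin),
    proposal_sd, log(init), as.numeric(seed)
  )
  exp(u)
}
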