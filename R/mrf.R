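# Markov random field prior over the latent frequency matrix.
#
# Potentials are Gaussian kernels on the log scale:
#   local     phi(t_ij)        = exp(-(log t_ij - log g_ij)^2 / (2 w2(d)))
#   pairwise  phi(t_ij, t_kl)  = exp(-(log t_ij - log t_kl)^2 / (2 s2_edge))
# with s2_edge = max(s2_ij, s2_kl) so the pairwise term is symmetric in its
# arguments.  Both variance fields are estimated empirically from the
# ICE-normalized map, on the log scale, because the potentials penalise
# log-scale differences.

# Dense symmetric matrix of log normalized values; NA outside the band and
# at non-positive / absent entries.
dense_log_matrix <- function(norm) {
  n <- norm$n_bins
  L <- matrix(NA_real_, n, n)
  e <- norm$entries[norm$entries$value > 0]
  L[cbind(e$i + 1L, e$j + 1L)] <- log(e$value)
  L[cbind(e$j + 1L, e$i + 1L)] <- log(e$value)
  L
}

#' Per-distance prior variance of the log frequency
#'
#' For each bin distance `d` in the band, the variance of log normalized
#' interaction frequencies over all (unmasked, positive) pixels at that
#' distance.  This is the empirical-Bayes estimate of the local-potential
#' variance: how far log t typically strays from the distance-decay
#' expectation.  Strata with fewer than 3 positive pixels borrow the value
#' of the nearest populated stratum (with a warning); all values are
#' floored at `variance_floor`.
#'
#' @param norm Normalized map ([freq_matrix()]) from [ice_balance()].
#' @param variance_floor Lower bound applied to every returned variance.
#' @return Numeric vector of length `max_distance_bins + 1`, element `d + 1`
#'   giving the variance at distance `d`.
#' @export
estimate_omega2 <- function(norm, variance_floor = 1e-4) {
  band <- norm$max_distance_bins
  e <- norm$entries[norm$entries$value > 0]
  d <- e$j - e$i
  lv <- log(e$value)
  out <- rep(NA_real_, band + 1L)
  cnt <- integer(band + 1L)
  for (dd in 0:band) {
    sel <- d == dd
    cnt[dd + 1L] <- sum(sel)
    if (cnt[dd + 1L] >= 3L) out[dd + 1L] <- stats::var(lv[sel])
  }
  if (anyNA(out)) {
    pop <- which(!is.na(out))
    if (!length(pop)) stop("no distance stratum has 3 or more positive pixels")
    warning(sum(is.na(out)), " distance strata with <3 positive pixels; ",
            "using nearest populated stratum")
    for (k in which(is.na(out))) {
      out[k] <- out[pop[which.min(abs(pop - k))]]
    }
  }
  pmax(out, variance_floor)
}

# Padded summed-area table: P[r+1, c+1] = sum(M[1:r, 1:c]) with non-finite
# entries treated as 0.
sat_pad <- function(M) {
  M[!is.finite(M)] <- 0
  S <- apply(M, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  cbind(0, rbind(0, S, deparse.level = 0), deparse.level = 0)
}

# Vectorised rectangle sums over a padded SAT; empty rectangles give 0.
rect_sum <- function(P, r1, r2, c1, c2) {
  empty <- r2 < r1 | c2 < c1
  r1 <- pmax(r1, 1L); c1 <- pmax(c1, 1L)
  r2p <- pmax(r2, r1 - 1L); c2p <- pmax(c2, c1 - 1L)
  out <- P[cbind(r2p + 1L, c2p + 1L)] - P[cbind(r1, c2p + 1L)] -
    P[cbind(r2p + 1L, c1)] + P[cbind(r1, c1)]
  out[empty] <- 0
  out
}

#' Per-pixel smoothness variance of the log frequency
#'
#' For each in-band pixel, the variance of first-order-adjacent log-value
#' differences within a `window x window` square centred on the pixel
#' (clipped at matrix and band edges).  This estimates the local-smoothness
#' variance of the pairwise potential; sharp but locally uniform regions get
#' small values, noisy or transitional regions large ones.  Values are
#' floored at `variance_floor`.
#'
#' @param norm Normalized map ([freq_matrix()]).
#' @param window Odd window size, at least 3.  17 is the default; on a new
#'   resolution it can be selected by held-out likelihood over a grid.
#' @param variance_floor Lower bound.
#' @return Band matrix (`n_bins x (band + 1)`) of variances; NA at cells
#'   outside the triangle.
#' @export
estimate_sigma2 <- function(norm, window = 17L, variance_floor = 1e-4) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  n <- norm$n_bins
  band <- norm$max_distance_bins
  h <- (window - 1L) %/% 2L
  L <- dense_log_matrix(norm)
  dh <- L[, 2:n, drop = FALSE] - L[, 1:(n - 1L), drop = FALSE]
  dv <- L[2:n, , drop = FALSE] - L[1:(n - 1L), , drop = FALSE]
  Ph_c <- sat_pad(matrix(as.numeric(is.finite(dh)), n, n - 1L))
  Ph_s <- sat_pad(dh)
  Ph_q <- sat_pad(dh^2)
  Pv_c <- sat_pad(matrix(as.numeric(is.finite(dv)), n - 1L, n))
  Pv_s <- sat_pad(dv)
  Pv_q <- sat_pad(dv^2)

  px <- valid_pixel_index(n, band)
  r <- px$i + 1L
  cc <- px$j + 1L
  r1 <- pmax(1L, r - h); r2 <- pmin(n, r + h)
  c1 <- pmax(1L, cc - h); c2 <- pmin(n, cc + h)
  m <- rect_sum(Ph_c, r1, r2, c1, pmin(c2 - 1L, n - 1L)) +
    rect_sum(Pv_c, r1, pmin(r2 - 1L, n - 1L), c1, c2)
  s <- rect_sum(Ph_s, r1, r2, c1, pmin(c2 - 1L, n - 1L)) +
    rect_sum(Pv_s, r1, pmin(r2 - 1L, n - 1L), c1, c2)
  q <- rect_sum(Ph_q, r1, r2, c1, pmin(c2 - 1L, n - 1L)) +
    rect_sum(Pv_q, r1, pmin(r2 - 1L, n - 1L), c1, c2)
  v <- ifelse(m >= 2, (q - s^2 / pmax(m, 1)) / pmax(m - 1, 1), 0)
  out <- band_matrix_skeleton(n, band, fill = NA_real_)
  out[px$idx] <- pmax(v, variance_floor)
  out
}

# Two-sample KS statistic, no ties assumed.
ks_d_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  o <- order(z)
  steps <- ifelse(o <= nx, 1 / nx, -1 / ny)
  max(abs(cumsum(steps)))
}

#' Detect sharp boundaries and prune Markov blankets
#'
#' For every horizontal and vertical transition between adjacent in-band
#' pixels, compares the strip of log normalized values on one side with the
#' strip on the other side (each strip runs `flank` pixels either way along
#' the transition, 2*flank+1 values) by an exact two-sample
#' Kolmogorov-Smirnov test.  Transitions with p-value below `alpha` -- the
#' signature of a domain boundary -- are removed from the Markov blankets of
#' both pixels.  Diagonal neighbour edges inherit pruning from the row and
#' column transitions they cross.  Strips with fewer than 5 usable values on
#' either side keep the edge (conservative).  `alpha = 0` disables pruning.
#'
#' @param norm Normalized map ([freq_matrix()]).
#' @param alpha Significance level of the KS test.
#' @param flank Half-length of the comparison strips, at least 5.
#' @return An object of class `pruned_edges`: logical band matrices
#'   `e_row` (transition between rows `i` and `i + 1` at pixel `(i, j)`) and
#'   `e_col` (between columns `j` and `j + 1`), plus parameters.
#' @export
prune_blanket <- function(norm, alpha = 0.01, flank = 8L) {
  n <- norm$n_bins
  band <- norm$max_distance_bins
  if (alpha > 0 && flank < 5L) stop("flank must be at least 5")
  e_row <- matrix(FALSE, n, band + 1L)
  e_col <- matrix(FALSE, n, band + 1L)
  res <- structure(
    list(e_row = e_row, e_col = e_col, n_bins = n, band = band,
         alpha = alpha, flank = as.integer(flank)),
    class = "pruned_edges"
  )
  if (alpha <= 0) return(res)
  L <- dense_log_matrix(norm)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  signif_split <- function(a, b) {
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (length(a) < 5L || length(b) < 5L) return(FALSE)
    D <- ks_d_stat(a, b)
    key <- sprintf("%d_%d_%d", length(a), length(b),
                   as.integer(round(D * length(a) * length(b))))
    p <- cache[[key]]
    if (is.null(p)) {
      p <- 1 - stats::psmirnov(D, sizes = c(length(a), length(b)),
                               exact = TRUE)
      cache[[key]] <- p
    }
    p < alpha
  }
  for (d in 0:band) {
    for (i in 0:(n - 1L - d)) {
      j <- i + d
      if (j + 1L < n && d + 1L <= band) {
        rs <- max(1L, i + 1L - flank):min(n, i + 1L + flank)
        e_col[i + 1L, d + 1L] <- signif_split(L[rs, j + 1L], L[rs, j + 2L])
      }
      if (d >= 1L && i + 1L < n) {
        cs <- max(1L, j + 1L - flank):min(n, j + 1L + flank)
        e_row[i + 1L, d + 1L] <- signif_split(L[i + 1L, cs], L[i + 2L, cs])
      }
    }
  }
  res$e_row <- e_row
  res$e_col <- e_col
  res
}

#' MRF prior specification
#'
#' Bundles the empirical-Bayes variance fields, the pruned-edge structure
#' and the prior-variant switch consumed by [log_conditional()] and
#' [hic_sample()].  Variants: `"full"` (local + pairwise, per-pixel
#' variances), `"uniform"` (no prior terms, likelihood only), `"gaussian"`
#' (local distance-decay term only), `"fixed_sigma"` (pairwise variance
#' fixed to the scalar `sigma2_fixed` everywhere).
#'
#' @param omega2 Per-distance variance vector from [estimate_omega2()].
#' @param sigma2 Per-pixel variance band matrix from [estimate_sigma2()].
#' @param pruned A `pruned_edges` object from [prune_blanket()], or `NULL`
#'   for intact blankets.
#' @param window Window size used for `sigma2` (metadata).
#' @param variant One of `"full"`, `"uniform"`, `"gaussian"`,
#'   `"fixed_sigma"`.
#' @param sigma2_fixed Scalar pairwise variance for the `"fixed_sigma"`
#'   variant; defaults to the median of `sigma2`.
#' @param variance_floor Floor already applied to the variance fields.
#' @param n_bins,band Geometry.
#' @return An object of class `mrf_spec`.
#' @export
mrf_spec <- function(omega2, sigma2, pruned = NULL, window = 17L,
                     variant = c("full", "uniform", "gaussian",
                                 "fixed_sigma"),
                     sigma2_fixed = NULL, variance_floor = 1e-4,
                     n_bins = nrow(sigma2), band = ncol(sigma2) - 1L) {
  variant <- match.arg(variant)
  stopifnot(length(omega2) == band + 1L, nrow(sigma2) == n_bins)
  if (any(omega2 < variance_floor - 1e-12)) stop("omega2 below the floor")
  if (any(sigma2 < variance_floor - 1e-12, na.rm = TRUE)) {
    stop("sigma2 below the floor")
  }
  if (is.null(pruned)) {
    pruned <- structure(
      list(e_row = matrix(FALSE, n_bins, band + 1L),
           e_col = matrix(FALSE, n_bins, band + 1L),
           n_bins = n_bins, band = band, alpha = 0, flank = 0L),
      class = "pruned_edges"
    )
  }
  if (variant == "fixed_sigma" && is.null(sigma2_fixed)) {
    sigma2_fixed <- stats::median(sigma2, na.rm = TRUE)
  }
  structure(
    list(omega2 = omega2, sigma2 = sigma2, pruned = pruned,
         window = as.integer(window), variant = variant,
         sigma2_fixed = sigma2_fixed %||% NA_real_,
         variance_floor = variance_floor,
         n_bins = as.integer(n_bins), band = as.integer(band)),
    class = "mrf_spec"
  )
}

#' Estimate a complete MRF prior from a normalized map
#'
#' Convenience wrapper running [estimate_omega2()], [estimate_sigma2()] and
#' [prune_blanket()] and assembling an [mrf_spec()].  For the `"uniform"`
#' and `"gaussian"` variants the pairwise machinery is skipped.
#'
#' @inheritParams estimate_sigma2
#' @inheritParams prune_blanket
#' @inheritParams mrf_spec
#' @return An [mrf_spec()].
#' @export
build_mrf <- function(norm, window = 17L, alpha = 0.01, flank = 8L,
                      variant = "full", sigma2_fixed = NULL,
                      variance_floor = 1e-4) {
  omega2 <- estimate_omega2(norm, variance_floor)
  needs_pairwise <- variant %in% c("full", "fixed_sigma")
  sigma2 <- if (needs_pairwise) {
    estimate_sigma2(norm, window, variance_floor)
  } else {
    band_matrix_skeleton(norm$n_bins, norm$max_distance_bins,
                         fill = variance_floor)
  }
  pruned <- if (needs_pairwise) prune_blanket(norm, alpha, flank) else NULL
  mrf_spec(omega2, sigma2, pruned, window = window, variant = variant,
           sigma2_fixed = sigma2_fixed, variance_floor = variance_floor,
           n_bins = norm$n_bins, band = norm$max_distance_bins)
}

#' Log local potential
#'
#' `-(log t - log g)^2 / (2 * omega2)`: maximal (0) at `t = g`, symmetric in
#' the sign of the log deviation.
#'
#' @param t Positive candidate frequency (vectorised).
#' @param g Positive distance-decay expectation.
#' @param omega2 Positive variance.
#' @return Numeric log-potential values.
#' @export
log_local_potential <- function(t, g, omega2) {
  if (any(t <= 0) || any(g <= 0)) stop("t and g must be positive")
  -(log(t) - log(g))^2 / (2 * omega2)
}

#' Log pairwise potential
#'
#' `-(log t_p - log t_q)^2 / (2 * sigma2_edge)` with `sigma2_edge` the
#' maximum of the two pixels' variances, making the term symmetric under
#' argument swap and invariant to a common rescaling of both frequencies.
#'
#' @param t_p,t_q Positive frequencies (vectorised).
#' @param sigma2_edge Positive edge variance.
#' @return Numeric log-potential values.
#' @export
log_pairwise_potential <- function(t_p, t_q, sigma2_edge) {
  if (any(t_p <= 0) || any(t_q <= 0)) stop("frequencies must be positive")
  -(log(t_p) - log(t_q))^2 / (2 * sigma2_edge)
}

# Second-order (8-)neighbourhood of pixel (i, j), canonicalised to the
# upper triangle, deduplicated (near the diagonal mirror images coincide),
# excluding self.  0-based indices, returns a 2-column matrix (qi, qj).
neighbors_of <- function(i, j, n_bins, band) {
  di <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  dj <- c(0L, 0L, -1L, 1L, -1L, 1L, 1L, -1L)
  qi <- i + di
  qj <- j + dj
  s <- qi > qj
  tmp <- qi[s]; qi[s] <- qj[s]; qj[s] <- tmp
  ok <- qi >= 0L & qj < n_bins & (qj - qi) <= band & !(qi == i & qj == j)
  unique(cbind(qi = qi[ok], qj = qj[ok]))
}

# Is the MRF edge between upper-triangle pixels (i1,j1) and (i2,j2) pruned?
# Row/column edges look up the transition flag directly; diagonal edges are
# pruned when either transition they cross is.
edge_is_pruned <- function(pruned, i1, j1, i2, j2) {
  if (i2 < i1 || (i2 == i1 && j2 < j1)) {
    tmp <- i1; i1 <- i2; i2 <- tmp
    tmp <- j1; j1 <- j2; j2 <- tmp
  }
  di <- i2 - i1
  dj <- j2 - j1
  ad <- j1 - i1
  if (di == 0L && dj == 1L) return(pruned$e_col[i1 + 1L, ad + 1L])
  if (di == 1L && dj == 0L) return(pruned$e_row[i1 + 1L, ad + 1L])
  if (di == 1L && dj == 1L) {
    return(pruned$e_row[i1 + 1L, ad + 1L] || pruned$e_col[i1 + 1L, ad + 1L])
  }
  if (di == 1L && dj == -1L) {
    cd <- (j1 - 1L) - (i1 + 1L)
    cc <- if (cd >= 0L) pruned$e_col[i1 + 2L, cd + 1L] else FALSE
    return(pruned$e_row[i1 + 1L, ad + 1L] || cc)
  }
  FALSE
}

#' All pruned edges as a table
#'
#' Enumerates every retained-candidate edge of the second-order
#' neighbourhood system that is pruned, each undirected edge once.
#'
#' @param spec An [mrf_spec()].
#' @return A data.table with columns `i1, j1, i2, j2` (0-based).
#' @export
pruned_edges <- function(spec) {
  n <- spec$n_bins
  band <- spec$band
  out <- list()
  k <- 0L
  for (d in 0:band) {
    for (i in 0:(n - 1L - d)) {
      j <- i + d
      nb <- neighbors_of(i, j, n, band)
      for (r in seq_len(nrow(nb))) {
        qi <- nb[r, 1L]; qj <- nb[r, 2L]
        if (qi > i || (qi == i && qj > j)) {
          if (edge_is_pruned(spec$pruned, i, j, qi, qj)) {
            k <- k + 1L
            out[[k]] <- c(i, j, qi, qj)
          }
        }
      }
    }
  }
  if (!k) {
    return(data.table::data.table(i1 = integer(), j1 = integer(),
                                  i2 = integer(), j2 = integer()))
  }
  m <- do.call(rbind, out)
  data.table::data.table(i1 = m[, 1L], j1 = m[, 2L], i2 = m[, 3L],
                         j2 = m[, 4L])
}

#' Unnormalised log full-conditional density of one pixel
#'
#' Reference (R) implementation of the single-site conditional targeted by
#' the sampler: Poisson log-likelihood at rate `b_ij * t`, plus the local
#' potential (except under the uniform variant), plus the pairwise potential
#' to every unpruned neighbour in the second-order Markov blanket (except
#' under the uniform and gaussian variants).  Non-positive candidates have
#' density zero (`-Inf`).
#'
#' @param t Candidate frequency values (vectorised).
#' @param i,j 0-based pixel coordinates (`i <= j`).
#' @param state Current frequency state: a band matrix or [freq_matrix()];
#'   NA / non-positive neighbours are skipped (masked).
#' @param o_ij Observed count.
#' @param b_ij Pairwise bias product.
#' @param g_ij Distance-decay expectation at this pixel.
#' @param spec An [mrf_spec()].
#' @return Numeric vector of unnormalised log densities.
#' @export
log_conditional <- function(t, i, j, state, o_ij, b_ij, g_ij, spec) {
  if (inherits(state, "freq_matrix")) {
    state <- sparse_to_band(state$entries, state$n_bins,
                            state$max_distance_bins, "value",
                            fill = NA_real_)
  }
  out <- rep(-Inf, length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tv <- t[pos]
  val <- stats::dpois(o_ij, b_ij * tv, log = TRUE)
  if (spec$variant != "uniform") {
    val <- val + log_local_potential(tv, g_ij, spec$omega2[j - i + 1L])
  }
  if (spec$variant %in% c("full", "fixed_sigma")) {
    nb <- neighbors_of(i, j, spec$n_bins, spec$band)
    for (r in seq_len(nrow(nb))) {
      qi <- nb[r, 1L]; qj <- nb[r, 2L]
      tq <- state[qi + 1L, qj - qi + 1L]
      if (!is.finite(tq) || tq <= 0) next
      if (edge_is_pruned(spec$pruned, i, j, qi, qj)) next
      s2 <- if (spec$variant == "fixed_sigma") {
        spec$sigma2_fixed
      } else {
        max(spec$sigma2[i + 1L, j - i + 1L],
            spec$sigma2[qi + 1L, qj - qi + 1L])
      }
      val <- val + log_pairwise_potential(tv, tq, s2)
    }
  }
  out[pos] <- val
  out
}

#' Joint log prior of a frequency state
#'
#' Sum of all local potentials plus each retained pairwise edge counted
#' once.  Together with the Poisson log-likelihood this is the log joint
#' density (up to a constant); single-site differences reproduce
#' [log_conditional()] differences exactly.
#'
#' @param state Band matrix or [freq_matrix()] of positive frequencies
#'   (NA = masked).
#' @param spec An [mrf_spec()].
#' @param g Per-distance expectation: numeric vector of length `band + 1`
#'   or a `decay_model`.
#' @return Scalar log prior (`-Inf` if any present value is non-positive).
#' @export
joint_log_prior <- function(state, spec, g) {
  if (inherits(state, "freq_matrix")) {
    state <- sparse_to_band(state$entries, state$n_bins,
                            state$max_distance_bins, "value",
                            fill = NA_real_)
  }
  if (inherits(g, "decay_model")) g <- predict_g(g, 0:spec$band)
  n <- spec$n_bins
  band <- spec$band
  total <- 0
  for (d in 0:band) {
    for (i in 0:(n - 1L - d)) {
      t_p <- state[i + 1L, d + 1L]
      if (!is.finite(t_p)) next
      if (t_p <= 0) return(-Inf)
      j <- i + d
      if (spec$variant != "uniform") {
        total <- total + log_local_potential(t_p, g[d + 1L],
                                             spec$omega2[d + 1L])
      }
      if (spec$variant %in% c("full", "fixed_sigma")) {
        nb <- neighbors_of(i, j, n, band)
        for (r in seq_len(nrow(nb))) {
          qi <- nb[r, 1L]; qj <- nb[r, 2L]
          if (qi < i || (qi == i && qj < j)) next  # count each edge once
          tq <- state[qi + 1L, qj - qi + 1L]
          if (!is.finite(tq) || tq <= 0) next
          if (edge_is_pruned(spec$pruned, i, j, qi, qj)) next
          s2 <- if (spec$variant == "fixed_sigma") {
            spec$sigma2_fixed
          } else {
            max(spec$sigma2[i + 1L, d + 1L],
                spec$sigma2[qi + 1L, qj - qi + 1L])
          }
          total <- total + log_pairwise_potential(t_p, tq, s2)
        }
      }
    }
  }
  total
}
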