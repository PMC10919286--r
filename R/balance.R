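#' Iterative correction (ICE) of a contact map
#'
#' Estimates per-bin multiplicative biases under the equal-visibility
#' assumption: after dividing each count by `b[i] * b[j]`, all usable bins
#' have (near-)equal marginal coverage.  The symmetric fixed point is found
#' by repeatedly scaling each bias by the square root of its current
#' relative marginal.  Balancing operates on the map as loaded, i.e. on the
#' analysis band; a bias vector estimated from a full-width map by external
#' tools may be supplied to downstream steps via [read_bias()] instead.
#'
#' Low-coverage bins -- raw marginal zero, or below the `mask_quantile`
#' quantile of the positive raw marginals -- are masked before iterating and
#' excluded from all later likelihood terms.
#'
#' @param o A [contact_map()].
#' @param max_iter Maximum number of update iterations.
#' @param tol Convergence threshold on the maximum relative change of any
#'   unmasked bias entry between iterations.
#' @param mask_quantile Fraction of lowest-coverage (positive-marginal) bins
#'   to mask, in addition to zero-coverage bins.
#' @return A list with components `bias` (a [bias_vector()] scaled to
#'   unmasked mean 1), `normalized` (a [freq_matrix()] with
#'   `value = count / (b[i] * b[j])`), `converged` (logical) and `n_iter`.
#' @export
ice_balance <- function(o, max_iter = 200L, tol = 1e-6,
                        mask_quantile = 0.02) {
  stopifnot(inherits(o, "contact_map"))
  if (!nrow(o$entries)) stop("cannot balance an empty contact map")
  n <- o$n_bins
  ei <- o$entries$i + 1L
  ej <- o$entries$j + 1L
  x <- o$entries$count

  marginal <- function(w) {
    m <- numeric(n)
    m[] <- 0
    agg_i <- rowsum(w, ei)
    m[as.integer(rownames(agg_i))] <- agg_i[, 1L]
    off <- ei != ej
    if (any(off)) {
      agg_j <- rowsum(w[off], ej[off])
      m[as.integer(rownames(agg_j))] <- m[as.integer(rownames(agg_j))] +
        agg_j[, 1L]
    }
    m
  }

  raw_marg <- marginal(x)
  pos <- raw_marg > 0
  cutoff <- if (any(pos)) stats::quantile(raw_marg[pos], mask_quantile) else 0
  mask <- pos & raw_marg >= cutoff
  if (sum(mask) < 2L) stop("fewer than 2 usable bins after masking")

  b <- rep(1, n)
  b[!mask] <- NA_real_
  converged <- FALSE
  iter <- 0L
  keep <- mask[ei] & mask[ej]
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- ifelse(keep, x / (b[ei] * b[ej]), 0)
    m <- marginal(w)
    s <- sqrt(m[mask] / mean(m[mask]))
    b[mask] <- b[mask] * s
    if (max(abs(s - 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("ICE did not converge in ", max_iter, " iterations")
  }
  b[mask] <- b[mask] / mean(b[mask])

  value <- ifelse(keep, x / (b[ei] * b[ej]), NA_real_)
  norm_entries <- data.table::data.table(
    i = o$entries$i, j = o$entries$j, value = value
  )[!is.na(value)]
  list(
    bias = bias_vector(b, mask),
    normalized = freq_matrix(norm_entries, n_bins = n,
                             bin_size = o$bin_size, chrom = o$chrom,
                             max_distance_bins = o$max_distance_bins),
    converged = converged,
    n_iter = iter
  )
}
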