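#' Fit the B-spline distance-decay model
#'
#' Poisson log-linear regression of observed counts on genomic distance:
#' `log E[o_ij] = w0 + B(|i - j|) + log(b_i * b_j)`, where `B` is a cubic
#' B-spline in the bin distance with knots at 0, 25, 50, 75 and 100 percent
#' of the maximum analysis distance, and the log pairwise bias enters as an
#' offset.  The model is trained by maximum likelihood (IRLS) on a random
#' subsample of the in-band pixels of the map; zero-count pixels are
#' included, as they carry information in a Poisson regression.
#'
#' @param o A [contact_map()].
#' @param b A [bias_vector()]; masked bins are excluded from the fit.
#' @param sample_frac Fraction of in-band unmasked pixels used for training
#'   (sampled uniformly without replacement).
#' @param seed Integer seed for the training subsample.
#' @return An object of class `decay_model` with fields `coef`, `knots`
#'   (the full 5-point knot vector in bins), `degree`,
#'   `max_distance_bins`.
#' @export
fit_decay <- function(o, b, sample_frac = 0.1, seed = 1L) {
  stopifnot(inherits(o, "contact_map"), inherits(b, "bias_vector"))
  stopifnot(sample_frac > 0, sample_frac <= 1)
  n <- o$n_bins
  band <- o$max_distance_bins
  if (band < 4L) stop("analysis band too narrow for the spline basis")
  px <- valid_pixel_index(n, band, b$mask)
  if (!length(px$idx)) stop("no usable pixels")
  counts <- sparse_to_band(o$entries, n, band)[px$idx]
  n_take <- max(1L, round(sample_frac * length(px$idx)))
  take <- if (n_take >= length(px$idx)) {
    seq_along(px$idx)
  } else {
    with_seed(seed, sample.int(length(px$idx), n_take))
  }
  d <- px$d[take]
  y <- counts[take]
  off <- log(b$values[px$i[take] + 1L]) + log(b$values[px$j[take] + 1L])
  if (length(unique(d)) < 8L) {
    stop("degenerate design: fewer than 8 distinct distances in the ",
         "training sample")
  }
  knots_all <- band * c(0, 0.25, 0.5, 0.75, 1)
  X <- splines::bs(d, knots = knots_all[2:4],
                   Boundary.knots = knots_all[c(1L, 5L)], degree = 3L)
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                        offset = off, family = stats::poisson(),
                        control = stats::glm.control(epsilon = 1e-8,
                                                     maxit = 100L))
  if (any(!is.finite(fit$coefficients))) {
    stop("decay fit produced non-finite coefficients")
  }
  structure(
    list(coef = fit$coefficients, knots = knots_all, degree = 3L,
         max_distance_bins = band, n_train = length(y),
         converged = fit$converged),
    class = "decay_model"
  )
}

#' Distance-decay expectation g(d)
#'
#' Evaluates the fitted expected normalized interaction frequency at bin
#' distance `d` (unit bias), i.e. `exp(w0 + B(d))`.  No extrapolation:
#' distances outside `[0, max_distance_bins]` are an error.
#'
#' @param m A `decay_model` from [fit_decay()].
#' @param d Vector of bin distances.
#' @return Positive numeric vector of expectations.
#' @export
predict_g <- function(m, d) {
  stopifnot(inherits(m, "decay_model"))
  if (any(d < 0 | d > m$max_distance_bins)) {
    stop("distance outside the fitted domain [0, ", m$max_distance_bins, "]")
  }
  X <- splines::bs(d, knots = m$knots[2:4],
                   Boundary.knots = m$knots[c(1L, 5L)], degree = m$degree)
  as.numeric(exp(cbind(1, X) %*% m$coef))
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("decay_model: cubic B-spline, knots {%s} bins, %d training pixels\n",
              paste(x$knots, collapse = ", "), x$n_train))
  invisible(x)
}

#' Serialize / restore a decay model as JSON
#'
#' @param m A `decay_model`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_decay` returns the model.
#' @export
write_decay <- function(m, path) {
  jsonlite::write_json(
    list(coef = as.list(m$coef), knots = m$knots, degree = m$degree,
         max_distance_bins = m$max_distance_bins, n_train = m$n_train),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coef = unlist(x$coef), knots = as.numeric(x$knots),
         degree = as.integer(x$degree),
         max_distance_bins = as.integer(x$max_distance_bins),
         n_train = x$n_train, converged = TRUE),
    class = "decay_model"
  )
}
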