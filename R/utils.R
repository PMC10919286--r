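# Internal helpers shared across modules.

# data.table is used via :: throughout; declare awareness so [.data.table
# keeps data.table semantics inside this namespace.
.datatable.aware <- TRUE
#
# Banded storage convention: a symmetric n x n matrix restricted to
# |i - j| <= band is held as an n x (band + 1) "band matrix" M with
# M[i + 1, d + 1] = value at bin pair (i, i + d), indices 0-based,
# d = j - i the genomic distance in bins.  Cells with i + d >= n do not
# correspond to a real pair and are NA.

band_matrix_skeleton <- function(n_bins, band, fill = 0) {
  m <- matrix(fill, nrow = n_bins, ncol = band + 1L)
  for (d in seq_len(band)) {
    m[(n_bins - d + 1L):n_bins, d + 1L] <- NA_real_
  }
  m
}

# entries: data.frame-like with columns i, j (0-based, i <= j) and a value
# column; absent pairs read as `fill`.
sparse_to_band <- function(entries, n_bins, band, value_col = "count",
                           fill = 0) {
  m <- band_matrix_skeleton(n_bins, band, fill = fill)
  if (nrow(entries)) {
    m[cbind(entries$i + 1L, entries$j - entries$i + 1L)] <- entries[[value_col]]
  }
  m
}

band_to_sparse <- function(m, value_col = "count", drop_zero = TRUE) {
  idx <- which(is.finite(m) & (!drop_zero | m != 0), arr.ind = TRUE)
  out <- data.table::data.table(
    i = idx[, 1L] - 1L,
    j = idx[, 1L] - 1L + idx[, 2L] - 1L
  )
  out[[value_col]] <- m[idx]
  data.table::setorderv(out, c("i", "j"))
  out[]
}

# Linear indices (into an n x (band+1) band matrix, column-major) of pixels
# that exist and whose two bins are both usable.
valid_pixel_index <- function(n_bins, band, mask = rep(TRUE, n_bins)) {
  i <- rep(seq_len(n_bins) - 1L, band + 1L)
  d <- rep(seq_len(band + 1L) - 1L, each = n_bins)
  ok <- (i + d) < n_bins & mask[i + 1L] & mask[i + d + 1L]
  list(
    idx = which(ok),
    i = i[ok],
    j = i[ok] + d[ok],
    d = d[ok]
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a component seed from a master seed
#'
#' Deterministically maps a master seed and a component label to a seed in
#' `[1, 2^31 - 2]`, so that independent pipeline stages (simulation, chain A,
#' chain B, downsampling, ...) get reproducible but distinct RNG streams from
#' one user-facing seed.
#'
#' @param master Integer master seed.
#' @param component Character label of the consuming component.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, component) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(component))
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(component)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
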