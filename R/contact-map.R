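#' Sparse banded Hi-C contact map
#'
#' Container for a single-chromosome, intra-chromosomal contact map at a
#' fixed bin size.  Only the upper triangle is stored (`i <= j`, 0-based bin
#' indices); querying `(j, i)` is equivalent to `(i, j)`.  Pairs farther
#' apart than `max_distance_bins` are outside the analysis band and dropped.
#' Absent pairs read as count 0.
#'
#' @param entries A data.frame with columns `i`, `j` (0-based bin indices)
#'   and `count` (non-negative integers).  Rows are symmetrised to `i <= j`
#'   and duplicate pairs are summed.
#' @param n_bins Number of bins on the chromosome.
#' @param bin_size Bin size in bp (metadata; distances are in bins).
#' @param chrom Chromosome label.
#' @param max_distance_bins Band width: pairs with `j - i` larger than this
#'   are dropped.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(entries, n_bins, bin_size = 1L, chrom = "chr1",
                        max_distance_bins = n_bins - 1L) {
  stopifnot(n_bins >= 1L, max_distance_bins >= 0L)
  dt <- data.table::as.data.table(entries)
  if (!nrow(dt)) {
    dt <- data.table::data.table(i = integer(), j = integer(),
                                 count = numeric())
  }
  stopifnot(all(c("i", "j", "count") %in% names(dt)))
  if (any(dt$count < 0)) {
    stop("negative counts at rows: ",
         paste(utils::head(which(dt$count < 0), 5L), collapse = ", "))
  }
  if (any(dt$i < 0 | dt$j < 0 | dt$i >= n_bins | dt$j >= n_bins)) {
    stop("bin indices out of range [0, n_bins)")
  }
  swap <- dt$i > dt$j
  if (any(swap)) {
    tmp <- dt$i[swap]
    dt$i[swap] <- dt$j[swap]
    dt$j[swap] <- tmp
  }
  dt <- dt[, list(count = sum(count)), by = c("i", "j")]
  dt <- dt[(dt$j - dt$i) <= max_distance_bins]
  data.table::setorderv(dt, c("i", "j"))
  structure(
    list(entries = dt[], n_bins = as.integer(n_bins),
         bin_size = as.integer(bin_size), chrom = chrom,
         max_distance_bins = as.integer(min(max_distance_bins, n_bins - 1L))),
    class = "contact_map"
  )
}

#' Real-valued interaction frequency matrix
#'
#' Same banded symmetric layout as [contact_map()] but with a real `value`
#' column, used for normalized maps, latent truth, and posterior summaries.
#'
#' @param entries data.frame with columns `i`, `j`, `value`.
#' @inheritParams contact_map
#' @return An object of class `freq_matrix`.
#' @export
freq_matrix <- function(entries, n_bins, bin_size = 1L, chrom = "chr1",
                        max_distance_bins = n_bins - 1L) {
  dt <- data.table::as.data.table(entries)
  if (!nrow(dt)) {
    dt <- data.table::data.table(i = integer(), j = integer(),
                                 value = numeric())
  }
  stopifnot(all(c("i", "j", "value") %in% names(dt)))
  swap <- dt$i > dt$j
  if (any(swap)) {
    tmp <- dt$i[swap]
    dt$i[swap] <- dt$j[swap]
    dt$j[swap] <- tmp
  }
  dt <- dt[(dt$j - dt$i) <= max_distance_bins]
  data.table::setorderv(dt, c("i", "j"))
  structure(
    list(entries = dt[], n_bins = as.integer(n_bins),
         bin_size = as.integer(bin_size), chrom = chrom,
         max_distance_bins = as.integer(min(max_distance_bins, n_bins - 1L))),
    class = "freq_matrix"
  )
}

#' Per-bin multiplicative bias vector
#'
#' Holds one positive multiplier per bin together with a usability mask.
#' The pairwise bias of pair `(i, j)` is always the product
#' `values[i] * values[j]`; it is never materialised as a dense matrix.
#' Masked bins (zero/low coverage) are excluded from all likelihood terms.
#'
#' @param values Numeric vector of per-bin biases; non-positive or missing
#'   entries are masked.
#' @param mask Optional logical vector (`TRUE` = usable); defaults to
#'   finite positive `values`.
#' @return An object of class `bias_vector`.
#' @export
bias_vector <- function(values, mask = NULL) {
  values <- as.numeric(values)
  if (is.null(mask)) {
    mask <- is.finite(values) & values > 0
  }
  stopifnot(length(mask) == length(values))
  values[!mask] <- NA_real_
  if (any(values[mask] <= 0)) stop("masked=FALSE bins must have positive bias")
  structure(list(values = values, mask = mask), class = "bias_vector")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins x %d bp, band %d bins, %d entries, total %g\n",
              x$chrom, x$n_bins, x$bin_size, x$max_distance_bins,
              nrow(x$entries), sum(x$entries$count)))
  invisible(x)
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("freq_matrix: %s, %d bins, band %d bins, %d entries\n",
              x$chrom, x$n_bins, x$max_distance_bins, nrow(x$entries)))
  invisible(x)
}

#' Query a contact map or frequency matrix
#'
#' Symmetric lookup: `map_value(m, i, j)` equals `map_value(m, j, i)`.
#' Absent in-band pairs return 0; out-of-band pairs return NA.
#'
#' @param m A `contact_map` or `freq_matrix`.
#' @param i,j 0-based bin indices (vectorised).
#' @return Numeric vector of counts/values.
#' @export
map_value <- function(m, i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- data.table::data.table(i = as.integer(lo), j = as.integer(hi))
  val_col <- if (inherits(m, "contact_map")) "count" else "value"
  res <- m$entries[key, on = c("i", "j")][[val_col]]
  res[is.na(res)] <- 0
  res[hi - lo > m$max_distance_bins] <- NA_real_
  res
}

format_header <- function(m, value_col) {
  sprintf("# dialect=bin bin_size=%d chrom=%s n_bins=%d max_distance_bins=%d value=%s",
          m$bin_size, m$chrom, m$n_bins, m$max_distance_bins, value_col)
}

parse_header <- function(line) {
  if (!startsWith(line, "#")) return(NULL)
  fields <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
  kv <- strsplit(fields, "=")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  as.list(stats::setNames(vals, keys))
}

#' Read a sparse contact map from a 3-column TSV
#'
#' The file holds tab-separated triples `(coord_i, coord_j, count)`.  Two
#' coordinate dialects are supported: `"bin"` (0-based bin indices) and
#' `"bp"` (0-based half-open bin start positions, which must be multiples of
#' `bin_size`).  A leading `# dialect=... key=value ...` header (as written
#' by [write_contacts()]) declares the dialect and geometry; explicit
#' arguments override the header.  Duplicate pairs are summed, pairs are
#' symmetrised to the upper triangle, and pairs beyond `max_distance` are
#' dropped.
#'
#' @param path File path.
#' @param bin_size Bin size in bp (required for the bp dialect).
#' @param chrom Chromosome label.
#' @param max_distance Maximum genomic distance retained, in bp (converted
#'   to bins); `NULL` keeps everything.
#' @param n_bins Number of bins; inferred from the header or the largest
#'   coordinate if omitted.
#' @param dialect `"auto"` (use header, fall back to `"bin"`), `"bin"`, or
#'   `"bp"`.
#' @return A [contact_map()].
#' @export
read_contacts <- function(path, bin_size = NULL, chrom = NULL,
                          max_distance = NULL, n_bins = NULL,
                          dialect = c("auto", "bin", "bp")) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  hdr <- if (length(first)) parse_header(first) else NULL
  if (dialect == "auto") dialect <- hdr$dialect %||% "bin"
  bin_size <- bin_size %||% as.integer(hdr$bin_size %||% 1L)
  chrom <- chrom %||% (hdr$chrom %||% "chr1")
  n_data <- length(readLines(path)) - if (is.null(hdr)) 0L else 1L
  dt <- if (n_data <= 0L) {
    data.table::data.table(ci = numeric(), cj = numeric(),
                           count = numeric())
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      col.names = c("ci", "cj", "count"),
                      skip = if (is.null(hdr)) 0L else 1L,
                      colClasses = list(numeric = 1:3))
  }
  if (nrow(dt) && any(dt$count < 0)) {
    stop("negative count at data row ", which(dt$count < 0)[1L])
  }
  if (dialect == "bp") {
    bad <- which(dt$ci %% bin_size != 0 | dt$cj %% bin_size != 0)
    if (length(bad)) {
      stop("bp coordinates not multiples of bin_size at data row ", bad[1L])
    }
    dt$ci <- dt$ci %/% bin_size
    dt$cj <- dt$cj %/% bin_size
  }
  n_bins <- as.integer(n_bins %||% (hdr$n_bins %||%
    (if (nrow(dt)) max(dt$ci, dt$cj) + 1 else 1)))
  band <- if (is.null(max_distance)) {
    as.integer(hdr$max_distance_bins %||% (n_bins - 1L))
  } else {
    as.integer(max_distance %/% bin_size)
  }
  contact_map(
    data.table::data.table(i = as.integer(dt$ci), j = as.integer(dt$cj),
                           count = dt$count),
    n_bins = n_bins, bin_size = bin_size, chrom = chrom,
    max_distance_bins = band
  )
}

#' Write a contact map or frequency matrix as TSV triples
#'
#' Upper triangle only, rows sorted by `(i, j)`, preceded by a `#` header
#' recording the geometry, so output is byte-identical across runs and
#' round-trips through [read_contacts()] / [read_freq_matrix()].
#'
#' @param m A `contact_map` or `freq_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path) {
  val_col <- if (inherits(m, "contact_map")) "count" else "value"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_header(m, val_col), con)
  if (nrow(m$entries)) {
    writeLines(sprintf("%d\t%d\t%.17g", m$entries$i, m$entries$j,
                       m$entries[[val_col]]), con)
  }
  invisible(path)
}

#' Read a frequency matrix written by [write_contacts()]
#'
#' @inheritParams read_contacts
#' @return A [freq_matrix()].
#' @export
read_freq_matrix <- function(path, n_bins = NULL, max_distance = NULL) {
  first <- readLines(path, n = 1L)
  hdr <- parse_header(first)
  n_data <- length(readLines(path)) - if (is.null(hdr)) 0L else 1L
  dt <- if (n_data <= 0L) {
    data.table::data.table(i = integer(), j = integer(), value = numeric())
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      col.names = c("i", "j", "value"),
                      skip = if (is.null(hdr)) 0L else 1L)
  }
  n_bins <- as.integer(n_bins %||% (hdr$n_bins %||% (max(dt$i, dt$j) + 1)))
  bin_size <- as.integer(hdr$bin_size %||% 1L)
  band <- if (is.null(max_distance)) {
    as.integer(hdr$max_distance_bins %||% (n_bins - 1L))
  } else {
    as.integer(max_distance %/% bin_size)
  }
  freq_matrix(dt, n_bins = n_bins, bin_size = bin_size,
              chrom = hdr$chrom %||% "chr1", max_distance_bins = band)
}

#' Read a per-bin bias vector
#'
#' Accepts either one value per line (length must equal `n_bins`) or
#' two-column `(bin, value)` TSV with 0-based bin indices (missing bins are
#' masked).  Non-positive or missing values are masked.
#'
#' @param path File path.
#' @param n_bins Expected number of bins.
#' @return A [bias_vector()].
#' @export
read_bias <- function(path, n_bins) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) == 1L) {
    if (nrow(dt) != n_bins) {
      stop("bias length ", nrow(dt), " does not match n_bins ", n_bins)
    }
    values <- as.numeric(dt[[1L]])
  } else {
    bins <- as.integer(dt[[1L]])
    if (any(bins < 0 | bins >= n_bins)) stop("bias bin index out of range")
    values <- rep(NA_real_, n_bins)
    values[bins + 1L] <- as.numeric(dt[[2L]])
  }
  values[!is.finite(values) | values <= 0] <- NA_real_
  bias_vector(values)
}

#' Write a bias vector as `(bin, value)` TSV
#'
#' Masked bins are written with value `NA`; values round-trip through
#' [read_bias()] to better than 1e-12.
#'
#' @param b A [bias_vector()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias <- function(b, path) {
  writeLines(sprintf("%d\t%.17g", seq_along(b$values) - 1L, b$values), path)
  invisible(path)
}
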