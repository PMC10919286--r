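#' Export a posterior sample set as a text container
#'
#' Writes a directory holding a JSON manifest (geometry, configuration,
#' seeds, burn-in and acceptance bookkeeping), the pixel coordinate table,
#' the summary matrices, and one TSV per posterior draw
#' (`sample_0001.tsv`, ...) in the triple format understood by
#' [read_contacts()], so each draw can be fed unchanged to downstream
#' contact-map tools.
#'
#' @param ps A `posterior_samples` object.
#' @param dir Output directory (created if needed).
#' @param summaries_only Skip the per-draw files.
#' @return `dir`, invisibly.
#' @export
export_samples <- function(ps, dir, summaries_only = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_draws <- if (is.null(ps$draws)) 0L else ncol(ps$draws)
  manifest <- list(
    n_bins = ps$n_bins, band = ps$band, bin_size = ps$bin_size,
    chrom = ps$chrom, n_samples = n_draws,
    mixed = ps$mixed, burn_in_sweeps = ps$burn_in_sweeps,
    accept_rate = ps$accept_rate, variant = ps$variant,
    config = ps$config[setdiff(names(ps$config), character())]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  data.table::fwrite(ps$pixels, file.path(dir, "pixels.tsv"), sep = "\t")
  if (!is.null(ps$mean)) {
    smry <- data.table::data.table(
      i = ps$pixels$i, j = ps$pixels$j, mean = ps$mean,
      variance = ps$variance, dispersion = ps$dispersion
    )
    data.table::fwrite(smry, file.path(dir, "summaries.tsv"), sep = "\t")
  }
  if (!summaries_only && n_draws > 0L) {
    for (s in seq_len(n_draws)) {
      write_contacts(as_freq_matrix(ps, "draw", index = s),
                     file.path(dir, sprintf("sample_%04d.tsv", s)))
    }
  }
  invisible(dir)
}

#' Re-import a posterior sample container
#'
#' Rebuilds a `posterior_samples` object (draws, pixels, summaries,
#' provenance) from a directory written by [export_samples()].
#'
#' @param dir Container directory.
#' @return A `posterior_samples` object.
#' @export
read_samples <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pixels <- data.table::fread(file.path(dir, "pixels.tsv"))
  files <- sort(list.files(dir, pattern = "^sample_\\d+\\.tsv$",
                           full.names = TRUE))
  draws <- NULL
  if (length(files)) {
    draws <- matrix(NA_real_, nrow = nrow(pixels), ncol = length(files))
    for (s in seq_along(files)) {
      fm <- read_freq_matrix(files[s])
      draws[, s] <- map_value(fm, pixels$i, pixels$j)
    }
  }
  ps <- structure(
    list(draws = draws, pixels = pixels,
         n_bins = as.integer(manifest$n_bins),
         band = as.integer(manifest$band),
         bin_size = as.integer(manifest$bin_size), chrom = manifest$chrom,
         mean = NULL, variance = NULL, dispersion = NULL,
         mixed = manifest$mixed,
         burn_in_sweeps = manifest$burn_in_sweeps,
         accept_rate = manifest$accept_rate,
         mixing_history = NULL, burn_in_draws = NULL,
         config = manifest$config, variant = manifest$variant, g = NULL),
    class = "posterior_samples"
  )
  smry_path <- file.path(dir, "summaries.tsv")
  if (file.exists(smry_path)) {
    smry <- data.table::fread(smry_path)
    ps$mean <- smry$mean
    ps$variance <- smry$variance
    ps$dispersion <- smry$dispersion
  }
  ps
}
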