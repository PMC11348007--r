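#' Write and read tabular results as TSV
#'
#' Plain tab-separated round-trip for trial tables, long spectra tables,
#' exponent tables, ANOVA tables, and cluster summaries. Numeric columns are
#' written with full precision (`format = "%.17g"` via `format()` is avoided;
#' values are written as R prints them with 17 significant digits) so tables
#' round-trip bit-identically.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `write_tsv_table()` returns `path` invisibly; `read_tsv_table()`
#'   returns a tibble.
#' @export
write_tsv_table <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.numeric(x[[col]]) && !is.integer(x[[col]])) {
      x[[col]] <- sprintf("%.17g", x[[col]])
    }
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE))
}

#' Serialize per-cell spectral fits
#'
#' One row per fit: index columns, aperiodic parameters, fit quality, then
#' the peak triplets flattened into a single `peaks` column
#' (`center:amplitude:bandwidth` separated by `;`).
#'
#' @param fits A [fit_spectra()] result.
#' @param path Output TSV path.
#' @export
write_fits <- function(fits, path) {
  flat <- fits
  flat$peaks <- purrr::map_chr(fits$peaks, function(pk) {
    if (nrow(pk) == 0) return("")
    paste(sprintf("%.17g:%.17g:%.17g", pk$center, pk$amplitude, pk$bandwidth),
          collapse = ";")
  })
  write_tsv_table(flat, path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  flat <- read_tsv_table(path)
  flat$peaks[is.na(flat$peaks)] <- ""
  flat$peaks <- purrr::map(flat$peaks, function(s) {
    if (identical(s, "")) {
      return(tibble(center = numeric(), amplitude = numeric(),
                    bandwidth = numeric()))
    }
    trip <- do.call(rbind, lapply(strsplit(strsplit(s, ";")[[1]], ":"),
                                  as.numeric))
    tibble(center = trip[, 1], amplitude = trip[, 2], bandwidth = trip[, 3])
  })
  flat
}

#' Write an epoch set to a directory
#'
#' Layout: `data.bin` (little-endian doubles, trial-major order
#' trials x electrodes x samples), `meta.json` (dimensions, sampling rate,
#' window, electrode names), and `trials.tsv` (the per-trial metadata).
#'
#' @param epochs An `epoch_set`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(
    dim = dim(epochs$data), srate = epochs$srate,
    window_label = epochs$window_label, t0_offset_ms = epochs$t0_offset_ms,
    electrodes = epochs$electrodes
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(epochs$metadata)) {
    write_tsv_table(epochs$metadata, file.path(dir, "trials.tsv"))
  }
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  con <- file(file.path(dir, "data.bin"), "rb")
  vals <- readBin(con, "double", n = prod(meta$dim), size = 8,
                  endian = "little")
  close(con)
  trials_path <- file.path(dir, "trials.tsv")
  structure(
    list(
      data = array(vals, dim = meta$dim),
      srate = meta$srate,
      window_label = meta$window_label,
      t0_offset_ms = meta$t0_offset_ms,
      electrodes = meta$electrodes,
      metadata = if (file.exists(trials_path)) read_tsv_table(trials_path) else NULL
    ),
    class = "epoch_set"
  )
}
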