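#' Read and write localization tables
#'
#' Localization clouds are exchanged as comma-delimited text with the header
#' `focus_id, x_nm, y_nm, z_nm, locprec_nm, locprec_z_nm, channel`.
#'
#' @param path File path.
#' @param cloud Localization table to write.
#' @return `read_localizations()` returns a tibble; `write_localizations()`
#'   returns `path` invisibly.
#' @export
read_localizations <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("focus_id", "x_nm", "y_nm", "z_nm", "locprec_nm", "locprec_z_nm")
  missing <- setdiff(req, names(out))
  if (length(missing)) {
    stop("localization table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_localizations
#' @export
write_localizations <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE)
  invisible(path)
}

#' Read and write genotype tables
#'
#' Genotype cohorts are comma-delimited text with columns `progeny_id` and
#' one column per marker with values `B`, `H`, or `NA` (missing).
#'
#' @param path File path.
#' @param cohort Genotype table to write.
#' @return A tibble, or `path` invisibly.
#' @export
read_genotypes <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                   na.strings = c("NA", "")))
  if (!"progeny_id" %in% names(out)) {
    stop("genotype table must have a progeny_id column", call. = FALSE)
  }
  out
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read and write spot tables
#'
#' Spot tables are comma-delimited text with columns `spot_id`, `x_nm`,
#' `y_nm`, `sigma_x_fit_nm`, `sigma_y_fit_nm`, `amplitude` (and optionally
#' `offset`); anchor tables need only `x_nm`, `y_nm`.
#'
#' @param path File path.
#' @param spots Spot table to write.
#' @return A tibble, or `path` invisibly.
#' @export
read_spots <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_spots
#' @export
write_spots <- function(spots, path) {
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE)
  invisible(path)
}

#' Read and write single-plane TIFF images
#'
#' Images are stored as 32-bit float single-plane TIFF. The TIFF writer
#' stores samples in `[0, 1]`, so intensities are divided by `scale` on
#' write and multiplied back on read; the default accommodates 16-bit ADU
#' ranges.
#'
#' @param path File path.
#' @param image Numeric matrix (rows = y).
#' @param scale Divisor applied before writing and re-applied after
#'   reading.
#' @return A numeric matrix, or `path` invisibly.
#' @export
read_image_tiff <- function(path, scale = 65535) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * scale
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path, scale = 65535) {
  tiff::writeTIFF(image / scale, path, bits.per.sample = 32L)
  invisible(path)
}
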