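# TIFF and table I/O for fields, label maps and run configuration.

#' Write a two-channel field as a multi-page TIFF
#'
#' Channel order is fixed: page 1 = DNA stain, page 2 = GFP receptor.
#' Intensities are stored at the acquisition bit depth.
#'
#' @param field A `field_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  bit <- field$meta$acq$bit_depth %||% 16L
  scale <- 2^bit - 1
  pages <- list(field$dna / scale, field$gfp / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = if (bit == 12) 16L else bit)
  invisible(path)
}

#' Read a two-channel field TIFF
#' @param path Path written by [write_field_tiff()].
#' @param bit_depth Bit depth used when writing.
#' @return List with `dna` and `gfp` matrices on the original scale.
#' @export
read_field_tiff <- function(path, bit_depth = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- 2^bit_depth - 1
  list(dna = pages[[1]] * scale, gfp = pages[[2]] * scale)
}

#' Write / read an integer label map as TIFF
#'
#' Labels are stored as 16-bit samples (supports up to 65535 objects).
#' @param labels Integer matrix.
#' @param path File path.
#' @return `read_labels_tiff` returns the integer label matrix.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop_ts("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Load a run configuration from YAML
#'
#' Builds the typed parameter objects of every stage from a flat YAML
#' file; omitted sections fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list with elements `acq`, `cells`, `transloc`,
#'   `noise`, `seg`, `qc`, `alpha`, `sided`, `seed`, `n_cells`,
#'   `min_cells_per_well`, and any layout parameters under `plate`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_run_config(y)
}

#' @rdname read_run_config
#' @param config A named list with the same structure as the YAML file.
#' @export
as_run_config <- function(config) {
  build <- function(fn, args) do.call(fn, args %||% list())
  structure(list(
    acq = build(acquisition_spec, config$acquisition),
    cells = build(cell_model, config$cell_model),
    transloc = build(translocation_model, config$translocation),
    noise = build(noise_model, config$noise),
    seg = build(segmentation_params, config$segmentation),
    qc = build(qc_policy, config$qc),
    plate = config$plate %||% list(rows = 8L, cols = 12L, n_samples = 12L,
                                   n_replicates = 4L),
    active_samples = unlist(config$active_samples),
    alpha = config$alpha %||% 0.05,
    sided = config$sided %||% "two_sided",
    n_cells = config$n_cells %||% 50L,
    min_cells_per_well = config$min_cells_per_well %||% 10L,
    seed = config$seed %||% 1L
  ), class = "run_config")
}
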