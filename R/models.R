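# Parameter objects for the synthetic screen generator.
#
# Defaults emulate the acquisition and plate design of an automated
# confocal translocation screen: 300 nm pixels (2x2 binned camera),
# 16-bit images, ~50 adherent cells per 512x512 field, 2 fields per well,
# 4 replicate wells per condition.

#' Acquisition settings for simulated fields
#'
#' @param field_width_px,field_height_px Field size in pixels (>= 128).
#' @param pixel_size_nm Physical pixel size in nanometres (default 300,
#'   matching a 2x2-binned high-NA confocal screening system).
#' @param bit_depth Camera bit depth; one of 8, 12, 16.
#' @param fields_per_well Number of fields imaged per well.
#' @return An `acquisition_spec` list.
#' @export
acquisition_spec <- function(field_width_px = 512L, field_height_px = 512L,
                             pixel_size_nm = 300, bit_depth = 16L,
                             fields_per_well = 2L) {
  if (field_width_px < 128 || field_height_px < 128) {
    stop_ts("field dimensions must be >= 128 px")
  }
  if (pixel_size_nm <= 0) stop_ts("pixel_size_nm must be positive")
  if (!bit_depth %in% c(8L, 12L, 16L)) stop_ts("bit_depth must be 8, 12 or 16")
  if (fields_per_well < 1) stop_ts("fields_per_well must be >= 1")
  structure(list(field_width_px = as.integer(field_width_px),
                 field_height_px = as.integer(field_height_px),
                 pixel_size_nm = pixel_size_nm,
                 bit_depth = as.integer(bit_depth),
                 fields_per_well = as.integer(fields_per_well)),
            class = "acquisition_spec")
}

#' Geometry and brightness model for simulated cells
#'
#' Cells are rendered as irregular ellipse-like nuclei strictly contained
#' in larger cell footprints; total GFP per cell is partitioned between the
#' compartments by the translocation model.
#'
#' @param nucleus_radius_px,nucleus_radius_sd Nuclear radius mean/sd (px).
#' @param cell_radius_px,cell_radius_sd Whole-cell radius mean/sd (px);
#'   the mean must exceed the nuclear mean.
#' @param total_gfp,total_gfp_sd Integrated GFP per cell (arbitrary units).
#' @param dna_intensity,dna_intensity_sd Per-pixel DNA-stain intensity in
#'   the nucleus (arbitrary units).
#' @param shape_irregularity Low-order radial perturbation amplitude in
#'   \[0, 1); 0 gives circles.
#' @return A `cell_model` list.
#' @export
cell_model <- function(nucleus_radius_px = 9, nucleus_radius_sd = 0.8,
                       cell_radius_px = 16, cell_radius_sd = 1.2,
                       total_gfp = 2.4e5, total_gfp_sd = 2.4e4,
                       dna_intensity = 120, dna_intensity_sd = 12,
                       shape_irregularity = 0.08) {
  if (min(nucleus_radius_px, cell_radius_px, total_gfp, dna_intensity) <= 0) {
    stop_ts("all model means must be positive")
  }
  if (cell_radius_px <= nucleus_radius_px) {
    stop_ts("cell_radius_px must exceed nucleus_radius_px")
  }
  if (shape_irregularity < 0 || shape_irregularity >= 1) {
    stop_ts("shape_irregularity must lie in [0, 1)")
  }
  structure(list(nucleus_radius_px = nucleus_radius_px,
                 nucleus_radius_sd = nucleus_radius_sd,
                 cell_radius_px = cell_radius_px,
                 cell_radius_sd = cell_radius_sd,
                 total_gfp = total_gfp, total_gfp_sd = total_gfp_sd,
                 dna_intensity = dna_intensity,
                 dna_intensity_sd = dna_intensity_sd,
                 shape_irregularity = shape_irregularity),
            class = "cell_model")
}

#' Hill-type dose dependence of the nuclear fraction
#'
#' The fraction of a cell's receptor pool residing in the nucleus follows a
#' saturating Hill curve in the effective dose:
#' `f(d) = f_min + (f_max - f_min) * d^h / (ec50^h + d^h)`.
#'
#' @param f_min Nuclear fraction at zero dose (unliganded receptor).
#' @param f_max Nuclear fraction at saturation; must exceed `f_min`.
#' @param ec50 Dose of half-maximal translocation (same units as treatment
#'   doses, e.g. concentration multipliers of the original water sample).
#' @param hill Cooperativity exponent (> 0).
#' @return A `translocation_model` list.
#' @export
translocation_model <- function(f_min = 0.25, f_max = 0.9, ec50 = 10,
                                hill = 1.5) {
  if (f_min < 0 || f_min > 1 || f_max < 0 || f_max > 1 || f_max <= f_min) {
    stop_ts("need 0 <= f_min < f_max <= 1")
  }
  if (ec50 <= 0 || hill <= 0) stop_ts("ec50 and hill must be positive")
  structure(list(f_min = f_min, f_max = f_max, ec50 = ec50, hill = hill),
            class = "translocation_model")
}

#' Evaluate the nuclear fraction at a dose
#'
#' @param dose Non-negative dose (vectorized). `Inf` returns `f_max`.
#' @param model A [translocation_model()].
#' @return Nuclear fraction(s) in \[f_min, f_max\].
#' @export
hill_fraction <- function(dose, model) {
  if (any(dose < 0)) stop_ts("dose must be non-negative")
  occ <- ifelse(is.infinite(dose), 1,
                dose^model$hill / (model$ec50^model$hill + dose^model$hill))
  occ[dose == 0] <- 0
  model$f_min + (model$f_max - model$f_min) * occ
}

#' Detector and optics noise model
#'
#' Each component can be switched off independently, giving a ladder from
#' analytically exact renderings to realistic noisy images: Gaussian PSF
#' blur, Poisson shot noise on expected counts, additive background and
#' Gaussian read noise.
#'
#' @param background_level Additive intensity offset (>= 0).
#' @param read_noise_sd Gaussian read noise sd (>= 0).
#' @param shot_noise Poisson-resample expected signal?
#' @param psf_sigma_px Gaussian PSF sigma in pixels (0 disables blur).
#' @return A `noise_model` list.
#' @export
noise_model <- function(background_level = 10, read_noise_sd = 2,
                        shot_noise = TRUE, psf_sigma_px = 1) {
  if (background_level < 0 || read_noise_sd < 0 || psf_sigma_px < 0) {
    stop_ts("noise parameters must be non-negative")
  }
  structure(list(background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 psf_sigma_px = psf_sigma_px),
            class = "noise_model")
}

#' Noise-free rendering settings
#'
#' Convenience constructor for the analytic end of the noise ladder.
#' @return A `noise_model` with all components disabled.
#' @export
noise_free <- function() {
  noise_model(background_level = 0, read_noise_sd = 0, shot_noise = FALSE,
              psf_sigma_px = 0)
}
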