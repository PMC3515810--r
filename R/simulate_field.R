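# Rendering of synthetic two-channel translocation fields with per-cell
# ground truth. Cells are irregular ellipse-like nuclei nested in larger
# cell footprints; footprints never overlap, so the rendered label maps are
# an unambiguous segmentation reference.

# Radial perturbation coefficients for one ellipse-like outline.
# Low-order Fourier terms scaled so |r(theta) - r0| <= irregularity * r0.
random_shape_coefs <- function(irregularity) {
  co <- stats::runif(4, -1, 1)
  s <- sum(abs(co))
  if (s > 0) co <- co / s
  co * irregularity
}

shape_radius <- function(theta, r0, coefs) {
  r0 * (1 + coefs[1] * cos(theta) + coefs[2] * sin(theta) +
          coefs[3] * cos(2 * theta) + coefs[4] * sin(2 * theta))
}

# Rasterize one outline into (row, col) pixel indices within the field.
rasterize_shape <- function(cx, cy, r0, coefs, nrow_px, ncol_px) {
  rmax <- r0 * (1 + sum(abs(coefs)))
  lo_r <- max(1L, floor(cy - rmax)); hi_r <- min(nrow_px, ceiling(cy + rmax))
  lo_c <- max(1L, floor(cx - rmax)); hi_c <- min(ncol_px, ceiling(cx + rmax))
  rr <- seq(lo_r, hi_r); cc <- seq(lo_c, hi_c)
  dy <- rep(rr - cy, times = length(cc))
  dx <- rep(cc - cx, each = length(rr))
  dist <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  inside <- dist <= shape_radius(theta, r0, coefs)
  cbind(row = rep(rr, times = length(cc))[inside],
        col = rep(cc, each = length(rr))[inside])
}

#' Simulate one two-channel field with ground truth
#'
#' Renders `n_cells` non-overlapping cells, partitions each cell's total
#' GFP between nucleus and cytoplasm according to the translocation model
#' evaluated at `dose`, then applies PSF blur, background, shot noise and
#' read noise as configured.
#'
#' @param dose Effective dose driving translocation (0 for vehicle wells).
#' @param acq An [acquisition_spec()].
#' @param cells A [cell_model()].
#' @param transloc A [translocation_model()].
#' @param noise A [noise_model()] (use [noise_free()] for exact renderings).
#' @param n_cells Target number of cells in the field (>= 1).
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @param well_id,field_id Metadata carried into the output.
#' @param jitter_n_cells If `TRUE`, draw the realized count from a Poisson
#'   distribution with mean `n_cells` (min 1); if `FALSE`, render exactly
#'   `n_cells`.
#' @param max_attempts Rejection-sampling budget for cell placement.
#' @return A list with `image` (a `field_image`: matrices `dna`, `gfp`,
#'   plus `meta`) and `truth` (a `ground_truth`: `nucleus_label_map`,
#'   `cell_label_map`, per-cell data.frame `cells`).
#' @export
simulate_field <- function(dose, acq = acquisition_spec(),
                           cells = cell_model(),
                           transloc = translocation_model(),
                           noise = noise_model(), n_cells = 50L,
                           seed = 1L, well_id = NA_character_,
                           field_id = 1L, jitter_n_cells = TRUE,
                           max_attempts = NULL) {
  if (n_cells < 1) stop_ts("n_cells must be >= 1")
  with_seed(seed, {
    h <- acq$field_height_px; w <- acq$field_width_px
    n <- if (jitter_n_cells) {
      # cap tail draws at the field's approximate random sequential
      # packing capacity so realized counts stay placeable
      r_out <- (cells$cell_radius_px + 2 * cells$cell_radius_sd) *
        (1 + cells$shape_irregularity)
      marg <- ceiling(r_out) + 1
      cap <- max(1L, floor(0.54 * (w - 2 * marg) * (h - 2 * marg) /
                             (pi * (r_out + 0.5)^2)))
      min(max(1L, stats::rpois(1, n_cells)), cap)
    } else as.integer(n_cells)
    max_attempts <- max_attempts %||% (500L * n)

    # Draw per-cell geometry first so overlap checks can use outer radii.
    r_nuc <- pmax(2, stats::rnorm(n, cells$nucleus_radius_px,
                                  cells$nucleus_radius_sd))
    r_cell <- stats::rnorm(n, cells$cell_radius_px, cells$cell_radius_sd)
    irr <- cells$shape_irregularity
    # Containment margin: outermost nuclear radius must stay inside the
    # innermost cell radius.
    r_cell <- pmax(r_cell, (r_nuc * (1 + irr) + 2) / max(1e-6, 1 - irr))
    r_outer <- r_cell * (1 + irr)

    margin <- ceiling(max(r_outer)) + 1
    if (2 * margin >= min(h, w)) {
      stop_ts("cells too large for the field; enlarge field or shrink cells")
    }
    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L; attempts <- 0L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_ts(sprintf(
          "placed only %d of %d cells after %d attempts; reduce n_cells or enlarge the field",
          placed, n, max_attempts))
      }
      x <- stats::runif(1, margin, w - margin)
      y <- stats::runif(1, margin, h - margin)
      i <- placed + 1L
      ok <- TRUE
      if (placed > 0L) {
        d <- sqrt((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2)
        ok <- all(d > r_outer[seq_len(placed)] + r_outer[i] + 1)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; placed <- i }
    }

    dna <- matrix(0, h, w); gfp <- matrix(0, h, w)
    nuc_lab <- matrix(0L, h, w); cell_lab <- matrix(0L, h, w)
    f <- hill_fraction(dose, transloc)
    total_gfp <- pmax(1, stats::rnorm(n, cells$total_gfp, cells$total_gfp_sd))
    dna_int <- pmax(1, stats::rnorm(n, cells$dna_intensity,
                                    cells$dna_intensity_sd))
    rec <- vector("list", n)
    for (i in seq_len(n)) {
      cell_co <- random_shape_coefs(irr)
      nuc_co <- random_shape_coefs(irr)
      px_cell <- rasterize_shape(cx[i], cy[i], r_cell[i], cell_co, h, w)
      px_nuc <- rasterize_shape(cx[i], cy[i], r_nuc[i], nuc_co, h, w)
      a_n <- nrow(px_nuc); a_c <- nrow(px_cell) - a_n
      if (a_n < 1 || a_c < 1) next
      cell_lab[px_cell] <- i
      nuc_lab[px_nuc] <- i
      gfp[px_cell] <- gfp[px_cell] + (1 - f) * total_gfp[i] / a_c
      # nucleus pixels carry the nuclear share instead of the cytoplasmic one
      gfp[px_nuc] <- f * total_gfp[i] / a_n
      dna[px_nuc] <- dna_int[i]
      rec[[i]] <- data.frame(cell_id = i, cx = cx[i], cy = cy[i],
                             nucleus_area_px = a_n, cytoplasm_area_px = a_c,
                             true_nuclear_fraction = f,
                             true_nc_ratio = (f / a_n) / ((1 - f) / a_c),
                             total_gfp = total_gfp[i])
    }
    truth_cells <- do.call(rbind, rec)

    dna <- apply_noise(dna, noise, acq$bit_depth)
    gfp <- apply_noise(gfp, noise, acq$bit_depth)

    image <- structure(list(dna = dna, gfp = gfp,
                            meta = list(well_id = well_id,
                                        field_id = field_id, dose = dose,
                                        seed = seed, acq = acq)),
                       class = "field_image")
    truth <- structure(list(nucleus_label_map = nuc_lab,
                            cell_label_map = cell_lab,
                            cells = truth_cells),
                       class = "ground_truth")
    list(image = image, truth = truth)
  })
}

#' Apply the noise ladder to an expected-intensity raster
#'
#' Order of operations: Gaussian PSF blur of the expected signal, additive
#' background, Poisson shot noise on the expected counts, additive Gaussian
#' read noise, clipping to the detector range. Draws from the current RNG
#' stream.
#'
#' @param img Numeric matrix of expected intensities.
#' @param noise A [noise_model()].
#' @param bit_depth Detector bit depth used for clipping.
#' @return Numeric matrix of observed intensities.
#' @export
apply_noise <- function(img, noise, bit_depth = 16L) {
  if (noise$psf_sigma_px > 0) {
    img_e <- EBImage::gblur(EBImage::Image(img), sigma = noise$psf_sigma_px)
    img <- matrix(EBImage::imageData(img_e), nrow(img), ncol(img))
  }
  expected <- img + noise$background_level
  out <- if (noise$shot_noise) {
    matrix(stats::rpois(length(expected), pmax(0, expected)),
           nrow(expected), ncol(expected))
  } else expected
  if (noise$read_noise_sd > 0) {
    out <- out + stats::rnorm(length(out), 0, noise$read_noise_sd)
  }
  pmin(pmax(out, 0), 2^bit_depth - 1)
}

#' Simulate every occupied well of a plate
#'
#' Each well receives `fields_per_well` fields; per-field seeds are derived
#' deterministically from the master seed so reruns are bit-identical.
#' Effective dose per well is `dose * potency(treatment)`: vehicle wells
#' have potency 0, positive controls 1, and water samples 0 (inactive)
#' unless listed in `active_samples`.
#'
#' @param layout A [make_plate_layout()] result.
#' @param acq,cells,transloc,noise Model objects as in [simulate_field()].
#' @param n_cells Target cells per field.
#' @param seed Master seed.
#' @param active_samples Named numeric vector of potencies for active
#'   treatments, e.g. `c(S001 = 1)`; values multiply the well dose.
#' @param jitter_n_cells Passed to [simulate_field()].
#' @return List of per-field entries `(well_id, field_id, image, truth)`,
#'   with the layout and master seed attached as attributes.
#' @export
simulate_plate <- function(layout, acq = acquisition_spec(),
                           cells = cell_model(),
                           transloc = translocation_model(),
                           noise = noise_model(), n_cells = 50L, seed = 1L,
                           active_samples = NULL, jitter_n_cells = TRUE) {
  validate_layout(layout)
  occ <- layout[layout$treatment_class != "empty", , drop = FALSE]
  out <- vector("list", nrow(occ) * acq$fields_per_well)
  k <- 0L
  for (i in seq_len(nrow(occ))) {
    wl <- occ[i, ]
    potency <- switch(wl$treatment_class,
                      vehicle = 0, membrane_blank = 0, positive_control = 1,
                      sample = unname(active_samples[wl$treatment_label] %|na|% 0))
    eff_dose <- wl$dose * potency
    for (fld in seq_len(acq$fields_per_well)) {
      k <- k + 1L
      fs <- derive_seed(seed, i, fld)
      sim <- simulate_field(eff_dose, acq, cells, transloc, noise,
                            n_cells = n_cells, seed = fs,
                            well_id = wl$well_id, field_id = fld,
                            jitter_n_cells = jitter_n_cells)
      out[[k]] <- list(well_id = wl$well_id, field_id = fld,
                       image = sim$image, truth = sim$truth)
    }
  }
  attr(out, "layout") <- layout
  attr(out, "seed") <- seed
  out
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
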