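# Shared fixtures: small fields, hand-built label pairs, dose ladders.

fast_acq <- function(size = 512L, fields = 1L) {
  acquisition_spec(field_width_px = size, field_height_px = size,
                   fields_per_well = fields)
}

# SNR here means Poisson signal-to-noise of the dominant signal level:
# a mean intensity of snr^2 gives sqrt(snr^2) = snr.
snr_cells <- function(snr, gfp_total = NULL) {
  cell_model(dna_intensity = snr^2, dna_intensity_sd = snr^2 / 10,
             total_gfp = gfp_total %||% 2.4e5,
             total_gfp_sd = (gfp_total %||% 2.4e5) / 10)
}

shot_noise_only <- function(psf = 0.8) {
  noise_model(background_level = 0, read_noise_sd = 0, shot_noise = TRUE,
              psf_sigma_px = psf)
}

# A one-cell fixture with exactly known compartment areas and intensities:
# 10x10 nucleus (100 px) centered in a 20x20 cell (300 px cytoplasm).
square_cell_fixture <- function(f = 0.8, size = 64L) {
  nuc <- matrix(0L, size, size); cell <- matrix(0L, size, size)
  cell[21:40, 21:40] <- 1L
  nuc[26:35, 26:35] <- 1L
  gfp <- matrix(0, size, size)
  gfp[cell == 1L] <- (1 - f) / 300
  gfp[nuc == 1L] <- f / 100
  list(field = structure(list(dna = nuc * 100, gfp = gfp,
                              meta = list(well_id = "A01", field_id = 1L)),
                         class = "field_image"),
       pair = structure(list(nucleus = nuc, cell = cell),
                        class = "label_pair"),
       true_ratio = (f / 100) / ((1 - f) / 300))
}

# Plate layout for a dose ladder: one sample at several doses plus
# vehicle controls; each dose level is its own replicate group.
ladder_layout <- function(doses, n_rep = 4L, n_vehicle = 4L) {
  n <- length(doses) * n_rep + n_vehicle
  rows <- ceiling(n / 12)
  lab <- c(rep("vehicle", n_vehicle),
           rep(sprintf("dose_%02d", seq_along(doses)), each = n_rep))
  cls <- c(rep("vehicle", n_vehicle), rep("sample", length(doses) * n_rep))
  dose <- c(rep(0, n_vehicle), rep(doses, each = n_rep))
  idx <- seq_len(n)
  layout <- data.frame(
    well_id = sprintf("%s%02d", LETTERS[(idx - 1) %/% 12 + 1],
                      (idx - 1) %% 12 + 1),
    row = (idx - 1) %/% 12 + 1, col = (idx - 1) %% 12 + 1,
    treatment_label = lab, treatment_class = cls, dose = dose,
    replicate_group = lab, stringsAsFactors = FALSE)
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

# Segment + measure every field of a simulated plate, pooled per well.
measure_plate <- function(plate, seg = segmentation_params(),
                          policy = qc_policy()) {
  recs <- lapply(plate, function(e) {
    nuc <- segment_nuclei(e$image$dna, seg)
    pair <- segment_cytoplasm(e$image$gfp, nuc, seg)
    measure_cells(e$image, pair, policy = policy)
  })
  do.call(rbind, recs)
}
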