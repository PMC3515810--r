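# Well-level statistical simulator: draws per-well N/C ratio summaries
# directly from the plate design, bypassing image rendering. Used for
# large replication studies (familywise error, power) where the quantity
# under test is the plate statistics, not the imaging chain.

#' Simulate per-well N/C ratio summaries without images
#'
#' Each usable well's mean N/C ratio is drawn as
#' `baseline * (1 + effect_sd_units(treatment) * well_cv) + N(0, baseline * well_cv)`,
#' i.e. treatment effects are expressed in multiples of the well-to-well
#' standard deviation, the natural scale for power and error-rate studies.
#'
#' @param layout A [make_plate_layout()] result.
#' @param effect_sd_units Named numeric vector of standardized effect
#'   sizes per `treatment_label` (e.g. `c(S001 = 5, positive = 8)`);
#'   unlisted treatments get 0.
#' @param baseline Vehicle-level mean N/C ratio.
#' @param well_cv Well-to-well coefficient of variation of the ratio.
#' @param n_cells Nominal kept-cell count recorded per well.
#' @param seed RNG seed.
#' @return A well-summary data.frame compatible with [normalize_plate()]
#'   and [dunnett_test()].
#' @export
simulate_well_values <- function(layout, effect_sd_units = NULL,
                                 baseline = 1.6, well_cv = 0.05,
                                 n_cells = 100L, seed = 1L) {
  validate_layout(layout)
  occ <- layout[layout$treatment_class != "empty", , drop = FALSE]
  sdw <- baseline * well_cv
  with_seed(seed, {
    eff <- rep(0, nrow(occ))
    if (!is.null(effect_sd_units)) {
      m <- match(occ$treatment_label, names(effect_sd_units))
      eff[!is.na(m)] <- effect_sd_units[m[!is.na(m)]]
    }
    vals <- baseline + eff * sdw + stats::rnorm(nrow(occ), 0, sdw)
    out <- data.frame(well_id = occ$well_id,
                      n_cells_kept = as.integer(n_cells),
                      mean_nc_ratio = pmax(vals, 1e-6),
                      sd_nc_ratio = sdw,
                      row = occ$row, col = occ$col,
                      treatment_label = occ$treatment_label,
                      treatment_class = occ$treatment_class,
                      dose = occ$dose,
                      replicate_group = occ$replicate_group,
                      usable = TRUE,
                      stringsAsFactors = FALSE)
    out[order(out$row, out$col), ]
  })
}
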