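# Per-cell compartment intensities and the nuclear/cytoplasmic ratio —
# the assay's core readout — with QC flagging.

#' QC thresholds for per-cell measurements
#'
#' @param min_nucleus_area_px Cells with smaller nuclei are flagged
#'   `too_small`.
#' @param min_cyto_area_px Cells with fewer cytoplasm pixels are flagged
#'   `degenerate_cyto`.
#' @param min_mean_intensity Cells whose compartment means (after
#'   background correction) both fall below this are flagged `low_signal`.
#' @param exclude_flags Flags that disqualify a cell in [filter_cells()].
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(min_nucleus_area_px = 40L, min_cyto_area_px = 20L,
                      min_mean_intensity = 1,
                      exclude_flags = c("too_small", "border",
                                        "degenerate_cyto", "saturated",
                                        "low_signal")) {
  structure(list(min_nucleus_area_px = as.integer(min_nucleus_area_px),
                 min_cyto_area_px = as.integer(min_cyto_area_px),
                 min_mean_intensity = min_mean_intensity,
                 exclude_flags = exclude_flags),
            class = "qc_policy")
}

#' Measure per-cell compartment intensities and N/C ratios
#'
#' For every label id, computes the arithmetic mean GFP intensity over
#' nucleus and cytoplasm pixels (optionally background-corrected by the
#' median intensity outside all cells) and their ratio. Cells with no
#' usable cytoplasm are emitted with a `degenerate_cyto` flag and `NA`
#' ratio rather than raising a division error.
#'
#' @param field A `field_image` (or list with `gfp` matrix and `meta`).
#' @param labels A `label_pair` from [segment_cytoplasm()].
#' @param background Background policy: `"median"` subtracts the median
#'   GFP intensity of non-cell pixels, `"none"` subtracts nothing.
#' @param policy A [qc_policy()].
#' @param guard_px Boundary guard (pixels) excluded from the intensity
#'   means: the nuclear mean is taken over the nucleus eroded by
#'   `guard_px`, and the cytoplasmic mean over cytoplasm pixels at least
#'   `guard_px` away from both the nuclear and the outer cell boundary,
#'   so PSF-blurred cross-compartment signal does not contaminate either
#'   mean. Full compartments are used when a guarded region is too small.
#'   Areas are always reported for the full compartments.
#' @return data.frame with one row per cell: areas, compartment means,
#'   `nc_ratio`, and a comma-separated `qc_flags` string ("" if clean).
#' @export
measure_cells <- function(field, labels, background = c("median", "none"),
                          policy = qc_policy(), guard_px = 2) {
  background <- match.arg(background)
  gfp <- field$gfp
  if (!identical(dim(gfp), dim(labels$cell))) {
    stop_ts("label maps do not match field dimensions")
  }
  nuc <- labels$nucleus; cell <- labels$cell
  ids <- sort(unique(nuc[nuc > 0]))
  meta <- field$meta %||% list()
  bit_depth <- tryCatch(meta$acq$bit_depth, error = function(e) NULL)
  sat_level <- if (is.null(bit_depth)) Inf else 2^bit_depth - 1

  bg <- if (background == "median" && any(cell == 0)) {
    stats::median(gfp[cell == 0])
  } else 0

  if (!length(ids)) {
    return(data.frame(cell_id = integer(), well_id = character(),
                      field_id = integer(), nucleus_area_px = integer(),
                      cytoplasm_area_px = integer(),
                      mean_nuclear_intensity = numeric(),
                      mean_cytoplasmic_intensity = numeric(),
                      nc_ratio = numeric(), qc_flags = character(),
                      stringsAsFactors = FALSE))
  }

  cyto <- cell
  cyto[nuc > 0] <- 0L                     # cytoplasm = cell minus nucleus
  a_n <- tabulate(nuc[nuc > 0], nbins = max(ids))[ids]
  a_c <- tabulate(cyto[cyto > 0], nbins = max(ids))[ids]
  a_c[is.na(a_c)] <- 0L
  mean_over <- function(lab_map) {
    a <- tabulate(lab_map[lab_map > 0], nbins = max(ids))[ids]
    a[is.na(a)] <- 0L
    s <- rep(NA_real_, length(ids))
    if (any(lab_map > 0)) {
      sm <- rowsum(gfp[lab_map > 0], lab_map[lab_map > 0])
      s[match(rownames(sm), as.character(ids))] <- sm[, 1]
    }
    list(mean = ifelse(a > 0, s / pmax(a, 1), NA_real_), area = a)
  }
  nuc_m <- nuc; cyto_m <- cyto
  if (guard_px > 0) {
    d_out_nuc <- as_matrix(EBImage::distmap(as_ebimage(1 - (nuc > 0))))
    d_in_nuc <- as_matrix(EBImage::distmap(as_ebimage((nuc > 0) * 1)))
    d_in_cell <- as_matrix(EBImage::distmap(as_ebimage((cell > 0) * 1)))
    nuc_m[d_in_nuc <= guard_px] <- 0L
    cyto_m[d_out_nuc <= guard_px | d_in_cell <= guard_px] <- 0L
  }
  min_guard_area <- pmax(5L, policy$min_cyto_area_px %/% 2L)
  mn_guard <- mean_over(nuc_m); mn_full <- mean_over(nuc)
  mc_guard <- mean_over(cyto_m); mc_full <- mean_over(cyto)
  mean_n <- ifelse(mn_guard$area >= min_guard_area,
                   mn_guard$mean, mn_full$mean) - bg
  mean_c <- ifelse(mc_guard$area >= min_guard_area,
                   mc_guard$mean, mc_full$mean) - bg
  mean_c[a_c == 0] <- NA_real_

  # border contact of the cell footprint
  edge_ids <- unique(c(cell[1, ], cell[nrow(cell), ],
                       cell[, 1], cell[, ncol(cell)]))
  # saturated GFP pixels anywhere in the cell
  sat_ids <- if (is.finite(sat_level) && any(gfp >= sat_level)) {
    unique(cell[cell > 0 & gfp >= sat_level])
  } else integer()

  flags <- vapply(seq_along(ids), function(j) {
    fl <- character()
    if (a_n[j] < policy$min_nucleus_area_px) fl <- c(fl, "too_small")
    if (ids[j] %in% edge_ids) fl <- c(fl, "border")
    if (a_c[j] < policy$min_cyto_area_px ||
        is.na(mean_c[j]) || mean_c[j] <= 0) fl <- c(fl, "degenerate_cyto")
    if (ids[j] %in% sat_ids) fl <- c(fl, "saturated")
    if (!is.na(mean_c[j]) && mean_n[j] < policy$min_mean_intensity &&
        mean_c[j] < policy$min_mean_intensity) fl <- c(fl, "low_signal")
    paste(fl, collapse = ",")
  }, character(1))

  nc <- ifelse(!is.na(mean_c) & mean_c > 0 & mean_n > 0,
               mean_n / mean_c, NA_real_)

  data.frame(cell_id = ids,
             well_id = meta$well_id %||% NA_character_,
             field_id = meta$field_id %||% NA_integer_,
             nucleus_area_px = a_n, cytoplasm_area_px = a_c,
             mean_nuclear_intensity = mean_n,
             mean_cytoplasmic_intensity = mean_c,
             nc_ratio = nc, qc_flags = flags,
             stringsAsFactors = FALSE)
}

#' Remove QC-flagged cells
#'
#' @param records data.frame from [measure_cells()] (rows from several
#'   fields may be concatenated).
#' @param policy A [qc_policy()]; its `exclude_flags` decide which flags
#'   disqualify a cell.
#' @return List with `kept` (clean records), `rejected`, and `tally`
#'   (named counts per rejection reason; a cell may count under several).
#' @export
filter_cells <- function(records, policy = qc_policy()) {
  if (!nrow(records)) {
    return(list(kept = records, rejected = records,
                tally = stats::setNames(integer(0), character(0))))
  }
  flag_list <- strsplit(records$qc_flags, ",", fixed = TRUE)
  bad <- vapply(flag_list, function(fl) any(fl %in% policy$exclude_flags),
                logical(1))
  bad <- bad | is.na(records$nc_ratio)
  tally <- table(unlist(lapply(flag_list[bad], intersect,
                               y = policy$exclude_flags)))
  list(kept = records[!bad, , drop = FALSE],
       rejected = records[bad, , drop = FALSE],
       tally = stats::setNames(as.integer(tally), names(tally)))
}
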