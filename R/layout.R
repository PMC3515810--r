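# Plate-layout construction and I/O.

#' Build a randomized screening plate layout
#'
#' Reproduces the design of an environmental-water screen: >= 4 vehicle
#' (DMSO) wells, >= 4 positive-control hormone wells at 100 nM, and
#' `n_replicates` wells for each of `n_samples` water samples, placed at
#' random over the remaining wells. Unused wells stay empty.
#'
#' @param rows,cols Plate geometry (8 x 12 for a 96-well plate).
#' @param n_samples Number of water samples on the plate.
#' @param n_replicates Replicate wells per sample (and per control group).
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param sample_dose Dose assigned to sample wells (concentration
#'   multiplier of the original water volume; the screen used 100x).
#' @param positive_dose Dose assigned to positive-control wells (the assay
#'   uses 100 nM hormone; represented on the same effective-dose axis).
#' @param n_vehicle,n_positive Number of control wells (each >= 4).
#' @return A `plate_layout` data.frame with columns `well_id`, `row`,
#'   `col`, `treatment_label`, `treatment_class`, `dose`,
#'   `replicate_group`.
#' @export
make_plate_layout <- function(rows = 8L, cols = 12L, n_samples,
                              n_replicates = 4L, seed = 1L,
                              sample_dose = 100, positive_dose = 100,
                              n_vehicle = 4L, n_positive = 4L) {
  if (n_vehicle < 4L || n_positive < 4L) {
    stop_ts("layouts require at least 4 vehicle and 4 positive-control wells")
  }
  needed <- n_samples * n_replicates + n_vehicle + n_positive
  avail <- rows * cols
  if (needed > avail) {
    stop_ts(sprintf(
      "plate capacity exceeded: need %d wells (%d samples x %d replicates + %d controls) but only %d available",
      needed, n_samples, n_replicates, n_vehicle + n_positive, avail))
  }
  well_ids <- as.vector(t(outer(LETTERS[seq_len(rows)],
                                sprintf("%02d", seq_len(cols)), paste0)))
  grid <- data.frame(well_id = well_ids,
                     row = rep(seq_len(rows), each = cols),
                     col = rep(seq_len(cols), times = rows),
                     stringsAsFactors = FALSE)
  labels <- c(rep("vehicle", n_vehicle), rep("positive", n_positive),
              rep(sprintf("S%03d", seq_len(n_samples)), each = n_replicates))
  classes <- c(rep("vehicle", n_vehicle),
               rep("positive_control", n_positive),
               rep("sample", n_samples * n_replicates))
  doses <- c(rep(0, n_vehicle), rep(positive_dose, n_positive),
             rep(sample_dose, n_samples * n_replicates))
  slots <- with_seed(seed, sample.int(avail, needed))
  layout <- grid
  layout$treatment_label <- NA_character_
  layout$treatment_class <- "empty"
  layout$dose <- NA_real_
  layout$treatment_label[slots] <- labels
  layout$treatment_class[slots] <- classes
  layout$dose[slots] <- doses
  layout$replicate_group <- layout$treatment_label
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Validate a plate layout
#' @param layout A `plate_layout` data.frame.
#' @return The layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  req <- c("well_id", "row", "col", "treatment_label", "treatment_class",
           "dose", "replicate_group")
  missing <- setdiff(req, names(layout))
  if (length(missing)) {
    stop_ts("layout is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(layout$well_id)) stop_ts("well_ids must be unique")
  if (anyDuplicated(layout[c("row", "col")])) {
    stop_ts("duplicate row/col coordinates in layout")
  }
  occ <- layout[layout$treatment_class != "empty", ]
  if (sum(occ$treatment_class == "vehicle") < 4) {
    stop_ts("layout must contain >= 4 vehicle wells")
  }
  counts <- table(occ$replicate_group[occ$treatment_class == "sample"])
  if (length(counts) && length(unique(as.integer(counts))) > 1) {
    stop_ts("unbalanced design: sample replicate groups differ in size")
  }
  invisible(layout)
}

#' Read / write plate layouts as CSV
#' @param layout A `plate_layout`.
#' @param path File path.
#' @return `read_layout_csv` returns a `plate_layout`.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE)
  layout$treatment_label <- as.character(layout$treatment_label)
  class(layout) <- c("plate_layout", "data.frame")
  validate_layout(layout)
  layout
}
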