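# End-to-end orchestration: simulate -> segment -> quantify -> screen,
# with all artifacts written to disk and a checksum manifest linking every
# output to the configuration and master seed.

#' Run the full image-based screening pipeline
#'
#' Simulates a plate from the configuration (or consumes a pre-simulated
#' plate), segments every field, measures and QC-filters cells,
#' aggregates wells, normalizes to vehicle, and calls hits via the
#' ANOVA-gated Dunnett comparison. All tables, the heat-map and a
#' manifest with MD5 checksums are written under `out_dir`.
#'
#' @param config A `run_config` (see [read_run_config()] /
#'   [as_run_config()]) or a path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param plate Optional pre-simulated plate from [simulate_plate()];
#'   when `NULL`, the plate is simulated from the config.
#' @param write_images Write per-field TIFFs and label maps? (Off by
#'   default: the tables are the analysis product.)
#' @return List with `layout`, `cells`, `well_summaries`, `hit_table`,
#'   `heatmap`, `manifest_path`.
#' @export
run_screen_pipeline <- function(config, out_dir, plate = NULL,
                                write_images = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_ts("config file not found: ", config)
    }
    config <- read_run_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  layout <- do.call(make_plate_layout,
                    c(config$plate, list(seed = config$seed)))
  if (is.null(plate)) {
    plate <- simulate_plate(layout, config$acq, config$cells,
                            config$transloc, config$noise,
                            n_cells = config$n_cells, seed = config$seed,
                            active_samples = config$active_samples)
  } else {
    layout <- attr(plate, "layout") %||% layout
  }

  cells <- vector("list", length(plate))
  for (i in seq_along(plate)) {
    entry <- plate[[i]]
    nuc <- tryCatch(segment_nuclei(entry$image$dna, config$seg),
                    error = function(e) stop_ts(
                      sprintf("stage segment failed on well %s field %d: %s",
                              entry$well_id, entry$field_id,
                              conditionMessage(e))))
    pair <- segment_cytoplasm(entry$image$gfp, nuc, config$seg)
    cells[[i]] <- measure_cells(entry$image, pair, policy = config$qc)
    if (write_images) {
      base <- file.path(out_dir, sprintf("%s_f%d", entry$well_id,
                                         entry$field_id))
      write_field_tiff(entry$image, paste0(base, ".tif"))
      write_labels_tiff(pair$nucleus, paste0(base, "_nuc.tif"))
      write_labels_tiff(pair$cell, paste0(base, "_cell.tif"))
    }
  }
  cells <- do.call(rbind, cells)
  filt <- filter_cells(cells, config$qc)

  ws <- aggregate_wells(filt$kept, layout,
                        min_cells_per_well = config$min_cells_per_well)
  ws <- normalize_plate(ws)
  gate <- anova_gate(ws)
  ht <- dunnett_test(ws, alpha = config$alpha, sided = config$sided,
                     gate = gate)
  hm <- heatmap_matrix(ws, layout)

  paths <- c(layout = file.path(out_dir, "layout.csv"),
             cells = file.path(out_dir, "cells.csv"),
             wells = file.path(out_dir, "well_summaries.csv"),
             hits = file.path(out_dir, "hit_table.csv"),
             heatmap_csv = file.path(out_dir, "heatmap.csv"),
             heatmap_png = file.path(out_dir, "heatmap.png"))
  write_layout_csv(layout, paths[["layout"]])
  utils::write.csv(cells, paths[["cells"]], row.names = FALSE)
  utils::write.csv(ws, paths[["wells"]], row.names = FALSE)
  utils::write.csv(as.data.frame(ht), paths[["hits"]], row.names = FALSE)
  utils::write.csv(hm, paths[["heatmap_csv"]], row.names = TRUE)
  ggplot2::ggsave(paths[["heatmap_png"]], plot_plate_heatmap(hm),
                  width = 7, height = 5, dpi = 120)

  manifest <- data.frame(artifact = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         seed = config$seed, stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)

  list(layout = layout, cells = cells, well_summaries = ws,
       hit_table = ht, heatmap = hm, gate = gate,
       rejection_tally = filt$tally, manifest_path = manifest_path)
}

#' Default demo configuration
#'
#' A small plate (12 water samples, 2 planted actives at saturating
#' potency, 4 replicate wells) with reduced field size so the full image
#' pipeline runs in seconds; used by the test suite and the tutorial.
#'
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1L) {
  as_run_config(list(
    acquisition = list(field_width_px = 256L, field_height_px = 256L,
                       fields_per_well = 1L),
    plate = list(rows = 8L, cols = 12L, n_samples = 12L, n_replicates = 4L),
    active_samples = list(S003 = 1, S007 = 1),
    noise = list(background_level = 5, read_noise_sd = 2,
                 shot_noise = TRUE, psf_sigma_px = 0.8),
    n_cells = 12L,
    min_cells_per_well = 5L,
    seed = seed
  ))
}

#' Generate the packaged demo dataset
#'
#' Writes the demo plate's images, ground truth, layout and config under
#' `out_dir` so the tutorial and tests can run the pipeline from files.
#'
#' @param out_dir Writable directory.
#' @param seed Master seed.
#' @param config Run configuration; defaults to [demo_config()].
#' @return List with `config`, `layout_path`, `image_paths`.
#' @export
make_demo_dataset <- function(out_dir, seed = 1L, config = demo_config(seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- do.call(make_plate_layout,
                    c(config$plate, list(seed = config$seed)))
  plate <- simulate_plate(layout, config$acq, config$cells, config$transloc,
                          config$noise, n_cells = config$n_cells,
                          seed = seed,
                          active_samples = config$active_samples)
  layout_path <- file.path(out_dir, "layout.csv")
  write_layout_csv(layout, layout_path)
  image_paths <- character(length(plate))
  truth_rows <- list()
  for (i in seq_along(plate)) {
    e <- plate[[i]]
    image_paths[i] <- file.path(out_dir, sprintf("%s_f%d.tif", e$well_id,
                                                 e$field_id))
    write_field_tiff(e$image, image_paths[i])
    tc <- e$truth$cells
    if (!is.null(tc)) {
      tc$well_id <- e$well_id; tc$field_id <- e$field_id
      truth_rows[[i]] <- tc
    }
  }
  utils::write.csv(do.call(rbind, truth_rows),
                   file.path(out_dir, "ground_truth_cells.csv"),
                   row.names = FALSE)
  list(config = config, layout_path = layout_path,
       image_paths = image_paths, plate = plate)
}
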