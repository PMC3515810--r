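# Nucleus and cytoplasm segmentation.
#
# The pipeline mirrors a standard high-content recipe: Gaussian smoothing,
# global Otsu threshold on the DNA channel, hole filling, area filtering,
# optional distance-transform watershed for touching nuclei; then seeded
# geodesic growth of each nucleus into the Otsu foreground of the GFP
# channel, capped at a maximum expansion distance.

#' Segmentation parameters
#'
#' @param nucleus_min_area_px,nucleus_max_area_px Area gate for nuclear
#'   objects (pixels); objects outside the gate are discarded.
#' @param smoothing_sigma_px Gaussian pre-smoothing sigma (0 disables).
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed?
#' @param watershed_tolerance Minimum depth (in distance-map units)
#'   separating two objects before they are split; raise to avoid
#'   over-splitting irregular nuclei.
#' @param cyto_max_expand_px Hard cap on cytoplasm growth beyond the
#'   nuclear boundary (pixels, >= 1).
#' @param border_policy `"exclude"` drops nuclei touching the field
#'   border, `"keep"` keeps them.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(nucleus_min_area_px = 60L,
                                nucleus_max_area_px = 2000L,
                                smoothing_sigma_px = 1,
                                split_touching = TRUE,
                                watershed_tolerance = 2,
                                cyto_max_expand_px = 12L,
                                border_policy = c("exclude", "keep")) {
  border_policy <- match.arg(border_policy)
  if (nucleus_min_area_px <= 0 || nucleus_max_area_px <= nucleus_min_area_px) {
    stop_ts("need 0 < nucleus_min_area_px < nucleus_max_area_px")
  }
  if (cyto_max_expand_px < 1) stop_ts("cyto_max_expand_px must be >= 1")
  if (smoothing_sigma_px < 0) stop_ts("smoothing_sigma_px must be >= 0")
  structure(list(nucleus_min_area_px = as.integer(nucleus_min_area_px),
                 nucleus_max_area_px = as.integer(nucleus_max_area_px),
                 smoothing_sigma_px = smoothing_sigma_px,
                 split_touching = isTRUE(split_touching),
                 watershed_tolerance = watershed_tolerance,
                 cyto_max_expand_px = as.integer(cyto_max_expand_px),
                 border_policy = border_policy),
            class = "segmentation_params")
}

as_ebimage <- function(m) EBImage::Image(m)
as_matrix <- function(img) {
  d <- dim(img)
  matrix(as.numeric(EBImage::imageData(img)), d[1], d[2])
}

# Relabel positive integer labels to 1..K preserving order of first use.
relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Segment nuclei from the DNA channel
#'
#' @param dna Numeric matrix of DNA-stain intensities (non-negative).
#' @param params A [segmentation_params()].
#' @return Integer label matrix (0 = background, 1..K = nuclei). A blank
#'   image yields an all-zero labeling with a warning.
#' @export
segment_nuclei <- function(dna, params = segmentation_params()) {
  if (!is.matrix(dna) || any(dna < 0, na.rm = TRUE)) {
    stop_ts("dna must be a non-negative 2-D intensity matrix")
  }
  rng <- range(dna)
  if (diff(rng) <= 0) {
    warning("blank DNA channel: no foreground found", call. = FALSE)
    return(matrix(0L, nrow(dna), ncol(dna)))
  }
  img <- (dna - rng[1]) / diff(rng)
  if (params$smoothing_sigma_px > 0) {
    img <- as_matrix(EBImage::gblur(as_ebimage(img),
                                    sigma = params$smoothing_sigma_px))
  }
  th <- EBImage::otsu(as_ebimage(img), range = c(0, 1))
  mask <- img > th
  if (!any(mask)) {
    warning("no foreground after thresholding", call. = FALSE)
    return(matrix(0L, nrow(dna), ncol(dna)))
  }
  mask_img <- EBImage::fillHull(as_ebimage(mask * 1))
  lab <- if (params$split_touching) {
    dm <- EBImage::distmap(mask_img)
    EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(mask_img)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(dna), ncol(dna))

  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < params$nucleus_min_area_px |
                  areas > params$nucleus_max_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (params$border_policy == "exclude") {
    edge_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    edge_ids <- edge_ids[edge_ids > 0]
    if (length(edge_ids)) lab[lab %in% edge_ids] <- 0L
  }
  relabel_sequential(lab)
}

#' Grow per-nucleus cell regions over the GFP channel
#'
#' Each nucleus seeds a cell region grown into the Otsu foreground of the
#' GFP channel by seeded propagation (geodesic nearest seed), capped at
#' `cyto_max_expand_px` beyond the nuclear boundary. If the GFP channel has
#' no usable foreground, cells degenerate to a one-pixel ring around the
#' nucleus (flagged downstream).
#'
#' @param gfp Numeric matrix of receptor-channel intensities.
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param params A [segmentation_params()].
#' @return A `label_pair` list with `nucleus` and `cell` label matrices
#'   sharing ids; nucleus pixels are a subset of same-id cell pixels.
#' @export
segment_cytoplasm <- function(gfp, nucleus_labels,
                              params = segmentation_params()) {
  if (!identical(dim(gfp), dim(nucleus_labels))) {
    stop_ts("gfp and nucleus_labels must have identical dimensions")
  }
  nuc <- nucleus_labels
  if (!any(nuc > 0)) {
    return(structure(list(nucleus = nuc, cell = nuc), class = "label_pair"))
  }
  # Foreground on the log-compressed GFP channel: with a bright nuclear
  # pool, linear Otsu splits nucleus vs everything else and loses the dim
  # cytoplasm; log compression restores the background/cell bimodality.
  lg <- log1p(pmax(gfp, 0))
  rng <- range(lg)
  fg <- if (diff(rng) > 0) {
    img <- (lg - rng[1]) / diff(rng)
    img > EBImage::otsu(as_ebimage(img), range = c(0, 1))
  } else {
    matrix(FALSE, nrow(gfp), ncol(gfp))
  }
  # distance from each background-of-nucleus pixel to the nearest nucleus
  dist_to_nuc <- as_matrix(EBImage::distmap(as_ebimage(1 - (nuc > 0))))
  ring <- dist_to_nuc <= 1.5          # minimum ring: guarantees a cell region
  allowed <- (fg & dist_to_nuc <= params$cyto_max_expand_px) | (nuc > 0) | ring
  cell <- EBImage::propagate(as_ebimage(gfp), seeds = as_ebimage(nuc),
                             mask = as_ebimage(allowed * 1), lambda = 1e4)
  cell <- matrix(as.integer(EBImage::imageData(cell)), nrow(gfp), ncol(gfp))
  cell[nuc > 0] <- nuc[nuc > 0]       # seeds always keep their own pixels
  structure(list(nucleus = nuc, cell = cell), class = "label_pair")
}

#' Check the structural invariants of a label pair
#'
#' Nucleus pixels must be a subset of same-id cell pixels and both maps
#' must carry exactly the same label ids.
#' @param pair A `label_pair`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_label_pair <- function(pair) {
  nuc <- pair$nucleus; cell <- pair$cell
  if (!identical(dim(nuc), dim(cell))) stop_ts("label maps differ in shape")
  sel <- nuc > 0
  if (any(cell[sel] != nuc[sel])) {
    stop_ts("nucleus pixels not contained in same-id cell pixels")
  }
  if (!setequal(unique(nuc[sel]), unique(cell[cell > 0]))) {
    stop_ts("label ids differ between nucleus and cell maps")
  }
  invisible(TRUE)
}

#' Score a segmentation against ground-truth labels
#'
#' Matches predicted to true objects by maximal pixel overlap and reports
#' the count error and mean intersection-over-union of matched pairs.
#'
#' @param pred Predicted integer label matrix.
#' @param truth Ground-truth integer label matrix (same shape).
#' @return List with `n_pred`, `n_truth`, `count_error` (pred - truth),
#'   `mean_iou`, and per-match data.frame `matches`.
#' @export
score_segmentation <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  ids_t <- sort(unique(truth[truth > 0]))
  ids_p <- sort(unique(pred[pred > 0]))
  matches <- data.frame(truth_id = integer(), pred_id = integer(),
                        iou = numeric())
  if (length(ids_t) && length(ids_p)) {
    sel <- truth > 0 & pred > 0
    ov <- table(truth_id = truth[sel], pred_id = pred[sel])
    area_t <- tabulate(truth[truth > 0], nbins = max(ids_t))
    area_p <- tabulate(pred[pred > 0], nbins = max(ids_p))
    iou <- numeric(length(ids_t)); best <- rep(NA_integer_, length(ids_t))
    for (j in seq_along(ids_t)) {
      tid <- as.character(ids_t[j])
      if (!tid %in% rownames(ov)) next     # unmatched object: IoU 0
      inter <- ov[tid, ]
      pids <- as.integer(colnames(ov))
      un <- area_t[ids_t[j]] + area_p[pids] - inter
      k <- which.max(inter / un)
      iou[j] <- (inter / un)[k]
      best[j] <- pids[k]
    }
    matches <- data.frame(truth_id = ids_t, pred_id = best, iou = iou)
  }
  list(n_pred = length(ids_p), n_truth = length(ids_t),
       count_error = length(ids_p) - length(ids_t),
       mean_iou = if (nrow(matches)) mean(matches$iou) else NA_real_,
       matches = matches)
}
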