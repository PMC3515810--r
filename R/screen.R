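# Plate-level screening statistics: well aggregation, vehicle
# normalization, one-way ANOVA gate, and Dunnett many-to-one hit calling.
# Hit tiers follow the screening convention: p05 (adjusted P < 0.05) and
# p01 (adjusted P < 0.01), assigned only when the plate-wide ANOVA F test
# reaches P < 0.05.

#' Aggregate kept cells into per-well summaries
#'
#' Cells from all fields of a well are pooled before averaging; the
#' per-well value is the mean N/C ratio over kept cells (median available
#' as a robust alternative).
#'
#' @param records Kept cell records (see [filter_cells()]).
#' @param layout Plate layout; every `well_id` in `records` must appear.
#' @param min_cells_per_well Wells with fewer kept cells are flagged
#'   `low_n` and excluded from downstream statistics.
#' @param center `"mean"` (default, matching per-well averaging of the
#'   assay) or `"median"`.
#' @return data.frame of well summaries with `n_cells_kept`,
#'   `mean_nc_ratio`, `sd_nc_ratio`, treatment annotation and `usable`.
#' @export
aggregate_wells <- function(records, layout, min_cells_per_well = 10L,
                            center = c("mean", "median")) {
  center <- match.arg(center)
  validate_layout(layout)
  unknown <- setdiff(unique(records$well_id), layout$well_id)
  if (length(unknown)) {
    stop_ts("cell records reference wells absent from the layout: ",
            paste(unknown, collapse = ", "))
  }
  cfun <- if (center == "mean") mean else stats::median
  sp <- split(records$nc_ratio, records$well_id)
  ws <- data.frame(well_id = names(sp),
                   n_cells_kept = vapply(sp, length, integer(1)),
                   mean_nc_ratio = vapply(sp, cfun, numeric(1)),
                   sd_nc_ratio = vapply(sp, stats::sd, numeric(1)),
                   stringsAsFactors = FALSE)
  out <- merge(ws, as.data.frame(layout), by = "well_id", sort = TRUE)
  out$usable <- out$n_cells_kept >= min_cells_per_well
  out[order(out$row, out$col), ]
}

#' Normalize well means to the plate's vehicle controls
#'
#' Divides every well's mean N/C ratio by the mean of the vehicle-well
#' means on the same plate, so the vehicle group averages exactly 1.
#'
#' @param summaries Output of [aggregate_wells()] for one plate.
#' @return `summaries` with a `normalized_translocation` column.
#' @export
normalize_plate <- function(summaries) {
  veh <- summaries$treatment_class == "vehicle" & summaries$usable
  if (!any(veh)) stop_ts("no usable vehicle wells on the plate; cannot normalize")
  v <- mean(summaries$mean_nc_ratio[veh])
  if (!is.finite(v) || v <= 0) stop_ts("vehicle mean is not positive")
  summaries$normalized_translocation <- summaries$mean_nc_ratio / v
  summaries
}

#' One-way ANOVA gate on per-well values
#'
#' Classical fixed-effects one-way ANOVA of the per-well values across
#' treatment groups (vehicle included). Groups with fewer than 2 usable
#' wells are dropped with a warning. If every group is constant (zero
#' within-group variance) but group means differ, the F statistic is
#' unbounded and p = 0 is returned with `zero_variance = TRUE`.
#'
#' @param summaries Normalized well summaries.
#' @param value Column holding the per-well response.
#' @return List with `F`, `p`, `df`, `groups`, `zero_variance`.
#' @export
anova_gate <- function(summaries, value = "normalized_translocation") {
  s <- summaries[summaries$usable & !is.na(summaries$treatment_label), ]
  counts <- table(s$treatment_label)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping groups with < 2 wells: ",
            paste(small, collapse = ", "), call. = FALSE)
    s <- s[!s$treatment_label %in% small, ]
  }
  if (length(unique(s$treatment_label)) < 2) {
    stop_ts("ANOVA gate needs >= 2 groups with >= 2 wells each")
  }
  x <- s[[value]]; g <- factor(s$treatment_label)
  within_var <- stats::ave(x, g, FUN = stats::var)
  if (all(within_var < .Machine$double.eps)) {
    means_differ <- stats::var(tapply(x, g, mean)) > .Machine$double.eps
    return(list(F = Inf, p = if (means_differ) 0 else 1,
                df = c(nlevels(g) - 1, length(x) - nlevels(g)),
                groups = levels(g), zero_variance = TRUE))
  }
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter), groups = levels(g),
       zero_variance = FALSE)
}

#' Dunnett many-to-one hit calling
#'
#' Compares every non-vehicle treatment group against the vehicle group
#' using the pooled one-way variance estimate. Adjusted p-values are
#' single-step Dunnett (see [dunnett_pvalues()]). Tiers `p05`/`p01` are
#' assigned only when the ANOVA gate p-value is below `gate_alpha`;
#' otherwise all treatments are reported `negative` with `adjusted_p = NA`
#' (not evaluated).
#'
#' @param summaries Normalized well summaries for one plate.
#' @param value Response column.
#' @param alpha Familywise alpha for the `p05` tier (0.05).
#' @param sided `"two_sided"` or `"upper"`.
#' @param gate Result of [anova_gate()]; computed if `NULL`.
#' @param gate_alpha ANOVA gate threshold.
#' @param vehicle_label Label of the control group.
#' @return A `hit_table` data.frame: per treatment group mean, SEM,
#'   group size, `t`, `adjusted_p`, `tier`, `direction`, plus the gate
#'   statistics as attributes.
#' @export
dunnett_test <- function(summaries, value = "normalized_translocation",
                         alpha = 0.05, sided = c("two_sided", "upper"),
                         gate = NULL, gate_alpha = 0.05,
                         vehicle_label = "vehicle") {
  sided <- match.arg(sided)
  s <- summaries[summaries$usable & !is.na(summaries$treatment_label), ]
  counts <- table(s$treatment_label)
  s <- s[s$treatment_label %in% names(counts)[counts >= 2], ]
  if (!vehicle_label %in% s$treatment_label) {
    stop_ts("vehicle group '", vehicle_label, "' missing or unusable")
  }
  gate <- gate %||% anova_gate(s, value)
  x <- s[[value]]; g <- factor(s$treatment_label)
  labs <- levels(g)
  nn <- tapply(x, g, length)
  mm <- tapply(x, g, mean)
  ss <- tapply(x, g, stats::var)
  nu <- sum(nn) - length(labs)
  s2 <- sum((nn - 1) * ss) / nu          # pooled one-way variance
  treat <- setdiff(labs, vehicle_label)
  k <- length(treat)
  n0 <- nn[[vehicle_label]]
  tstat <- (mm[treat] - mm[[vehicle_label]]) /
    sqrt(s2 * (1 / nn[treat] + 1 / n0))
  spec <- dunnett_spec(k = k, n_control = n0, n_treat = as.numeric(nn[treat]),
                       alpha = alpha, sided = sided, nu = nu)
  gate_passed <- is.finite(gate$p) && gate$p < gate_alpha
  adj_p <- if (gate_passed) dunnett_pvalues(as.numeric(tstat), spec) else
    rep(NA_real_, k)
  tier <- rep("negative", k)
  if (gate_passed) {
    tier[adj_p < 0.05] <- "p05"
    tier[adj_p < 0.01] <- "p01"
  }
  out <- data.frame(treatment_label = treat,
                    n_wells = as.integer(nn[treat]),
                    group_mean = as.numeric(mm[treat]),
                    sem = sqrt(as.numeric(ss[treat]) / as.numeric(nn[treat])),
                    t = as.numeric(tstat),
                    adjusted_p = adj_p,
                    tier = tier,
                    direction = ifelse(tstat >= 0, "increase", "decrease"),
                    stringsAsFactors = FALSE)
  vehicle_row <- data.frame(treatment_label = vehicle_label,
                            n_wells = as.integer(n0),
                            group_mean = as.numeric(mm[[vehicle_label]]),
                            sem = sqrt(as.numeric(ss[[vehicle_label]]) / n0),
                            t = NA_real_, adjusted_p = NA_real_,
                            tier = "negative", direction = NA_character_,
                            stringsAsFactors = FALSE)
  out <- rbind(vehicle_row, out)
  attr(out, "gate") <- gate
  attr(out, "gate_passed") <- gate_passed
  attr(out, "spec") <- spec
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Dose-response summary for one treatment across doses
#'
#' Summarizes normalized translocation per dose level, reports the
#' Spearman rank correlation of dose versus per-dose mean, and the lowest
#' dose whose Dunnett-adjusted p-value falls below `alpha` (the detection
#' threshold dose; `NA` when nothing is significant).
#'
#' @param summaries Normalized well summaries containing the vehicle wells
#'   and one treatment at >= 3 dose levels (distinct `dose` values with
#'   `treatment_label` per dose level or a shared label).
#' @param alpha Significance level for the detection threshold.
#' @param sided Passed to [dunnett_test()].
#' @param vehicle_label Control group label.
#' @return List with `table` (per-dose mean, SEM, adjusted p, tier),
#'   `spearman`, and `detection_threshold_dose`.
#' @export
dose_response_summary <- function(summaries, alpha = 0.05,
                                  sided = c("two_sided", "upper"),
                                  vehicle_label = "vehicle") {
  sided <- match.arg(sided)
  s <- summaries[summaries$usable, ]
  is_veh <- s$treatment_label == vehicle_label
  doses <- sort(unique(s$dose[!is_veh]))
  if (length(doses) < 3) stop_ts("need >= 3 dose levels")
  counts <- table(s$dose[!is_veh])
  unrep <- as.numeric(names(counts)[counts < 2])
  if (length(unrep)) {
    warning("excluding unreplicated doses: ",
            paste(unrep, collapse = ", "), call. = FALSE)
    s <- s[is_veh | !s$dose %in% unrep, ]
    is_veh <- s$treatment_label == vehicle_label
    doses <- setdiff(doses, unrep)
  }
  # one group per dose level, vehicle as control
  s$group <- ifelse(is_veh, vehicle_label, sprintf("dose_%g", s$dose))
  s2 <- s; s2$treatment_label <- s2$group
  ht <- dunnett_test(s2, alpha = alpha, sided = sided,
                     vehicle_label = vehicle_label)
  tab <- ht[ht$treatment_label != vehicle_label, ]
  tab$dose <- as.numeric(sub("^dose_", "", tab$treatment_label))
  tab <- tab[order(tab$dose), ]
  rho <- stats::cor(tab$dose, tab$group_mean, method = "spearman")
  sig <- tab$dose[!is.na(tab$adjusted_p) & tab$adjusted_p < alpha &
                    tab$direction == "increase"]
  list(table = tab, spearman = rho,
       detection_threshold_dose = if (length(sig)) min(sig) else NA_real_)
}

#' Plate-geometry matrix of a well statistic
#'
#' @param summaries Well summaries with `row`/`col` coordinates.
#' @param layout Plate layout providing the full geometry.
#' @param value Column to place in the matrix (`normalized_translocation`
#'   or `mean_nc_ratio`).
#' @return Numeric matrix (rows = plate rows, letters as dimnames); wells
#'   without a value are `NA`.
#' @export
heatmap_matrix <- function(summaries, layout,
                           value = "normalized_translocation") {
  validate_layout(layout)
  nr <- max(layout$row); nc <- max(layout$col)
  m <- matrix(NA_real_, nr, nc,
              dimnames = list(LETTERS[seq_len(nr)], seq_len(nc)))
  if (anyDuplicated(summaries$well_id)) {
    stop_ts("duplicate well coordinates in summaries")
  }
  m[cbind(summaries$row, summaries$col)] <- summaries[[value]]
  m
}

#' Render a plate heat-map
#'
#' @param m Matrix from [heatmap_matrix()].
#' @param title Plot title.
#' @return A ggplot object (plate orientation: row A at the top).
#' @export
plot_plate_heatmap <- function(m, title = "Normalized translocation") {
  df <- data.frame(row = factor(rep(rownames(m), ncol(m)),
                                levels = rev(rownames(m))),
                   col = factor(rep(colnames(m), each = nrow(m)),
                                levels = colnames(m)),
                   value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "N/C") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
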