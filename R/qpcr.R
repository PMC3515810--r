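# qPCR: synthetic Cq generation, standard curves from serial dilutions,
# and standard-curve relative quantification normalized to a reference
# gene, reported as fold change versus vehicle.

#' Simulate qPCR Cq tables with known fold changes
#'
#' Generates (i) a per-gene 10-fold serial-dilution series for standard
#' curves and (ii) replicate Cq values per condition. The amplification
#' model is `Cq = Cq_base - log(quantity) / log(1 + efficiency)` plus
#' Gaussian cycle noise; the reference gene has fold change 1 in every
#' condition by construction.
#'
#' @param genes Character vector of target gene names.
#' @param fold_changes Planted fold changes vs vehicle: a data.frame with
#'   columns `condition`, `fold_change` (applied to every target gene) or
#'   `gene`, `condition`, `fold_change` for per-gene profiles (e.g. a
#'   rise-then-fall dose profile). The vehicle condition is added
#'   automatically with fold 1.
#' @param reference_gene Name of the normalizer gene (e.g. "Actb").
#' @param vehicle_label Condition label of the vehicle control.
#' @param n_replicates Independent replicates per condition (>= 3 in the
#'   assay convention).
#' @param dilution_points Number of 10-fold dilution points (>= 3).
#' @param efficiency Amplification efficiency in (0, 1]; 1 = perfect
#'   doubling per cycle.
#' @param cq_noise_sd Gaussian noise on Cq values (cycles).
#' @param base_cq Modal Cq of the undiluted template.
#' @param seed RNG seed.
#' @return List with `cq` (gene, condition, replicate, cq) and
#'   `dilutions` (gene, log10_quantity, cq) data.frames.
#' @export
simulate_qpcr <- function(genes, fold_changes, reference_gene = "Actb",
                          vehicle_label = "DMSO", n_replicates = 4L,
                          dilution_points = 5L, efficiency = 1,
                          cq_noise_sd = 0.1, base_cq = 22, seed = 1L) {
  if (efficiency <= 0 || efficiency > 1) {
    stop_ts("efficiency must lie in (0, 1]")
  }
  if (dilution_points < 3) stop_ts("dilution_points must be >= 3")
  fc <- as.data.frame(fold_changes)
  if (!"gene" %in% names(fc)) {
    fc <- do.call(rbind, lapply(genes, function(g) cbind(gene = g, fc)))
  }
  if (any(fc$fold_change <= 0)) stop_ts("fold changes must be positive")
  all_genes <- union(genes, reference_gene)
  conds <- unique(c(vehicle_label, fc$condition))
  slope_factor <- 1 / log10(1 + efficiency)   # cycles per log10 quantity

  with_seed(seed, {
    rows <- list()
    for (g in all_genes) {
      for (cond in conds) {
        fold <- if (g == reference_gene || cond == vehicle_label) 1 else {
          hit <- fc$fold_change[fc$gene == g & fc$condition == cond]
          if (!length(hit)) 1 else hit[[1]]
        }
        cq <- base_cq - log10(fold) * slope_factor +
          stats::rnorm(n_replicates, 0, cq_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, condition = cond, replicate = seq_len(n_replicates),
          cq = cq, stringsAsFactors = FALSE)
      }
    }
    lq <- -(seq_len(dilution_points) - 1)      # 1, 0.1, 0.01, ...
    dil <- do.call(rbind, lapply(all_genes, function(g) {
      data.frame(gene = g, log10_quantity = lq,
                 cq = base_cq - lq * slope_factor +
                   stats::rnorm(dilution_points, 0, cq_noise_sd),
                 stringsAsFactors = FALSE)
    }))
    list(cq = do.call(rbind, rows), dilutions = dil)
  })
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(quantity) for one gene's serial
#' dilution; amplification efficiency is `10^(-1/slope) - 1` (slope
#' -3.3219 at 100% efficiency).
#'
#' @param dilutions data.frame with columns `log10_quantity`, `cq` (and
#'   optionally `gene`, which must then be unique).
#' @return A `standard_curve` list: `gene`, `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `cq_range`.
#' @export
fit_standard_curve <- function(dilutions) {
  if ("gene" %in% names(dilutions)) {
    g <- unique(dilutions$gene)
    if (length(g) > 1) stop_ts("fit one gene at a time; got: ",
                               paste(g, collapse = ", "))
  } else g <- NA_character_
  if (nrow(dilutions) < 3) stop_ts("need >= 3 dilution points")
  if (diff(range(dilutions$log10_quantity)) < 2) {
    stop_ts("dilution series must span >= 2 log10 units")
  }
  fit <- stats::lm(cq ~ log10_quantity, data = dilutions)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop_ts("positive standard-curve slope; dilution quantities look mislabeled")
  }
  ss_tot <- sum((dilutions$cq - mean(dilutions$cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(gene = g, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 cq_range = range(dilutions$cq)),
            class = "standard_curve")
}

#' Fit standard curves for every gene in a dilution table
#' @param dilutions data.frame with `gene`, `log10_quantity`, `cq`.
#' @return Named list of [fit_standard_curve()] results.
#' @export
fit_standard_curves <- function(dilutions) {
  sp <- split(dilutions, dilutions$gene)
  lapply(sp, fit_standard_curve)
}

#' Relative expression via standard-curve interpolation
#'
#' For each replicate, interpolates the template quantity from the gene's
#' standard curve, normalizes it to the reference-gene quantity of the
#' same replicate, and expresses it as fold change over the mean vehicle
#' normalized quantity. Means and SEM are taken across replicates, and
#' significance vs vehicle is assessed per gene with the Dunnett
#' machinery on log2 fold changes.
#'
#' @param cq data.frame with `gene`, `condition`, `replicate`, `cq`.
#' @param curves Named list of standard curves (one per gene, names =
#'   genes), from [fit_standard_curves()].
#' @param reference_gene Normalizer gene present in every condition.
#' @param vehicle_label Vehicle condition label.
#' @param alpha Significance level for the Dunnett tiers.
#' @param significance Run the per-gene Dunnett comparison? Disable for
#'   plain quantification (columns `adjusted_p`/`tier` become `NA`).
#' @return data.frame with one row per gene x condition:
#'   `mean_fold_change`, `sem`, `n_replicates`, `extrapolated` (any Cq
#'   outside the calibrated range), `adjusted_p`, `tier`.
#' @export
relative_expression <- function(cq, curves, reference_gene = "Actb",
                                vehicle_label = "DMSO", alpha = 0.05,
                                significance = TRUE) {
  genes <- setdiff(unique(cq$gene), reference_gene)
  missing_curves <- setdiff(unique(cq$gene), names(curves))
  if (length(missing_curves)) {
    stop_ts("no standard curve for: ", paste(missing_curves, collapse = ", "))
  }
  if (!all(vehicle_label %in% cq$condition)) {
    stop_ts("vehicle condition '", vehicle_label, "' absent from Cq table")
  }
  quantify <- function(gene, cqv) {
    cv <- curves[[gene]]
    list(q = 10^((cqv - cv$intercept) / cv$slope),
         extra = cqv < cv$cq_range[1] - 0.5 | cqv > cv$cq_range[2] + 0.5)
  }
  ref <- cq[cq$gene == reference_gene, ]
  out <- list()
  for (g in genes) {
    tg <- cq[cq$gene == g, ]
    m <- merge(tg, ref[, c("condition", "replicate", "cq")],
               by = c("condition", "replicate"),
               suffixes = c("", "_ref"))
    if (!nrow(m)) stop_ts("reference gene missing for gene ", g)
    qt <- quantify(g, m$cq); qr <- quantify(reference_gene, m$cq_ref)
    m$norm_q <- qt$q / qr$q
    m$extrapolated <- qt$extra | qr$extra
    veh_mean <- mean(m$norm_q[m$condition == vehicle_label])
    m$fold <- m$norm_q / veh_mean
    if (any(m$extrapolated)) {
      warning(sprintf("gene %s: %d Cq value(s) outside the calibrated range",
                      g, sum(m$extrapolated)), call. = FALSE)
    }
    # Dunnett vs vehicle on log2 fold change, family = this gene
    stats_in <- data.frame(treatment_label = m$condition,
                           normalized_translocation = log2(m$fold),
                           usable = TRUE)
    tiers <- if (!significance) {
      data.frame(treatment_label = unique(m$condition),
                 adjusted_p = NA_real_, tier = NA_character_)
    } else tryCatch({
      ht <- dunnett_test(stats_in, alpha = alpha,
                         vehicle_label = vehicle_label)
      ht[, c("treatment_label", "adjusted_p", "tier")]
    }, error = function(e) data.frame(treatment_label = unique(m$condition),
                                      adjusted_p = NA_real_,
                                      tier = NA_character_))
    agg <- do.call(rbind, lapply(split(m, m$condition), function(d) {
      data.frame(gene = g, condition = d$condition[1],
                 mean_fold_change = mean(d$fold),
                 sem = stats::sd(d$fold) / sqrt(nrow(d)),
                 n_replicates = nrow(d),
                 extrapolated = any(d$extrapolated),
                 stringsAsFactors = FALSE)
    }))
    agg <- merge(agg, tiers, by.x = "condition", by.y = "treatment_label",
                 all.x = TRUE)
    out[[g]] <- agg[, c("gene", "condition", "mean_fold_change", "sem",
                        "n_replicates", "extrapolated", "adjusted_p",
                        "tier")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
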