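# Plate statistics: aggregation, vehicle normalization, ANOVA gate,
# Dunnett machinery, dose-response summaries, heat-maps.

make_summaries <- function(values_by_group, layout = NULL) {
  labs <- rep(names(values_by_group), lengths(values_by_group))
  vals <- unlist(values_by_group, use.names = FALSE)
  data.frame(well_id = sprintf("W%02d", seq_along(vals)),
             treatment_label = labs,
             treatment_class = ifelse(labs == "vehicle", "vehicle", "sample"),
             dose = ifelse(labs == "vehicle", 0, 100),
             mean_nc_ratio = vals, n_cells_kept = 100L,
             row = 1L, col = seq_along(vals),
             replicate_group = labs, usable = TRUE,
             stringsAsFactors = FALSE)
}

test_that("wells aggregate pooled cells and reject unknown wells", {
  layout <- make_plate_layout(rows = 2, cols = 6, n_samples = 1,
                              n_replicates = 1, seed = 1, n_vehicle = 4,
                              n_positive = 4)
  well <- layout$well_id[layout$treatment_class == "sample"][1]
  rec <- data.frame(cell_id = 1:6, well_id = well,
                    field_id = c(1, 1, 1, 2, 2, 2),
                    nc_ratio = c(1, 2, 3, 2, 2, 2), qc_flags = "",
                    stringsAsFactors = FALSE)
  ws <- aggregate_wells(rec, layout, min_cells_per_well = 2)
  expect_equal(ws$mean_nc_ratio[ws$well_id == well], 2)   # fields pooled
  expect_equal(ws$n_cells_kept[ws$well_id == well], 6L)
  bad <- rec; bad$well_id <- "Z99"
  expect_error(aggregate_wells(bad, layout), "Z99")
  # sparse wells flagged unusable
  ws2 <- aggregate_wells(rec, layout, min_cells_per_well = 10)
  expect_false(ws2$usable[ws2$well_id == well])
})

test_that("vehicle normalization fixes the vehicle mean at exactly 1", {
  s <- make_summaries(list(vehicle = c(1.1, 0.9, 1.0, 1.0),
                           S001 = c(3, 3, 3, 3)))
  n <- normalize_plate(s)
  veh <- n$treatment_label == "vehicle"
  expect_identical(mean(n$normalized_translocation[veh]), 1)
  expect_equal(n$normalized_translocation[!veh], rep(3, 4))
  s$usable[s$treatment_label == "vehicle"] <- FALSE
  expect_error(normalize_plate(s), "vehicle")
})

test_that("the ANOVA gate matches the classical one-way F test", {
  set.seed(1)
  s <- make_summaries(list(vehicle = rnorm(4, 1, 0.05),
                           A = rnorm(4, 1, 0.05), B = rnorm(4, 1.5, 0.05)))
  g <- anova_gate(s, value = "mean_nc_ratio")
  ref <- summary(stats::aov(mean_nc_ratio ~ treatment_label, data = s))[[1]]
  expect_equal(g$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(g$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  # separated constant groups: zero-variance guard path
  s0 <- make_summaries(list(vehicle = c(1, 1), A = c(2, 2)))
  g0 <- anova_gate(s0, value = "mean_nc_ratio")
  expect_true(g0$zero_variance)
  expect_equal(g0$p, 0)
  # strongly separated groups with tiny jitter are significant
  s1 <- make_summaries(list(vehicle = c(0, 1e-6), A = c(1, 1 + 1e-6)))
  expect_lt(anova_gate(s1, value = "mean_nc_ratio")$p, 0.001)
})

test_that("the null ANOVA gate rejects at its nominal rate", {
  set.seed(99)
  rej <- 0; nsim <- 600
  for (i in seq_len(nsim)) {
    s <- make_summaries(list(vehicle = rnorm(4), A = rnorm(4), B = rnorm(4)))
    if (anova_gate(s, value = "mean_nc_ratio")$p < 0.05) rej <- rej + 1
  }
  se <- sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(rej / nsim - 0.05), 3 * se)
})

test_that("Dunnett critical values reduce to Student t at k = 1", {
  for (nu in c(6, 12, 30)) {
    spec <- dunnett_spec(k = 1, n_control = 4, alpha = 0.05, nu = nu)
    expect_equal(dunnett_critical(spec), qt(0.975, nu), tolerance = 1e-6)
  }
  spec_up <- dunnett_spec(k = 1, n_control = 4, alpha = 0.05,
                          sided = "upper", nu = 10)
  expect_equal(dunnett_critical(spec_up), qt(0.95, 10), tolerance = 1e-6)
})

test_that("Dunnett critical values are monotone in alpha with proper limits", {
  spec_lo <- dunnett_spec(k = 4, n_control = 4, alpha = 0.9)
  spec_mid <- dunnett_spec(k = 4, n_control = 4, alpha = 0.05)
  spec_hi <- dunnett_spec(k = 4, n_control = 4, alpha = 0.001)
  d <- c(dunnett_critical(spec_lo), dunnett_critical(spec_mid),
         dunnett_critical(spec_hi))
  expect_true(all(diff(d) > 0))
  expect_lt(d[1], 1)
  expect_gt(d[3], 4)
})

test_that("quadrature agrees with an independent Monte-Carlo oracle", {
  spec <- dunnett_spec(k = 4, n_control = 4, alpha = 0.05)
  mc <- dunnett_mc_oracle(spec, n_draws = 2e5, seed = 7)
  d <- dunnett_critical(spec)
  expect_lt(abs(d - mc$quantile), 4 * mc$se)
  # distribution function agreement at several points
  for (x in c(1.5, 2.5, 3.5)) {
    expect_lt(abs(dunnett_prob(x, spec) - mc$prob(x)), 0.005)
  }
})

test_that("quadrature matches mvtnorm for unbalanced designs", {
  skip_if_not_installed("mvtnorm")
  spec <- dunnett_spec(k = 3, n_control = 6, n_treat = c(3, 4, 5))
  corr <- outer(spec$lambda, spec$lambda)
  diag(corr) <- 1
  set.seed(1)
  ref <- mvtnorm::qmvt(0.95, tail = "both.tails", df = spec$nu,
                       corr = corr, abseps = 1e-5)$quantile
  expect_equal(dunnett_critical(spec), ref, tolerance = 1e-3)
})

test_that("hit calling tiers planted effects and spares nulls", {
  set.seed(5)
  s <- make_summaries(list(vehicle = 1 + rnorm(4, 0, 0.05),
                           null1 = 1 + rnorm(4, 0, 0.05),
                           hit = 1.5 + rnorm(4, 0, 0.05)))
  ht <- dunnett_test(s, value = "mean_nc_ratio")
  expect_s3_class(ht, "hit_table")
  expect_equal(ht$tier[ht$treatment_label == "hit"], "p01")
  expect_equal(ht$tier[ht$treatment_label == "null1"], "negative")
  expect_gt(ht$adjusted_p[ht$treatment_label == "null1"], 0.2)
  expect_equal(ht$tier[ht$treatment_label == "vehicle"], "negative")
  # p01 implies p05: adjusted p below 0.01 whenever tier is p01
  expect_true(all(ht$adjusted_p[ht$tier == "p01"] < 0.01))
})

test_that("no tier is assigned when the ANOVA gate fails", {
  set.seed(8)
  s <- make_summaries(list(vehicle = 1 + rnorm(4, 0, 0.05),
                           A = 1 + rnorm(4, 0, 0.05),
                           B = 1 + rnorm(4, 0, 0.05)))
  g <- anova_gate(s, value = "mean_nc_ratio")
  expect_gt(g$p, 0.05)
  ht <- dunnett_test(s, value = "mean_nc_ratio", gate = g)
  expect_true(all(ht$tier == "negative"))
  expect_true(all(is.na(ht$adjusted_p[ht$treatment_label != "vehicle"])))
  expect_false(attr(ht, "gate_passed"))
})

test_that("tiers are invariant to plate-constant rescaling", {
  set.seed(13)
  s <- make_summaries(list(vehicle = 1 + rnorm(4, 0, 0.04),
                           A = 1.35 + rnorm(4, 0, 0.04),
                           B = 1 + rnorm(4, 0, 0.04)))
  ht1 <- dunnett_test(s, value = "mean_nc_ratio")
  s2 <- s; s2$mean_nc_ratio <- s2$mean_nc_ratio * 7.3
  ht2 <- dunnett_test(s2, value = "mean_nc_ratio")
  expect_equal(ht1$adjusted_p, ht2$adjusted_p, tolerance = 1e-9)
  expect_identical(ht1$tier, ht2$tier)
})

test_that("dose-response summaries find the detection threshold", {
  layout <- ladder_layout(c(1, 3, 10, 30, 100))
  # effect planted only at the top two doses
  eff <- c(dose_04 = 6, dose_05 = 8)
  ws <- normalize_plate(simulate_well_values(layout, effect_sd_units = eff,
                                             seed = 21))
  ws$treatment_label[ws$treatment_class == "sample"] <- "SS97"
  dr <- dose_response_summary(ws)
  expect_equal(dr$detection_threshold_dose, 30)
  # flat null ladder: no threshold
  ws0 <- normalize_plate(simulate_well_values(layout, seed = 22))
  ws0$treatment_label[ws0$treatment_class == "sample"] <- "SS97"
  dr0 <- dose_response_summary(ws0)
  expect_true(is.na(dr0$detection_threshold_dose))
  expect_error(dose_response_summary(
    normalize_plate(simulate_well_values(ladder_layout(c(1, 10)), seed = 1))),
    "3 dose")
})

test_that("heat-map matrices sit in plate geometry and round-trip", {
  layout <- make_plate_layout(rows = 8, cols = 12, n_samples = 4,
                              n_replicates = 4, seed = 2)
  ws <- normalize_plate(simulate_well_values(layout, seed = 3))
  m <- heatmap_matrix(ws, layout)
  expect_equal(dim(m), c(8, 12))
  empties <- layout[layout$treatment_class == "empty", ]
  expect_true(all(is.na(m[cbind(empties$row, empties$col)])))
  occupied <- layout[layout$treatment_class != "empty", ]
  expect_false(anyNA(m[cbind(occupied$row, occupied$col)]))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(m, path, row.names = TRUE)
  back <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(m))
  dup <- rbind(ws, ws[1, ])
  expect_error(heatmap_matrix(dup, layout), "duplicate")
})
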