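# Synthetic-plate generator: layout accounting, Hill dose dependence,
# photon conservation, label/ground-truth consistency, determinism.

test_that("plate layout balances wells and respects capacity", {
  layout <- make_plate_layout(rows = 8, cols = 12, n_samples = 1,
                              n_replicates = 4, seed = 1)
  counts <- table(layout$treatment_class)
  expect_equal(unname(counts[["vehicle"]]), 4)
  expect_equal(unname(counts[["positive_control"]]), 4)
  expect_equal(unname(counts[["sample"]]), 4)
  expect_equal(unname(counts[["empty"]]), 84)
  expect_false(anyDuplicated(layout$well_id) > 0)

  expect_error(make_plate_layout(rows = 8, cols = 12, n_samples = 69,
                                 n_replicates = 4),
               "capacity exceeded")

  again <- make_plate_layout(rows = 8, cols = 12, n_samples = 1,
                             n_replicates = 4, seed = 1)
  expect_identical(layout, again)
  other <- make_plate_layout(rows = 8, cols = 12, n_samples = 1,
                             n_replicates = 4, seed = 2)
  expect_false(identical(layout, other))
})

test_that("layout CSV round-trips", {
  layout <- make_plate_layout(n_samples = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_layout_csv(layout, path)
  back <- read_layout_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(layout))
})

test_that("Hill curve hits its limits and is monotone", {
  tm <- translocation_model(f_min = 0.2, f_max = 0.95, ec50 = 5, hill = 2)
  expect_equal(hill_fraction(0, tm), 0.2)
  expect_equal(hill_fraction(Inf, tm), 0.95)
  expect_equal(hill_fraction(5, tm), 0.2 + 0.75 / 2)  # half occupancy at ec50
  # monotonicity over random valid models
  set.seed(11)
  for (i in 1:20) {
    tmr <- translocation_model(f_min = runif(1, 0, 0.4),
                               f_max = runif(1, 0.5, 1),
                               ec50 = runif(1, 0.1, 100),
                               hill = runif(1, 0.3, 4))
    d <- sort(c(0, 10^runif(8, -2, 3)))
    expect_true(all(diff(hill_fraction(d, tmr)) >= 0))
  }
  expect_error(translocation_model(f_min = 0.5, f_max = 0.4), "f_min")
})

test_that("noise-free fields conserve GFP and match their label maps", {
  sim <- simulate_field(dose = 0, acq = fast_acq(), noise = noise_free(),
                        n_cells = 20, seed = 3, jitter_n_cells = FALSE)
  tc <- sim$truth$cells
  lab <- sim$truth$cell_label_map
  nuc <- sim$truth$nucleus_label_map
  for (i in tc$cell_id) {
    expect_equal(sum(sim$image$gfp[lab == i]), tc$total_gfp[tc$cell_id == i],
                 tolerance = 1e-9)
    expect_equal(sum(nuc == i), tc$nucleus_area_px[tc$cell_id == i])
    expect_equal(sum(lab == i) - sum(nuc == i),
                 tc$cytoplasm_area_px[tc$cell_id == i])
  }
  # nucleus pixels are a subset of same-id cell pixels; no overlap between cells
  expect_true(all(lab[nuc > 0] == nuc[nuc > 0]))
})

test_that("planted nuclear fraction drives the ground-truth ratio", {
  tm <- translocation_model(f_min = 0.2, f_max = 0.95, ec50 = 5, hill = 2)
  s0 <- simulate_field(dose = 0, acq = fast_acq(), transloc = tm,
                       noise = noise_free(), n_cells = 5, seed = 1)
  expect_true(all(s0$truth$cells$true_nuclear_fraction == 0.2))
  shi <- simulate_field(dose = 1e9, acq = fast_acq(), transloc = tm,
                        noise = noise_free(), n_cells = 5, seed = 1)
  expect_true(all(abs(shi$truth$cells$true_nuclear_fraction - 0.95) < 1e-6))
  # rendered image reproduces the analytic ratio exactly when noise-free
  tc <- shi$truth$cells[1, ]
  lab <- shi$truth$cell_label_map; nuc <- shi$truth$nucleus_label_map
  mn <- mean(shi$image$gfp[nuc == tc$cell_id])
  mc <- mean(shi$image$gfp[lab == tc$cell_id & nuc != tc$cell_id])
  expect_equal(mn / mc, tc$true_nc_ratio, tolerance = 1e-9)
})

test_that("plate simulation is seed-deterministic and dose-aware", {
  layout <- make_plate_layout(rows = 4, cols = 6, n_samples = 2,
                              n_replicates = 2, seed = 5)
  acq <- fast_acq(size = 128L, fields = 2L)
  p1 <- simulate_plate(layout, acq = acq, noise = noise_free(),
                       n_cells = 4, seed = 9, jitter_n_cells = FALSE)
  expect_length(p1, sum(layout$treatment_class != "empty") * 2)
  p2 <- simulate_plate(layout, acq = acq, noise = noise_free(),
                       n_cells = 4, seed = 9, jitter_n_cells = FALSE)
  expect_identical(p1[[1]]$image$gfp, p2[[1]]$image$gfp)
  expect_identical(p1[[7]]$truth$cells, p2[[7]]$truth$cells)
  # vehicle wells sit at the basal fraction
  tm <- translocation_model()
  veh <- layout$well_id[layout$treatment_class == "vehicle"]
  for (e in p1) {
    if (e$well_id %in% veh) {
      expect_true(all(e$truth$cells$true_nuclear_fraction == tm$f_min))
    }
  }
})

test_that("overcrowded fields fail with a density error", {
  expect_error(simulate_field(0, acq = fast_acq(128L), noise = noise_free(),
                              n_cells = 60, seed = 1,
                              jitter_n_cells = FALSE, max_attempts = 500),
               "reduce n_cells|too large")
})

test_that("simulated Cq tables follow the amplification model", {
  # 10-fold steps at perfect doubling: spacing log(10)/log(2) cycles
  sim <- simulate_qpcr(genes = "Tgm2",
                       fold_changes = data.frame(condition = "hit",
                                                 fold_change = 8),
                       efficiency = 1, cq_noise_sd = 0, seed = 1)
  dil <- sim$dilutions[sim$dilutions$gene == "Tgm2", ]
  expect_equal(diff(dil$cq[order(-dil$log10_quantity)]),
               rep(log(10) / log(2), nrow(dil) - 1), tolerance = 1e-9)
  cq <- sim$cq
  veh <- cq$cq[cq$gene == "Tgm2" & cq$condition == "DMSO"]
  hit <- cq$cq[cq$gene == "Tgm2" & cq$condition == "hit"]
  expect_equal(unique(hit - veh), -3)            # log2(8) cycles earlier
  ref <- cq[cq$gene == "Actb", ]
  expect_equal(unique(ref$cq), unique(veh))      # reference fold fixed at 1
  expect_error(simulate_qpcr("g", data.frame(condition = "x",
                                             fold_change = -1)),
               "positive")
  expect_error(simulate_qpcr("g", data.frame(condition = "x",
                                             fold_change = 2),
                             efficiency = 1.4),
               "efficiency")
})
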