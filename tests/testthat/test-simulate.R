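test_that("identical seed and config reproduce the simulation exactly", {
  cfg <- simulation_config(seed = 11, n_embryos = 2, store_replicates = TRUE)
  r1 <- simulate_embryos(cfg)
  r2 <- simulate_embryos(cfg)
  expect_identical(r1$datasets, r2$datasets)
  expect_identical(r1$truth$episodes, r2$truth$episodes)
  expect_false(identical(
    simulate_embryos(simulation_config(seed = 12, n_embryos = 2))$datasets,
    r1$datasets
  ))
})

test_that("a disparity-free noise-free configuration yields all-zero series", {
  cfg <- simulation_config(
    seed = 4, n_embryos = 2, noise_cv = 0,
    arc_disparity0 = 0, width_disparity0 = c(0, 0),
    p_delta0 = c(`0` = 1, `1` = 0, `2` = 0),
    p_delta_tF = c(`0` = 1, `1` = 0, `2` = 0),
    p_interstripe_delta = c(`0` = 1, `1` = 0, `2` = 0),
    p_peripheral_delta1 = 0, p_type2 = 0, p_other = 0,
    force_equalization = FALSE
  )
  res <- simulate_embryos(cfg)
  for (ds in res$datasets) {
    expect_identical(nrow(ds$events), 0L)
    expect_equal(max(abs(disparity_series(ds, "arc_length")$value)), 0)
    expect_equal(max(abs(disparity_series(ds, "dme_arc")$value)), 0)
    for (seg in c("A2", "A3", "A4")) {
      expect_equal(max(abs(disparity_series(ds, "width", seg, "stripe")$value)), 0)
      expect_equal(max(abs(disparity_series(ds, "dme_compartment", seg, "stripe")$value)), 0)
    }
  }
})

test_that("whole-arc counts change only at addition events, by their delta_n", {
  res <- simulate_embryos(simulation_config(seed = 17, n_embryos = 4))
  for (ds in res$datasets) {
    for (side in c("upper", "lower")) {
      fl <- ds$flanks[ds$flanks$side == side & !is.na(ds$flanks$N_cells), ]
      fl <- fl[order(fl$t_min), ]
      ev <- ds$events[ds$events$side %in% c(side, "both"), ]
      for (i in 2:nrow(fl)) {
        in_frame <- ev$t_min > fl$t_min[i - 1] & ev$t_min <= fl$t_min[i]
        expect_equal(fl$N_cells[i] - fl$N_cells[i - 1], sum(ev$delta_n[in_frame]))
      }
    }
  }
})

test_that("fusion order follows the configured chronology", {
  cfg <- simulation_config(seed = 1, n_embryos = 1)
  res <- simulate_embryos(cfg)
  tf <- res$datasets[[1]]$timeline$t_F
  expect_equal(unname(tf[c("Lb", "A7")]), c(-130, -130))
  # both arms converge monotonically on A3 at completion
  expect_true(all(diff(unname(tf[c("Lb", "T1", "T2", "T3", "A1", "A2", "A3")])) > 0))
  expect_true(all(diff(unname(tf[c("A8", "A6", "A5", "A4", "A3")])) > 0))
  expect_equal(unname(tf[["A3"]]), 0)
  # tension-deficient closure is delayed
  tfd <- simulate_embryos(simulation_config(seed = 1, n_embryos = 1,
                                            mode = "tension_deficient"))$datasets[[1]]$timeline$t_F
  expect_true(all(tfd[c("Lb", "A7")] > tf[c("Lb", "A7")]))
})

test_that("configured disparity probabilities are recovered from many pairs", {
  res <- simulate_embryos(simulation_config(seed = 31, n_embryos = 110))
  pairs <- res$truth$pairs
  free <- pairs[pairs$segment_id %in% c("A2", "A4"), ] # not scenario-forced
  expect_gte(nrow(free), 200)
  p1 <- mean(free$delta0 == 1)
  ci <- 1.96 * sqrt(0.4 * 0.6 / nrow(free))
  expect_lt(abs(p1 - 0.4), ci + 0.035)
  # no control stripe pair retains a two-cell disparity at fusion
  central <- pairs[pairs$segment_id %in% c("A2", "A3", "A4"), ]
  expect_true(all(central$delta_tF <= 1))
})

test_that("interlock completion times recover the configured kinetics", {
  res <- simulate_embryos(simulation_config(seed = 23, n_embryos = 4))
  tr <- res$truth$interfaces
  tau <- tr$interlock_time[!is.na(tr$interlock_time)]
  expect_gte(length(tau), 50)
  sem <- stats::sd(tau) / sqrt(length(tau))
  expect_lt(abs(mean(tau) - 15.9), 3 * sem)

  resb <- simulate_embryos(simulation_config(seed = 23, n_embryos = 6, mode = "baz_deficient"))
  taub <- resb$truth$interfaces$interlock_time
  taub <- taub[!is.na(taub)]
  semb <- stats::sd(taub) / sqrt(length(taub))
  expect_lt(abs(mean(taub) - 24.6), 3 * semb)
  # interlocking is delayed relative to control with the configured gap
  expect_gt(mean(taub), mean(tau))
})

test_that("mean eligible-interface angles recover the configured values", {
  res <- simulate_embryos(simulation_config(seed = 29, n_embryos = 6, mode = "baz_deficient"))
  post <- do.call(rbind, lapply(res$datasets, function(d) d$interfaces))
  post <- post[post$stage == "post_fusion", ]
  m <- mean_interface_angle(post)
  expect_lt(abs(m$mean_deg - 32.3), 3 * m$sem_deg)
})

test_that("interface geometry classes match ground truth in every labeled case", {
  for (mode in c("control", "tension_deficient", "baz_deficient")) {
    res <- simulate_embryos(simulation_config(seed = 37, n_embryos = 2, mode = mode))
    ifc <- do.call(rbind, lapply(res$datasets, function(d) d$interfaces))
    lab <- classify_interfaces(ifc)
    m <- merge(lab[, c("interface_id", "label")],
               res$truth$interfaces[, c("interface_id", "class")],
               by = "interface_id")
    expect_equal(nrow(m), nrow(res$truth$interfaces))
    expect_identical(m$label, m$class)
  }
})

test_that("defect calls on snapshots match ground truth across modes", {
  for (mode in c("control", "tension_deficient")) {
    res <- simulate_embryos(simulation_config(seed = 41, n_embryos = 3, mode = mode))
    defs <- do.call(rbind, lapply(res$datasets, interlocking_defects))
    m <- merge(defs, res$truth$snapshots,
               by = c("embryo_id", "segment_id", "compartment", "side"))
    expect_equal(nrow(m), nrow(res$truth$snapshots))
    expect_identical(m$status.x, m$status.y)
    assessable <- m[m$status.y != "not_assessable", ]
    if (mode == "control") {
      expect_true(all(assessable$status.y == "not_defective"))
    } else {
      expect_true(all(assessable$status.y == "defective"))
    }
  }
})

test_that("stripes carry about half as many DME cells as interstripes", {
  res <- simulate_embryos(simulation_config(seed = 43, n_embryos = 8))
  cp <- do.call(rbind, lapply(res$datasets, function(d) d$compartments))
  cp <- cp[!is.na(cp$n_cells), ]
  ratio <- mean(cp$n_cells[cp$compartment == "stripe"]) /
    mean(cp$n_cells[cp$compartment == "interstripe"])
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.7)
})

test_that("worked fixtures give their hand-computed values", {
  eq <- make_fixture("equal_pair")
  expect_equal(max(abs(disparity_series(eq, "dme_arc")$value)), 0)
  expect_equal(max(abs(disparity_series(eq, "width", "A3", "stripe")$value)), 0)

  gap <- make_fixture("one_cell_gap")
  s <- disparity_series(gap, "dme_compartment", "A3", "stripe")
  expect_equal(unique(s$value), 1 / 2.5) # delta = 1 over mean 2.5

  def <- make_fixture("defective_stripe")
  defs <- interlocking_defects(def)
  expect_identical(defs$status[defs$segment_id == "A2"], "defective")
  expect_identical(defs$status[defs$segment_id == "Lb"], "not_assessable")

  expect_error(make_fixture("no_such_fixture"))
})
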