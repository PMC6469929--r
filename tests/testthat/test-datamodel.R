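test_that("replicate averaging is the plain arithmetic mean", {
  expect_equal(replicate_average(c(100, 102, 98, 101, 99, 100)), 100)
  expect_equal(replicate_average(7), 7)
  expect_equal(replicate_average(c(10, 11, 10, 10, 11, 11)), 10.5)
  expect_error(replicate_average(numeric(0)), "at least one")
})

test_that("timeline convention enforces retrospective ordering and grids", {
  tl <- timeline_convention(-190, c(A3 = 0, A2 = -20))
  expect_s3_class(tl, "timeline_convention")
  expect_error(timeline_convention(-190, c(A3 = 10)), "non-positive")
  expect_error(timeline_convention(-10, c(A3 = -20)), "t_E")
  expect_error(timeline_convention(-190, c(Z9 = 0)), "unknown segment")
  expect_error(
    timeline_convention(-190, c(A3 = 0), frame_interval_length = 2, frame_interval_count = 5),
    "multiple"
  )
})

test_that("retrospective mapping is an order-preserving affine shift", {
  ds <- make_fixture("equal_pair")
  prospective <- ds
  prospective$timeline$t_E <- ds$timeline$t_E + 190
  prospective$timeline$t_F <- ds$timeline$t_F + 190
  prospective$flanks$t_min <- ds$flanks$t_min + 190
  prospective$compartments$t_min <- ds$compartments$t_min + 190
  prospective$compartments$visible_from <- ds$compartments$visible_from + 190
  prospective$interfaces$t_min <- ds$interfaces$t_min + 190

  retro <- to_retrospective(prospective)
  expect_equal(retro$flanks$t_min, ds$flanks$t_min)
  expect_equal(retro$timeline$t_F, ds$timeline$t_F)
  # pairwise differences conserved exactly
  expect_equal(diff(retro$flanks$t_min), diff(prospective$flanks$t_min))
  # idempotent on an already-retrospective dataset
  expect_identical(to_retrospective(ds), ds)
})

test_that("t_minus resolves landmarks relative to a segment's fusion", {
  ds <- make_fixture("equal_pair")
  ds$timeline$t_F[["A3"]] <- -30
  expect_equal(t_minus(ds, "A3", 100), -130)
  expect_equal(t_minus(ds, "A2"), -110)
  expect_error(t_minus(ds, "A8"), "no fusion time")
})

test_that("validation rejects single-field violations of each invariant", {
  base <- make_fixture("defective_stripe")
  expect_silent(validate_dataset(base))

  corruptions <- list(
    list(tab = "compartments", col = "W_um", val = -1, msg = "nonpositive fusing-front width"),
    list(tab = "compartments", col = "n_cells", val = 0, msg = "integer >= 1"),
    list(tab = "compartments", col = "segment_id", val = "A9", msg = "A9"),
    list(tab = "flanks", col = "L_um", val = 0, msg = "nonpositive arc length"),
    list(tab = "flanks", col = "N_cells", val = -2, msg = "non-negative integer"),
    list(tab = "flanks", col = "N_cells", val = 2.5, msg = "non-negative integer"),
    list(tab = "flanks", col = "side", val = "top", msg = "not in"),
    list(tab = "interfaces", col = "angle_deg", val = 95, msg = "\\[0, 90\\]"),
    list(tab = "interfaces", col = "vdeg_a", val = 1L, msg = "vertex degree"),
    list(tab = "interfaces", col = "length_um", val = -0.5, msg = "nonpositive interface length"),
    list(tab = "intensities", col = "I_DV", val = 0, msg = "must be positive"),
    list(tab = "intensities", col = "I", val = -1, msg = "negative"),
    list(tab = "snapshots", col = "dv_length_um", val = 0, msg = "must be positive")
  )
  for (cr in corruptions) {
    ds <- base
    ds[[cr$tab]][[cr$col]][1] <- cr$val
    expect_error(validate_dataset(ds), cr$msg,
                 class = "fusefid_validation_error",
                 label = paste(cr$tab, cr$col))
  }

  # an event referencing a segment with no stripe track
  ds <- base
  ds$events <- data.frame(
    embryo_id = "fx_def", segment_id = "A8", side = "upper", t_min = -10,
    source = "mixer_cell", delta_n = 1L, stringsAsFactors = FALSE
  )
  expect_error(validate_dataset(ds), "A8", class = "fusefid_validation_error")

  # an event outside the visible window of its track
  ds <- base
  ds$events <- data.frame(
    embryo_id = "fx_def", segment_id = "A3", side = "upper", t_min = -120,
    source = "mixer_cell", delta_n = 1L, stringsAsFactors = FALSE
  )
  expect_error(validate_dataset(ds), "outside visible window",
               class = "fusefid_validation_error")

  # missing one flank
  ds <- base
  ds$flanks <- ds$flanks[ds$flanks$side == "upper", ]
  expect_error(validate_dataset(ds), "missing lower flank",
               class = "fusefid_validation_error")
})

test_that("stored arc lengths must equal the mean of their replicate tracings", {
  res <- simulate_embryos(simulation_config(seed = 42, n_embryos = 1,
                                            store_replicates = TRUE))
  ds <- res$datasets[[1]]
  expect_silent(validate_dataset(ds))
  ds$flanks$L_um[5] <- ds$flanks$L_um[5] + 1
  expect_error(validate_dataset(ds), "arithmetic mean",
               class = "fusefid_validation_error")
})
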