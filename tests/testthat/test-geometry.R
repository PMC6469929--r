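test_that("chord angle is the acute angle to the A/P axis", {
  expect_equal(chord_angle(rbind(c(0, 0), c(5, 0))), 0)
  expect_equal(chord_angle(rbind(c(0, 0), c(0, 5))), 90)
  expect_equal(chord_angle(rbind(c(0, 0), c(1, 1))), 45)
  expect_error(chord_angle(rbind(c(1, 1), c(1, 1))), "degenerate")
  expect_error(chord_angle(rbind(c(1, 1))), "two points")
})

test_that("chord angle is invariant to orientation, translation and reflection", {
  set.seed(7)
  for (i in 1:50) {
    p <- matrix(stats::runif(6, -10, 10), ncol = 2)
    a <- chord_angle(p)
    expect_gte(a, 0)
    expect_lte(a, 90)
    expect_equal(chord_angle(p[3:1, ]), a) # reversal
    shift <- matrix(rep(stats::runif(2, -5, 5), each = 3), ncol = 2)
    expect_equal(chord_angle(p + shift), a) # translation
    expect_equal(chord_angle(p * matrix(rep(c(-1, 1), each = 3), ncol = 2)), a)
    expect_equal(chord_angle(p * matrix(rep(c(1, -1), each = 3), ncol = 2)), a)
  }
})

test_that("polyline length and sinuosity follow from the geometry", {
  p <- grid_polyline(30, 1.2, chord = 2)
  expect_equal(polyline_sinuosity(p), 1.2)
  expect_equal(polyline_length(p), 2 * 1.2)
  expect_equal(polyline_sinuosity(grid_polyline(45, 1)), 1)
})

iface <- function(angle, sinuosity = 1, length_um = 2, segment = "A3",
                  connects = TRUE, curved_flag = NA) {
  list(
    segment_id = segment, angle_deg = angle, sinuosity = sinuosity,
    length_um = length_um, connects_two_DV = connects, curved_flag = curved_flag
  )
}

test_that("interface classification matches the documented bins", {
  expect_identical(classify_interface(iface(45))$label, "angular")
  expect_identical(classify_interface(iface(10))$label, "straight")
  expect_identical(classify_interface(iface(45, length_um = 0.8))$label, "ineligible")
  expect_identical(classify_interface(iface(45, segment = "Lb"))$label, "ineligible")
  expect_identical(classify_interface(iface(45, segment = "A7"))$label, "ineligible")
  expect_identical(classify_interface(iface(45, connects = FALSE))$label, "ineligible")
  expect_identical(classify_interface(iface(45, sinuosity = 1.06))$label, "curved")
  expect_identical(classify_interface(iface(10, curved_flag = TRUE))$label, "curved")
  # the 20-degree boundary goes to angular (closed lower bound)
  expect_identical(classify_interface(iface(20))$label, "angular")
  expect_identical(classify_interface(iface(19.9))$label, "straight")
  # both knobs are configurable
  expect_identical(classify_interface(iface(22), angle_split = 25)$label, "straight")
  expect_identical(classify_interface(iface(45, sinuosity = 1.06), sinuosity_threshold = 1.1)$label, "angular")
})

test_that("classification from a polyline agrees with stored fields", {
  p <- grid_polyline(40, 1)
  rec <- list(segment_id = "A3", connects_two_DV = TRUE,
              polyline = jsonlite::toJSON(p), angle_deg = NA_real_,
              sinuosity = NA_real_, length_um = NA_real_)
  expect_identical(classify_interface(rec)$label, "angular")
})

test_that("mean interface angle averages eligible records with a sem", {
  recs <- rbind(
    data.frame(segment_id = "A3", compartment = "stripe", angle_deg = 30,
               sinuosity = 1, length_um = 2, connects_two_DV = TRUE,
               curved_flag = FALSE, polyline = "", stringsAsFactors = FALSE),
    data.frame(segment_id = "A3", compartment = "stripe", angle_deg = 50,
               sinuosity = 1, length_um = 2, connects_two_DV = TRUE,
               curved_flag = FALSE, polyline = "", stringsAsFactors = FALSE)
  )
  m <- mean_interface_angle(recs)
  expect_equal(m$mean_deg, 40)
  expect_equal(m$n, 2L)
  single <- mean_interface_angle(recs[1, ])
  expect_equal(single$mean_deg, 30)
  expect_true(is.na(single$sem_deg))
  recs$connects_two_DV <- FALSE
  expect_error(mean_interface_angle(recs), "no eligible")
})

test_that("interlocking requires an angular label and two degree-3 vertices", {
  expect_true(interlocked(3, 3, "angular"))
  expect_false(interlocked(4, 4, "straight"))
  expect_false(interlocked(3, 3, "curved"))
  expect_false(interlocked(3, 4, "angular"))
})

snap <- function(lacking, n = 10, segment = "A2", stage = "post_closure",
                 distance = 15, central = FALSE) {
  data.frame(
    segment_id = segment, stage = stage,
    distance_from_canthus_cells = distance, is_central_most = central,
    has_interlocked_interface = seq_len(n) > lacking,
    stringsAsFactors = FALSE
  )
}

test_that("the 70% interlocking-defect boundary and exclusions hold", {
  expect_identical(interlocking_defective(snap(7)), "defective")
  expect_identical(interlocking_defective(snap(6)), "not_defective")
  expect_identical(interlocking_defective(snap(7, n = 10)), "defective") # 70% exactly
  expect_identical(interlocking_defective(snap(7, segment = "Lb")), "not_assessable")
  expect_identical(interlocking_defective(snap(7, segment = "A7")), "not_assessable")
  expect_identical(interlocking_defective(snap(7, stage = "closure", distance = 9)), "not_assessable")
  expect_identical(interlocking_defective(snap(7, stage = "closure", distance = 10)), "defective")
  expect_identical(interlocking_defective(snap(7, central = TRUE)), "not_assessable")
  expect_error(interlocking_defective(snap(0)[0, ]), "empty cell list")
})

test_that("gaining an interlocked interface never flips not-defective to defective", {
  for (lacking in 0:10) {
    s <- snap(lacking)
    status <- interlocking_defective(s)
    if (lacking > 0) {
      s2 <- s
      s2$has_interlocked_interface[lacking] <- TRUE # one fewer lacking cell
      status2 <- interlocking_defective(s2)
      if (status == "not_defective") expect_identical(status2, "not_defective")
    }
  }
})

test_that("alignment index is zero for vertical boundaries and symmetric", {
  expect_equal(alignment_index(c(0, 10), c(0, 0)), 0)
  a75 <- c(cos(75 * pi / 180), sin(75 * pi / 180))
  expect_equal(alignment_index(a75, c(0, 0)), 15)
  expect_equal(alignment_index(c(0, 0), a75), 15) # swap-symmetric
  expect_error(alignment_index(c(1, 1), c(1, 1)), "coincide")
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(2, -5, 5)
    q <- stats::runif(2, -5, 5)
    th <- alignment_index(p, q)
    expect_gte(th, 0)
    expect_lte(th, 90)
  }
})

test_that("aspect ratio and its high fraction behave as defined", {
  expect_equal(aspect_ratio(10, 2), 5)
  expect_equal(aspect_ratio(3, 3), 1)
  expect_error(aspect_ratio(0, 2), "positive")
  expect_equal(high_ar_fraction(c(5, 6, 7)), 2 / 3) # >= cutoff is inclusive
  expect_equal(high_ar_fraction(c(5, 6, 7), cutoff = 8), 0)
})
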