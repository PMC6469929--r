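test_that("norm_diff matches its definition on forced cases", {
  expect_equal(norm_diff(100, 100), 0)
  expect_equal(norm_diff(120, 80), 0.4)
  expect_equal(norm_diff(3, 0), 2) # algebraic boundary, one count zero
  expect_equal(norm_diff(0, 3), -2)
  expect_error(norm_diff(0, 0), "both paired measurements are zero")
  expect_error(norm_diff(-1, 5), "non-negative")
})

test_that("norm_diff is antisymmetric, zero iff equal, bounded and scale-free", {
  set.seed(1)
  a <- stats::runif(500, 0.01, 1000)
  b <- stats::runif(500, 0.01, 1000)
  k <- stats::runif(500, 0.01, 50)
  expect_equal(norm_diff(a, b), -norm_diff(b, a))
  expect_equal(norm_diff(a, a), rep(0, 500))
  expect_true(all(norm_diff(a, b) == 0 | a != b))
  expect_true(all(abs(norm_diff(a, b)) < 2))
  expect_equal(norm_diff(k * a, k * b), norm_diff(a, b))
})

test_that("disparity series equal hand arithmetic frame by frame", {
  # constant equal tracks -> all-zero series
  ds0 <- hand_dataset(rep(100, 10), rep(100, 10))
  s0 <- disparity_series(ds0, "arc_length")
  expect_equal(s0$value, rep(0, 10))

  # upper grows linearly while lower stays flat; oracle is per-frame
  # arithmetic written out explicitly
  t <- seq(-100, 0, by = 5)
  upper <- 100 + (t + 100) / 10
  lower <- rep(100, length(t))
  ds <- hand_dataset(upper, lower, t = t)
  s <- disparity_series(ds, "arc_length")
  expected <- (upper - lower) / ((upper + lower) / 2)
  expect_equal(s$value, expected)
  expect_equal(s$t_min, t)
  expect_identical(attr(s, "descriptor"), "arc_length")
  expect_identical(attr(s, "pair_id"), "whole-arc")
})

test_that("whole-arc count series default to the [-100, 0] window", {
  t <- seq(-150, 0, by = 5)
  ds <- hand_dataset(rep(100, length(t)), rep(100, length(t)), t = t,
                     upper_N = rep(21, length(t)), lower_N = rep(20, length(t)))
  s <- disparity_series(ds, "dme_arc")
  expect_equal(range(s$t_min), c(-100, 0))
  expect_equal(s$value, rep(norm_diff(21, 20), length(s$t_min)))
  # but the length series keeps the full tracked range
  expect_equal(min(disparity_series(ds, "arc_length")$t_min), -150)
})

test_that("pairs with disjoint visibility yield an empty flagged series", {
  ds <- make_fixture("equal_pair")
  cp <- ds$compartments
  keep_u <- !(cp$side == "upper" & cp$segment_id == "A2" & cp$compartment == "stripe" & cp$t_min > -30)
  keep_l <- !(cp$side == "lower" & cp$segment_id == "A2" & cp$compartment == "stripe" & cp$t_min <= -30)
  ds$compartments <- cp[keep_u & keep_l, ]
  s <- disparity_series(ds, "width", "A2", "stripe")
  expect_identical(nrow(s), 0L)
  expect_true(attr(s, "empty"))
  expect_error(disparity_series(ds, "width", "A6", "stripe"),
               class = "fusefid_validation_error")
})

test_that("equalization time follows the terminal-run definition", {
  mk <- function(values) {
    structure(
      data.frame(t_min = seq(-5 * (length(values) - 1), 0, by = 5), value = values),
      class = c("disparity_series", "data.frame"), descriptor = "dme_arc"
    )
  }
  # forced by definition: first frame of the terminal zero run
  s <- mk(c(0.4, 0.2, 0, 0, 0))
  expect_equal(equalization_time(s, epsilon = 0, hold = 2), s$t_min[3])
  # never inside the band -> undefined
  expect_true(is.na(equalization_time(mk(c(0.4, 0.3, 0.2)), epsilon = 0.05)))
  # transient re-divergence pushes detection later
  s2 <- mk(c(0.4, 0, 0, 0.3, 0, 0))
  expect_equal(equalization_time(s2, epsilon = 0, hold = 2), s2$t_min[5])
  # terminal run shorter than `hold` -> undefined
  expect_true(is.na(equalization_time(mk(c(0.4, 0.2, 0)), epsilon = 0, hold = 2)))
  # descriptor-specific default epsilon: counts demand exact equality
  expect_true(is.na(equalization_time(mk(c(0.04, 0.04, 0.04, 0.04)))))
  expect_equal(equalization_time(mk(rep(0, 4))), -15)
})

test_that("ddme variance is the population variance averaged over embryos", {
  v <- ddme_variance(list(e1 = c(0, 1, 2)))
  expect_equal(v$per_embryo_sigma2[["e1"]], 2 / 3) # mu = 1, SS = 2, N = 3
  expect_equal(v$var_ddme, 2 / 3)
  expect_equal(ddme_variance(list(a = c(1, 1, 1)))$var_ddme, 0)
  # arithmetic mean of per-embryo variances: 0.5 and 1.5 -> 1.0
  v2 <- ddme_variance(list(
    a = sqrt(0.5) * c(-1, 1),
    b = sqrt(1.5) * c(-1, 1)
  ))
  expect_equal(unname(v2$per_embryo_sigma2), c(0.5, 1.5))
  expect_equal(v2$var_ddme, 1.0)
  expect_error(ddme_variance(list()), "at least one embryo")
})

test_that("constriction index is width per cell and linear in width", {
  expect_equal(constriction_index(30, 6), 5)
  expect_equal(constriction_index(17.3, 1), 17.3)
  expect_error(constriction_index(30, 0), "at least one")
  expect_error(constriction_index(0, 3), "positive width")
  set.seed(2)
  W <- stats::runif(100, 5, 50)
  N <- sample(1:9, 100, replace = TRUE)
  expect_equal(constriction_index(2 * W, N), 2 * constriction_index(W, N))
})

test_that("intensity normalization divides by the D/V reference", {
  expect_equal(normalized_intensity(2, 2), 1)
  expect_equal(normalized_intensity(3, 2), 1.5)
  expect_error(normalized_intensity(3, 0), "positive")
  expect_error(normalized_intensity(-1, 2), "non-negative")
  rec <- data.frame(I = c(4, 3, 2), I_DV = c(2, 2, 2))
  expect_equal(normalized_intensity(rec), c(2, 1.5, 1))
  expect_true(all(diff(normalized_intensity(rec)) < 0))
})

test_that("arc disparity shrinks between -190 and -100 min in control embryos", {
  res <- simulate_embryos(simulation_config(seed = 8, n_embryos = 6))
  at <- function(s, t) abs(s$value[which.min(abs(s$t_min - t))])
  early <- late <- numeric(0)
  for (ds in res$datasets) {
    s <- disparity_series(ds, "arc_length")
    early <- c(early, at(s, -190))
    late <- c(late, at(s, -100))
  }
  expect_lt(stats::median(late), stats::median(early))
})
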