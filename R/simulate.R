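# Seeded phenomenological generator of embryo datasets. It emulates the
# tracked measurement tables at the level of the measurements themselves
# (no mechanical tissue model): scheduled discrete cell-addition events
# plus width relaxation drive disparity decay, interface records follow
# the en-face -> interlocked remodelling schedule, and every emitted
# record carries a ground-truth entry for the downstream classifiers.

rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower)
}

# Beta sample rescaled to [lo, hi] with exact mean `mean` (no truncation
# bias, so configured population means are recovered by sample averages).
rbeta_mean <- function(n, lo, hi, mean, k = 25) {
  p <- (mean - lo) / (hi - lo)
  stopifnot(p > 0, p < 1)
  lo + (hi - lo) * stats::rbeta(n, k * p, k * (1 - p))
}

MODE_PRESETS <- list(
  control = list(
    fusion_delay = 0,
    p_delta_tF = c(`0` = 0.538, `1` = 0.462, `2` = 0),
    p_type2 = 0.3, p_other = 0.15,
    force_equalization = TRUE,
    width_endfactor_stripe = 0.6, width_endfactor_interstripe = 0.28,
    interface_class_probs = c(straight = 0.15, angular = 0.75, curved = 0.10),
    mean_interface_angle = 39.7,
    interlock_time = 15.9, bazooka_recruitment_delay = 11.2,
    bazooka_recruitment_sd = 2.5,
    actin_clearance_time = 10.9,
    snapshot_lacking_range = c(0.05, 0.30),
    angular_vertex_degree = 3L,
    actin_interlocked_ratio = 0.9
  ),
  tension_deficient = list(
    fusion_delay = 20,
    p_delta_tF = NULL, # disparities invariant: delta at fusion = initial delta
    p_type2 = 0, p_other = 0,
    force_equalization = FALSE,
    width_endfactor_stripe = 1, width_endfactor_interstripe = 1,
    interface_class_probs = c(straight = 0.55, angular = 0.10, curved = 0.35),
    mean_interface_angle = 18,
    interlock_time = NA_real_, bazooka_recruitment_delay = 11.2,
    bazooka_recruitment_sd = 2.5,
    actin_clearance_time = 25,
    snapshot_lacking_range = c(0.75, 0.95),
    angular_vertex_degree = 4L,
    actin_interlocked_ratio = 1.5
  ),
  baz_deficient = list(
    fusion_delay = 0,
    p_delta0 = c(`0` = 0.15, `1` = 0.3, `2` = 0.55),
    p_delta_tF = c(`0` = 0.234, `1` = 0.35, `2` = 0.416),
    p_type2 = 0.3, p_other = 0.15,
    force_equalization = TRUE,
    width_endfactor_stripe = 0.8, width_endfactor_interstripe = 0.5,
    interface_class_probs = c(straight = 0.25, angular = 0.35, curved = 0.40),
    mean_interface_angle = 32.3,
    interlock_time = 24.6, bazooka_recruitment_delay = 20.4,
    bazooka_recruitment_sd = 6,
    actin_clearance_time = 25,
    snapshot_lacking_range = c(0.75, 0.95),
    angular_vertex_degree = 3L,
    actin_interlocked_ratio = 1.7
  )
)

#' Configuration of the synthetic-embryo generator
#'
#' Defaults encode the study conditions the generator emulates: closure
#' runs on a retrospective axis from `t_E = -190` min; Lb and A7 fuse
#' around -130 min, zippering onset is at -100 min and the central
#' segments fuse in succession until A3 completes closure at 0. Length and
#' width tracings are sampled every minute with 2% multiplicative Gaussian
#' tracing noise averaged over six replicate tracings; cell counts sit on
#' the exact 5-minute grid. Whole-arc length disparity decays so that its
#' expected magnitude crosses the 0.05 detection band at `t_len_eq = -100`
#' min; whole-arc count disparity reaches zero at `t_count_eq = -50` min
#' through scheduled addition events (arc length equalizes before cell
#' number). Stripe counts are about half the interstripe counts. Interface
#' remodelling and snapshot parameters switch with `mode`: control
#' interfaces interlock 15.9 min after fusion at a mean eligible-interface
#' angle of 39.7 deg; `baz_deficient` delays recruitment and interlocking
#' (24.6 min), lowers the mean angle to 32.3 deg, shifts the
#' \eqn{\Delta}DME-at-fusion mass toward 2 and keeps actin on fused
#' interfaces; `tension_deficient` freezes the disparities in time, delays
#' fusion, leaves interfaces straight/curved and makes at least 70% of
#' snapshot cells lack interlocked interfaces.
#'
#' @param seed Integer RNG seed; identical (seed, config) pairs produce
#'   byte-identical serialized datasets.
#' @param n_embryos Number of embryos to generate.
#' @param mode `"control"`, `"tension_deficient"` or `"baz_deficient"`.
#' @param chronology Named fusion-time map (minutes, retrospective, on the
#'   5-min grid).
#' @param t_E Earliest analyzable frame (minutes).
#' @param arc_length_start,arc_length_end Arc length (um) at `t_E` and at
#'   completion.
#' @param arc_disparity0 Initial magnitude of the normalized arc-length
#'   difference.
#' @param t_len_eq,len_eq_epsilon,len_ramp_slope Length-equalization
#'   target: the expected disparity magnitude crosses `len_eq_epsilon`
#'   exactly at `t_len_eq`, decaying linearly at `len_ramp_slope` per
#'   minute.
#' @param t_count_eq Whole-arc count-equalization time (minutes).
#' @param arc_n_base Baseline whole-arc DME cell count.
#' @param noise_cv Coefficient of variation of one manual tracing.
#' @param n_replicates Tracings averaged per stored arc length.
#' @param store_replicates Keep the individual tracings in the dataset.
#' @param stripe_n_range,interstripe_n_range Inclusive ranges of baseline
#'   compartment DME counts.
#' @param stripe_width,interstripe_width `c(mean, sd)` of initial front
#'   widths (um).
#' @param width_contraction Fractional width decrease over the visible
#'   window.
#' @param width_disparity0 `c(min, max)` of the initial normalized width
#'   difference magnitude.
#' @param width_event_relief Multiplier applied to the width disparity for
#'   5 minutes after a cell addition (transient width equalization).
#' @param p_delta0 Probabilities of initial \eqn{\Delta}DME 0/1/2 for
#'   central stripe pairs.
#' @param p_interstripe_delta Probabilities of the persistent interstripe
#'   \eqn{\Delta}DME.
#' @param p_peripheral_delta1 Probability that a peripheral stripe pair
#'   carries a persistent one-cell disparity.
#' @param mixer_fraction Fraction of addition events sourced from mixer
#'   cells (the rest are posterior intercalating cells).
#' @param interlock_time_sd SD (min) of the interlock-completion time.
#' @param actin_clearance_sd SD (min) of the actin clearance time.
#' @param interfaces_per_compartment,interface_segments Interface records
#'   emitted per central compartment.
#' @param snapshot_segments Segments receiving post-closure cell
#'   snapshots.
#' @param intensity_noise_cv CV of intensity measurements.
#' @param central_segments Segments treated as central (scenario-driven
#'   stripe pairs; A3 fuses last and completes closure).
#' @param ... Mode-preset overrides: `fusion_delay`, `p_delta_tF`,
#'   `p_type2`, `p_other`, `force_equalization`,
#'   `width_endfactor_stripe`, `width_endfactor_interstripe`,
#'   `interface_class_probs`, `mean_interface_angle`, `interlock_time`,
#'   `bazooka_recruitment_delay`, `bazooka_recruitment_sd`,
#'   `actin_clearance_time`, `snapshot_lacking_range`,
#'   `angular_vertex_degree`, `actin_interlocked_ratio`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_embryos = 1L,
                              mode = c("control", "tension_deficient", "baz_deficient"),
                              chronology = c(
                                Lb = -130, T1 = -95, T2 = -80, T3 = -60,
                                A1 = -45, A2 = -20, A3 = 0, A4 = -35,
                                A5 = -70, A6 = -90, A7 = -130, A8 = -135
                              ),
                              t_E = -190,
                              arc_length_start = 350, arc_length_end = 8,
                              arc_disparity0 = 0.2,
                              t_len_eq = -100, len_eq_epsilon = 0.05,
                              len_ramp_slope = 1 / 150,
                              t_count_eq = -50,
                              arc_n_base = 110L,
                              noise_cv = 0.02, n_replicates = 6L,
                              store_replicates = FALSE,
                              stripe_n_range = c(3L, 5L),
                              interstripe_n_range = c(6L, 9L),
                              stripe_width = c(18, 2),
                              interstripe_width = c(32, 3),
                              width_contraction = 0.25,
                              width_disparity0 = c(0.10, 0.25),
                              width_event_relief = 0.3,
                              p_delta0 = c(`0` = 0.3, `1` = 0.4, `2` = 0.3),
                              p_interstripe_delta = c(`0` = 0.57, `1` = 0.30, `2` = 0.13),
                              p_peripheral_delta1 = 0.3,
                              mixer_fraction = 0.6,
                              interlock_time_sd = 5,
                              actin_clearance_sd = 2,
                              interfaces_per_compartment = 6L,
                              interface_segments = c("A2", "A3", "A4"),
                              snapshot_segments = c("A1", "A2", "A3", "A4", "A5"),
                              intensity_noise_cv = 0.10,
                              central_segments = c("A2", "A3", "A4"),
                              ...) {
  mode <- match.arg(mode)
  cfg <- list(
      seed = as.integer(seed), n_embryos = as.integer(n_embryos), mode = mode,
      chronology = chronology, t_E = t_E,
      arc_length_start = arc_length_start, arc_length_end = arc_length_end,
      arc_disparity0 = arc_disparity0,
      t_len_eq = t_len_eq, len_eq_epsilon = len_eq_epsilon,
      len_ramp_slope = len_ramp_slope, t_count_eq = t_count_eq,
      arc_n_base = as.integer(arc_n_base),
      noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
      store_replicates = store_replicates,
      stripe_n_range = stripe_n_range, interstripe_n_range = interstripe_n_range,
      stripe_width = stripe_width, interstripe_width = interstripe_width,
      width_contraction = width_contraction,
      width_disparity0 = width_disparity0,
      width_event_relief = width_event_relief,
      p_delta0 = p_delta0, p_interstripe_delta = p_interstripe_delta,
      p_peripheral_delta1 = p_peripheral_delta1,
      mixer_fraction = mixer_fraction,
      interlock_time_sd = interlock_time_sd,
      actin_clearance_sd = actin_clearance_sd,
      interfaces_per_compartment = as.integer(interfaces_per_compartment),
      interface_segments = interface_segments,
      snapshot_segments = snapshot_segments,
      intensity_noise_cv = intensity_noise_cv,
      central_segments = central_segments
    )
  preset <- MODE_PRESETS[[mode]]
  cfg[names(preset)] <- preset
  overrides <- list(...)
  allowed <- unique(unlist(lapply(MODE_PRESETS, names)))
  bad <- setdiff(names(overrides), allowed)
  if (length(bad)) stop("unknown simulation_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$p_delta_tF)) {
    # at-fusion disparities are reached by disparity-reducing events, so
    # the at-fusion distribution must be stochastically below the initial
    # one (comonotone coupling feasibility)
    for (k in 2:3) {
      if (sum(cfg$p_delta_tF[k:3]) > sum(cfg$p_delta0[k:3]) + 1e-9) {
        stop("p_delta_tF is not stochastically dominated by p_delta0")
      }
    }
  }
  stopifnot(
    all(names(cfg$chronology) %in% SEGMENT_IDS),
    all(cfg$chronology <= 0), cfg$t_E <= min(cfg$chronology),
    abs(sum(cfg$p_delta0) - 1) < 1e-9,
    is.null(cfg$p_delta_tF) || abs(sum(cfg$p_delta_tF) - 1) < 1e-9,
    abs(sum(cfg$p_interstripe_delta) - 1) < 1e-9,
    abs(sum(cfg$interface_class_probs) - 1) < 1e-9,
    cfg$noise_cv >= 0, cfg$n_replicates >= 1
  )
  structure(cfg, class = "simulation_config")
}

# Class-conditional mean for angular/curved chords such that the mixture
# over {straight ~ mean 10 deg, angular, curved} hits the configured mean.
angular_class_mean <- function(cfg) {
  p <- cfg$interface_class_probs
  m <- (cfg$mean_interface_angle - p[["straight"]] * 10) /
    (p[["angular"]] + p[["curved"]])
  if (m <= 21 || m >= 89) {
    stop("configured mean interface angle is unreachable with these class probabilities")
  }
  m
}

noisy_tracing <- function(true, cv, n_rep) {
  n <- length(true)
  if (cv == 0) {
    reps <- matrix(rep(true, n_rep), nrow = n)
  } else {
    reps <- matrix(true * (1 + stats::rnorm(n * n_rep, 0, cv)), nrow = n)
  }
  reps <- round(reps, 4)
  list(mean = round(rowMeans(reps), 4), reps = reps)
}

polyline_json <- function(p) {
  paste0("[", paste(sprintf("[%s,%s]", format_roundtrip(p[, 1]), format_roundtrip(p[, 2])),
                    collapse = ","), "]")
}

make_interface_polyline <- function(angle_deg, sinuosity) {
  x0 <- round(stats::runif(1, 0, 60), 4)
  y0 <- round(stats::runif(1, -3, 3), 4)
  chord <- stats::runif(1, 1.5, 4)
  a <- angle_deg * pi / 180
  sgn <- sample(c(-1, 1), 1)
  p2 <- c(x0 + chord * cos(a), y0 + sgn * chord * sin(a))
  if (sinuosity > 1) {
    h <- (chord / 2) * sqrt(sinuosity^2 - 1) * sample(c(-1, 1), 1)
  } else {
    h <- 0
  }
  mid <- (c(x0, y0) + p2) / 2
  perp <- c(-(p2[2] - y0), p2[1] - x0) / chord
  pts <- rbind(c(x0, y0), mid + h * perp, p2)
  round(pts, 4)
}

quantile_discrete <- function(u, probs) {
  sum(u > cumsum(probs) + 1e-12)
}

plan_stripe_pair <- function(cfg, seg, forced) {
  grid_times <- seq(-95, -55, by = 5)
  if (is.null(cfg$p_delta_tF)) { # disparities invariant over time
    delta0 <- sample(0:2, 1, prob = cfg$p_delta0)
    return(list(delta0 = delta0, deltaF = delta0, ops = list()))
  }
  # comonotone coupling of initial and at-fusion disparities: both
  # configured marginals are honored exactly, and deltaF <= delta0 so the
  # gap is closed by disparity-reducing additions
  u <- stats::runif(1)
  delta0 <- quantile_discrete(u, cfg$p_delta0)
  deltaF <- quantile_discrete(u, cfg$p_delta_tF)
  if (deltaF > delta0) delta0 <- deltaF
  if (forced && delta0 == deltaF) delta0 <- delta0 + 1L
  other_op <- (!forced) && stats::runif(1) < cfg$p_other
  type2_op <- stats::runif(1) < cfg$p_type2
  cur <- delta0 + if (other_op) 1L else 0L
  n_type3 <- cur - deltaF
  kinds <- character(0)
  if (other_op) kinds <- "other"
  tail_kinds <- rep("type3", n_type3)
  if (type2_op) {
    pos <- sample(seq_len(n_type3 + 1), 1)
    tail_kinds <- append(tail_kinds, "type2", after = pos - 1)
  }
  kinds <- c(kinds, tail_kinds)
  if (!length(kinds)) {
    return(list(delta0 = delta0, deltaF = deltaF, ops = list()))
  }
  times <- sort(sample(grid_times, length(kinds)))
  ops <- Map(function(k, t) list(kind = k, t = t), kinds, times)
  names(ops) <- NULL
  list(delta0 = delta0, deltaF = deltaF, ops = ops)
}

sim_one_embryo <- function(cfg, embryo_id) {
  tf <- pmin(cfg$chronology + cfg$fusion_delay, 0)
  t_E <- cfg$t_E
  segments <- names(tf)
  central <- cfg$central_segments
  tension <- cfg$mode == "tension_deficient"

  # -- stripe-pair scenarios (central segments) -------------------------
  plans <- list()
  for (seg in central) {
    plans[[seg]] <- plan_stripe_pair(cfg, seg, forced = (seg == "A3" && cfg$force_equalization))
  }
  # Relocate the last disparity-reducing op of A3 to t_count_eq so the
  # whole-arc count disparity settles to zero exactly there.
  relocated <- FALSE
  if (cfg$force_equalization && length(plans[["A3"]]$ops)) {
    idx <- which(vapply(plans[["A3"]]$ops, function(o) o$kind, "") == "type3")
    if (length(idx)) {
      plans[["A3"]]$ops[[max(idx)]]$t <- cfg$t_count_eq
      relocated <- TRUE
    }
  }

  # -- compartment count trajectories and events ------------------------
  ev_rows <- list()
  truth_ep <- list()
  truth_pairs <- list()
  pair_state <- list() # per segment: n_u(t), n_l(t) step data
  for (seg in segments) {
    is_central <- seg %in% central
    if (is_central) {
      plan <- plans[[seg]]
      side_low <- sample(SIDES, 1)
      nb <- sample(seq(cfg$stripe_n_range[1], cfg$stripe_n_range[2]), 1)
      n_u <- if (side_low == "upper") nb else nb + plan$delta0
      n_l <- if (side_low == "lower") nb else nb + plan$delta0
      steps <- data.frame(t = -Inf, n_u = n_u, n_l = n_l)
      ops <- plan$ops
      if (length(ops)) {
        ord <- order(vapply(ops, function(o) o$t, 0))
        ops <- ops[ord]
      }
      for (op in ops) {
        src <- if (stats::runif(1) < cfg$mixer_fraction) "mixer_cell" else "posterior_intercalating_cell"
        if (op$kind == "type3") {
          side <- if (n_u < n_l) "upper" else "lower"
          if (side == "upper") n_u <- n_u + 1L else n_l <- n_l + 1L
          ev_side <- side
        } else if (op$kind == "other") {
          side <- if (n_u > n_l) "upper" else if (n_l > n_u) "lower" else sample(SIDES, 1)
          if (side == "upper") n_u <- n_u + 1L else n_l <- n_l + 1L
          ev_side <- side
        } else { # type2
          n_u <- n_u + 1L
          n_l <- n_l + 1L
          ev_side <- "both"
        }
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          embryo_id = embryo_id, segment_id = seg, side = ev_side,
          t_min = op$t, source = src, delta_n = 1L, stringsAsFactors = FALSE
        )
        truth_ep[[length(truth_ep) + 1L]] <- data.frame(
          embryo_id = embryo_id, segment_id = seg, t_min = op$t,
          label = if (op$kind == "type3") "type3" else if (op$kind == "type2") "type2" else "other",
          stringsAsFactors = FALSE
        )
        steps <- rbind(steps, data.frame(t = op$t, n_u = n_u, n_l = n_l))
      }
      pair_state[[seg]] <- list(steps = steps, has_events = length(ops) > 0)
      truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
        embryo_id = embryo_id, segment_id = seg, compartment = "stripe",
        delta0 = plan$delta0, delta_tF = abs(n_u - n_l),
        has_events = length(ops) > 0,
        pair_label = if (length(ops)) NA_character_ else if (plan$delta0 == 0) "type1" else "other",
        stringsAsFactors = FALSE
      )
    } else {
      d <- if (stats::runif(1) < cfg$p_peripheral_delta1) 1L else 0L
      side_low <- sample(SIDES, 1)
      nb <- sample(seq(cfg$stripe_n_range[1], cfg$stripe_n_range[2]), 1)
      n_u <- if (side_low == "upper") nb else nb + d
      n_l <- if (side_low == "lower") nb else nb + d
      pair_state[[seg]] <- list(steps = data.frame(t = -Inf, n_u = n_u, n_l = n_l),
                                has_events = FALSE)
      truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
        embryo_id = embryo_id, segment_id = seg, compartment = "stripe",
        delta0 = d, delta_tF = d, has_events = FALSE,
        pair_label = if (d == 0) "type1" else "other",
        stringsAsFactors = FALSE
      )
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else empty_table("events")
  if (nrow(events)) events <- events[order(events$t_min, events$segment_id), ]
  rownames(events) <- NULL

  # -- whole-arc length tracks -----------------------------------------
  tL <- seq(t_E, 0, by = 1)
  L_base <- cfg$arc_length_end + (cfg$arc_length_start - cfg$arc_length_end) * (tL / t_E)
  sgn_arc <- sample(c(-1, 1), 1)
  if (tension) {
    d_len <- rep(cfg$arc_disparity0, length(tL))
  } else {
    t_zero <- cfg$t_len_eq + cfg$len_eq_epsilon / cfg$len_ramp_slope
    d_len <- pmin(cfg$arc_disparity0, pmax(0, (t_zero - tL) * cfg$len_ramp_slope))
  }
  d_len <- sgn_arc * d_len
  L_low_true <- L_base
  L_up_true <- L_base * (2 + d_len) / (2 - d_len)
  tr_u <- noisy_tracing(L_up_true, cfg$noise_cv, cfg$n_replicates)
  tr_l <- noisy_tracing(L_low_true, cfg$noise_cv, cfg$n_replicates)

  # -- whole-arc counts: baseline + cumulative additions ----------------
  tn_arc <- seq(-100, 0, by = 5)
  add_u <- add_l <- numeric(length(tn_arc))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      later <- tn_arc >= events$t_min[i] - 1e-9
      if (events$side[i] %in% c("upper", "both")) add_u[later] <- add_u[later] + events$delta_n[i]
      if (events$side[i] %in% c("lower", "both")) add_l[later] <- add_l[later] + events$delta_n[i]
    }
  }
  N_l0 <- cfg$arc_n_base + sample(-5:5, 1)
  if (tension) {
    D0 <- sgn_arc * sample(0:2, 1, prob = cfg$p_delta0)
  } else {
    D0 <- -(add_u[length(add_u)] - add_l[length(add_l)])
  }
  N_u <- N_l0 + D0 + add_u
  N_l <- N_l0 + add_l

  flanks <- rbind(
    data.frame(
      embryo_id = embryo_id, side = "upper", t_min = tL, L_um = tr_u$mean,
      N_cells = ifelse(tL %in% tn_arc, N_u[match(tL, tn_arc)], NA_real_),
      stringsAsFactors = FALSE
    ),
    data.frame(
      embryo_id = embryo_id, side = "lower", t_min = tL, L_um = tr_l$mean,
      N_cells = ifelse(tL %in% tn_arc, N_l[match(tL, tn_arc)], NA_real_),
      stringsAsFactors = FALSE
    )
  )
  replicates <- NULL
  if (cfg$store_replicates) {
    replicates <- rbind(
      data.frame(
        embryo_id = embryo_id, side = rep("upper", length(tL) * cfg$n_replicates),
        t_min = rep(tL, cfg$n_replicates),
        replicate = rep(seq_len(cfg$n_replicates), each = length(tL)),
        L_um = as.vector(tr_u$reps), stringsAsFactors = FALSE
      ),
      data.frame(
        embryo_id = embryo_id, side = rep("lower", length(tL) * cfg$n_replicates),
        t_min = rep(tL, cfg$n_replicates),
        replicate = rep(seq_len(cfg$n_replicates), each = length(tL)),
        L_um = as.vector(tr_l$reps), stringsAsFactors = FALSE
      )
    )
  }

  # -- compartment tracks ----------------------------------------------
  cp_rows <- list()
  for (seg in segments) {
    t_F <- tf[[seg]]
    visible_from <- max(t_E, t_F - 100)
    tW <- seq(visible_from, t_F, by = 1)
    span <- max(t_F - visible_from, 1)
    frac <- (tW - visible_from) / span
    tn <- tW[tW %% 5 == 0]
    state <- pair_state[[seg]]
    for (comp in COMPARTMENT_TYPES) {
      if (comp == "stripe") {
        wm <- cfg$stripe_width
        endfac <- cfg$width_endfactor_stripe
      } else {
        wm <- cfg$interstripe_width
        endfac <- cfg$width_endfactor_interstripe
      }
      w0 <- rtrunc_norm(1, wm[1], wm[2], 6)
      W_base <- w0 * (1 - cfg$width_contraction * frac)
      dW0 <- sample(c(-1, 1), 1) * stats::runif(1, cfg$width_disparity0[1], cfg$width_disparity0[2])
      dW <- dW0 * (1 + (endfac - 1) * frac)
      if (comp == "stripe" && state$has_events) {
        ev_t <- events$t_min[events$segment_id == seg]
        for (te in ev_t) {
          relief <- tW >= te & tW <= te + 4
          dW[relief] <- dW[relief] * cfg$width_event_relief
        }
      }
      W_l_true <- W_base
      W_u_true <- W_base * (2 + dW) / (2 - dW)
      if (cfg$noise_cv > 0) {
        W_u_obs <- round(W_u_true * (1 + stats::rnorm(length(tW), 0, cfg$noise_cv)), 4)
        W_l_obs <- round(W_l_true * (1 + stats::rnorm(length(tW), 0, cfg$noise_cv)), 4)
      } else {
        W_u_obs <- round(W_u_true, 4)
        W_l_obs <- round(W_l_true, 4)
      }
      if (comp == "stripe") {
        steps <- state$steps
        n_at <- function(col) {
          vapply(tn, function(t) {
            steps[[col]][max(which(steps$t <= t + 1e-9))]
          }, numeric(1))
        }
        n_u_grid <- n_at("n_u")
        n_l_grid <- n_at("n_l")
      } else {
        d_i <- sample(0:2, 1, prob = cfg$p_interstripe_delta)
        nb <- sample(seq(cfg$interstripe_n_range[1], cfg$interstripe_n_range[2]), 1)
        low_up <- sample(c(TRUE, FALSE), 1)
        n_u_grid <- rep(if (low_up) nb else nb + d_i, length(tn))
        n_l_grid <- rep(if (low_up) nb + d_i else nb, length(tn))
      }
      for (side in SIDES) {
        W <- if (side == "upper") W_u_obs else W_l_obs
        n_grid <- if (side == "upper") n_u_grid else n_l_grid
        cp_rows[[length(cp_rows) + 1L]] <- data.frame(
          embryo_id = embryo_id, side = side, segment_id = seg,
          compartment = comp, t_min = tW, W_um = W,
          n_cells = ifelse(tW %in% tn, n_grid[match(tW, tn)], NA_real_),
          visible_from = visible_from, stringsAsFactors = FALSE
        )
      }
    }
  }
  compartments <- do.call(rbind, cp_rows)
  rownames(compartments) <- NULL

  # -- interface records ------------------------------------------------
  m_ac <- angular_class_mean(cfg)
  if_rows <- list()
  truth_if <- list()
  add_iface <- function(id, seg, comp, t, stage, angle, sinu, vdeg, truth_class,
                        interlock_time = NA_real_, recruit_time = NA_real_) {
    poly <- make_interface_polyline(angle, sinu)
    if_rows[[length(if_rows) + 1L]] <<- data.frame(
      embryo_id = embryo_id, interface_id = id, segment_id = seg,
      compartment = comp, t_min = t, stage = stage,
      angle_deg = round(chord_angle(poly), 4),
      length_um = round(polyline_length(poly), 4),
      sinuosity = round(polyline_sinuosity(poly), 4),
      vdeg_a = vdeg[1], vdeg_b = vdeg[2],
      connects_two_DV = TRUE, curved_flag = FALSE,
      polyline = polyline_json(poly), stringsAsFactors = FALSE
    )
    truth_if[[length(truth_if) + 1L]] <<- data.frame(
      embryo_id = embryo_id, interface_id = id, stage = stage,
      class = truth_class, interlock_time = interlock_time,
      recruit_time = recruit_time, stringsAsFactors = FALSE
    )
  }
  for (seg in cfg$interface_segments) {
    t_F <- tf[[seg]]
    for (comp in COMPARTMENT_TYPES) {
      for (k in seq_len(cfg$interfaces_per_compartment)) {
        base_id <- sprintf("%s_%s_%s_%02d", embryo_id, seg, comp, k)
        cls <- sample(names(cfg$interface_class_probs), 1, prob = cfg$interface_class_probs)
        angle <- switch(cls,
          straight = stats::runif(1, 0.5, 19.5),
          angular = rbeta_mean(1, 20.5, 89.5, m_ac),
          curved = rbeta_mean(1, 0.5, 89.5, m_ac)
        )
        sinu <- if (cls == "curved") stats::runif(1, 1.1, 1.3) else 1
        recruit <- rtrunc_norm(1, cfg$bazooka_recruitment_delay,
                               cfg$bazooka_recruitment_sd, 0.5)
        interlocks <- cls == "angular" && cfg$angular_vertex_degree == 3L
        tau <- if (interlocks) {
          rtrunc_norm(1, cfg$interlock_time, cfg$interlock_time_sd, 1)
        } else {
          30
        }
        vdeg_post <- if (cls == "angular") {
          rep(cfg$angular_vertex_degree, 2)
        } else {
          sample(3:4, 2, replace = TRUE)
        }
        add_iface(paste0(base_id, "_pre"), seg, comp, t_F - 5, "pre_fusion",
                  stats::runif(1, 0.5, 8), 1, c(3L, 3L), "straight")
        add_iface(paste0(base_id, "_enf"), seg, comp, t_F, "en_face",
                  stats::runif(1, 0.5, 8), 1, c(4L, 4L), "straight")
        add_iface(paste0(base_id, "_post"), seg, comp, round(t_F + tau, 4),
                  "post_fusion", angle, sinu, as.integer(vdeg_post), cls,
                  interlock_time = if (interlocks) round(tau, 4) else NA_real_,
                  recruit_time = round(recruit, 4))
      }
    }
  }
  interfaces <- if (length(if_rows)) do.call(rbind, if_rows) else empty_table("interfaces")
  rownames(interfaces) <- NULL

  # -- post-closure snapshots -------------------------------------------
  sn_rows <- list()
  truth_sn <- list()
  for (seg in cfg$snapshot_segments) {
    for (comp in COMPARTMENT_TYPES) {
      for (side in SIDES) {
        n_cells <- 10L
        lacking <- as.integer(round(n_cells * stats::runif(1, cfg$snapshot_lacking_range[1],
                                                           cfg$snapshot_lacking_range[2])))
        central_most <- seg == "A3"
        sn_rows[[length(sn_rows) + 1L]] <- data.frame(
          embryo_id = embryo_id, segment_id = seg, compartment = comp,
          side = side, stage = "post_closure",
          distance_from_canthus_cells = 15L,
          is_central_most = central_most,
          cell_id = sprintf("%s_%s_%s_%s_c%02d", embryo_id, seg, comp, side, seq_len(n_cells)),
          has_interlocked_interface = seq_len(n_cells) > lacking,
          dv_length_um = round(rtrunc_norm(n_cells, 10, 1, 3), 4),
          ap_length_um = round(rtrunc_norm(n_cells, 2.2, 0.25, 0.8), 4),
          stringsAsFactors = FALSE
        )
        truth_sn[[length(truth_sn) + 1L]] <- data.frame(
          embryo_id = embryo_id, segment_id = seg, compartment = comp, side = side,
          status = if (central_most) "not_assessable" else if (lacking / n_cells >= 0.7) "defective" else "not_defective",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  snapshots <- if (length(sn_rows)) do.call(rbind, sn_rows) else empty_table("snapshots")
  rownames(snapshots) <- NULL

  # -- intensity records -------------------------------------------------
  ratio_table <- list(
    ecadherin = c(pre_fusion = 1.3, en_face = 1.5, interlocked = 1.2),
    actin = c(pre_fusion = 2.0, en_face = 1.8, interlocked = cfg$actin_interlocked_ratio),
    myosin = c(pre_fusion = 1.8, en_face = 1.6, interlocked = 0.8),
    bazooka = c(pre_fusion = 0.15, en_face = 1.0, interlocked = 1.8),
    vinculin = c(pre_fusion = 1.8, en_face = 2.0, interlocked = 0.9)
  )
  set_plan <- list(ecadherin = c(sets = 2, n = 10), actin = c(sets = 2, n = 5),
                   myosin = c(sets = 1, n = 5), bazooka = c(sets = 1, n = 5),
                   vinculin = c(sets = 1, n = 5))
  in_rows <- list()
  for (marker in names(set_plan)) {
    for (stage in INTENSITY_STAGES) {
      for (s in seq_len(set_plan[[marker]][["sets"]])) {
        I_DV <- rtrunc_norm(1, 100, 10, 10)
        ratio <- ratio_table[[marker]][[stage]]
        I <- max(0, ratio * I_DV * (1 + stats::rnorm(1, 0, cfg$intensity_noise_cv)))
        in_rows[[length(in_rows) + 1L]] <- data.frame(
          embryo_id = embryo_id, marker = marker, stage = stage,
          I = round(I, 4), I_DV = round(I_DV, 4),
          n_interfaces = as.integer(set_plan[[marker]][["n"]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  intensities <- do.call(rbind, in_rows)
  rownames(intensities) <- NULL

  timeline <- timeline_convention(t_E = t_E, t_F = tf)
  ds <- embryo_dataset(
    embryo_id = embryo_id, genotype_label = cfg$mode, timeline = timeline,
    flanks = flanks, compartments = compartments, interfaces = interfaces,
    events = events, intensities = intensities, snapshots = snapshots,
    replicates = replicates,
    provenance = list(simulator = "fusefid", seed = cfg$seed, mode = cfg$mode),
    validate = FALSE
  )

  truth_eq <- data.frame(
    embryo_id = embryo_id,
    descriptor = c("arc_length", "dme_arc"),
    t_true = c(
      if (!tension && cfg$arc_disparity0 > cfg$len_eq_epsilon) cfg$t_len_eq else NA_real_,
      if (!tension && relocated) cfg$t_count_eq else NA_real_
    ),
    stringsAsFactors = FALSE
  )
  list(
    dataset = ds,
    truth = list(
      equalization = truth_eq,
      episodes = if (length(truth_ep)) do.call(rbind, truth_ep) else NULL,
      pairs = do.call(rbind, truth_pairs),
      interfaces = if (length(truth_if)) do.call(rbind, truth_if) else NULL,
      snapshots = if (length(truth_sn)) do.call(rbind, truth_sn) else NULL
    )
  )
}

#' Simulate embryo datasets with ground truth
#'
#' Runs the generator under the supplied configuration. The same
#' (seed, config) pair always yields byte-identical serialized datasets.
#' Whole-arc DME counts change only at the emitted addition events, and by
#' exactly their `delta_n`; fusion order follows the configured
#' chronology.
#'
#' @param config A [simulation_config()].
#' @return A `simulation_result`: `datasets` (list of
#'   [embryo_dataset()]) and `truth`, with per-pair equalization times,
#'   per-episode rearrangement labels, per-interface geometry classes and
#'   interlock/recruitment times, and per-snapshot defect status.
#' @export
simulate_embryos <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  results <- lapply(seq_len(config$n_embryos), function(i) {
    sim_one_embryo(config, sprintf("sim%03d_%s", i, config$mode))
  })
  datasets <- lapply(results, `[[`, "dataset")
  names(datasets) <- vapply(datasets, function(d) d$embryo_id, "")
  bind <- function(field) {
    pieces <- Filter(Negate(is.null), lapply(results, function(r) r$truth[[field]]))
    if (!length(pieces)) return(NULL)
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  }
  structure(
    list(
      datasets = datasets,
      truth = list(
        equalization = bind("equalization"),
        episodes = bind("episodes"),
        pairs = bind("pairs"),
        interfaces = bind("interfaces"),
        snapshots = bind("snapshots"),
        config = config
      )
    ),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- x$truth$config
  cat("<simulation_result>", length(x$datasets), "embryo(s), mode =", cfg$mode,
      ", seed =", cfg$seed, "\n")
  invisible(x)
}
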