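# Independent oracles, kept free of the package's own code paths.

# Two-pass brute-force variance summary: explicit loops, population
# variance per embryo, plain mean across embryos.
brute_force_var_ddme <- function(pair_deltas_by_embryo) {
  sigma2 <- numeric(length(pair_deltas_by_embryo))
  for (e in seq_along(pair_deltas_by_embryo)) {
    x <- pair_deltas_by_embryo[[e]]
    mu <- 0
    for (v in x) mu <- mu + v
    mu <- mu / length(x)
    ss <- 0
    for (v in x) ss <- ss + (v - mu)^2
    sigma2[e] <- ss / length(x)
  }
  total <- 0
  for (s in sigma2) total <- total + s
  total / length(sigma2)
}

# Exhaustive-enumeration two-sided Mann-Whitney p-value for tie-free
# samples: every assignment of the pooled ranks to group a is visited.
enumerated_ranksum_p <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  u_all <- colSums(matrix(sort(r)[sets], nrow = na)) - na * (na + 1) / 2
  mid <- na * nb / 2
  p <- if (u_obs > mid) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * p, 1)
}

# Small retrospective dataset with hand-set flank tracks (5-min grid).
hand_dataset <- function(upper_L, lower_L, t = NULL,
                         upper_N = NULL, lower_N = NULL) {
  n <- length(upper_L)
  if (is.null(t)) t <- seq(-5 * (n - 1), 0, by = 5)
  if (is.null(upper_N)) upper_N <- rep(20, n)
  if (is.null(lower_N)) lower_N <- rep(20, n)
  timeline <- timeline_convention(
    t_E = min(t), t_F = c(A3 = 0),
    frame_interval_length = 5, frame_interval_count = 5
  )
  flanks <- rbind(
    data.frame(embryo_id = "hand", side = "upper", t_min = t, L_um = upper_L,
               N_cells = upper_N, stringsAsFactors = FALSE),
    data.frame(embryo_id = "hand", side = "lower", t_min = t, L_um = lower_L,
               N_cells = lower_N, stringsAsFactors = FALSE)
  )
  comp <- rbind(
    data.frame(embryo_id = "hand", side = "upper", segment_id = "A3",
               compartment = "stripe", t_min = t, W_um = 20, n_cells = 3,
               visible_from = min(t), stringsAsFactors = FALSE),
    data.frame(embryo_id = "hand", side = "lower", segment_id = "A3",
               compartment = "stripe", t_min = t, W_um = 20, n_cells = 3,
               visible_from = min(t), stringsAsFactors = FALSE)
  )
  embryo_dataset("hand", "control", timeline, flanks, comp)
}

# A three-point polyline with a prescribed chord angle (degrees) and
# sinuosity, independent of the simulator's generator.
grid_polyline <- function(angle_deg, sinuosity, chord = 2) {
  a <- angle_deg * pi / 180
  p1 <- c(1, 1)
  p2 <- p1 + chord * c(cos(a), sin(a))
  h <- if (sinuosity > 1) (chord / 2) * sqrt(sinuosity^2 - 1) else 0
  mid <- (p1 + p2) / 2
  perp <- c(-(p2[2] - p1[2]), p2[1] - p1[1]) / chord
  rbind(p1, mid + h * perp, p2)
}
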