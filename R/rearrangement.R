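# Typing of cell-addition events and width changes around them.

#' Type a cell-rearrangement episode from counts around it
#'
#' \eqn{\Delta}DME is the absolute difference in leading-edge cell number
#' between the partner stripes, taken on the integer counts at the last
#' count frame before the episode and the first count frame after it.
#' The rule table:
#' \itemize{
#'   \item `type1`: \eqn{\Delta}DME = 0 before and after, no addition in
#'     either partner;
#'   \item `type2`: \eqn{\Delta}DME unchanged, addition in both partner
#'     stripes;
#'   \item `type3`: \eqn{\Delta}DME reduced, addition in the stripe with
#'     the lower cell number;
#'   \item `other`: everything else (disparity-increasing additions,
#'     additions on the higher-count side, persistent nonzero disparity
#'     without additions).
#' }
#' The bins are mutually exclusive and exhaustive in that order.
#'
#' @param ddme_before,ddme_after Non-negative integer \eqn{|\Delta}DME|
#'   before/after the episode.
#' @param added_upper,added_lower Cells added to each partner during the
#'   episode (>= 0).
#' @param lower_count_side Which partner had the lower count before the
#'   episode: `"upper"`, `"lower"` or `"tie"`.
#' @return A `rearrangement_label` list with `label`, `ddme_before`,
#'   `ddme_after`.
#' @export
classify_rearrangement <- function(ddme_before, ddme_after,
                                   added_upper, added_lower,
                                   lower_count_side = c("upper", "lower", "tie")) {
  lower_count_side <- match.arg(lower_count_side)
  vals <- c(ddme_before, ddme_after, added_upper, added_lower)
  if (any(is.na(vals)) || any(vals < 0) || any(!is_wholenumber(vals))) {
    stop("counts and deltas must be non-negative integers")
  }
  no_addition <- added_upper == 0 && added_lower == 0
  label <- if (ddme_before == 0 && ddme_after == 0 && no_addition) {
    "type1"
  } else if (ddme_after == ddme_before && added_upper > 0 && added_lower > 0) {
    "type2"
  } else if (ddme_after < ddme_before &&
    ((lower_count_side == "upper" && added_upper > 0) ||
      (lower_count_side == "lower" && added_lower > 0))) {
    "type3"
  } else {
    "other"
  }
  structure(
    list(label = label, ddme_before = as.integer(ddme_before),
         ddme_after = as.integer(ddme_after)),
    class = "rearrangement_label"
  )
}

pair_counts <- function(ds, segment) {
  cp <- ds$compartments
  sel <- cp$segment_id == segment & cp$compartment == "stripe" & !is.na(cp$n_cells)
  u <- cp[sel & cp$side == "upper", c("t_min", "n_cells")]
  l <- cp[sel & cp$side == "lower", c("t_min", "n_cells")]
  m <- merge(u, l, by = "t_min", suffixes = c("_u", "_l"))
  m[order(m$t_min), , drop = FALSE]
}

count_at <- function(counts, col, t) {
  i <- which(counts$t_min <= t + 1e-9)
  if (!length(i)) return(NA_real_)
  counts[[col]][max(i)]
}

#' Type every cell-addition episode of a dataset
#'
#' Addition events of one stripe pair falling in the same count frame are
#' merged into one episode (a multi-cell addition). For each episode the
#' counts at the last count frame before the first addition and at the
#' first count frame at/after the last addition bracket the episode, and
#' [classify_rearrangement()] is applied. Stripe pairs without any event
#' are reported once, labelled `type1` when their disparity is zero at all
#' common frames and `other` when a nonzero disparity persists.
#'
#' @param ds An [embryo_dataset()].
#' @param segments Stripe pairs to analyse (default: all with events or
#'   count tracks on both sides).
#' @return Data frame with one row per episode/event-free pair: segment,
#'   episode time (`NA` for event-free pairs), additions per side, counts
#'   before/after, and `label`.
#' @export
rearrangement_labels <- function(ds, segments = NULL) {
  ev <- ds$events
  cp <- ds$compartments
  if (is.null(segments)) {
    both_sides <- intersect(
      unique(cp$segment_id[cp$compartment == "stripe" & cp$side == "upper"]),
      unique(cp$segment_id[cp$compartment == "stripe" & cp$side == "lower"])
    )
    segments <- intersect(SEGMENT_IDS, both_sides)
  }
  grid <- ds$timeline$frame_interval_count
  rows <- list()
  for (seg in segments) {
    counts <- pair_counts(ds, seg)
    if (!nrow(counts)) next
    seg_ev <- ev[ev$segment_id == seg, , drop = FALSE]
    if (nrow(seg_ev)) {
      frames <- floor(seg_ev$t_min / grid + 1e-9) * grid
      for (fr in sort(unique(frames))) {
        ep <- seg_ev[frames == fr, , drop = FALSE]
        added_u <- sum(ep$delta_n[ep$side %in% c("upper", "both")])
        added_l <- sum(ep$delta_n[ep$side %in% c("lower", "both")])
        t_before <- fr - grid
        n_u0 <- count_at(counts, "n_cells_u", t_before)
        n_l0 <- count_at(counts, "n_cells_l", t_before)
        n_u1 <- count_at(counts, "n_cells_u", fr)
        n_l1 <- count_at(counts, "n_cells_l", fr)
        if (anyNA(c(n_u0, n_l0, n_u1, n_l1))) next
        side_low <- if (n_u0 < n_l0) "upper" else if (n_l0 < n_u0) "lower" else "tie"
        lab <- classify_rearrangement(
          abs(n_u0 - n_l0), abs(n_u1 - n_l1), added_u, added_l, side_low
        )
        rows[[length(rows) + 1L]] <- data.frame(
          embryo_id = ds$embryo_id, segment_id = seg, t_min = fr,
          added_upper = added_u, added_lower = added_l,
          ddme_before = lab$ddme_before, ddme_after = lab$ddme_after,
          lower_count_side = side_low, label = lab$label,
          stringsAsFactors = FALSE
        )
      }
    } else {
      dd <- abs(counts$n_cells_u - counts$n_cells_l)
      lab <- classify_rearrangement(dd[1], dd[length(dd)], 0, 0, "tie")
      if (any(dd != 0)) lab$label <- "other"
      rows[[length(rows) + 1L]] <- data.frame(
        embryo_id = ds$embryo_id, segment_id = seg, t_min = NA_real_,
        added_upper = 0, added_lower = 0,
        ddme_before = dd[1], ddme_after = dd[length(dd)],
        lower_count_side = "tie", label = lab$label,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      embryo_id = character(0), segment_id = character(0), t_min = numeric(0),
      added_upper = numeric(0), added_lower = numeric(0),
      ddme_before = integer(0), ddme_after = integer(0),
      lower_count_side = character(0), label = character(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalized width disparity around a cell-addition episode
#'
#' Evaluates the pair's normalized width difference at three instants:
#' about 10 minutes before the addition completes (pre-CR), immediately
#' after it (at CR) and 10 minutes later (post-CR), using the nearest
#' sampled frames. Slots without a frame within `tolerance` minutes (an
#' episode too close to the track boundary) are returned as `NA`.
#'
#' @param ds An [embryo_dataset()].
#' @param segment Stripe pair.
#' @param t_event Completion time of the addition episode (minutes).
#' @param offset Minutes before/after the episode (default 10).
#' @param tolerance Maximal distance to the nearest sampled frame.
#' @return Named numeric `c(pre_cr, at_cr, post_cr)`.
#' @export
width_change_at_addition <- function(ds, segment, t_event, offset = 10,
                                     tolerance = 2.5) {
  cp <- ds$compartments
  sel <- cp$segment_id == segment & cp$compartment == "stripe" & !is.na(cp$W_um)
  u <- cp[sel & cp$side == "upper", c("t_min", "W_um")]
  l <- cp[sel & cp$side == "lower", c("t_min", "W_um")]
  m <- merge(u, l, by = "t_min", suffixes = c("_u", "_l"))
  if (!nrow(m)) {
    abort_validation(paste0("no paired width frames for stripe pair ", segment))
  }
  value_near <- function(target) {
    i <- which.min(abs(m$t_min - target))
    if (abs(m$t_min[i] - target) > tolerance) return(NA_real_)
    norm_diff(m$W_um_u[i], m$W_um_l[i])
  }
  c(
    pre_cr = value_near(t_event - offset),
    at_cr = value_near(t_event),
    post_cr = value_near(t_event + offset)
  )
}
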