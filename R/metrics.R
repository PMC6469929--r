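# Fidelity descriptors: normalized pairwise differences, their time
# series, variance summaries, constriction index, intensity
# normalization and equalization-time detection.

#' Normalized difference between contralateral measurements
#'
#' The core disparity descriptor: for paired measurements `upper` and
#' `lower` it returns `(upper - lower) / ((upper + lower)/2)` — the signed
#' difference normalized by the pair mean, the form used for
#' Norm.\eqn{\Delta}Arclength, Norm.\eqn{\Delta}Width and
#' Norm.\eqn{\Delta}DME. The sign convention is upper minus lower. For
#' positive inputs the value lies strictly inside (-2, 2); it reaches
#' \eqn{\pm 2} only when one cell count is zero, and is 0 exactly when the
#' two measurements are equal.
#'
#' @param upper,lower Non-negative measurements (vectorized); at least one
#'   of each pair must be positive.
#' @return Dimensionless signed disparity.
#' @export
#' @examples
#' norm_diff(120, 80) # 0.4
norm_diff <- function(upper, lower) {
  upper <- as.numeric(upper)
  lower <- as.numeric(lower)
  ok <- !is.na(upper) & !is.na(lower)
  if (any(ok & (upper < 0 | lower < 0))) {
    stop("norm_diff() is defined for non-negative measurements only")
  }
  if (any(ok & upper == 0 & lower == 0)) {
    stop("norm_diff() undefined when both paired measurements are zero")
  }
  (upper - lower) / ((upper + lower) / 2)
}

lookup_track <- function(ds, descriptor, segment, compartment) {
  if (descriptor %in% c("arc_length", "dme_arc")) {
    fl <- ds$flanks
    col <- if (descriptor == "arc_length") "L_um" else "N_cells"
    u <- fl[fl$side == "upper" & !is.na(fl[[col]]), c("t_min", col)]
    l <- fl[fl$side == "lower" & !is.na(fl[[col]]), c("t_min", col)]
  } else {
    cp <- ds$compartments
    sel <- cp$segment_id == segment & cp$compartment == compartment
    if (!any(sel)) {
      abort_validation(
        paste0("no compartment track for pair ", segment, "/", compartment),
        file = "compartments"
      )
    }
    col <- if (descriptor == "width") "W_um" else "n_cells"
    u <- cp[sel & cp$side == "upper" & !is.na(cp[[col]]), c("t_min", col)]
    l <- cp[sel & cp$side == "lower" & !is.na(cp[[col]]), c("t_min", col)]
  }
  names(u) <- names(l) <- c("t_min", "value")
  list(upper = u, lower = l)
}

#' Disparity time series for one contralateral pair
#'
#' Applies [norm_diff()] frame-wise to the paired measurement selected by
#' `descriptor`: whole-arc length (`"arc_length"`), whole-arc DME cell
#' count (`"dme_arc"`), compartment fusing-front width (`"width"`) or
#' compartment DME count (`"dme_compartment"`). Frames at which either
#' member is missing are skipped, never interpolated. By default whole-arc
#' count series are restricted to \[-100, 0\] (counts cannot be obtained
#' earlier), whole-arc length series run from `t_E`, and compartment series
#' run from the pair's common visible window to its fusion time.
#'
#' @param ds An [embryo_dataset()] on the retrospective axis.
#' @param descriptor One of `"arc_length"`, `"dme_arc"`, `"width"`,
#'   `"dme_compartment"`.
#' @param segment,compartment Pair identity for compartment descriptors.
#' @param window Optional `c(from, to)` override in minutes.
#' @return A `disparity_series`: data frame with `t_min` and `value`,
#'   carrying `descriptor` and `pair_id` attributes. Zero rows (flagged
#'   via the `empty` attribute) when the pair shares no visible frame.
#' @export
disparity_series <- function(ds, descriptor = c("arc_length", "dme_arc", "width", "dme_compartment"),
                             segment = NULL, compartment = NULL,
                             window = NULL) {
  descriptor <- match.arg(descriptor)
  compartment_like <- descriptor %in% c("width", "dme_compartment")
  if (compartment_like) {
    if (is.null(segment) || is.null(compartment)) {
      abort_validation("segment and compartment must be given for compartment descriptors")
    }
    pair_id <- paste(segment, compartment, sep = ":")
  } else {
    pair_id <- "whole-arc"
  }
  tr <- lookup_track(ds, descriptor, segment, compartment)
  m <- merge(tr$upper, tr$lower, by = "t_min", suffixes = c("_u", "_l"))
  if (is.null(window)) {
    window <- if (compartment_like) {
      c(-Inf, ds$timeline$t_F[[segment]])
    } else if (descriptor == "dme_arc") {
      c(-100, 0)
    } else {
      c(ds$timeline$t_E, 0)
    }
  }
  m <- m[m$t_min >= window[1] & m$t_min <= window[2], , drop = FALSE]
  m <- m[order(m$t_min), , drop = FALSE]
  out <- data.frame(t_min = m$t_min,
                    value = if (nrow(m)) norm_diff(m$value_u, m$value_l) else numeric(0))
  structure(out,
    class = c("disparity_series", "data.frame"),
    descriptor = descriptor, pair_id = pair_id,
    empty = nrow(out) == 0L
  )
}

#' Detect the time of equalization on a disparity series
#'
#' The equalization time is the earliest retrospective time `t*` from
#' which `|value(t)|` stays at or below `epsilon` for the remainder of the
#' series, with at least `hold` consecutive frames in that terminal run.
#' Transient re-divergence above `epsilon` pushes detection later; a
#' series that never settles returns `NA` (undefined is a valid outcome).
#'
#' Defaults: `epsilon = 0` for integer-valued cell-count descriptors and
#' `0.05` for length/width tracings (which carry tracing noise).
#'
#' @param series A [disparity_series()].
#' @param epsilon Tolerance band on `|value|`; `NULL` picks the
#'   descriptor-specific default.
#' @param hold Minimum length of the terminal within-band run (frames).
#' @return Equalization time in minutes, or `NA_real_`.
#' @export
equalization_time <- function(series, epsilon = NULL, hold = 2) {
  if (is.null(epsilon)) {
    descriptor <- attr(series, "descriptor")
    epsilon <- if (!is.null(descriptor) && descriptor %in% c("dme_arc", "dme_compartment")) 0 else 0.05
  }
  v <- abs(series$value)
  n <- length(v)
  if (!n) return(NA_real_)
  bad <- which(v > epsilon)
  start <- if (length(bad)) max(bad) + 1L else 1L
  if (start > n) return(NA_real_)
  if (n - start + 1L < hold) return(NA_real_)
  series$t_min[start]
}

#' Variance of DME cell-number differences across partner pairs
#'
#' For each embryo the population variance (divide by N, not N-1) of its
#' pair-wise \eqn{\Delta}DME values is computed:
#' \eqn{\sigma^2 = \sum (X - \mu)^2 / N}; the summary statistic is the
#' unweighted arithmetic mean of these per-embryo variances across
#' embryos, \eqn{Var.\Delta DME = \sum \sigma^2 / \nu}.
#'
#' @param pair_deltas_by_embryo Named list; one numeric vector of
#'   \eqn{\Delta}DME values (one per partner pair) per embryo.
#' @param relation,timepoint Optional labels carried into the summary
#'   (`"contralateral"`/`"ipsilateral"`, `"t_E"`/`"t_-100"`/`"t_F"`).
#' @return A `variance_summary` with `per_embryo_sigma2` and `var_ddme`.
#' @export
ddme_variance <- function(pair_deltas_by_embryo, relation = NA_character_,
                          timepoint = NA_character_) {
  if (!length(pair_deltas_by_embryo)) stop("ddme_variance() needs at least one embryo")
  sigma2 <- vapply(pair_deltas_by_embryo, function(x) {
    x <- as.numeric(x)
    if (!length(x)) stop("each embryo must contribute at least one pair")
    mean((x - mean(x))^2)
  }, numeric(1))
  structure(
    list(
      relation = relation, timepoint = timepoint,
      per_embryo_sigma2 = sigma2,
      var_ddme = mean(sigma2)
    ),
    class = "variance_summary"
  )
}

#' @export
print.variance_summary <- function(x, ...) {
  cat("<variance_summary>", x$relation, x$timepoint, "\n")
  cat("  per-embryo sigma^2:", paste(signif(x$per_embryo_sigma2, 6), collapse = ", "), "\n")
  cat("  Var.dDME:", signif(x$var_ddme, 6), "\n")
  invisible(x)
}

#' Constriction index of a fusing front
#'
#' Fusing-front width divided by its DME cell count, in micrometres per
#' cell, conventionally evaluated on one flank of the fusing stripe pair
#' at its fusion time.
#'
#' @param W Width in micrometres (> 0).
#' @param N DME cell count (>= 1).
#' @return Micrometres per cell.
#' @export
constriction_index <- function(W, N) {
  W <- as.numeric(W)
  N <- as.numeric(N)
  if (any(!is.na(N) & N < 1)) stop("constriction index requires at least one DME cell")
  if (any(!is.na(W) & W <= 0)) stop("constriction index requires a positive width")
  W / N
}

#' Normalize an interface intensity to its D/V reference
#'
#' Mean fluorescence along fusing/fused interfaces divided by the mean
#' fluorescence along the D/V-oriented interfaces of the same cells,
#' removing acquisition-level intensity scale.
#'
#' @param I Mean interface intensity (>= 0), or a data frame of intensity
#'   records with columns `I` and `I_DV`.
#' @param I_DV Mean D/V reference intensity (> 0).
#' @return Dimensionless normalized intensity.
#' @export
normalized_intensity <- function(I, I_DV = NULL) {
  if (is.data.frame(I)) {
    I_DV <- I$I_DV
    I <- I$I
  }
  I <- as.numeric(I)
  I_DV <- as.numeric(I_DV)
  if (any(!is.na(I_DV) & I_DV <= 0)) stop("D/V reference intensity must be positive")
  if (any(!is.na(I) & I < 0)) stop("interface intensity must be non-negative")
  I / I_DV
}
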