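# Interface-geometry classification, interlocking-defect calls, seam
# alignment and cell-shape indices. Coordinates: x increases
# anterior -> posterior (A/P axis), y across the midline; angles are
# measured against x and always reported acute, in [0, 90] degrees.

as_polyline <- function(polyline) {
  if (is.character(polyline)) {
    polyline <- jsonlite::fromJSON(polyline)
  }
  p <- as.matrix(polyline)
  if (!is.numeric(p) || ncol(p) != 2) stop("polyline must be an n x 2 numeric matrix of (x, y) points")
  p
}

#' Acute angle of a polyline's endpoint chord to the A/P axis
#'
#' Draws the straight line between the first and last vertex and returns
#' the acute angle it subtends to the horizontal, in degrees. Invariant to
#' polyline orientation, translation and reflection about either axis.
#'
#' @param polyline An n x 2 matrix/data frame of (x, y) points in
#'   micrometres, or its JSON encoding.
#' @return Angle in \[0, 90\] degrees.
#' @export
chord_angle <- function(polyline) {
  p <- as_polyline(polyline)
  if (nrow(p) < 2) stop("polyline needs at least two points")
  d <- p[nrow(p), ] - p[1, ]
  if (all(abs(d) < 1e-12)) stop("degenerate polyline: endpoint chord has zero length")
  atan2(abs(d[2]), abs(d[1])) * 180 / pi
}

#' Length along a polyline
#' @param polyline An n x 2 matrix of points, or its JSON encoding.
#' @return Summed segment length in micrometres.
#' @export
polyline_length <- function(polyline) {
  p <- as_polyline(polyline)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Sinuosity of a polyline
#'
#' Polyline length divided by endpoint chord length; 1 for a straight
#' interface, larger for curved or squiggly ones.
#' @param polyline An n x 2 matrix of points, or its JSON encoding.
#' @return Sinuosity >= 1.
#' @export
polyline_sinuosity <- function(polyline) {
  p <- as_polyline(polyline)
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord < 1e-12) stop("degenerate polyline: endpoint chord has zero length")
  polyline_length(p) / chord
}

#' Classify the geometry of one fused/fusing interface
#'
#' Eligible interfaces (length at least 1 um, connecting two D/V
#' interfaces, within segments T2-A6) are partitioned into exactly one of
#' three bins: `curved` when the sinuosity exceeds `sinuosity_threshold`
#' (or a manual curved flag is set), otherwise `angular` when the chord
#' subtends \[`angle_split`, 90\] degrees to the A/P axis and `straight`
#' when it subtends \[0, `angle_split`) degrees. The boundary angle is
#' assigned to `angular` (closed lower bound) so the partition is
#' well-defined. Anything failing eligibility is labelled `ineligible`
#' with the reason.
#'
#' @param rec One interface record: a one-row data frame or list with
#'   `segment_id`, `length_um`, `connects_two_DV` and either
#'   `angle_deg`/`sinuosity` or a `polyline` to derive them from;
#'   an optional logical `curved_flag` overrides sinuosity.
#' @param sinuosity_threshold Curvature cutoff (default 1.05).
#' @param angle_split Angular/straight boundary in degrees (default 20).
#' @return A `geometry_label` list with `label` and `reason`.
#' @export
classify_interface <- function(rec, sinuosity_threshold = 1.05, angle_split = 20) {
  get <- function(nm) if (nm %in% names(rec)) rec[[nm]][1] else NA
  angle <- get("angle_deg")
  sinu <- get("sinuosity")
  len <- get("length_um")
  poly <- get("polyline")
  if ((is.na(angle) || is.na(sinu) || is.na(len)) && !is.na(poly) && nzchar(poly)) {
    if (is.na(angle)) angle <- chord_angle(poly)
    if (is.na(sinu)) sinu <- polyline_sinuosity(poly)
    if (is.na(len)) len <- polyline_length(poly)
  }
  label <- function(lab, reason) {
    structure(list(label = lab, reason = reason), class = "geometry_label")
  }
  if (is.na(len)) return(label("ineligible", "length unknown"))
  if (len < 1) return(label("ineligible", "shorter than 1 um"))
  conn <- get("connects_two_DV")
  if (is.na(conn) || !conn) return(label("ineligible", "does not connect two D/V interfaces"))
  seg <- get("segment_id")
  if (is.na(seg) || !(seg %in% ELIGIBLE_SEGMENTS)) {
    return(label("ineligible", "segment outside T2-A6"))
  }
  curved_flag <- get("curved_flag")
  if (!is.na(curved_flag) && isTRUE(as.logical(curved_flag))) {
    return(label("curved", "manual curved flag"))
  }
  if (!is.na(sinu) && sinu > sinuosity_threshold) {
    return(label("curved", sprintf("sinuosity %.3f > %.3f", sinu, sinuosity_threshold)))
  }
  if (is.na(angle)) return(label("ineligible", "angle unknown"))
  if (angle >= angle_split) {
    label("angular", sprintf("chord angle %.1f deg >= %g deg", angle, angle_split))
  } else {
    label("straight", sprintf("chord angle %.1f deg < %g deg", angle, angle_split))
  }
}

#' Classify every interface record in a table or dataset
#'
#' @param x An [embryo_dataset()] or an interfaces data frame.
#' @inheritParams classify_interface
#' @return The interfaces table with `label` and `reason` columns added.
#' @export
classify_interfaces <- function(x, sinuosity_threshold = 1.05, angle_split = 20) {
  df <- if (inherits(x, "embryo_dataset")) x$interfaces else x
  n <- nrow(df)
  labels <- character(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    gl <- classify_interface(df[i, ], sinuosity_threshold, angle_split)
    labels[i] <- gl$label
    reasons[i] <- gl$reason
  }
  df$label <- labels
  df$reason <- reasons
  df
}

#' Mean interface angle with standard error
#'
#' Arithmetic mean of chord angles over eligible interfaces (all three
#' geometry classes), with the standard error of the mean. A single
#' eligible record yields its own angle and `NA` sem.
#'
#' @param records Interfaces data frame (as in an [embryo_dataset()]).
#' @inheritParams classify_interface
#' @return List with `mean_deg`, `sem_deg` and `n`.
#' @export
mean_interface_angle <- function(records, sinuosity_threshold = 1.05, angle_split = 20) {
  labelled <- classify_interfaces(records, sinuosity_threshold, angle_split)
  keep <- labelled[labelled$label != "ineligible" & !is.na(labelled$angle_deg), ]
  if (!nrow(keep)) stop("no eligible interface records to average")
  ang <- keep$angle_deg
  list(
    mean_deg = mean(ang),
    sem_deg = if (length(ang) > 1) stats::sd(ang) / sqrt(length(ang)) else NA_real_,
    n = length(ang)
  )
}

#' Is an interface interlocked?
#'
#' Operationalizes the Y-shaped tricellular configuration: an interface is
#' interlocked when its geometry class is `angular` and both endpoint
#' vertices have degree 3.
#'
#' @param vdeg_a,vdeg_b Endpoint vertex degrees.
#' @param label Geometry label (string or `geometry_label`).
#' @return Logical.
#' @export
interlocked <- function(vdeg_a, vdeg_b, label) {
  if (inherits(label, "geometry_label")) label <- label$label
  label == "angular" & vdeg_a == 3L & vdeg_b == 3L
}

#' Interlocking-defect call for one compartment snapshot
#'
#' A compartment (one side of the midline) is interlocking defective when
#' at least 70% of its cells lack interlocked (Y-shaped tricellular)
#' interfaces. Compartments from segments Lb and A7, closure-stage
#' compartments closer than 10 cells to a canthus, and the central-most
#' compartment of a post-closure embryo are not assessable.
#'
#' @param snap Data frame of the compartment's cells: columns
#'   `segment_id`, `stage`, `distance_from_canthus_cells`,
#'   `is_central_most`, `has_interlocked_interface` (one row per cell).
#' @param threshold Fraction of lacking cells that triggers the call
#'   (default 0.70).
#' @return `"defective"`, `"not_defective"` or `"not_assessable"`.
#' @export
interlocking_defective <- function(snap, threshold = 0.70) {
  if (!nrow(snap)) stop("empty cell list: nothing to assess")
  seg <- snap$segment_id[1]
  stage <- snap$stage[1]
  if (seg %in% c("Lb", "A7")) return("not_assessable")
  if (stage == "closure" && snap$distance_from_canthus_cells[1] < 10) {
    return("not_assessable")
  }
  if (stage == "post_closure" && isTRUE(snap$is_central_most[1])) {
    return("not_assessable")
  }
  frac_lacking <- mean(!snap$has_interlocked_interface)
  if (frac_lacking >= threshold - 1e-12) "defective" else "not_defective"
}

#' Interlocking-defect calls for every snapshot in a dataset
#'
#' @param ds An [embryo_dataset()] with a snapshots table.
#' @inheritParams interlocking_defective
#' @return Data frame with one row per (segment, compartment, side)
#'   snapshot and its `status`.
#' @export
interlocking_defects <- function(ds, threshold = 0.70) {
  sn <- ds$snapshots
  if (!nrow(sn)) {
    return(data.frame(
      embryo_id = character(0), segment_id = character(0),
      compartment = character(0), side = character(0),
      frac_lacking = numeric(0), status = character(0),
      stringsAsFactors = FALSE
    ))
  }
  key <- interaction(sn$segment_id, sn$compartment, sn$side, drop = TRUE)
  pieces <- lapply(split(sn, key), function(g) {
    data.frame(
      embryo_id = g$embryo_id[1], segment_id = g$segment_id[1],
      compartment = g$compartment[1], side = g$side[1],
      frac_lacking = mean(!g$has_interlocked_interface),
      status = interlocking_defective(g, threshold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$segment_id, out$compartment, out$side), ]
}

#' Alignment index of contralateral segment boundaries
#'
#' Joins the anterior stripe-boundary anchor on each flank by a straight
#' line, measures the acute angle \eqn{\alpha} that line subtends to the
#' A/P axis, and returns \eqn{\theta = |90 - \alpha|} degrees: 0 for a
#' perfectly aligned (vertical) boundary pair, growing with misalignment.
#' Symmetric under swapping the two anchors.
#'
#' @param boundary_upper,boundary_lower Numeric (x, y) anchor points in
#'   micrometres.
#' @return \eqn{\theta} in \[0, 90\] degrees.
#' @export
alignment_index <- function(boundary_upper, boundary_lower) {
  d <- as.numeric(boundary_upper) - as.numeric(boundary_lower)
  if (all(abs(d) < 1e-12)) stop("boundary anchor points coincide")
  alpha <- atan2(abs(d[2]), abs(d[1])) * 180 / pi
  abs(90 - alpha)
}

#' Aspect ratio of a DME cell
#'
#' Ratio of the cell's D/V length to its A/P length; leading-edge cells
#' are strongly elongated along D/V, so typical values are well above 1.
#'
#' @param dv_length,ap_length Positive lengths in micrometres.
#' @return Dimensionless ratio.
#' @export
aspect_ratio <- function(dv_length, ap_length) {
  dv_length <- as.numeric(dv_length)
  ap_length <- as.numeric(ap_length)
  if (any(!is.na(dv_length) & dv_length <= 0) || any(!is.na(ap_length) & ap_length <= 0)) {
    stop("cell axis lengths must be positive")
  }
  dv_length / ap_length
}

#' Fraction of cells with high aspect ratio
#'
#' @param ratios Aspect ratios (from [aspect_ratio()]).
#' @param cutoff Inclusive threshold (default 6).
#' @return Fraction of cells with ratio >= cutoff.
#' @export
high_ar_fraction <- function(ratios, cutoff = 6) {
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("no aspect ratios supplied")
  mean(ratios >= cutoff)
}
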