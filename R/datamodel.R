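# Tabular schemas, timeline conventions and dataset validation.

TABLE_SCHEMAS <- list(
  flanks = c(
    embryo_id = "character", side = "character", t_min = "numeric",
    L_um = "numeric", N_cells = "numeric"
  ),
  compartments = c(
    embryo_id = "character", side = "character", segment_id = "character",
    compartment = "character", t_min = "numeric", W_um = "numeric",
    n_cells = "numeric", visible_from = "numeric"
  ),
  interfaces = c(
    embryo_id = "character", interface_id = "character",
    segment_id = "character", compartment = "character", t_min = "numeric",
    stage = "character", angle_deg = "numeric", length_um = "numeric",
    sinuosity = "numeric", vdeg_a = "integer", vdeg_b = "integer",
    connects_two_DV = "logical", curved_flag = "logical",
    polyline = "character"
  ),
  events = c(
    embryo_id = "character", segment_id = "character", side = "character",
    t_min = "numeric", source = "character", delta_n = "integer"
  ),
  intensities = c(
    embryo_id = "character", marker = "character", stage = "character",
    I = "numeric", I_DV = "numeric", n_interfaces = "integer"
  ),
  snapshots = c(
    embryo_id = "character", segment_id = "character",
    compartment = "character", side = "character", stage = "character",
    distance_from_canthus_cells = "integer", is_central_most = "logical",
    cell_id = "character", has_interlocked_interface = "logical",
    dv_length_um = "numeric", ap_length_um = "numeric"
  ),
  replicates = c(
    embryo_id = "character", side = "character", t_min = "numeric",
    replicate = "integer", L_um = "numeric"
  )
)

#' Create an empty measurement table with the documented columns
#'
#' @param which One of `"flanks"`, `"compartments"`, `"interfaces"`,
#'   `"events"`, `"intensities"`, `"snapshots"`, `"replicates"`.
#' @return A zero-row data frame carrying the full column set of that table.
#' @export
empty_table <- function(which) {
  schema <- TABLE_SCHEMAS[[match.arg(which, names(TABLE_SCHEMAS))]]
  cols <- lapply(schema, function(cls) vector(cls, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Timeline convention for one embryo
#'
#' Times are retrospective: 0 marks the completion of closure and every
#' earlier frame is negative. `t_F` holds the fusion time of each segment
#' pair; `t_E` is the earliest analyzable frame (beginning of dorsal
#' closure). Length and width tracings are sampled every
#' `frame_interval_length` minutes, cell counts every
#' `frame_interval_count` minutes (the coarser five-minute grid used for
#' manual counting).
#'
#' @param t_E Earliest analyzable frame, minutes (non-positive).
#' @param t_F Named numeric vector, fusion time in minutes per segment id.
#' @param frame_interval_length Minutes between length/width frames.
#' @param frame_interval_count Minutes between cell-count frames; must be a
#'   multiple of `frame_interval_length`.
#' @return An object of class `timeline_convention`.
#' @export
timeline_convention <- function(t_E, t_F, frame_interval_length = 1,
                                frame_interval_count = 5) {
  if (is.null(names(t_F)) || any(!nzchar(names(t_F)))) {
    abort_validation("t_F must be a named vector keyed by segment id")
  }
  t_F <- stats::setNames(as.numeric(t_F), names(t_F))
  bad <- setdiff(names(t_F), SEGMENT_IDS)
  if (length(bad)) {
    abort_validation(paste0("unknown segment id(s) in t_F: ", paste(bad, collapse = ", ")))
  }
  if (any(t_F > 0)) {
    abort_validation("fusion times must be non-positive on the retrospective axis")
  }
  if (t_E > min(t_F)) {
    abort_validation("t_E must not be later than the earliest fusion time")
  }
  ratio <- frame_interval_count / frame_interval_length
  if (frame_interval_length <= 0 || frame_interval_count <= 0 ||
    abs(ratio - round(ratio)) > 1e-9) {
    abort_validation("frame_interval_count must be a positive integer multiple of frame_interval_length")
  }
  structure(
    list(
      t_E = as.numeric(t_E), t_F = t_F,
      frame_interval_length = frame_interval_length,
      frame_interval_count = frame_interval_count
    ),
    class = "timeline_convention"
  )
}

#' Assemble an embryo dataset from its measurement tables
#'
#' The dataset is the unit of analysis: one embryo's timeline plus the long
#' tables of tracked measurements (flank arcs, compartment fronts, fused
#' interfaces, cell-addition events, interface intensities, post-fusion cell
#' snapshots, and optional replicate tracings of the arcs).
#'
#' @param embryo_id Character scalar.
#' @param genotype_label Free-text genotype/perturbation label
#'   (e.g. `"control"`, `"tension_deficient"`, `"baz_deficient"`).
#' @param timeline A [timeline_convention()].
#' @param flanks,compartments,interfaces,events,intensities,snapshots,replicates
#'   Data frames with the documented columns (see [empty_table()]).
#'   `replicates` may be `NULL` when only averaged tracings are stored.
#' @param provenance Optional list recording simulator seed/parameters.
#' @param validate Check all invariants on construction (default `TRUE`).
#' @return An object of class `embryo_dataset`.
#' @export
embryo_dataset <- function(embryo_id, genotype_label, timeline,
                           flanks, compartments,
                           interfaces = empty_table("interfaces"),
                           events = empty_table("events"),
                           intensities = empty_table("intensities"),
                           snapshots = empty_table("snapshots"),
                           replicates = NULL,
                           provenance = NULL,
                           validate = TRUE) {
  ds <- structure(
    list(
      embryo_id = as.character(embryo_id),
      genotype_label = as.character(genotype_label),
      timeline = timeline,
      flanks = flanks, compartments = compartments,
      interfaces = interfaces, events = events,
      intensities = intensities, snapshots = snapshots,
      replicates = replicates, provenance = provenance
    ),
    class = "embryo_dataset"
  )
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.embryo_dataset <- function(x, ...) {
  cat("<embryo_dataset> ", x$embryo_id, " (", x$genotype_label, ")\n", sep = "")
  cat("  timeline: t_E =", x$timeline$t_E, "min,",
      length(x$timeline$t_F), "segment fusion times\n")
  for (nm in c("flanks", "compartments", "interfaces", "events", "intensities", "snapshots")) {
    cat(sprintf("  %-12s %d rows\n", nm, nrow(x[[nm]])))
  }
  if (!is.null(x$replicates)) cat("  replicates  ", nrow(x$replicates), "rows\n")
  invisible(x)
}

check_in <- function(values, allowed, table, column) {
  bad <- which(!is.na(values) & !(values %in% allowed))
  if (length(bad)) {
    abort_validation(
      paste0(
        "value '", values[bad[1]], "' not in {",
        paste(allowed, collapse = ", "), "}"
      ),
      file = table, row = bad[1], column = column
    )
  }
}

#' Validate every invariant of an embryo dataset
#'
#' Checks positivity of lengths and widths, integer non-negative cell
#' counts, the one-upper-one-lower flank requirement, segment and
#' compartment vocabularies, that events reference existing compartment
#' tracks within their visible window, angle and vertex-degree ranges on
#' interfaces, intensity positivity, and timeline consistency. Throws a
#' `fusefid_validation_error` naming table, row and column on the first
#' violation.
#'
#' @param ds An [embryo_dataset()].
#' @return `TRUE`, invisibly.
#' @export
validate_dataset <- function(ds) {
  if (!inherits(ds, "embryo_dataset")) abort_validation("not an embryo_dataset")
  tl <- ds$timeline
  if (!inherits(tl, "timeline_convention")) abort_validation("timeline must be a timeline_convention")

  fl <- ds$flanks
  check_in(fl$side, SIDES, "flanks", "side")
  for (s in SIDES) {
    if (!any(fl$side == s)) {
      abort_validation(paste0("missing ", s, " flank track"), file = "flanks")
    }
  }
  if (anyDuplicated(fl[c("side", "t_min")])) {
    abort_validation("duplicated (side, t_min) frame", file = "flanks",
                     row = anyDuplicated(fl[c("side", "t_min")]))
  }
  bad <- which(!is.na(fl$L_um) & fl$L_um <= 0)
  if (length(bad)) {
    abort_validation(paste0("nonpositive arc length ", fl$L_um[bad[1]]),
                     file = "flanks", row = bad[1], column = "L_um")
  }
  bad <- which(!is.na(fl$N_cells) & (fl$N_cells < 0 | !is_wholenumber(fl$N_cells)))
  if (length(bad)) {
    abort_validation(paste0("DME cell count must be a non-negative integer, got ", fl$N_cells[bad[1]]),
                     file = "flanks", row = bad[1], column = "N_cells")
  }

  cp <- ds$compartments
  check_in(cp$segment_id, SEGMENT_IDS, "compartments", "segment_id")
  check_in(cp$compartment, COMPARTMENT_TYPES, "compartments", "compartment")
  check_in(cp$side, SIDES, "compartments", "side")
  bad <- which(!is.na(cp$W_um) & cp$W_um <= 0)
  if (length(bad)) {
    abort_validation(paste0("nonpositive fusing-front width ", cp$W_um[bad[1]]),
                     file = "compartments", row = bad[1], column = "W_um")
  }
  bad <- which(!is.na(cp$n_cells) & (cp$n_cells < 1 | !is_wholenumber(cp$n_cells)))
  if (length(bad)) {
    abort_validation(paste0("compartment DME count must be an integer >= 1, got ", cp$n_cells[bad[1]]),
                     file = "compartments", row = bad[1], column = "n_cells")
  }
  bad <- which(!is.na(cp$t_min) & !is.na(cp$visible_from) & cp$t_min < cp$visible_from)
  if (length(bad)) {
    abort_validation("measurement frame precedes visible_from; mark missing instead",
                     file = "compartments", row = bad[1], column = "t_min")
  }

  ev <- ds$events
  check_in(ev$segment_id, SEGMENT_IDS, "events", "segment_id")
  check_in(ev$side, c(SIDES, "both"), "events", "side")
  check_in(ev$source, EVENT_SOURCES, "events", "source")
  bad <- which(!is.na(ev$delta_n) & ev$delta_n < 1)
  if (length(bad)) {
    abort_validation("delta_n must be >= 1", file = "events", row = bad[1], column = "delta_n")
  }
  if (nrow(ev)) {
    known <- unique(cp$segment_id[cp$compartment == "stripe"])
    bad <- which(!(ev$segment_id %in% known))
    if (length(bad)) {
      abort_validation(
        paste0("event references segment '", ev$segment_id[bad[1]], "' with no stripe track"),
        file = "events", row = bad[1], column = "segment_id"
      )
    }
    for (i in seq_len(nrow(ev))) {
      sides <- if (ev$side[i] == "both") SIDES else ev$side[i]
      for (s in sides) {
        tr <- cp[cp$segment_id == ev$segment_id[i] & cp$compartment == "stripe" & cp$side == s, ]
        if (!nrow(tr)) {
          abort_validation(
            paste0("event references missing ", s, " stripe track for ", ev$segment_id[i]),
            file = "events", row = i, column = "side"
          )
        }
        if (ev$t_min[i] < min(tr$t_min) - 1e-9 || ev$t_min[i] > max(tr$t_min) + 1e-9) {
          abort_validation(
            paste0("event time ", ev$t_min[i], " outside visible window of ", ev$segment_id[i], " ", s, " stripe"),
            file = "events", row = i, column = "t_min"
          )
        }
      }
    }
  }

  fc <- ds$interfaces
  check_in(fc$segment_id, SEGMENT_IDS, "interfaces", "segment_id")
  check_in(fc$compartment, COMPARTMENT_TYPES, "interfaces", "compartment")
  check_in(fc$stage, INTERFACE_STAGES, "interfaces", "stage")
  bad <- which(!is.na(fc$angle_deg) & (fc$angle_deg < 0 | fc$angle_deg > 90))
  if (length(bad)) {
    abort_validation("interface angle outside [0, 90] degrees",
                     file = "interfaces", row = bad[1], column = "angle_deg")
  }
  bad <- which(!is.na(fc$length_um) & fc$length_um <= 0)
  if (length(bad)) {
    abort_validation("nonpositive interface length",
                     file = "interfaces", row = bad[1], column = "length_um")
  }
  bad <- which(!is.na(fc$sinuosity) & fc$sinuosity < 1 - 1e-9)
  if (length(bad)) {
    abort_validation("sinuosity below 1 (polyline shorter than its chord)",
                     file = "interfaces", row = bad[1], column = "sinuosity")
  }
  for (col in c("vdeg_a", "vdeg_b")) {
    bad <- which(!is.na(fc[[col]]) & fc[[col]] < 2)
    if (length(bad)) {
      abort_validation("endpoint vertex degree must be >= 2",
                       file = "interfaces", row = bad[1], column = col)
    }
  }

  it <- ds$intensities
  check_in(it$marker, INTENSITY_MARKERS, "intensities", "marker")
  check_in(it$stage, INTENSITY_STAGES, "intensities", "stage")
  bad <- which(!is.na(it$I) & it$I < 0)
  if (length(bad)) {
    abort_validation("negative interface intensity", file = "intensities", row = bad[1], column = "I")
  }
  bad <- which(!is.na(it$I_DV) & it$I_DV <= 0)
  if (length(bad)) {
    abort_validation("D/V reference intensity must be positive",
                     file = "intensities", row = bad[1], column = "I_DV")
  }

  sn <- ds$snapshots
  check_in(sn$segment_id, SEGMENT_IDS, "snapshots", "segment_id")
  check_in(sn$compartment, COMPARTMENT_TYPES, "snapshots", "compartment")
  check_in(sn$side, SIDES, "snapshots", "side")
  check_in(sn$stage, SNAPSHOT_STAGES, "snapshots", "stage")
  for (col in c("dv_length_um", "ap_length_um")) {
    bad <- which(!is.na(sn[[col]]) & sn[[col]] <= 0)
    if (length(bad)) {
      abort_validation("cell axis length must be positive",
                       file = "snapshots", row = bad[1], column = col)
    }
  }

  rp <- ds$replicates
  if (!is.null(rp) && nrow(rp)) {
    check_in(rp$side, SIDES, "replicates", "side")
    agg <- stats::aggregate(L_um ~ side + t_min, data = rp, FUN = mean)
    for (i in seq_len(nrow(agg))) {
      stored <- fl$L_um[fl$side == agg$side[i] & fl$t_min == agg$t_min[i]]
      if (length(stored) == 1 && !is.na(stored) &&
          abs(stored - round(agg$L_um[i], 4)) > 1e-8) {
        abort_validation(
          paste0("stored L_um is not the arithmetic mean of its replicate tracings at t = ", agg$t_min[i]),
          file = "replicates", column = "L_um"
        )
      }
    }
  }

  invisible(TRUE)
}

#' Re-express a dataset on the retrospective time axis
#'
#' Maps all time columns so that completion of closure sits at 0 and every
#' earlier frame is negative. The completion time is taken as the latest
#' fusion time in the timeline (the first frame at which all compartment
#' pairs have fused). A dataset that is already retrospective is returned
#' unchanged; the mapping is an order-preserving affine shift, so pairwise
#' time differences are conserved exactly.
#'
#' @param ds An [embryo_dataset()].
#' @return The dataset with all `t_min`, `visible_from`, `t_E` and `t_F`
#'   values shifted.
#' @export
to_retrospective <- function(ds) {
  tl <- ds$timeline
  if (!length(tl$t_F)) {
    stop("no fusion times recorded: completion frame unknown, analyse on the prospective axis")
  }
  completion <- max(tl$t_F)
  times <- c(ds$flanks$t_min, ds$compartments$t_min, tl$t_F, tl$t_E)
  if (completion <= 0 && max(times, na.rm = TRUE) <= 0) {
    return(ds) # already retrospective
  }
  shift <- function(x) x - completion
  ds$timeline$t_E <- shift(tl$t_E)
  ds$timeline$t_F <- shift(tl$t_F)
  ds$flanks$t_min <- shift(ds$flanks$t_min)
  ds$compartments$t_min <- shift(ds$compartments$t_min)
  ds$compartments$visible_from <- shift(ds$compartments$visible_from)
  if (nrow(ds$interfaces)) ds$interfaces$t_min <- shift(ds$interfaces$t_min)
  if (nrow(ds$events)) ds$events$t_min <- shift(ds$events$t_min)
  if (!is.null(ds$replicates) && nrow(ds$replicates)) {
    ds$replicates$t_min <- shift(ds$replicates$t_min)
  }
  ds
}

#' Resolve a time relative to a segment's fusion
#'
#' `t_minus(ds, "A3", 100)` gives the t_-100 landmark of segment A3,
#' i.e. 100 minutes before that pair fuses.
#'
#' @param ds An [embryo_dataset()].
#' @param segment Segment id.
#' @param minutes Minutes before fusion (default 100).
#' @return Time in minutes on the dataset's (retrospective) axis.
#' @export
t_minus <- function(ds, segment, minutes = 100) {
  tf <- ds$timeline$t_F
  if (!(segment %in% names(tf))) {
    abort_validation(paste0("no fusion time recorded for segment ", segment))
  }
  unname(tf[[segment]] - minutes)
}

#' Average repeated tracings of one measurement
#'
#' Manual tracings are repeated (six times by convention) and the
#' arithmetic mean is stored. Fractional means of integer cell counts are
#' retained unrounded so that downstream disparity descriptors keep full
#' precision.
#'
#' @param traces Numeric vector of repeated measurements (length >= 1).
#' @return The arithmetic mean.
#' @export
replicate_average <- function(traces) {
  if (!length(traces)) stop("replicate_average() needs at least one trace")
  mean(as.numeric(traces))
}
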