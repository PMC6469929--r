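# Tiny hand-checkable datasets used in unit tests; every expected metric
# value is forced by simple arithmetic on the constants below.

fixture_base <- function(embryo_id, n_u_A3 = 3, n_l_A3 = 3) {
  tgrid <- seq(-45, 0, by = 5)
  timeline <- timeline_convention(
    t_E = -45, t_F = c(A2 = -10, A3 = 0),
    frame_interval_length = 5, frame_interval_count = 5
  )
  flanks <- rbind(
    data.frame(embryo_id = embryo_id, side = "upper", t_min = tgrid,
               L_um = 100, N_cells = 20, stringsAsFactors = FALSE),
    data.frame(embryo_id = embryo_id, side = "lower", t_min = tgrid,
               L_um = 100, N_cells = 20, stringsAsFactors = FALSE)
  )
  comp_row <- function(side, seg, comp, W, n) {
    data.frame(
      embryo_id = embryo_id, side = side, segment_id = seg, compartment = comp,
      t_min = tgrid, W_um = W, n_cells = n, visible_from = -45,
      stringsAsFactors = FALSE
    )
  }
  compartments <- rbind(
    comp_row("upper", "A2", "stripe", 20, 3),
    comp_row("lower", "A2", "stripe", 20, 3),
    comp_row("upper", "A2", "interstripe", 30, 6),
    comp_row("lower", "A2", "interstripe", 30, 6),
    comp_row("upper", "A3", "stripe", 20, n_u_A3),
    comp_row("lower", "A3", "stripe", 20, n_l_A3),
    comp_row("upper", "A3", "interstripe", 30, 6),
    comp_row("lower", "A3", "interstripe", 30, 6)
  )
  interfaces <- data.frame(
    embryo_id = embryo_id, interface_id = paste0(embryo_id, "_if1"),
    segment_id = "A3", compartment = "stripe", t_min = 0,
    stage = "post_fusion", angle_deg = 45, length_um = 2, sinuosity = 1,
    vdeg_a = 3L, vdeg_b = 3L, connects_two_DV = TRUE, curved_flag = FALSE,
    polyline = NA_character_, stringsAsFactors = FALSE
  )
  intensities <- data.frame(
    embryo_id = embryo_id, marker = "ecadherin", stage = "interlocked",
    I = 3, I_DV = 2, n_interfaces = 10L, stringsAsFactors = FALSE
  )
  embryo_dataset(
    embryo_id = embryo_id, genotype_label = "control", timeline = timeline,
    flanks = flanks, compartments = compartments, interfaces = interfaces,
    intensities = intensities
  )
}

#' Built-in worked fixtures
#'
#' Small datasets (two segments, ten frames) whose descriptor values are
#' forced by construction:
#' * `equal_pair`: all contralateral measurements equal, so every
#'   disparity descriptor is identically zero. Carries an interstripe
#'   pair with width 30 um and 6 DME cells (constriction index 5 um per
#'   cell) and an intensity record with I = 3, I_DV = 2 (normalized
#'   intensity 1.5).
#' * `one_cell_gap`: as `equal_pair` but the A3 stripe counts are
#'   3 (upper) vs 2 (lower), so the pair's DME difference is one cell at
#'   fusion and its normalized count disparity is 1/2.5 = 0.4 at every
#'   frame.
#' * `defective_stripe`: adds post-closure snapshots; the A2 stripe
#'   has 7 of 10 cells lacking interlocked interfaces (defective at the
#'   70 percent rule) and an Lb interstripe snapshot is not assessable.
#'
#' @param name Fixture name.
#' @return An [embryo_dataset()].
#' @export
make_fixture <- function(name = c("equal_pair", "one_cell_gap", "defective_stripe")) {
  name <- match.arg(name)
  switch(name,
    equal_pair = fixture_base("fx_equal"),
    one_cell_gap = fixture_base("fx_gap", n_u_A3 = 3, n_l_A3 = 2),
    defective_stripe = {
      ds <- fixture_base("fx_def")
      snap_row <- function(seg, comp, lacking, n = 10L) {
        data.frame(
          embryo_id = "fx_def", segment_id = seg, compartment = comp,
          side = "upper", stage = "post_closure",
          distance_from_canthus_cells = 15L, is_central_most = FALSE,
          cell_id = sprintf("fx_def_%s_%s_c%02d", seg, comp, seq_len(n)),
          has_interlocked_interface = seq_len(n) > lacking,
          dv_length_um = 10, ap_length_um = 2, stringsAsFactors = FALSE
        )
      }
      ds$snapshots <- rbind(
        snap_row("A2", "stripe", lacking = 7L),
        snap_row("Lb", "interstripe", lacking = 10L)
      )
      validate_dataset(ds)
      ds
    }
  )
}
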