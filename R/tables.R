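#' Reference lumen geometry of the reconstructed femoropopliteal models
#'
#' Bundled per-model geometry of a clinical femoropopliteal cohort
#' (eight patients imaged before and after endovascular treatment):
#' region-of-interest length, inlet cross-section area, total lumen
#' surface area and the surface/volume element counts of the
#' corresponding CFD meshes.  These printed values drive the group
#' statistics and serve as scale references for phantom design.
#'
#' @return tibble with columns `patient`, `time_point` (`pre_pta`,
#'   `post_pta`, `post_stent_str`, `post_stent_flx`), `inlet_location`,
#'   `length_mm`, `inlet_area_mm2`, `total_area_cm2`,
#'   `surface_elements`, `volume_elements`.
#' @export
#' @examples
#' g <- fp_lumen_geometry()
#' mean(g$total_area_cm2[g$time_point == "pre_pta"]) # 7.00 cm^2
fp_lumen_geometry <- function() {
  tibble::tribble(
    ~patient, ~time_point, ~inlet_location, ~length_mm, ~inlet_area_mm2, ~total_area_cm2, ~surface_elements, ~volume_elements,
    "P1", "pre_pta",        "distal_to_upstream_lesion", 49.03, 10.76,  4.44, 197988L, 5328000L,
    "P1", "post_pta",       "distal_to_upstream_stent",  50.53, 14.30,  7.97, 236736L, 7111860L,
    "P2", "pre_pta",        "proximal_to_lesion",        56.25, 13.39,  6.11, 206240L, 5647489L,
    "P2", "post_pta",       "proximal_to_lesion",        56.03, 12.82,  9.02, 222788L, 6371831L,
    "P3", "pre_pta",        "proximal_to_lesion",        63.33, 10.81,  6.53, 225686L, 6255287L,
    "P3", "post_pta",       "proximal_to_lesion",        62.64, 16.19,  9.85, 221462L, 6179122L,
    "P4", "pre_pta",        "proximal_to_lesion",        68.02, 17.92, 10.94, 232894L, 6616151L,
    "P4", "post_pta",       "proximal_to_lesion",        68.81, 16.79, 11.34, 228434L, 6450666L,
    "P5", "post_pta",       "intra_lesion",              60.35,  9.45,  7.75, 222052L, 6120032L,
    "P5", "post_stent",     "intra_stent",               60.52, 14.82, 10.33, 229954L, 6372419L,
    "P6", "post_pta",       "intra_lesion",              62.88, 16.73,  8.32, 260382L, 7215475L,
    "P6", "post_stent",     "intra_stent",               61.64, 20.23,  9.47, 265200L, 7510878L,
    "P7", "post_stent_str", "intra_stent",               54.90, 24.82,  9.99, 254698L, 7524110L,
    "P7", "post_stent_flx", "intra_stent",               54.90, 25.57,  9.67, 275128L, 7956485L,
    "P8", "post_pta",       "intra_lesion",              52.47, 15.20,  7.70, 278216L, 8199703L,
    "P8", "post_stent",     "intra_stent",               52.60, 46.34, 11.87, 292484L, 9283600L
  )
}

#' Duplex-ultrasound velocity averages by treatment stage and segment
#'
#' Population-average peak systolic velocity (PSV) and minimum
#' diastolic velocity (MDV) from a 24-patient duplex-ultrasound
#' femoropopliteal cohort, by treatment stage and arterial segment
#' relative to the lesion/treated region.  Segments without a reverse
#' diastolic phase (monophasic flow) carry `NA` MDV.  These values
#' parameterize the inlet waveform templates of [build_waveform].
#'
#' @return tibble with columns `time_point`, `segment` (`proximal`,
#'   `intra`, `distal`), `psv_cm_s`, `psv_sd`, `mdv_cm_s`, `mdv_sd`,
#'   `phase_type`.
#' @export
fp_dus_velocities <- function() {
  tibble::tribble(
    ~time_point, ~segment, ~psv_cm_s, ~psv_sd, ~mdv_cm_s, ~mdv_sd, ~phase_type,
    "pre_pta",    "proximal", 88.30, 28.40, -14.90, 3.42, "triphasic",
    "pre_pta",    "intra",   262.68, 77.32,  NA,    NA,   "monophasic",
    "pre_pta",    "distal",   43.01, 16.87,  NA,    NA,   "monophasic",
    "post_pta",   "proximal",103.00, 48.21, -17.20, 5.54, "triphasic",
    "post_pta",   "intra",    81.60, 38.53, -13.80, 3.09, "triphasic",
    "post_pta",   "distal",   62.75, 24.36, -13.67, 2.77, "triphasic",
    "post_stent", "proximal",123.00, 53.78, -21.21, 4.63, "triphasic",
    "post_stent", "intra",    70.64, 33.87, -11.90, 4.51, "triphasic",
    "post_stent", "distal",   60.63, 37.18, -10.17, 1.25, "triphasic"
  )
}

#' Time-averaged inlet flow rates of the reconstructed models
#'
#' Per-model time-averaged volumetric flow rate at the inlet (ml/min)
#' resulting from the adopted inlet boundary conditions.
#'
#' @return tibble with columns `patient`, `time_point`,
#'   `flow_ml_min`.
#' @export
#' @examples
#' f <- fp_inlet_flows()
#' mean(f$flow_ml_min[f$time_point == "post_pta" &
#'                    f$patient %in% c("P1", "P2", "P3", "P4")]) # 86.73
fp_inlet_flows <- function() {
  tibble::tribble(
    ~patient, ~time_point, ~flow_ml_min,
    "P1", "pre_pta",  23.72, "P1", "post_pta", 52.05,
    "P2", "pre_pta",  72.24, "P2", "post_pta", 81.13,
    "P3", "pre_pta",  61.13, "P3", "post_pta", 104.81,
    "P4", "pre_pta",  99.85, "P4", "post_pta", 108.94,
    "P5", "post_pta", 49.06, "P5", "post_stent", 61.68,
    "P6", "post_pta", 83.21, "P6", "post_stent", 88.04,
    "P7", "post_stent_str", 124.21, "P7", "post_stent_flx", 111.06,
    "P8", "post_pta", 77.80, "P8", "post_stent", 163.53
  )
}
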