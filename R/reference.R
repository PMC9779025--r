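#' Published damage-induction rates along a therapeutic proton SOBP
#'
#' Mean damage-induction rates (events per Mbp per Gy, with standard errors
#' of the mean) measured for pBR322 in aqueous solution irradiated at three
#' positions along a clinical spread-out Bragg peak proton plan and with
#' reference 200-kV X-rays. These published beamline measurements serve as
#' the default simulator ground truth and as inputs for the derived
#' summaries (RBE, damage ratios).
#'
#' @return A tibble with columns `condition`, `radiation`, `position`,
#'   `metric` (`ssb`, `dsb`, `base_lesions`, `non_dsb_clusters`), `g_value`
#'   and `sem`.
#' @examples
#' reference_yields()
#' @export
reference_yields <- function() {
  tibble::tribble(
    ~condition, ~radiation, ~position, ~metric, ~g_value, ~sem,
    "proton_entrance", "proton", "entrance", "ssb", 101.101, 16.868,
    "proton_entrance", "proton", "entrance", "dsb", 1.914, 0.247,
    "proton_entrance", "proton", "entrance", "base_lesions", 275.852, 114.295,
    "proton_entrance", "proton", "entrance", "non_dsb_clusters", 10.908, 1.778,
    "proton_mid_sobp", "proton", "mid_sobp", "ssb", 96.012, 27.211,
    "proton_mid_sobp", "proton", "mid_sobp", "dsb", 1.529, 0.169,
    "proton_mid_sobp", "proton", "mid_sobp", "base_lesions", 52.085, 2.365,
    "proton_mid_sobp", "proton", "mid_sobp", "non_dsb_clusters", 10.415, 1.666,
    "proton_falloff", "proton", "falloff", "ssb", 51.069, 6.923,
    "proton_falloff", "proton", "falloff", "dsb", 0.579, 0.060,
    "proton_falloff", "proton", "falloff", "base_lesions", 54.453, 6.350,
    "proton_falloff", "proton", "falloff", "non_dsb_clusters", 3.255, 0.092,
    "xray", "xray", "entrance", "ssb", 89.559, 4.490,
    "xray", "xray", "entrance", "dsb", 3.147, 0.141,
    "xray", "xray", "entrance", "base_lesions", 191.102, 10.867,
    "xray", "xray", "entrance", "non_dsb_clusters", 14.723, 0.856
  )
}

#' Irradiation positions along the proton treatment plan
#'
#' Condition metadata for the three sampling positions along the spread-out
#' Bragg peak: depth (in PMMA), dose-averaged LET and beam energy range.
#'
#' @return A tibble with `position`, `depth_cm`, `let_kev_um`, `energy_mev`.
#' @export
beam_conditions <- function() {
  tibble::tribble(
    ~position, ~depth_cm, ~let_kev_um, ~energy_mev,
    "entrance", 2, 1, "198",
    "mid_sobp", 15, 3, "137-167",
    "falloff", 16.8, 9, "137-167"
  )
}
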