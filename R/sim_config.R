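#' Simulation configuration
#'
#' Parameters of the synthetic sequential-mapping generator. Defaults follow
#' the clinical acquisition setup where one is stated (1000 Hz electrogram
#' sampling, 40 Hz coordinate sampling) and desk-scale choices elsewhere;
#' see the methods vignette for the rationale behind each free knob.
#'
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration including this seed.
#' @param duration_s recording length in seconds (> 4 so every mapping point
#'   has a full 2-s analysis window on both sides).
#' @param signal_fs electrogram sampling rate, Hz.
#' @param coord_fs electrode-coordinate sampling rate, Hz.
#' @param n_channels number of bipolar mapping channels (electrodes riding
#'   on one catheter, so channels cluster spatially).
#' @param noise_sd additive Gaussian noise standard deviation, mV.
#' @param artifact_rate large-amplitude (> 16 mV) artifact events per minute
#'   per channel.
#' @param dropout_rate poor-contact dropout segments (amplitude scaled below
#'   0.2 mV, 0.5-2 s long) per minute per channel.
#' @param powerline_hz mains frequency, 50 or 60 Hz.
#' @param powerline_amp amplitude of the continuous mains sinusoid, mV.
#' @param cycle_jitter_frac multiplicative Gaussian jitter on each activation
#'   cycle length (truncated at +/- 3 SD), unitless fraction.
#' @param trajectory_step_mm RMS drift of the catheter per coordinate sample
#'   while dwelling at a mapping site, mm.
#' @param site_dwell_s length-2 range of the dwell time per mapping site, s.
#'   Dwells longer than the 2-s analysis window keep the central windows
#'   spatially stationary.
#' @param site_transition_s catheter repositioning time between sites, s.
#' @param revisit_prob probability that a site revisits a previously mapped
#'   location instead of advancing the sweep, creating long per-voxel time
#'   spans.
#' @param cs_cycle_ms activation cycle length of the reference
#'   (coronary-sinus-like) channel during fibrillation, ms.
#' @param non_af_cycle_ms reference cycle length outside fibrillation, ms.
#' @param af_spans list of `c(start_s, end_s)` fibrillation spans for the
#'   reference channel; `NULL` means the whole recording is fibrillatory.
#' @param deflection_amp_mv nominal activation deflection amplitude, mV.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 90,
                       signal_fs = 1000,
                       coord_fs = 40,
                       n_channels = 6L,
                       noise_sd = 0.05,
                       artifact_rate = 2,
                       dropout_rate = 1,
                       powerline_hz = 50,
                       powerline_amp = 0.02,
                       cycle_jitter_frac = 0.03,
                       trajectory_step_mm = 0.15,
                       site_dwell_s = c(2.5, 5),
                       site_transition_s = 0.3,
                       revisit_prob = 0.15,
                       cs_cycle_ms = 170,
                       non_af_cycle_ms = 600,
                       af_spans = NULL,
                       deflection_amp_mv = 1.0) {
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              signal_fs = signal_fs, coord_fs = coord_fs,
              n_channels = as.integer(n_channels), noise_sd = noise_sd,
              artifact_rate = artifact_rate, dropout_rate = dropout_rate,
              powerline_hz = powerline_hz, powerline_amp = powerline_amp,
              cycle_jitter_frac = cycle_jitter_frac,
              trajectory_step_mm = trajectory_step_mm,
              site_dwell_s = site_dwell_s,
              site_transition_s = site_transition_s,
              revisit_prob = revisit_prob, cs_cycle_ms = cs_cycle_ms,
              non_af_cycle_ms = non_af_cycle_ms, af_spans = af_spans,
              deflection_amp_mv = deflection_amp_mv)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$duration_s > 4,
            cfg$signal_fs > 0, cfg$coord_fs > 0,
            cfg$n_channels >= 1L,
            cfg$noise_sd >= 0, cfg$artifact_rate >= 0, cfg$dropout_rate >= 0,
            cfg$powerline_hz %in% c(50, 60),
            cfg$cycle_jitter_frac >= 0, cfg$cycle_jitter_frac < 0.5,
            cfg$trajectory_step_mm > 0,
            length(cfg$site_dwell_s) == 2L,
            cfg$site_dwell_s[1] > 0,
            cfg$site_dwell_s[1] <= cfg$site_dwell_s[2],
            cfg$site_transition_s >= 0,
            cfg$revisit_prob >= 0, cfg$revisit_prob < 1)
  if (!is.null(cfg$af_spans)) {
    for (sp in cfg$af_spans)
      stopifnot(length(sp) == 2L, sp[1] < sp[2], sp[1] >= 0,
                sp[2] <= cfg$duration_s)
  }
  invisible(cfg)
}
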