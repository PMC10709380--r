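#' Simulator configuration
#'
#' Builds the parameter set for the synthetic resting-state EEG generator.
#' The generated signal is a sum of: a 1/f ("pink") background, a
#' narrowband region-weighted alpha oscillation (random-phase, Gaussian
#' spectral bump), mains harmonics, an optional 217 Hz pulsed-carrier
#' artifact with its 868 Hz harmonic when the RF exposure is on, and white
#' sensor noise.
#'
#' @param sampling_rate Sampling rate in Hz (default 2500).
#' @param channels Channel labels, a subset of the montage in
#'   [region_map()]. Default: one representative channel per region
#'   (Cz, Fz, Oz, Pz, T7, T8); use `unlist(region_map())` for the full
#'   63-channel montage.
#' @param alpha_center Alpha peak frequency in Hz; kept inside the 6-10 Hz
#'   analysis band so a configured exposure effect is visible to it.
#' @param alpha_bandwidth Full width at half maximum of the alpha spectral
#'   bump, Hz.
#' @param alpha_power_by_region Named vector (uV^2/Hz): peak PSD of the
#'   alpha bump per region in the eyes-closed, sham condition. Occipital
#'   and parietal are strongest, as on the resting scalp.
#' @param eo_attenuation Multiplicative factor (0, 1] applied to alpha
#'   power with eyes open (alpha blocking).
#' @param emf_effect Named vector `c(EO = , EC = )` of multiplicative
#'   factors applied to alpha power while the RF exposure is active.
#'   Default: EC unaffected, and EO calibrated with
#'   [calibrate_emf_effect()] so the expected measured group difference in
#'   eyes-open band contrasts is 0.72 uV^2/Hz, the size of effect the
#'   design is meant to resolve.
#' @param pink_exponent Spectral slope beta of the 1/f background.
#' @param pink_scale PSD of the background at 1 Hz, uV^2/Hz.
#' @param mains Named vector of mains-harmonic amplitudes (uV) by frequency
#'   (Hz); harmonics above Nyquist are skipped.
#' @param pulsation Named vector of pulsed-carrier component amplitudes
#'   (uV) by frequency (Hz), synthesized only while RF is on. The 900 MHz
#'   carrier itself is metadata (`carrier_frequency_hz`), never sampled.
#' @param sensor_noise_sd White sensor noise standard deviation, uV.
#' @param subject_sd Standard deviation (log scale) of the per-subject
#'   log-normal alpha power multiplier; the multiplier has mean 1 so
#'   cohort-level expectations are unchanged.
#' @param carryover If `TRUE` (default), the exposure effect persists into
#'   the sham session that follows an exposed session, so group 1 (exposed
#'   first) has expected contrast ~0 while group 2 carries the full effect.
#' @param carrier_frequency_hz RF carrier frequency, metadata only.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 2500,
                       channels = c("Cz", "Fz", "Oz", "Pz", "T7", "T8"),
                       alpha_center = 10,
                       alpha_bandwidth = 2,
                       alpha_power_by_region = c(central = 10, frontal = 8,
                                                 occipital = 20, parietal = 16,
                                                 temporal_left = 9,
                                                 temporal_right = 9),
                       eo_attenuation = 0.5,
                       emf_effect = NULL,
                       pink_exponent = 1,
                       pink_scale = 15,
                       mains = c(`50` = 2, `150` = 0.5, `250` = 0.4,
                                 `350` = 0.3, `450` = 0.3, `650` = 0.2,
                                 `750` = 0.2),
                       pulsation = c(`217` = 0.8, `868` = 0.4),
                       sensor_noise_sd = 1,
                       subject_sd = 0.4,
                       carryover = TRUE,
                       carrier_frequency_hz = 9e8) {
  channel_region(channels)  # validates labels
  stopifnot(sampling_rate > 0,
            alpha_center >= 6, alpha_center <= 10,
            alpha_bandwidth > 0,
            all(alpha_power_by_region >= 0),
            identical(sort(names(alpha_power_by_region)), sort(regions())),
            eo_attenuation > 0, eo_attenuation <= 1,
            pink_scale >= 0, all(mains >= 0), all(pulsation >= 0),
            sensor_noise_sd >= 0, subject_sd >= 0)
  cfg <- list(sampling_rate = sampling_rate, channels = channels,
              alpha_center = alpha_center, alpha_bandwidth = alpha_bandwidth,
              alpha_power_by_region = alpha_power_by_region,
              eo_attenuation = eo_attenuation,
              emf_effect = c(EO = 1, EC = 1),
              pink_exponent = pink_exponent, pink_scale = pink_scale,
              mains = mains, pulsation = pulsation,
              sensor_noise_sd = sensor_noise_sd, subject_sd = subject_sd,
              carryover = carryover,
              carrier_frequency_hz = carrier_frequency_hz)
  class(cfg) <- "sim_config"
  if (is.null(emf_effect)) {
    emf_effect <- c(EO = calibrate_emf_effect(cfg, target = 0.72), EC = 1)
  }
  stopifnot(all(emf_effect > 0), all(c("EO", "EC") %in% names(emf_effect)))
  cfg$emf_effect <- emf_effect[c("EO", "EC")]
  cfg
}

#' Session block schedule
#'
#' Builds the timeline of one recording session: a washout rest period
#' followed by alternating eyes-open / eyes-closed blocks separated by
#' short self-paced breaks (drawn uniformly from `break_range` seconds).
#' The exposure state is constant within a session.
#'
#' @param rf_on Logical: is the RF exposure active during this session?
#' @param n_cycles Number of EO/EC alternations (default 5).
#' @param eo_s,ec_s Eyes-open / eyes-closed block durations, seconds.
#' @param washout_s Washout duration in seconds (default 15 min); set to 0
#'   to skip it (it contributes no analysis epochs).
#' @param break_range Range (seconds) of the uniform break duration.
#' @param seed Integer seed for the break durations, or `NULL`.
#' @return A `block_schedule` data frame with columns `label`
#'   (washout/EO/break/EC), `duration` (s) and `rf_on`.
#' @export
session_schedule <- function(rf_on, n_cycles = 5, eo_s = 90, ec_s = 90,
                             washout_s = 900, break_range = c(6, 16),
                             seed = NULL) {
  stopifnot(is.logical(rf_on), length(rf_on) == 1L, n_cycles >= 1)
  brk <- with_seed(seed, stats::runif(2 * n_cycles, break_range[1], break_range[2]))
  lab <- character(0); dur <- numeric(0)
  if (washout_s > 0) { lab <- "washout"; dur <- washout_s }
  for (i in seq_len(n_cycles)) {
    lab <- c(lab, "EO", "break", "EC", "break")
    dur <- c(dur, eo_s, brk[2 * i - 1], ec_s, brk[2 * i])
  }
  out <- data.frame(label = lab, duration = dur, rf_on = rf_on)
  class(out) <- c("block_schedule", "data.frame")
  out
}
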