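# Closed-form expectations for the generator, used to calibrate the
# configured exposure effect against what the spectral pipeline measures.
# Average referencing mixes channel spectra: for independent per-channel
# sources on C channels, the referenced density of channel c is
# (1-1/C)^2 S_c + (1/C^2) sum_{k != c} S_k.

analysis_band_bins <- function(band = c(6, 10), df = 0.25) {
  seq(band[1], band[2], by = df)
}

# expected per-channel alpha contribution to the band-mean density
# (uV^2/Hz), before referencing; `scale` multiplies alpha power
channel_alpha_band <- function(config, scale = 1, band = c(6, 10)) {
  bins <- analysis_band_bins(band)
  bump_mean <- mean(alpha_bump(bins, config$alpha_center, config$alpha_bandwidth))
  p <- config$alpha_power_by_region[channel_region(config$channels)] * scale
  unname(p * bump_mean)
}

avg_reference_mix <- function(s) {
  C <- length(s)
  if (C == 1L) return(s)
  (1 - 1 / C)^2 * s + (sum(s) - s) / C^2
}

#' Expected measured group difference for a configuration
#'
#' Computes, in closed form, the expected difference between group-2 and
#' group-1 mean eyes-open band contrasts that the spectral pipeline would
#' measure on data from [simulate_cohort()]: the exposure adds
#' `(emf_effect[EO] - 1)` times the eyes-open alpha band density to the
#' exposed session; average referencing and region averaging are applied
#' as in the pipeline. With carryover, group 1's expected contrast is 0;
#' without it, it is minus the group-2 contrast.
#'
#' @param config A [sim_config()].
#' @param band Analysis band, Hz.
#' @return Expected difference in uV^2/Hz.
#' @export
expected_group_difference <- function(config, band = c(6, 10)) {
  delta <- config$emf_effect[["EO"]] - 1
  added <- channel_alpha_band(config, scale = config$eo_attenuation * delta,
                              band = band)
  mixed <- avg_reference_mix(added)
  reg <- channel_region(config$channels)
  g2 <- mean(tapply(mixed, factor(reg, levels = unique(reg)), mean))
  if (config$carryover) g2 else 2 * g2
}

#' Calibrate the exposure effect to a target group difference
#'
#' Solves for the eyes-open alpha power multiplier `emf_effect[EO]` such
#' that [expected_group_difference()] equals `target`. The relation is
#' linear in `emf_effect[EO] - 1`.
#'
#' @param config A [sim_config()] (its current `emf_effect` is ignored).
#' @param target Target expected group difference, uV^2/Hz (default 0.72,
#'   the effect size the crossover design is meant to resolve).
#' @return The calibrated `emf_effect[EO]` multiplier.
#' @export
calibrate_emf_effect <- function(config, target = 0.72) {
  unit <- config
  unit$emf_effect <- c(EO = 2, EC = 1)  # delta = 1
  per_unit <- expected_group_difference(unit)
  if (per_unit <= 0) stop("configuration has no eyes-open alpha to modulate")
  1 + target / per_unit
}
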