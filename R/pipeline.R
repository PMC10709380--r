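# End-to-end wrappers from recordings to the analysis-ready contrast table.

#' Per-subject session contrasts from a pair of recordings
#'
#' Runs the full spectral chain on both sessions of one subject:
#' preprocess (downsample, high-pass, average reference), segment the
#' requested condition into 4-s epochs, amplitude-threshold rejection,
#' Welch PSD, region averaging, band power, and the B - A contrast.
#'
#' @param rec_a,rec_b Session A and B `recording`s.
#' @param condition Condition label to analyze (default `"EO"`).
#' @param band Analysis band in Hz.
#' @param target_rate Analysis sampling rate, Hz.
#' @param threshold_uv Epoch rejection threshold, uV.
#' @return Named numeric vector of per-region contrasts.
#' @export
subject_contrasts <- function(rec_a, rec_b, condition = "EO", band = c(6, 10),
                              target_rate = 250, threshold_uv = 100) {
  bp <- lapply(list(rec_a, rec_b), function(rec) {
    rec <- preprocess(rec, target_rate = target_rate)
    ep <- reject_epochs(segment_epochs(rec, condition), threshold_uv)
    band_power(region_average(welch_psd(ep)), band = band)
  })
  session_contrast(bp[[1L]], bp[[2L]])
}

#' Simulate and analyze a whole cohort
#'
#' Streams through `n` subjects (group assignment from
#' [generate_blinding_table()]), simulating both sessions and reducing them
#' to per-region contrasts one subject at a time, so memory stays flat.
#'
#' @inheritParams simulate_subject
#' @inheritParams subject_contrasts
#' @param n Even number of subjects.
#' @return A [contrast_table()] with `6 * n` rows.
#' @export
cohort_contrasts <- function(n, config, seed, schedule_args = list(),
                             condition = "EO", band = c(6, 10),
                             threshold_uv = 100) {
  blinding <- generate_blinding_table(n, seed)
  target_rate <- min(250, config$sampling_rate)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- simulate_subject(config, blinding$group[i], i, seed,
                             schedule_args = schedule_args)
    ct <- subject_contrasts(pair$A, pair$B, condition = condition,
                            band = band, target_rate = target_rate,
                            threshold_uv = threshold_uv)
    rows[[i]] <- data.frame(subject = i, group = blinding$group[i],
                            region = names(ct), contrast = unname(ct))
  }
  df <- do.call(rbind, rows)
  # contrast_table() wants equal group sizes; blinding guarantees this
  contrast_table(df)
}
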