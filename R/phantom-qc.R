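#' Phantom quality-control comparison
#'
#' Compares phantom-recording PSDs with the exposure on and off. A clean
#' acquisition chain shows the pulsed-carrier peak (217 Hz and its 868 Hz
#' harmonic) only while RF is on, and no difference in the physiological
#' range: the check passes iff no pulsation-frequency peak appears in the
#' RF-off spectrum and the 0-50 Hz PSD difference stays below
#' `max_se` pooled across-epoch standard errors at every bin.
#'
#' Peaks are local maxima exceeding `peak_ratio` times a running-median
#' noise floor. Channel spectra are pooled (averaged) before comparison.
#'
#' @param psd_on,psd_off `psd` objects on identical frequency grids
#'   (full-rate phantom analysis, no downsampling).
#' @param phys_band Physiological band to test for interference, Hz.
#' @param peak_ratio Peak detection threshold over the local median floor.
#' @param max_se Pass threshold on the banded difference, in pooled SEs.
#' @return A `phantom_qc` list: detected `peaks_on` / `peaks_off` (Hz),
#'   `max_diff_se` over the physiological band, `pulsation_only_on`,
#'   and `pass`.
#' @export
phantom_qc <- function(psd_on, psd_off, phys_band = c(0, 50),
                       peak_ratio = 5, max_se = 3) {
  if (!isTRUE(all.equal(psd_on$freq, psd_off$freq))) {
    stop("PSD frequency grids differ")
  }
  pool <- function(p) list(
    power = colMeans(p$power),
    se = colMeans(p$sd) / sqrt(p$n_epochs)
  )
  on <- pool(psd_on); off <- pool(psd_off)
  find_peaks <- function(power, freq) {
    k <- max(3L, 2L * (round(4 / (freq[2] - freq[1])) %/% 2L) + 1L)
    floor_ <- stats::runmed(power, k)
    i <- which(power > peak_ratio * floor_)
    i <- i[i > 1 & i < length(power)]
    i <- i[power[i] >= power[i - 1] & power[i] >= power[i + 1]]
    freq[i]
  }
  peaks_on <- find_peaks(on$power, psd_on$freq)
  peaks_off <- find_peaks(off$power, psd_off$freq)
  pulse_freqs <- c(217, 868)
  near_pulse <- function(peaks) any(vapply(pulse_freqs, function(f)
    any(abs(peaks - f) <= 1), logical(1)))
  sel <- psd_on$freq >= phys_band[1] & psd_on$freq <= phys_band[2]
  se <- sqrt(on$se[sel]^2 + off$se[sel]^2)
  dse <- abs(on$power[sel] - off$power[sel]) / pmax(se, .Machine$double.eps)
  max_diff_se <- max(dse)
  pulsation_only_on <- !near_pulse(peaks_off)
  structure(list(peaks_on = peaks_on, peaks_off = peaks_off,
                 max_diff_se = max_diff_se,
                 pulsation_only_on = pulsation_only_on,
                 pass = pulsation_only_on && max_diff_se < max_se),
            class = "phantom_qc")
}

#' @export
print.phantom_qc <- function(x, ...) {
  cat("phantom QC:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  max |PSD difference| in physiological band: %.2f SE\n",
              x$max_diff_se))
  cat("  peaks RF on (Hz): ", paste(round(x$peaks_on, 2), collapse = ", "), "\n")
  cat("  peaks RF off (Hz):", paste(round(x$peaks_off, 2), collapse = ", "), "\n")
  invisible(x)
}
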