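# Spectral pipeline: recordings -> preprocessed signal -> 4-s epochs ->
# Welch PSD -> region spectra -> alpha band power -> session contrasts.

#' Preprocess a recording
#'
#' Downsamples to `target_rate` (anti-alias low-pass at 0.8x the target
#' Nyquist, then decimation), applies a zero-phase (forward-backward)
#' high-pass, and re-references every sample to the channel average.
#' Annotations are re-indexed to the new rate.
#'
#' @param recording A `recording`.
#' @param target_rate Target sampling rate, Hz; the input rate must be an
#'   integer multiple of it.
#' @param highpass High-pass cutoff in Hz (default 1); 0 disables it.
#' @return The preprocessed `recording`.
#' @export
preprocess <- function(recording, target_rate = 250, highpass = 1) {
  fs <- recording$rate
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop("sampling rate ", fs, " is not an integer multiple of ", target_rate)
  }
  factor <- as.integer(round(factor))
  X <- recording$samples
  if (factor > 1L) {
    aa <- signal::butter(4, (0.8 * target_rate / 2) / (fs / 2), type = "low")
    X <- t(apply(X, 1L, function(x) signal::filtfilt(aa, x)))
    X <- X[, seq(1L, ncol(X), by = factor), drop = FALSE]
  }
  if (highpass > 0) {
    hp <- signal::butter(2, highpass / (target_rate / 2), type = "high")
    X <- t(apply(X, 1L, function(x) signal::filtfilt(hp, x)))
  }
  if (nrow(X) > 1L) X <- sweep(X, 2L, colMeans(X))
  ann <- recording$annotations
  ann$onset <- (ann$onset - 1L) %/% factor + 1L
  ann$n_samples <- ann$n_samples %/% factor
  out <- recording
  out$samples <- X
  out$rate <- target_rate
  out$annotations <- ann
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts non-overlapping consecutive windows of `epoch_s` seconds from
#' every annotated interval with the requested condition label; partial
#' windows at interval ends are dropped.
#'
#' @param recording A `recording` with annotations.
#' @param condition Block label to extract (e.g. `"EO"`, `"EC"`,
#'   `"phantom"`).
#' @param epoch_s Epoch length in seconds (default 4).
#' @return An `epoch_set`: array `[epoch, channel, sample]` with the
#'   sampling rate, condition and a logical `kept` flag per epoch as
#'   attributes.
#' @export
segment_epochs <- function(recording, condition, epoch_s = 4) {
  ann <- recording$annotations
  sel <- ann[ann$label == condition, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no interval with condition '", condition, "'")
  len <- as.integer(round(epoch_s * recording$rate))
  starts <- integer(0)
  for (b in seq_len(nrow(sel))) {
    k <- sel$n_samples[b] %/% len
    if (k > 0L) starts <- c(starts, sel$onset[b] + (0:(k - 1L)) * len)
  }
  if (length(starts) == 0L) {
    stop("no interval with condition '", condition,
         "' is long enough for a ", epoch_s, " s epoch")
  }
  E <- array(0, dim = c(length(starts), nrow(recording$samples), len),
             dimnames = list(NULL, recording$channels, NULL))
  for (i in seq_along(starts)) {
    E[i, , ] <- recording$samples[, starts[i]:(starts[i] + len - 1L)]
  }
  structure(E, rate = recording$rate, condition = condition,
            kept = rep(TRUE, length(starts)), class = "epoch_set")
}

#' Amplitude-threshold epoch rejection
#'
#' Flags any epoch whose absolute amplitude exceeds `threshold_uv` on any
#' channel. An automated stand-in for visual artifact screening.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Rejection threshold in uV (default 100).
#' @return The `epoch_set` with its `kept` attribute updated.
#' @export
reject_epochs <- function(epochs, threshold_uv = 100) {
  peak <- apply(abs(epochs), 1L, max)
  kept <- peak <= threshold_uv
  if (!any(kept)) {
    stop("all epochs exceed ", threshold_uv, " uV; nothing left to analyze")
  }
  attr(epochs, "kept") <- kept
  epochs
}

#' Welch power spectral density over epochs
#'
#' Estimates the one-sided PSD per channel as the average over kept epochs
#' of Hann-tapered periodograms (one taper per epoch, no sub-segmentation).
#' Densities are normalized so the integral over frequency equals the
#' window-power-normalized variance of the tapered epoch (Parseval), in
#' uV^2/Hz. The standard deviation over epochs is returned alongside.
#'
#' @param epochs An `epoch_set` (after [reject_epochs()] if desired).
#' @return A `psd`: list with `freq` (Hz), `power` (channels x frequency),
#'   `sd` (same shape, across-epoch SD), `n_epochs`, `rate`.
#' @export
welch_psd <- function(epochs) {
  kept <- which(attr(epochs, "kept"))
  if (length(kept) == 0L) stop("no kept epochs")
  fs <- attr(epochs, "rate")
  n <- dim(epochs)[3L]
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)
  wpow <- sum(w^2)
  nfreq <- n %/% 2L + 1L
  freq <- (0:(nfreq - 1L)) * fs / n
  scale <- 2 / (fs * wpow)          # one-sided density
  scale_edge <- 1 / (fs * wpow)     # DC and Nyquist bins are not doubled
  nch <- dim(epochs)[2L]
  acc <- matrix(0, nch, nfreq)
  acc2 <- matrix(0, nch, nfreq)
  for (i in kept) {
    seg <- epochs[i, , , drop = FALSE]
    dim(seg) <- dim(epochs)[2:3]
    ft <- stats::mvfft(t(seg * rep(w, each = nch)))
    p <- Mod(ft[seq_len(nfreq), , drop = FALSE])^2
    p <- t(p) * scale
    p[, 1L] <- p[, 1L] / 2
    if (n %% 2L == 0L) p[, nfreq] <- p[, nfreq] / 2
    acc <- acc + p
    acc2 <- acc2 + p^2
  }
  m <- acc / length(kept)
  v <- pmax(acc2 / length(kept) - m^2, 0)
  sd <- if (length(kept) > 1L) {
    sqrt(v * length(kept) / (length(kept) - 1L))
  } else {
    matrix(NA_real_, nch, nfreq)
  }
  dimnames(m) <- dimnames(sd) <- list(dimnames(epochs)[[2L]], NULL)
  structure(list(freq = freq, power = m, sd = sd,
                 n_epochs = length(kept), rate = fs,
                 condition = attr(epochs, "condition")),
            class = "psd")
}

#' Average channel spectra into region spectra
#'
#' @param psd A `psd` with channel rows.
#' @param map Region map as from [region_map()]; regions with no available
#'   channel raise an error, missing channels within a region are skipped.
#' @return A `psd` whose rows are the six regions.
#' @export
region_average <- function(psd, map = region_map()) {
  chans <- rownames(psd$power)
  P <- matrix(0, length(map), ncol(psd$power),
              dimnames = list(names(map), NULL))
  S <- P
  for (r in names(map)) {
    have <- intersect(map[[r]], chans)
    if (length(have) == 0L) stop("no channels available for region ", r)
    P[r, ] <- colMeans(psd$power[have, , drop = FALSE])
    S[r, ] <- colMeans(psd$sd[have, , drop = FALSE])
  }
  out <- psd
  out$power <- P
  out$sd <- S
  out
}

#' Band power: mean PSD over a frequency band
#'
#' Mean of the PSD bins with `band[1] <= f <= band[2]` (both endpoints
#' inclusive), per row. The band statistic is a mean density (uV^2/Hz),
#' not an integral, matching the units of the study's contrasts.
#'
#' @param psd A `psd` (typically region-averaged).
#' @param band Numeric length-2, Hz. Default `c(6, 10)`.
#' @return Named numeric vector (one value per row of the PSD) with class
#'   `band_power`.
#' @export
band_power <- function(psd, band = c(6, 10)) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("band [", band[1], ", ", band[2], "] is empty on this grid")
  structure(rowMeans(psd$power[, sel, drop = FALSE]),
            band = band, condition = psd$condition, class = "band_power")
}

#' Session contrast of band powers
#'
#' `contrast = session B - session A`, per region. The exposure-second
#' group (RF in session B) is expected to show positive contrasts when the
#' exposure raises alpha power.
#'
#' @param bp_a,bp_b `band_power` vectors from sessions A and B over the
#'   same regions.
#' @return Named numeric vector of contrasts (uV^2/Hz).
#' @export
session_contrast <- function(bp_a, bp_b) {
  if (!identical(names(bp_a), names(bp_b))) {
    stop("band powers cover different region sets")
  }
  unclass(bp_b) - unclass(bp_a)
}
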