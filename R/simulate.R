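# Synthetic EEG generation. Stochastic components (pink background, alpha)
# are synthesized in the frequency domain with random phases and
# deterministic amplitudes set by the target one-sided PSD, so the realized
# spectrum of each block matches the configured density and long-run Welch
# estimates converge tightly to it.

# random-phase realization of a one-sided target PSD S(f) [uV^2/Hz]
synth_from_psd <- function(n, fs, S) {
  if (n < 4L) return(numeric(n))
  half <- (n - 1L) %/% 2L
  f <- (1:half) * fs / n
  amp <- sqrt(S(f) * fs * n / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  Z <- complex(length.out = n)
  Z[2:(half + 1L)] <- amp * exp(1i * phase)
  Z[n:(n - half + 1L)] <- Conj(Z[2:(half + 1L)])
  if (n %% 2L == 0L) {
    fn <- fs / 2
    Z[n %/% 2L + 1L] <- sqrt(S(fn) * fs * n) * sample(c(-1, 1), 1L)
  }
  Re(stats::fft(Z, inverse = TRUE)) / n
}

# Gaussian alpha bump (unit peak) on frequency grid f
alpha_bump <- function(f, center, bandwidth) {
  s <- bandwidth / (2 * sqrt(2 * log(2)))
  exp(-(f - center)^2 / (2 * s^2))
}

# power scale applied to the alpha component of one block
alpha_block_scale <- function(config, label, rf_active) {
  if (!label %in% c("EO", "EC", "break", "washout")) return(0)
  cond <- if (label == "EC") "EC" else "EO"  # breaks/washout: eyes open
  sc <- if (cond == "EO") config$eo_attenuation else 1
  if (rf_active) sc <- sc * config$emf_effect[[cond]]
  sc
}

#' Simulate one recording session
#'
#' Generates a multichannel recording following a [session_schedule()]:
#' each block is an independent realization of pink background +
#' region-weighted narrowband alpha (attenuated with eyes open, scaled by
#' the configured exposure effect while RF is active) + mains harmonics +
#' pulsed-carrier components (RF on only) + white sensor noise.
#'
#' @param config A [sim_config()].
#' @param schedule A [session_schedule()]; `rf_on` must be constant.
#' @param seed Integer seed (or `NULL` to use the current RNG stream).
#' @param alpha_multiplier Per-subject alpha power multiplier (default 1).
#' @param residual_rf If `TRUE`, the exposure effect on alpha persists even
#'   though `rf_on` is `FALSE` (carryover into a sham session); pulsation
#'   components still require `rf_on`.
#' @param metadata List stored on the recording (subject, session, group).
#' @return A `recording`: list with `samples` (channels x time matrix, uV),
#'   `rate`, `channels`, `annotations` (one row per block with sample
#'   indices) and `metadata`.
#' @export
simulate_session <- function(config, schedule, seed = NULL,
                             alpha_multiplier = 1, residual_rf = FALSE,
                             metadata = list()) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "block_schedule"))
  if (length(unique(schedule$rf_on)) != 1L) {
    stop("rf_on must be constant within a session")
  }
  fs <- config$sampling_rate
  chans <- config$channels
  ch_region <- channel_region(chans)
  n_per_block <- round(schedule$duration * fs)
  total <- sum(n_per_block)
  X <- matrix(0, nrow = length(chans), ncol = total,
              dimnames = list(chans, NULL))
  ann <- data.frame(label = schedule$label,
                    onset = cumsum(c(0, utils::head(n_per_block, -1L))) + 1L,
                    n_samples = n_per_block,
                    rf_on = schedule$rf_on)
  with_seed(seed, {
    for (b in seq_len(nrow(schedule))) {
      n <- n_per_block[b]
      if (n < 4L) next
      idx <- ann$onset[b]:(ann$onset[b] + n - 1L)
      rf_active <- schedule$rf_on[b] || residual_rf
      a_scale <- alpha_block_scale(config, schedule$label[b], rf_active) *
        alpha_multiplier
      t <- (idx - 1L) / fs
      common <- numeric(n)
      for (h in names(config$mains)) {
        fh <- as.numeric(h)
        if (fh < fs / 2 && config$mains[[h]] > 0) {
          common <- common + config$mains[[h]] *
            sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
        }
      }
      if (schedule$rf_on[b]) {
        for (h in names(config$pulsation)) {
          fh <- as.numeric(h)
          if (fh < fs / 2 && config$pulsation[[h]] > 0) {
            common <- common + config$pulsation[[h]] *
              sin(2 * pi * fh * t + stats::runif(1, 0, 2 * pi))
          }
        }
      }
      for (c in seq_along(chans)) {
        x <- common
        if (config$pink_scale > 0) {
          x <- x + synth_from_psd(n, fs, function(f)
            config$pink_scale / pmax(f, 1 / max(schedule$duration[b], 4))^config$pink_exponent)
        }
        p_alpha <- config$alpha_power_by_region[[ch_region[c]]] * a_scale
        if (p_alpha > 0) {
          x <- x + synth_from_psd(n, fs, function(f)
            p_alpha * alpha_bump(f, config$alpha_center, config$alpha_bandwidth))
        }
        if (config$sensor_noise_sd > 0) {
          x <- x + stats::rnorm(n, 0, config$sensor_noise_sd)
        }
        X[c, idx] <- x
      }
    }
  })
  structure(list(samples = X, rate = fs, channels = chans,
                 annotations = ann, metadata = metadata),
            class = "recording")
}

#' Simulate both sessions of one crossover subject
#'
#' Group 1 receives RF in session A, group 2 in session B. A per-subject
#' log-normal alpha power multiplier (mean 1) is drawn once and shared by
#' both sessions, so between-subject variability exceeds within-subject
#' variability. With `config$carryover`, group 1's session B retains the
#' exposure effect on alpha (but no pulsation artifact).
#'
#' @param config A [sim_config()].
#' @param group 1 or 2.
#' @param subject_id Integer identifier.
#' @param seed Integer base seed; sub-seeds for the subject multiplier,
#'   schedules and sessions are derived from it.
#' @param schedule_args List of extra arguments to [session_schedule()]
#'   (e.g. `washout_s = 0` for desk-scale runs).
#' @return List with elements `A` and `B`, each a `recording`.
#' @export
simulate_subject <- function(config, group, subject_id, seed,
                             schedule_args = list()) {
  stopifnot(group %in% c(1L, 2L))
  mult <- with_seed(sub_seed(seed, subject_id, 0),
                    stats::rlnorm(1, -config$subject_sd^2 / 2, config$subject_sd))
  out <- list()
  for (session in c("A", "B")) {
    s_i <- if (session == "A") 1L else 2L
    rf <- (group == 1L) == (session == "A")
    sched <- do.call(session_schedule,
                     c(list(rf_on = rf, seed = sub_seed(seed, subject_id, s_i)),
                       schedule_args))
    residual <- config$carryover && group == 1L && session == "B"
    out[[session]] <- simulate_session(
      config, sched, seed = sub_seed(seed, subject_id, s_i + 10L),
      alpha_multiplier = mult, residual_rf = residual,
      metadata = list(subject = subject_id, session = session, group = group))
  }
  out
}

#' Simulate a counterbalanced cohort
#'
#' Group assignment comes from [generate_blinding_table()]; half the
#' subjects receive RF in session A. Intended for small `n`; for a full
#' cohort analysis use [cohort_contrasts()], which processes subjects one
#' at a time without holding all recordings in memory.
#'
#' @inheritParams simulate_subject
#' @param n Even number of subjects.
#' @return List of per-subject session pairs, with the blinding table as
#'   attribute `blinding`.
#' @export
simulate_cohort <- function(n, config, seed, schedule_args = list()) {
  blinding <- generate_blinding_table(n, seed)
  subs <- lapply(seq_len(n), function(i)
    simulate_subject(config, blinding$group[i], i, seed,
                     schedule_args = schedule_args))
  attr(subs, "blinding") <- blinding
  subs
}

#' Simulate a phantom recording
#'
#' A phantom (conductive test object in place of a head) has no brain
#' activity: the recording is pink floor + mains harmonics + sensor noise,
#' plus the pulsed-carrier components when RF is on. Used to test whether
#' the exposure contaminates the acquisition chain.
#'
#' @param config A [sim_config()]; the alpha component is ignored.
#' @param rf_on Logical.
#' @param duration_s Recording length in seconds.
#' @param seed Integer seed.
#' @return A `recording` with a single `phantom` annotation interval.
#' @export
simulate_phantom <- function(config, rf_on, duration_s = 120, seed = NULL) {
  cfg <- config
  cfg$alpha_power_by_region[] <- 0
  sched <- data.frame(label = "phantom", duration = duration_s, rf_on = rf_on)
  class(sched) <- c("block_schedule", "data.frame")
  simulate_session(cfg, sched, seed = seed,
                   metadata = list(phantom = TRUE, rf_on = rf_on))
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat("  blocks:", paste(x$annotations$label, collapse = " "), "\n")
  invisible(x)
}
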