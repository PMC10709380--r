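one_block <- function(duration, rf_on = FALSE, label = "EC") {
  s <- data.frame(label = label, duration = duration, rf_on = rf_on)
  class(s) <- c("block_schedule", "data.frame")
  s
}

test_that("every generator is deterministic in its seed", {
  cfg <- desk_config()
  s <- one_block(8)
  expect_identical(simulate_session(cfg, s, seed = 5)$samples,
                   simulate_session(cfg, s, seed = 5)$samples)
  expect_false(identical(simulate_session(cfg, s, seed = 5)$samples,
                         simulate_session(cfg, s, seed = 6)$samples))
  a <- simulate_subject(cfg, 1, 3, seed = 9, schedule_args = desk_schedule)
  b <- simulate_subject(cfg, 1, 3, seed = 9, schedule_args = desk_schedule)
  expect_identical(a$A$samples, b$A$samples)
  expect_identical(a$B$samples, b$B$samples)
  ph <- simulate_phantom(cfg, TRUE, duration_s = 8, seed = 2)
  expect_identical(ph$samples, simulate_phantom(cfg, TRUE, 8, seed = 2)$samples)
})

test_that("degenerate configuration yields pure white sensor noise", {
  cfg <- desk_config(alpha_power_by_region = setNames(rep(0, 6), regions()),
                     pink_scale = 0, mains = c(`50` = 0),
                     sensor_noise_sd = 2, emf_effect = c(EO = 1, EC = 1))
  rec <- simulate_session(cfg, one_block(60), seed = 21)
  v <- apply(rec$samples, 1, var)
  expect_true(all(abs(v - 4) / 4 < 0.05))
})

test_that("realized alpha band density matches the configured target", {
  # single channel, no pink/mains: EC Welch band power should equal the
  # configured alpha density plus the white noise floor
  cfg <- desk_config(channels = "Oz", pink_scale = 0, mains = c(`50` = 0),
                     sensor_noise_sd = 0.5, emf_effect = c(EO = 1, EC = 1))
  rec <- simulate_session(cfg, one_block(480), seed = 31)  # 120 epochs
  psd <- welch_psd(segment_epochs(rec, "EC"))
  got <- mean(psd$power[1, psd$freq >= 6 & psd$freq <= 10])
  bins <- seq(6, 10, by = 0.25)
  s <- cfg$alpha_bandwidth / (2 * sqrt(2 * log(2)))
  bump <- mean(exp(-(bins - cfg$alpha_center)^2 / (2 * s^2)))
  want <- cfg$alpha_power_by_region[["occipital"]] * bump + 2 * 0.5^2 / 250
  expect_equal(got, want, tolerance = 0.1)
})

test_that("pink background has the configured spectral slope", {
  cfg <- desk_config(channels = "Cz",
                     alpha_power_by_region = setNames(rep(0, 6), regions()),
                     mains = c(`50` = 0), sensor_noise_sd = 0,
                     pink_exponent = 1, pink_scale = 15,
                     emf_effect = c(EO = 1, EC = 1))
  rec <- simulate_session(cfg, one_block(480), seed = 41)
  psd <- welch_psd(segment_epochs(rec, "EC"))
  sel <- psd$freq >= 2 & psd$freq <= 40
  slope <- coef(lm(log(psd$power[1, sel]) ~ log(psd$freq[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.1)
})

test_that("alpha reacts to eye state: EC band power exceeds EO", {
  cfg <- desk_config()
  sched <- session_schedule(rf_on = FALSE, n_cycles = 3, eo_s = 40, ec_s = 40,
                            washout_s = 0, seed = 3)
  rec <- preprocess(simulate_session(cfg, sched, seed = 51))
  bp <- function(cond) {
    band_power(region_average(welch_psd(segment_epochs(rec, cond))))
  }
  eo <- bp("EO"); ec <- bp("EC")
  expect_true(all(unclass(ec) > unclass(eo)))
})

test_that("measured alpha band power is linear in the exposure multiplier", {
  effs <- c(1, 1.25, 1.5, 1.75, 2)
  got <- vapply(effs, function(e) {
    cfg <- desk_config(channels = "Oz", pink_scale = 0, mains = c(`50` = 0),
                       sensor_noise_sd = 0.2, emf_effect = c(EO = e, EC = 1))
    rec <- simulate_session(cfg, one_block(120, rf_on = TRUE, label = "EO"),
                            seed = 61)
    psd <- welch_psd(segment_epochs(rec, "EO"))
    mean(psd$power[1, psd$freq >= 6 & psd$freq <= 10])
  }, 0)
  fit <- lm(got ~ effs)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("contrast signs follow the crossover design and carryover", {
  # strong effect, quiet background, so single-subject signs are stable
  base <- list(channels = c("Cz", "Fz", "Oz", "Pz", "T7", "T8"),
               pink_scale = 1, sensor_noise_sd = 0.2,
               emf_effect = c(EO = 2, EC = 1))
  mean_ct <- function(carry, group) {
    cfg <- do.call(desk_config, c(base, list(carryover = carry)))
    pair <- simulate_subject(cfg, group, 1, seed = 71,
                             schedule_args = desk_schedule)
    mean(subject_contrasts(pair$A, pair$B))
  }
  g2 <- mean_ct(TRUE, 2)
  expect_gt(g2, 0)                      # exposed second: positive B - A
  g1_nocarry <- mean_ct(FALSE, 1)
  expect_lt(g1_nocarry, 0)              # exposed first, no carryover
  g1_carry <- mean_ct(TRUE, 1)
  expect_lt(abs(g1_carry), 0.5 * abs(g1_nocarry))  # carryover ~ cancels
})

test_that("null effect gives contrasts centred on zero", {
  cfg <- desk_config(emf_effect = c(EO = 1, EC = 1))
  ct <- cohort_contrasts(8, cfg, seed = 81, schedule_args = desk_schedule)
  means <- tapply(ct$contrast, ct$group, mean)
  se <- sd(ct$contrast) / sqrt(nrow(ct) / 2)
  expect_lt(abs(means[["2"]] - means[["1"]]), 4 * se)
})

test_that("cohorts are counterbalanced and reproducible", {
  cfg <- desk_config(channels = "Oz", pink_scale = 1)
  co <- simulate_cohort(4, cfg, seed = 91,
                        schedule_args = desk_sched(n_cycles = 1))
  expect_length(co, 4L)
  expect_equal(sum(attr(co, "blinding")$group == 1L), 2L)
  co2 <- simulate_cohort(4, cfg, seed = 91,
                         schedule_args = desk_sched(n_cycles = 1))
  expect_identical(co[[2]]$A$samples, co2[[2]]$A$samples)
  expect_error(simulate_cohort(5, cfg, seed = 1), "even")
})

test_that("phantom recordings carry the pulsation only when RF is on", {
  cfg <- sim_config()  # full rate: 217/868 Hz must be representable
  on <- welch_psd(segment_epochs(simulate_phantom(cfg, TRUE, 60, seed = 13),
                                 "phantom"))
  off <- welch_psd(segment_epochs(simulate_phantom(cfg, FALSE, 60, seed = 14),
                                  "phantom"))
  peak <- function(psd, f) max(psd$power[, abs(psd$freq - f) <= 0.5])
  floor_near <- function(psd, f) median(psd$power[, abs(psd$freq - f) < 8 &
                                                    abs(psd$freq - f) > 2])
  expect_gt(peak(on, 217), 8 * floor_near(on, 217))
  expect_gt(peak(on, 868), 8 * floor_near(on, 868))
  expect_lt(peak(off, 217), 4 * floor_near(off, 217))
  # no alpha bump in a phantom: the 6-10 Hz band follows the pink floor
  band_ratio <- mean(on$power[, on$freq >= 6 & on$freq <= 10]) /
    mean(on$power[, on$freq >= 16 & on$freq <= 20])
  expect_lt(band_ratio, 4)  # ~2 expected for a 1/f floor, >> for alpha

  # pulsation contributes nothing below 50 Hz
  sel <- on$freq <= 50 & on$freq >= 0.5
  bp_on <- mean(on$power[, sel]); bp_off <- mean(off$power[, sel])
  se <- sqrt(mean(on$sd[, sel]^2) / on$n_epochs +
               mean(off$sd[, sel]^2) / off$n_epochs)
  expect_lt(abs(bp_on - bp_off), 2 * se)
})
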