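test_that("preprocessing decimates, removes DC and annihilates common mode", {
  set.seed(1)
  X <- matrix(rnorm(6 * 25000), nrow = 6)
  rownames(X) <- c("Cz", "Fz", "Oz", "Pz", "T7", "T8")
  rec <- raw_recording(X, rate = 2500)
  out <- preprocess(rec)
  expect_equal(ncol(out$samples), 2500L)  # 10 s at 250 Hz
  expect_equal(out$rate, 250)
  expect_equal(out$annotations$n_samples, 2500L)

  # constant-offset channel goes to ~0 after the high-pass (single channel:
  # no average reference involved)
  off <- raw_recording(matrix(50, 1, 25000, dimnames = list("Cz", NULL)), 2500)
  y <- preprocess(off)$samples
  interior <- y[1, 500:2000]
  expect_lt(max(abs(interior)), 0.01 * 50)

  # identical signal on all channels is removed by the average reference
  same <- raw_recording(matrix(rep(rnorm(25000), each = 6), nrow = 6,
                               dimnames = list(rownames(X), NULL)), 2500)
  expect_lt(max(abs(preprocess(same)$samples)), 1e-8)

  expect_error(preprocess(raw_recording(X[, 1:100, drop = FALSE], rate = 300)),
               "integer multiple")
})

test_that("segmentation yields floor(duration / 4 s) epochs per block", {
  fs <- 250
  X <- matrix(0, 1, 90 * fs, dimnames = list("Cz", NULL))
  rec <- raw_recording(X, fs)
  ep <- segment_epochs(rec, "EO")
  expect_equal(dim(ep)[1], 22L)
  expect_equal(dim(ep)[3], 1000L)

  # five 90-s blocks -> 110 epochs
  rec5 <- raw_recording(matrix(0, 1, 5 * 90 * fs, dimnames = list("Cz", NULL)), fs)
  rec5$annotations <- data.frame(label = "EO", onset = seq(1, by = 90 * fs, length.out = 5),
                                 n_samples = 90 * fs, rf_on = FALSE)
  expect_equal(dim(segment_epochs(rec5, "EO"))[1], 110L)

  short <- raw_recording(matrix(0, 1, 3 * fs, dimnames = list("Cz", NULL)), fs)
  expect_error(segment_epochs(short, "EO"), "long enough")
  expect_error(segment_epochs(rec, "EC"), "no interval")
})

test_that("amplitude rejection flags exactly the contaminated epochs", {
  fs <- 250
  set.seed(2)
  X <- matrix(rnorm(1 * 40 * fs, sd = 10), 1, dimnames = list("Cz", NULL))
  rec <- raw_recording(X, fs)
  ep <- segment_epochs(rec, "EO")
  expect_true(all(attr(reject_epochs(ep, 100), "kept")))
  # inject a 500 uV spike into epoch 3
  ep2 <- ep
  ep2[3, 1, 17] <- 500
  kept <- attr(reject_epochs(ep2, 100), "kept")
  expect_identical(which(!kept), 3L)
  expect_error(reject_epochs(ep, 0), "all epochs")
})

test_that("Welch PSD is correctly normalized (white noise, sinusoid, Parseval)", {
  fs <- 250
  set.seed(3)
  sigma <- 3
  X <- matrix(rnorm(120 * 4 * fs, sd = sigma), 1, dimnames = list("Cz", NULL))
  ep <- segment_epochs(raw_recording(X, fs), "EO")  # 120 epochs
  psd <- welch_psd(ep)
  expect_equal(psd$freq[2] - psd$freq[1], 0.25)
  flat <- mean(psd$power[1, psd$freq > 5 & psd$freq < 100])
  expect_equal(flat, 2 * sigma^2 / fs, tolerance = 0.1)

  # pure 10 Hz sinusoid: band-integrated power ~ A^2 / 2
  A <- 4
  t <- (0:(40 * fs - 1)) / fs
  Xs <- matrix(A * sin(2 * pi * 10 * t), 1, dimnames = list("Cz", NULL))
  ps <- welch_psd(segment_epochs(raw_recording(Xs, fs), "EO"))
  sel <- ps$freq >= 9 & ps$freq <= 11
  expect_equal(sum(ps$power[1, sel]) * 0.25, A^2 / 2, tolerance = 0.05)

  # zero signal -> identically zero PSD
  pz <- welch_psd(segment_epochs(raw_recording(matrix(0, 1, 8 * fs,
    dimnames = list("Cz", NULL)), fs), "EO"))
  expect_true(all(pz$power == 0))

  # Parseval: integral of one-epoch periodogram = window-normalized power
  x <- rnorm(1000)
  ep1 <- segment_epochs(raw_recording(matrix(x, 1, dimnames = list("Cz", NULL)), fs), "EO")
  p1 <- welch_psd(ep1)
  n <- 1000
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  expect_equal(sum(p1$power[1, ]) * (fs / n), sum((x * w)^2) / sum(w^2),
               tolerance = 1e-6)
})

test_that("region averaging is an unweighted mean over mapped channels", {
  fs <- 250
  map <- region_map()
  chans <- unlist(map, use.names = FALSE)
  X <- matrix(1, length(chans), 8 * fs, dimnames = list(chans, NULL))
  X[map$frontal, ] <- 2  # frontal twice as large (flat spectra scale by 4)
  ts <- rnorm(ncol(X))
  X <- X * matrix(ts, nrow(X), ncol(X), byrow = TRUE)
  ep <- segment_epochs(raw_recording(X, fs), "EO")
  rp <- region_average(welch_psd(ep))
  expect_identical(rownames(rp$power), regions())
  ratio <- mean(rp$power["frontal", -1]) / mean(rp$power["central", -1])
  expect_equal(ratio, 4, tolerance = 0.05)

  # subset montage: one channel per region acts as identity
  sub <- c("Cz", "Fp1", "Oz", "Pz", "T7", "T8")
  Xs <- X[sub, ]
  ps <- welch_psd(segment_epochs(raw_recording(Xs, fs), "EO"))
  rs <- region_average(ps)
  expect_equal(unname(rs$power["occipital", ]), unname(ps$power["Oz", ]))

  # a region with no channels errors
  ps2 <- welch_psd(segment_epochs(raw_recording(Xs[1:5, ], fs), "EO"))
  expect_error(region_average(ps2), "temporal_right")
})

test_that("band power is the mean density over 6-10 Hz inclusive", {
  psd <- structure(list(freq = seq(0, 125, by = 0.25),
                        power = NULL, sd = NULL, n_epochs = 1, rate = 250,
                        condition = "EO"), class = "psd")
  psd$power <- matrix(1, 1, length(psd$freq), dimnames = list("central", NULL))
  expect_equal(as.numeric(band_power(psd)), 1)
  psd$power[1, ] <- psd$freq  # identity ramp
  expect_equal(as.numeric(band_power(psd)), 8)  # 17 bins, midpoint 8
  expect_error(band_power(psd, band = c(300, 301)), "empty")
})

test_that("session contrasts subtract B - A per region and check regions", {
  a <- structure(setNames(rep(2, 6), regions()), class = "band_power")
  b <- structure(setNames(rep(2.5, 6), regions()), class = "band_power")
  expect_equal(unname(session_contrast(a, b)), rep(0.5, 6))
  expect_equal(unname(session_contrast(a, a)), rep(0, 6))
  bad <- structure(setNames(rep(1, 5), regions()[1:5]), class = "band_power")
  expect_error(session_contrast(a, bad), "different region")
})

test_that("pipeline is quadratic in amplitude: scaling by c scales PSD by c^2", {
  fs <- 250
  set.seed(4)
  X <- matrix(rnorm(2 * 20 * fs), 2, dimnames = list(c("Cz", "Fz"), NULL))
  p1 <- welch_psd(segment_epochs(raw_recording(X, fs), "EO"))
  p3 <- welch_psd(segment_epochs(raw_recording(3 * X, fs), "EO"))
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-10)
})

test_that("phantom QC passes on clean pairs and fails on in-band interference", {
  mkpsd <- function(power_fun, f = seq(0, 1250, by = 0.25)) {
    p <- matrix(power_fun(f), 1, length(f), dimnames = list("Cz", NULL))
    structure(list(freq = f, power = p,
                   sd = p * 0.3 + 0.01, n_epochs = 30, rate = 2500,
                   condition = "phantom"), class = "psd")
  }
  base <- function(f) 10 / pmax(f, 0.5) + 0.01
  with_pulse <- function(f) base(f) + 50 * (abs(f - 217) < 0.2) +
    10 * (abs(f - 868) < 0.2)
  qc <- phantom_qc(mkpsd(with_pulse), mkpsd(base))
  expect_true(qc$pass)
  expect_true(any(abs(qc$peaks_on - 217) <= 1))
  expect_true(any(abs(qc$peaks_on - 868) <= 1))

  # identical PSDs pass with zero difference
  qc0 <- phantom_qc(mkpsd(base), mkpsd(base))
  expect_true(qc0$pass)
  expect_equal(qc0$max_diff_se, 0)

  # adversarial: interference at 10 Hz must fail
  with_low <- function(f) base(f) + 50 * (abs(f - 10) < 0.2)
  expect_false(phantom_qc(mkpsd(with_low), mkpsd(base))$pass)

  # mismatched grids error
  expect_error(phantom_qc(mkpsd(base), mkpsd(base, f = seq(0, 125, by = 0.25))),
               "grids differ")
})
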