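# Spectral estimation: normalization oracles, cross-spectra, surrogate
# bands, residual and signal/noise spectra.

test_that("Poisson spectra are flat at the rate lambda", {
  for (lam in c(20, 50, 100)) {
    tr <- generate_renewal_spiketrain(lam, 1, 300, seed = lam)
    est <- power_spectrum(tr)
    expect_lt(abs(band_power(est, c(1, 20)) - lam) / lam, 0.1)
  }
})

test_that("gamma renewal low-frequency power approaches lambda * CV^2", {
  tr <- generate_renewal_spiketrain(50, 0.3, 300, seed = 3)
  est <- power_spectrum(tr)
  expect_lt(abs(band_power(est, c(0.5, 2)) - 50 * 0.3^2) / (50 * 0.3^2), 0.15)
})

test_that("a clock-like train shows peaks at the firing fundamental and harmonics", {
  per <- spike_train(seq(0.01, 120, by = 0.02)[-1] - 0.005, duration = 120)
  est <- power_spectrum(per)  # 50 sp/s
  peak_near <- function(f0) {
    sel <- est$freq > f0 - 2 & est$freq < f0 + 2
    near <- max(est$power[sel])
    bg <- stats::median(est$power[est$freq > 5 & est$freq < 45])
    near / max(bg, 1e-12)
  }
  expect_gt(peak_near(50), 100)
  expect_gt(peak_near(100), 100)
  expect_gt(peak_near(150), 100)
})

test_that("trace spectra satisfy Parseval and quadratic scaling", {
  x <- white_band_trace(120000, 100, 5, seed = 10)
  est <- power_spectrum(x)
  expect_lt(abs(vestcoding:::trapz(est$freq, est$power) - var(x$values)) /
              var(x$values), 0.02)
  x2 <- trace(3 * x$values, sample_rate = x$sample_rate)
  est2 <- power_spectrum(x2)
  expect_equal(est2$power, 9 * est$power, tolerance = 1e-10)
})

test_that("cross-spectrum: self-consistency, Hermitian symmetry, delay phase", {
  x <- white_band_trace(60000, 50, 1, seed = 11)
  cs <- cross_spectrum(x, x)
  ps <- power_spectrum(x)
  expect_equal(2 * Re(cs$cross[-1]), ps$power[-1], tolerance = 1e-9)
  expect_lt(max(abs(Im(cs$cross))), 1e-9)
  y <- white_band_trace(60000, 50, 1, seed = 12)
  expect_equal(cross_spectrum(x, y)$cross,
               Conj(cross_spectrum(y, x)$cross), tolerance = 1e-9)
  # delay by tau: phase slope -2 pi tau
  tau_n <- 5
  yd <- trace(c(rep(0, tau_n), x$values[1:(60000 - tau_n)]))
  cd <- cross_spectrum(x, yd)
  sel <- cd$freq > 2 & cd$freq < 30  # |phase| stays below pi: no unwrapping
  ph <- Arg(cd$cross[sel])
  fit <- coef(lm(ph ~ cd$freq[sel]))[2]
  expect_lt(abs(fit - (-2 * pi * tau_n / 1000)) / (2 * pi * tau_n / 1000), 0.02)
  # independent signals: cross magnitude far below the auto spectra
  ci <- cross_spectrum(x, y)
  sel <- ci$freq > 1 & ci$freq < 40
  expect_lt(mean(Mod(ci$cross[sel])) / band_power(ps, c(1, 40)) * 2, 0.2)
})

test_that("Poisson surrogate band covers a Poisson train and rejects a regular one", {
  # per-frequency coverage holds on average over realizations (one train's
  # estimate can drift as a block because neighbouring bins are correlated)
  cover <- sapply(1:6, function(i) {
    tr <- generate_renewal_spiketrain(50, 1, 60, seed = 20 + i)
    cb <- poisson_confidence_band(tr, n = 400, seed = i)
    est <- power_spectrum(tr)
    sel <- cb$freq > 0.4 & cb$freq <= 20
    mean(est$power[sel] >= cb$low[sel] & est$power[sel] <= cb$high[sel])
  })
  expect_gt(mean(cover), 0.9)
  tr <- generate_renewal_spiketrain(50, 1, 120, seed = 21)
  # regular train: below the band at low f, above at the fundamental
  reg <- generate_renewal_spiketrain(50, 0.1, 120, seed = 22)
  cbr <- poisson_confidence_band(reg, n = 200, seed = 2)
  pr <- power_spectrum(reg)
  low <- pr$freq > 0.4 & pr$freq <= 10
  expect_gt(mean(pr$power[low] < cbr$low[low]), 0.95)
  fund <- pr$freq > 48 & pr$freq < 52
  expect_true(any(pr$power[fund] > cbr$high[fund]))
  # n = 1 degenerates to the single surrogate
  cb1 <- poisson_confidence_band(tr, n = 1, seed = 3)
  expect_equal(cb1$low, cb1$high)
})

test_that("residual spectrum: zero for identical trials, pairwise algebra for two", {
  g <- generate_renewal_spiketrain(40, 0.5, 60, seed = 31)
  B <- cbind(binarize(g), binarize(g))
  expect_equal(max(residual_noise_spectrum(B)$power), 0)
  g2 <- generate_renewal_spiketrain(40, 0.5, 60, seed = 32)
  B2 <- cbind(binarize(g), binarize(g2))
  res <- residual_noise_spectrum(B2)
  diff_spec <- power_spectrum((binarize(g) - binarize(g2)) * 1000)
  expect_equal(res$power, diff_spec$power / 2, tolerance = 1e-9)
  expect_error(residual_noise_spectrum(B2[, 1, drop = FALSE]), ">= 2")
})

test_that("SNR decomposition separates drive from noise and tracks CV", {
  stim <- fix_stimulus()
  band_snr <- function(cv, seed) {
    ns <- neuron_spec(base_rate = 50, target_cv = cv, sensitivity = 0.5,
                      seed = seed)
    trials <- generate_trials(stim, ns, 6, seed = seed)
    dec <- signal_noise_decomposition(trials)
    sel <- dec$snr$freq > 0.4 & dec$snr$freq <= 15 & !dec$snr$capped
    mean(dec$snr$snr[sel])
  }
  expect_gt(band_snr(0.1, 41), band_snr(0.8, 42))
  # zero-sensitivity neuron: band SNR near zero
  ns0 <- neuron_spec(base_rate = 50, target_cv = 0.4, sensitivity = 0,
                     seed = 43)
  dec0 <- signal_noise_decomposition(generate_trials(stim, ns0, 6, seed = 43))
  sel <- dec0$snr$freq > 0.4 & dec0$snr$freq <= 15
  expect_lt(mean(dec0$snr$snr[sel]), 0.2)
  # identical trials: noise zero, SNR capped where signal exists
  g <- generate_renewal_spiketrain(40, 0.5, 60, seed = 44)
  dec1 <- signal_noise_decomposition(cbind(binarize(g), binarize(g)))
  expect_true(all(dec1$snr$capped))
})

test_that("estimator refuses windows longer than every segment", {
  g <- generate_renewal_spiketrain(50, 0.5, 10, seed = 51)
  expect_error(power_spectrum(g, window_s = 2.048,
                              segments = data.frame(start_s = 0, end_s = 1)),
               "window")
})
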