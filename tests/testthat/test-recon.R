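# Wiener reconstruction and coding fraction.

test_that("self-reconstruction of a band-limited trace is near-perfect", {
  s <- white_band_trace(60000, 15, 10, seed = 1)
  k <- optimal_kernel_single(s, s)
  rec <- reconstruct(s, k)
  cf <- coding_fraction(s, rec$reconstruction, rec$valid)$cf
  expect_gt(cf, 0.98)
  # scaled response: kernel gain compensates (R = 2 S decodes to S)
  r2 <- trace(2 * s$values)
  k2 <- optimal_kernel_single(r2, s)
  rec2 <- reconstruct(r2, k2)
  expect_gt(coding_fraction(s, rec2$reconstruction, rec2$valid)$cf, 0.98)
  # in-band kernel frequency response has gain ~ 0.5
  expect_equal(sum(k2$value) / sum(k$value), 0.5, tolerance = 0.01)
  expect_error(optimal_kernel_single(spike_train(numeric(0), 1),
                                     trace(numeric(1000))), "empty")
})

test_that("zero and impulse kernels behave as stated", {
  s <- white_band_trace(30000, 15, 5, seed = 2)
  k <- optimal_kernel_single(s, s)
  k0 <- k
  k0$value <- 0 * k0$value
  rec0 <- reconstruct(s, k0)
  expect_equal(max(abs(rec0$reconstruction$values)), 0)
  # mean-predictor scores CF = 0; perfect copy scores CF = 1
  expect_equal(coding_fraction(s, rec0$reconstruction, rec0$valid)$cf, 0,
               tolerance = 1e-4)
  expect_equal(coding_fraction(s, trace(s$values - mean(s$values)))$cf, 1)
  expect_error(coding_fraction(trace(rep(1, 30000)), rec0$reconstruction),
               "zero variance")
  expect_error(coding_fraction(s, rec0$reconstruction,
                               valid = rep(FALSE, 30000)), "valid")
})

test_that("frequency-domain kernel matches the least-squares FIR oracle", {
  stim <- fix_stimulus60()
  s <- stim$values - mean(stim$values)
  ns <- neuron_spec(base_rate = 50, target_cv = 0.1, sensitivity = 1,
                    seed = 22)
  resp <- generate_ln_response(stim, ns)
  ws <- wiener_settings(window_s = 10, n_tapers = 3, max_lag_s = 0.3,
                        band = c(0, 500), taper_frac = 0)
  k <- optimal_kernel_single(resp, stim, ws)
  z <- binarize(resp) - mean(binarize(resp))
  L <- 300
  X <- stats::embed(z, 2 * L + 1)
  yv <- s[(L + 1):(length(s) - L)]
  b <- as.numeric(solve(crossprod(X), crossprod(X, yv)))
  expect_lt(rel_rms(k$value, b), 0.02)
})

test_that("pair decoder: uninformative channel, duplicate fallback, gains", {
  stim <- fix_stimulus60()
  ns1 <- neuron_spec(base_rate = 50, target_cv = 0.3, sensitivity = 0.5,
                     seed = 61)
  r1 <- generate_ln_response(stim, ns1)
  # second neuron independent of stimulus and of r1: K2 ~ 0, CF unchanged
  r2 <- generate_renewal_spiketrain(50, 0.3, 60, seed = 99)
  kp <- optimal_kernel_pair(r1, r2, stim)
  expect_lt(sqrt(mean(kp$k2$value^2)) / sqrt(mean(kp$k1$value^2)), 0.25)
  recp <- reconstruct(list(r1, r2), list(kp$k1, kp$k2))
  cfp <- coding_fraction(stim, recp$reconstruction, recp$valid)$cf
  k1 <- optimal_kernel_single(r1, stim)
  rec1 <- reconstruct(r1, k1)
  cf1 <- coding_fraction(stim, rec1$reconstruction, rec1$valid)$cf
  expect_lt(abs(cfp - cf1), 0.03)
  # identical trains: flagged singular fallback
  expect_warning(kd <- optimal_kernel_pair(r1, r1, stim), "identical")
  expect_true(kd$fallback)
  # informative pair beats either single neuron
  ns2 <- neuron_spec(base_rate = 50, target_cv = 0.3, sensitivity = 0.5,
                     seed = 62)
  r2b <- generate_ln_response(stim, ns2)
  kpb <- optimal_kernel_pair(r1, r2b, stim)
  recb <- reconstruct(list(r1, r2b), list(kpb$k1, kpb$k2))
  cfb <- coding_fraction(stim, recb$reconstruction, recb$valid)$cf
  expect_gte(cfb, cf1 - 0.005)
  expect_gt(cfb, cf1 + 0.03)  # independent noise: clear improvement
})

test_that("fitted kernel is optimal on training data and time-invariant", {
  stim <- fix_stimulus60()
  ns <- neuron_spec(base_rate = 50, target_cv = 0.3, sensitivity = 0.5,
                    seed = 63)
  resp <- generate_ln_response(stim, ns)
  k <- optimal_kernel_single(resp, stim)
  rec <- reconstruct(resp, k)
  cf0 <- coding_fraction(stim, rec$reconstruction, rec$valid)$cf
  for (g in c(0.95, 1.05)) {
    kg <- k
    kg$value <- g * kg$value
    recg <- reconstruct(resp, kg)
    expect_lt(coding_fraction(stim, recg$reconstruction, recg$valid)$cf, cf0)
  }
  # shifting the response by 10 ms and refitting leaves CF unchanged
  shift <- 0.010
  resp_sh <- spike_train(resp$times[resp$times < resp$duration - shift] +
                           shift, resp$duration)
  k_sh <- optimal_kernel_single(resp_sh, stim)
  rec_sh <- reconstruct(resp_sh, k_sh)
  cf_sh <- coding_fraction(stim, rec_sh$reconstruction, rec_sh$valid)$cf
  expect_lt(abs(cf_sh - cf0) / cf0, 0.01)
})

test_that("coding fraction matches the analytic Wiener limit on a known channel", {
  # constructed Gaussian channel, flat spectra in band: C constant, so
  # CF -> 1 - sqrt(1 - C)
  s <- white_band_trace(120000, 20, 20, seed = 41)
  noise <- white_band_trace(120000, 20, 20, seed = 42)
  r <- trace(s$values + noise$values)   # C = 0.5
  ws <- wiener_settings(window_s = 4.096, n_tapers = 3)
  k <- optimal_kernel_single(r, s, ws)
  rec <- reconstruct(r, k)
  cf <- coding_fraction(s, rec$reconstruction, rec$valid)$cf
  expect_lt(abs(cf - (1 - sqrt(0.5))), 0.03 * (1 - sqrt(0.5)) + 0.01)
})

test_that("cohort property: CF decreases with CV", {
  tab <- fix_cohort()$table
  expect_lt(cor(tab$cv, tab$cf, method = "spearman"), -0.9)
})

test_that("low-variability pairs outperform mixed pairs", {
  stim <- fix_stimulus60()
  mk <- function(cv, seed) generate_ln_response(
    stim, neuron_spec(base_rate = 50, target_cv = cv, sensitivity = 0.5,
                      seed = seed))
  pair_cf <- function(ra, rb) {
    kp <- optimal_kernel_pair(ra, rb, stim)
    rec <- reconstruct(list(ra, rb), list(kp$k1, kp$k2))
    coding_fraction(stim, rec$reconstruction, rec$valid)$cf
  }
  low1 <- mk(0.1, 71); low2 <- mk(0.1, 72); high <- mk(0.8, 73)
  expect_gt(pair_cf(low1, low2), pair_cf(low1, high))
})
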