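# Synthetic generators: stimulus statistics, renewal spiking, LN responses,
# repeated trials, model eye movements.

test_that("stimulus generator refuses degenerate specs", {
  expect_error(stimulus_spec(duration = 0), "> 0")
  expect_error(generate_naturalistic_stimulus(stimulus_spec(duration = 1)),
               "too short")
  expect_error(stimulus_spec(duration = 10, corner_freq = 25), "corner_freq")
})

test_that("stimulus is zero-mean, Gaussian-symmetric, at target SD, band-limited", {
  skews <- means <- sds <- numeric(10)
  for (i in 1:10) {
    s <- generate_naturalistic_stimulus(
      stimulus_spec(duration = 120, target_sd = 30, seed = i))
    means[i] <- mean(s$values)
    sds[i] <- sd(s$values)
    skews[i] <- skewness(s$values)
  }
  expect_lt(max(abs(means)), 0.5)
  expect_lt(max(abs(sds - 30) / 30), 0.05)
  # linear filtering of symmetric noise: skewness centered on zero
  expect_lt(abs(mean(skews)), 0.05)
  # hard band limit: out-of-band power fraction < 1% (periodogram integration)
  s <- generate_naturalistic_stimulus(
    stimulus_spec(duration = 120, target_sd = 30, seed = 1))
  pg <- Mod(stats::fft(s$values))^2
  f <- abs(vestcoding:::dft_freqs(length(s$values), 1000))
  expect_lt(sum(pg[f > 20 & f <= 500]) / sum(pg[f <= 500]), 0.01)
})

test_that("stimulus generation is seed-deterministic", {
  a <- generate_naturalistic_stimulus(stimulus_spec(duration = 10, seed = 3))
  b <- generate_naturalistic_stimulus(stimulus_spec(duration = 10, seed = 3))
  expect_identical(a$values, b$values)
  c <- generate_naturalistic_stimulus(stimulus_spec(duration = 10, seed = 4))
  expect_false(identical(a$values, c$values))
})

test_that("renewal generator hits target rate and CV", {
  expect_error(generate_renewal_spiketrain(50, 0, 10, 1), "cv")
  # cv = 1 is Poisson
  p <- generate_renewal_spiketrain(50, 1, 200, seed = 2)
  expect_lt(abs(isi_stats(p)$cv - 1), 0.05)
  # gamma shape 4: cv exactly 0.5; estimate within [0.47, 0.53]
  g <- generate_renewal_spiketrain(50, 0.5, 200, seed = 7)
  expect_gt(isi_stats(g)$cv, 0.47)
  expect_lt(isi_stats(g)$cv, 0.53)
  # count statistics: N ~ rate*duration, var ~ N*cv^2
  n <- length(generate_renewal_spiketrain(50, 0.5, 100, seed = 11)$times)
  expect_lt(abs(n - 5000), 3 * sqrt(5000 * 0.25) + 3)
})

test_that("renewal CV estimate converges ~ 1/sqrt(n)", {
  err <- sapply(c(500, 2000, 8000), function(n) {
    mean(sapply(1:5, function(s) {
      tr <- generate_renewal_spiketrain(50, 0.4, n / 50, seed = 100 * s + n)
      abs(isi_stats(tr)$cv - 0.4)
    }))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
  expect_lt(err[3], 4 * 0.4 / sqrt(2 * 8000))
})

test_that("LN response with zero sensitivity matches the renewal process", {
  stim <- fix_stimulus()
  ns <- neuron_spec(base_rate = 50, target_cv = 0.4, sensitivity = 0,
                    seed = 5)
  resp <- generate_ln_response(stim, ns)
  st <- isi_stats(resp)
  expect_lt(abs(st$firing_rate - 50) / 50, 0.05)
  expect_lt(abs(st$cv - 0.4), 0.05)
})

test_that("LN response follows the stimulus: in-band coherence and rate floor", {
  stim <- fix_stimulus()
  ns <- neuron_spec(base_rate = 50, target_cv = 0.1, sensitivity = 1,
                    seed = 6)
  resp <- generate_ln_response(stim, ns)
  coh <- coherence(resp, stim)
  expect_gt(approx(coh$freq, coh$coherence, xout = 2)$y, 0.5)
  # rectification contract: rate never negative by construction
  expect_true(all(ln_rate(stim, ns)$values >= 0))
  nsr <- neuron_spec(base_rate = 10, target_cv = 0.3, sensitivity = 3,
                     seed = 6)
  expect_true(all(ln_rate(stim, nsr)$values >= 0))
})

test_that("transfer gain of a weak identity-nonlinearity neuron recovers sensitivity", {
  stim <- fix_stimulus()
  ns <- neuron_spec(base_rate = 60, target_cv = 0.3, sensitivity = 0.4,
                    seed = 8)
  resp <- generate_ln_response(stim, ns)
  tf <- estimate_transfer(stim, resp)
  expect_lt(abs(tf$sensitivity_1hz - 0.4) / 0.4, 0.1)
})

test_that("repeated trials share the drive but not the noise", {
  stim <- fix_stimulus()
  ns <- neuron_spec(base_rate = 50, target_cv = 0.4, sensitivity = 1,
                    seed = 9)
  expect_error(generate_trials(stim, ns, 1), "n_trials")
  expect_error(generate_trials(stim, ns, 2, seeds = c(5, 5)), "duplicated")
  trials <- generate_trials(stim, ns, 8, seed = 9)
  expect_false(identical(trials[[1]]$times, trials[[2]]$times))
  # trial-averaged rate correlates with the deterministic drive
  B <- sapply(trials, function(tr) binarize(tr))
  mu <- vestcoding:::smooth_rate(rowMeans(B) * 1000, 1000)
  drv <- ln_rate(stim, ns)$values
  expect_gt(cor(mu, drv), 0.5)
})

test_that("residual spectrum of zero-sensitivity trials matches the resting spectrum", {
  stim <- fix_stimulus()
  ns <- neuron_spec(base_rate = 50, target_cv = 0.5, sensitivity = 0,
                    seed = 13)
  trials <- generate_trials(stim, ns, 12, seed = 13)
  res <- residual_noise_spectrum(trials)
  rest <- generate_renewal_spiketrain(50, 0.5, 120, seed = 14)
  p0 <- power_spectrum(rest)
  bp_res <- band_power(res, c(1, 20))
  bp_p0 <- band_power(p0, c(1, 20))
  expect_lt(abs(bp_res - bp_p0) / bp_p0, 0.15)
})

test_that("model eye movements oppose the head and flag quick phases", {
  # 1 Hz sinusoidal head, no quick phases: gain near 1, eye ~ -head
  tt <- (0:59999) / 1000
  head <- trace(30 * sin(2 * pi * tt))
  out <- generate_eye_movement(head, vor_params(), quick_phase_rate = 0)
  g <- sd(out$eye_velocity$values) / sd(head$values)
  g_cf <- Mod(vestcoding:::vor_pathway_gain(vor_params(), 1, "full"))
  expect_lt(abs(g - g_cf) / g_cf, 0.02)
  expect_gt(g, 0.9); expect_lt(g, 1.1)
  expect_lt(cor(out$eye_velocity$values, head$values), -0.99)
  # zero head -> zero eye
  z <- generate_eye_movement(trace(numeric(2000)), vor_params())
  expect_equal(max(abs(z$eye_velocity$values)), 0)
  # quick phases: mask covers transients; masked gain regression unchanged
  stim <- fix_stimulus()
  qp <- generate_eye_movement(stim, vor_params(), quick_phase_rate = 1,
                              seed = 2)
  expect_gt(nrow(qp$quick_phase_mask$intervals), 50)
  expect_lt(max(qp$quick_phase_mask$intervals[, 2] -
                  qp$quick_phase_mask$intervals[, 1]), 0.081)
  g_clean <- vor_gain(stim, simulate_vor(stim))$gain
  g_masked <- vor_gain(stim, qp$eye_velocity,
                       exclude = qp$quick_phase_mask)$gain
  expect_lt(abs(g_masked - g_clean) / g_clean, 0.02)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_renewal_spiketrain(50, 0.5, 20, seed = 77)
  b <- generate_renewal_spiketrain(50, 0.5, 20, seed = 77)
  expect_identical(a$times, b$times)
  stim <- generate_naturalistic_stimulus(stimulus_spec(duration = 10, seed = 1))
  ns <- neuron_spec(seed = 42)
  expect_identical(generate_ln_response(stim, ns)$times,
                   generate_ln_response(stim, ns)$times)
})
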