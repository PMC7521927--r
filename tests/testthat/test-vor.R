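# VOR transfer-function cascade, spike-driven eye prediction, matching
# index, regression gain.

test_that("stage responses match closed forms", {
  p <- vor_params()
  # NI x plant simplifies to a delayed first-order low-pass
  f <- c(0.5, 1, 2, 5, 10, 15)
  ni_plant <- stage_response(p, f, "ni") * stage_response(p, f, "plant")
  expect_equal(Mod(ni_plant), 1 / sqrt(1 + (2 * pi * f * p$Te2)^2),
               tolerance = 1e-12)
  expect_equal(Mod(ni_plant[f == 1]), 0.995, tolerance = 1e-3)
  # delay contributes phase -2 pi f tau exactly
  no_delay <- Arg(1 / (1 + 2i * pi * f * p$Te2))
  expect_equal(Arg(ni_plant), no_delay - 2 * pi * f * p$tau,
               tolerance = 1e-9)
  # afferent x VN: canal time constant cancels into velocity storage
  aff_vn <- stage_response(p, f, "afferents") * stage_response(p, f, "vn")
  s <- 2i * pi * f
  expect_equal(aff_vn,
               -p$g_vor * s * p$T_vor * (1 + s * p$T1) /
                 ((1 + s * p$T2) * (1 + s * p$T_vor)), tolerance = 1e-12)
  expect_equal(Mod(aff_vn[f == 1]), 1.0, tolerance = 0.01)
  # NI pole at DC
  expect_true(is.infinite(Mod(stage_response(p, 0, "ni"))))
})

test_that("composite gain is insensitive to the canal time constant", {
  f <- seq(0.5, 20, by = 0.5)
  base <- Mod(vestcoding:::vor_pathway_gain(vor_params(), f, "full"))
  for (fac in c(0.9, 1.1)) {
    pert <- Mod(vestcoding:::vor_pathway_gain(vor_params(Tc = 5.7 * fac),
                                              f, "full"))
    expect_lt(max(abs(pert - base) / base), 0.005)
  }
})

test_that("FFT simulation matches analytic gain and phase on sinusoidal probes", {
  p <- vor_params()
  fs <- 1000
  tt <- (0:99999) / fs
  for (f0 in c(0.5, 1, 2, 5, 10, 15)) {
    head <- trace(20 * sin(2 * pi * f0 * tt))
    eye <- simulate_vor(head, p)
    sel <- 10000:90000  # avoid wrap-around edges
    g_sim <- sd(eye$values[sel]) / sd(head$values[sel])
    ref <- vestcoding:::vor_pathway_gain(p, f0, "full")
    expect_lt(abs(g_sim - Mod(ref)) / Mod(ref), 0.02)
    # phase via complex demodulation
    z <- exp(-2i * pi * f0 * tt[sel])
    ph_sim <- Arg(sum(eye$values[sel] * z) / sum(head$values[sel] * z))
    dph <- Arg(exp(1i * (ph_sim - Arg(ref))))
    expect_lt(abs(dph) * 180 / pi, 3)
    # compensatory below the delay-dominated range: phase near 180 deg
    if (f0 <= 2) expect_gt(abs(Arg(ref)) * 180 / pi, 160)
  }
})

test_that("zero head gives zero eye; naturalistic gain is near unity", {
  expect_equal(max(abs(simulate_vor(trace(numeric(5000)))$values)), 0)
  stim <- fix_stimulus()
  g <- vor_gain(stim, simulate_vor(stim))$gain
  expect_gt(g, 0.85); expect_lt(g, 1.05)
  # reduced-gain model recovers its own g_vor
  g9 <- vor_gain(stim, simulate_vor(stim, vor_params(g_vor = 0.9)))$gain
  expect_gt(g9, 0.85); expect_lt(g9, 0.95)
})

test_that("vor_gain is the negative regression slope and honours masks", {
  stim <- fix_stimulus()
  eye <- trace(-0.95 * stim$values)
  expect_equal(vor_gain(stim, eye)$gain, 0.95, tolerance = 1e-9)
  # large transients confined to an excluded mask do not bias the fit
  v <- eye$values
  v[20000:20400] <- v[20000:20400] + 500
  v[60000:60400] <- v[60000:60400] - 500
  mask <- segment_mask(rbind(c(19.99, 20.41), c(59.99, 60.41)), "saccade")
  out <- vor_gain(stim, trace(v), exclude = mask)
  expect_equal(out$gain, 0.95, tolerance = 1e-9)
  expect_error(vor_gain(stim, trace(v),
                        exclude = segment_mask(rbind(c(0, 119.9)))), "1 s")
})

test_that("spike-driven prediction is consistent with the full simulation", {
  stim <- fix_stimulus()
  p <- vor_params()
  # near-deterministic VOR neuron: spectra agree in band
  vt <- generate_vor_neuron(stim, p, base_rate = 80, cv = 0.05, seed = 1)
  pred <- predict_eye_from_spikes(vt, p)
  actual <- power_spectrum(simulate_vor(stim, p))
  sel <- actual$freq > 0.4 & actual$freq <= 15
  ratio <- vestcoding:::trapz(actual$freq[sel], pred$spectrum$power[sel]) /
    vestcoding:::trapz(actual$freq[sel], actual$power[sel])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
  # resting discharge only: prediction is the filtered noise floor
  rest <- generate_renewal_spiketrain(80, 0.5, 120, seed = 3)
  pr <- predict_eye_from_spikes(rest, p)
  noise_floor <- 80 * 0.5^2
  sel2 <- pr$spectrum$freq > 1 & pr$spectrum$freq <= 15
  expected <- 2 * noise_floor *
    Mod(vestcoding:::vor_pathway_gain(p, pr$spectrum$freq[sel2], "motor"))^2
  expect_lt(abs(mean(pr$spectrum$power[sel2] / expected) - 1), 0.2)
  expect_error(predict_eye_from_spikes(spike_train(numeric(0), 1), p),
               "empty")
})

test_that("matching index: algebraic identities and degradation with noise", {
  f <- seq(0.5, 20, by = 0.5)
  pa <- spectral_estimate(f, exp(-f / 4) + 0.01)
  expect_equal(matching_index(pa, pa)$mi, 1)
  # constant log offset c: mi = 1 - |log c| / SD(log P)
  pc <- spectral_estimate(f, 3 * pa$power)
  sda <- sd(log(pa$power))
  expect_equal(matching_index(pc, pa)$mi, max(0, 1 - log(3) / sda),
               tolerance = 1e-9)
  # common rescaling of both spectra leaves mi unchanged
  expect_equal(matching_index(
    spectral_estimate(f, 10 * pc$power),
    spectral_estimate(f, 10 * pa$power))$mi,
    matching_index(pc, pa)$mi, tolerance = 1e-12)
  # uncorrelated random log-spectra clip near zero
  set.seed(9)
  mis <- replicate(20, {
    p1 <- spectral_estimate(f, exp(rnorm(length(f), 0, 2)))
    p2 <- spectral_estimate(f, exp(rnorm(length(f), 0, 2)))
    matching_index(p1, p2)$mi
  })
  expect_lt(mean(mis), 0.1)
})

test_that("matching index is higher for low-variability VOR neurons", {
  stim <- fix_stimulus()
  p <- vor_params()
  actual <- power_spectrum(simulate_vor(stim, p))
  mi_for <- function(cv) {
    vt <- generate_vor_neuron(stim, p, base_rate = 50, cv = cv, seed = 4)
    matching_index(predict_eye_from_spikes(vt, p)$spectrum, actual)$mi
  }
  expect_gt(mi_for(0.1), mi_for(0.8))
})
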