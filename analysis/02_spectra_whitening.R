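#!/usr/bin/env Rscript
# Spike-train spectral statistics and temporal whitening: resting spectra
# across the CV range with Poisson surrogate bands, response spectra under
# naturalistic stimulation, and the whitening index per neuron.

library(vestcoding)

dir.create("results", showWarnings = FALSE)
seed <- 1
stim <- generate_naturalistic_stimulus(
  stimulus_spec(duration = 200, seed = seed))
cat(sprintf("stimulus whitening index: %.3f (head velocity is strongly low-pass)\n",
            stimulus_whitening_index(stim)$wi))

rows <- list()
for (cv in c(0.1, 0.3, 0.5, 0.8)) {
  rest <- generate_renewal_spiketrain(50, cv, 100,
                                      seed = derive_seed(seed, paste0("r", cv)))
  ns <- neuron_spec(base_rate = 50, target_cv = cv, sensitivity = 0.5,
                    seed = derive_seed(seed, paste0("n", cv)))
  resp <- generate_ln_response(stim, ns)
  prr <- power_spectrum(resp)
  p0 <- power_spectrum(rest)
  band <- poisson_confidence_band(rest, n = 200,
                                  seed = derive_seed(seed, paste0("b", cv)))
  sel <- p0$freq > 0.4 & p0$freq <= 20
  frac_out <- mean(p0$power[sel] < band$low[sel] | p0$power[sel] > band$high[sel])
  wi <- whitening_index(prr)$wi
  cat(sprintf("CV %.1f: resting low-f power %.2f sp^2/s (theory %.2f), %2.0f%% of bins outside Poisson band, response WI %.2f\n",
              cv, band_power(p0, c(0.5, 2)), 50 * cv^2, 100 * frac_out, wi))
  rows[[length(rows) + 1]] <- data.frame(
    cv = cv, lowfreq_power = band_power(p0, c(0.5, 2)),
    theory_lowfreq = 50 * cv^2, frac_outside_poisson_band = frac_out,
    whitening_index = wi)
  if (cv %in% c(0.1, 0.8))
    write_spectral_estimate(prr, sprintf("results/response_spectrum_cv%.1f.csv", cv))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/whitening_by_cv.csv", row.names = FALSE)
cat("-> low-variability neurons deviate from the Poisson band and are far from white;\n")
cat("   high-variability neurons are close to temporally whitened (WI near 1)\n")
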