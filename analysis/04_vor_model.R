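#!/usr/bin/env Rscript
# VOR transfer-function model: closed-form probe table, naturalistic
# simulation with regression gain, and the spike-driven eye-velocity
# prediction with its matching index across the CV range.

library(vestcoding)

dir.create("results", showWarnings = FALSE)
seed <- 1
p <- vor_params()

# probe table: analytic gain/phase of the full cascade
probes <- data.frame(freq_hz = c(0.5, 1, 2, 5, 10, 15))
resp <- stage_response(p, probes$freq_hz, "afferents") *
  stage_response(p, probes$freq_hz, "vn") *
  stage_response(p, probes$freq_hz, "ni") *
  stage_response(p, probes$freq_hz, "plant")
probes$gain <- Mod(resp)
probes$phase_deg <- Arg(resp) * 180 / pi
write.csv(probes, "results/vor_probe_table.csv", row.names = FALSE)
cat("head-to-eye cascade at probe frequencies:\n")
print(probes, digits = 3, row.names = FALSE)

stim <- generate_naturalistic_stimulus(stimulus_spec(duration = 200, seed = seed))
eye <- simulate_vor(stim, p)
g <- vor_gain(stim, eye)
cat(sprintf("naturalistic VOR gain (g_vor = 1): %.3f (R^2 = %.3f)\n",
            g$gain, g$r_squared))

# spike-driven prediction: CV-matched model VOR neurons
actual <- power_spectrum(eye)
rows <- lapply(c(0.1, 0.3, 0.5, 0.8), function(cv) {
  vt <- generate_vor_neuron(stim, p, base_rate = 50, cv = cv,
                            seed = derive_seed(seed, paste0("vor", cv)))
  mi <- matching_index(predict_eye_from_spikes(vt, p)$spectrum, actual)$mi
  cat(sprintf("VOR neuron CV %.1f: matching index %.3f\n", cv, mi))
  data.frame(cv = cv, matching_index = mi)
})
write.csv(do.call(rbind, rows), "results/matching_index_by_cv.csv",
          row.names = FALSE)
cat("-> compensatory eye movements are reproduced from low-variability\n")
cat("   VOR neurons; spiking noise from high-variability neurons degrades them\n")
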