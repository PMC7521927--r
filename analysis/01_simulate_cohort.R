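#!/usr/bin/env Rscript
# Build the synthetic study inputs: one frozen naturalistic head-velocity
# stimulus and a variability-graded cohort of model vestibular neurons
# (fixed rate 50 sp/s, ISI CV 0.1-0.8, fixed sensitivity). Writes example
# traces and spike trains as plain text under results/.

library(vestcoding)

dir.create("results", showWarnings = FALSE)
seed <- 1

stim <- generate_naturalistic_stimulus(
  stimulus_spec(duration = 200, corner_freq = 2, target_sd = 20, seed = seed))
cat(sprintf("stimulus: %.0f s at 1 kHz, sd %.2f deg/s, mean %.3f deg/s\n",
            duration_s(stim), sd(stim$values), mean(stim$values)))
write_trace(mask_and_concatenate(
  stim, segment_mask(rbind(c(0, 10))))$data, "results/stimulus_head_velocity_10s.csv")

# two example neurons at the variability extremes
for (cv in c(0.1, 0.8)) {
  ns <- neuron_spec(base_rate = 50, target_cv = cv, sensitivity = 0.5,
                    seed = derive_seed(seed, paste0("example", cv)))
  rest <- generate_renewal_spiketrain(50, cv, 100,
                                      seed = derive_seed(seed, paste0("rest", cv)))
  resp <- generate_ln_response(stim, ns)
  st <- isi_stats(rest)
  cat(sprintf("example neuron CV %.1f: resting %.1f sp/s, measured CV %.2f, %d response spikes\n",
              cv, st$firing_rate, st$cv, length(resp$times)))
  write_spikes(rest, sprintf("results/resting_cv%.1f.spikes", cv))
  write_spikes(resp, sprintf("results/response_cv%.1f.spikes", cv))
}

# model eye movements with quick phases, plus their exclusion mask
eye <- generate_eye_movement(stim, vor_params(), quick_phase_rate = 1,
                             seed = seed)
cat(sprintf("eye movements: %d quick phases over %.0f s\n",
            nrow(eye$quick_phase_mask$intervals), duration_s(stim)))
write_mask(eye$quick_phase_mask, "results/quick_phase_mask.csv")
write_trace(mask_and_concatenate(
  eye$eye_velocity, segment_mask(rbind(c(0, 10))))$data,
  "results/eye_velocity_10s.csv")
cat("wrote example inputs under results/\n")
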