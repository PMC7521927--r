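# Cohort orchestration: generate a synthetic neuron cohort, run every metric
# per neuron, assemble the cohort table, and compute the trend statistics
# against resting-discharge CV.

#' Default cohort configuration
#'
#' The default cohort holds firing rate (50 sp/s) and linear sensitivity
#' fixed while the resting-discharge CV spans 0.1-0.8, with `n_seeds`
#' independent neurons per CV (24 neurons in total), mirroring a
#' fixed-rate, variability-graded population. Class labels cycle through
#' PVP/EH/VO as metadata.
#'
#' @param duration stimulus/response duration per neuron (s)
#' @param rest_duration resting-discharge duration per neuron (s)
#' @param rate resting firing rate (sp/s)
#' @param cv_grid resting-discharge CV values
#' @param n_seeds neurons per CV value
#' @param sensitivity linear-stage gain ((sp/s)/(deg/s))
#' @param target_sd stimulus SD (deg/s)
#' @param corner_freq stimulus shaping knee (Hz)
#' @param window_s,n_tapers spectral estimator settings
#' @param band analysis band (Hz)
#' @param seed master seed
#' @param log_cv compute Pearson trend correlations on log-transformed CV
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(duration = 200, rest_duration = 100, rate = 50,
                          cv_grid = seq(0.1, 0.8, by = 0.1), n_seeds = 3,
                          sensitivity = 0.5, target_sd = 20, corner_freq = 2,
                          window_s = 2.048, n_tapers = 4, band = c(0, 20),
                          seed = 1, log_cv = TRUE) {
  cfg <- list(duration = duration, rest_duration = rest_duration, rate = rate,
              cv_grid = cv_grid, n_seeds = n_seeds, sensitivity = sensitivity,
              target_sd = target_sd, corner_freq = corner_freq,
              window_s = window_s, n_tapers = n_tapers, band = band,
              seed = seed, log_cv = log_cv)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  checks <- c(
    duration = is.numeric(cfg$duration) && cfg$duration >= 20,
    rest_duration = is.numeric(cfg$rest_duration) && cfg$rest_duration >= 10,
    rate = is.numeric(cfg$rate) && cfg$rate > 0,
    cv_grid = is.numeric(cfg$cv_grid) && length(cfg$cv_grid) >= 1 &&
      all(cfg$cv_grid > 0 & cfg$cv_grid <= 1.5),
    n_seeds = is.numeric(cfg$n_seeds) && cfg$n_seeds >= 1,
    sensitivity = is.numeric(cfg$sensitivity) && cfg$sensitivity >= 0,
    target_sd = is.numeric(cfg$target_sd) && cfg$target_sd > 0,
    band = is.numeric(cfg$band) && length(cfg$band) == 2 &&
      cfg$band[2] > cfg$band[1],
    seed = is.numeric(cfg$seed))
  if (any(!checks))
    stop("invalid cohort config field(s): ",
         paste(names(checks)[!checks], collapse = ", "))
  invisible(cfg)
}

#' Load a cohort configuration from a YAML or JSON file
#'
#' Fields mirror [cohort_config()] arguments; unspecified fields take the
#' defaults.
#'
#' @param path file ending in .yaml/.yml or .json
#' @return a `cohort_config`
#' @export
read_cohort_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required to read JSON configs")
    jsonlite::fromJSON(path)
  } else stop("config must be a .yaml/.yml or .json file")
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(cohort_config, lst)
}

#' Run the full analysis pipeline over a synthetic cohort
#'
#' Generates one frozen naturalistic stimulus and, per neuron: a resting
#' discharge (rate, CV, resting spectrum P0), an LN-cascade response to the
#' stimulus, the measured response spectrum and whitening index, a fitted LN
#' model and its predicted whitening index, stimulus-response coherence with
#' mutual-information rate and optimality, band SNR (stimulus-driven power
#' over resting noise power), Wiener reconstruction with coding fraction,
#' and a VOR branch (CV-matched synthetic VOR neuron driven by the model
#' pathway, spike-predicted vs model eye-velocity spectra, matching index).
#'
#' @param config a `cohort_config`, a path to one (YAML/JSON), or a list of
#'   [cohort_config()] arguments
#' @return list of class `cohort_result` with `table` (one row per neuron),
#'   `trends` (correlations of each metric against CV), `config`, and
#'   `vor_gain` of the model simulation
#' @export
run_cohort <- function(config = cohort_config()) {
  if (is.character(config)) config <- read_cohort_config(config)
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config

  stim <- generate_naturalistic_stimulus(stimulus_spec(
    duration = cfg$duration, corner_freq = cfg$corner_freq,
    target_sd = cfg$target_sd, seed = derive_seed(cfg$seed, "cohort_stimulus")))
  vparams <- vor_params()
  actual_eye <- simulate_vor(stim, vparams)
  eye_spec <- power_spectrum(actual_eye, window_s = cfg$window_s,
                             n_tapers = cfg$n_tapers)
  gain <- vor_gain(stim, actual_eye)$gain
  drive_vor <- vor_neuron_drive(stim, vparams)
  classes <- c("PVP", "EH", "VO")

  grid <- expand.grid(rep = seq_len(cfg$n_seeds), cv = cfg$cv_grid)
  rows <- vector("list", nrow(grid))
  ws <- wiener_settings(window_s = cfg$window_s, n_tapers = cfg$n_tapers)
  for (i in seq_len(nrow(grid))) {
    cv <- grid$cv[i]
    nid <- sprintf("n%02d_cv%.2f_r%d", i, cv, grid$rep[i])
    seed_i <- derive_seed(cfg$seed, nid)
    nspec <- neuron_spec(base_rate = cfg$rate, target_cv = cv,
                         sensitivity = cfg$sensitivity, seed = seed_i,
                         class_label = classes[(i - 1) %% 3 + 1])

    rest <- generate_renewal_spiketrain(cfg$rate, cv, cfg$rest_duration,
                                        seed = derive_seed(seed_i, "rest"))
    rs <- isi_stats(rest)
    p0 <- power_spectrum(rest, window_s = cfg$window_s,
                         n_tapers = cfg$n_tapers)

    resp <- generate_ln_response(stim, nspec)
    prr <- power_spectrum(resp, window_s = cfg$window_s,
                          n_tapers = cfg$n_tapers)
    wi <- whitening_index(prr, band = cfg$band)$wi

    model <- fit_ln_model(stim, resp, rest, window_s = cfg$window_s,
                          n_tapers = cfg$n_tapers)
    wi_pred <- whitening_index(predict_response_spectrum(model, stim),
                               band = cfg$band)$wi

    coh <- coherence(resp, stim, window_s = cfg$window_s,
                     n_tapers = cfg$n_tapers)
    mi_rate <- mutual_information_rate(coh, band = cfg$band)$mi_rate
    # noise = resting spectrum (resting and trial-to-trial variability have
    # the same spectrum); signal = stimulus-driven excess response power
    sel <- prr$freq >= cfg$band[1] & prr$freq <= cfg$band[2]
    sig_p <- pmax(prr$power[sel] - p0$power[sel], 0)
    budget <- trapz(prr$freq[sel], sig_p)
    snr_band <- budget / trapz(p0$freq[sel], p0$power[sel])
    opt <- optimality(mi_rate, p0, budget, band = cfg$band)$optimality

    kern <- optimal_kernel_single(resp, stim, settings = ws)
    rec <- reconstruct(resp, kern)
    cf <- coding_fraction(stim, rec$reconstruction, rec$valid)$cf

    vtrain <- generate_vor_neuron(stim, vparams, base_rate = cfg$rate,
                                  cv = cv, seed = seed_i)
    pred <- predict_eye_from_spikes(vtrain, vparams, window_s = cfg$window_s,
                                    n_tapers = cfg$n_tapers)
    mi_match <- matching_index(pred$spectrum, eye_spec, band = cfg$band)$mi

    rows[[i]] <- data.frame(
      neuron_id = nid, class_label = nspec$class_label,
      rate = rs$firing_rate, cv = rs$cv, cv_target = cv,
      sensitivity_1hz = model$linear$sensitivity_1hz,
      wi = wi, wi_predicted = wi_pred, cf = cf, mi_rate = mi_rate,
      optimality = opt, snr_band = snr_band, matching_index = mi_match,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, trends = cohort_trends(tab, cfg$log_cv),
                 config = cfg, vor_gain = gain),
            class = "cohort_result")
}

# Spearman and Pearson correlations of each metric against measured CV
cohort_trends <- function(tab, log_cv = TRUE) {
  metrics <- c("wi", "cf", "mi_rate", "optimality", "matching_index",
               "snr_band")
  x_p <- if (log_cv) log(tab$cv) else tab$cv
  do.call(rbind, lapply(metrics, function(m) {
    y <- tab[[m]]
    ok <- is.finite(y) & is.finite(tab$cv)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0)
      return(data.frame(metric = m, spearman = NA_real_, pearson = NA_real_,
                        n = sum(ok)))
    data.frame(metric = m,
               spearman = stats::cor(tab$cv[ok], y[ok], method = "spearman"),
               pearson = stats::cor(x_p[ok], y[ok]),
               n = sum(ok))
  }))
}

#' Human-readable cohort summary with per-neuron consistency flags
#'
#' Flags any neuron whose measured and LN-predicted whitening indices
#' disagree by more than `wi_tol` (internal-consistency check of the LN
#' prediction). Summary statistics are invariant to the row order of the
#' table.
#'
#' @param result a `cohort_result` (or its `table`)
#' @param wi_tol flag threshold on |wi - wi_predicted|, default 0.15
#' @return list of class `cohort_report` with `summary` (character lines),
#'   `flags` (data.frame), `trends`
#' @export
cohort_report <- function(result, wi_tol = 0.15) {
  tab <- if (inherits(result, "cohort_result")) result$table else result
  if (is.null(tab) || nrow(tab) == 0) stop("empty cohort table")
  tab <- tab[order(tab$neuron_id), , drop = FALSE]
  trends <- if (inherits(result, "cohort_result")) result$trends
            else cohort_trends(tab)
  dev <- abs(tab$wi - tab$wi_predicted)
  flags <- tab[dev > wi_tol, c("neuron_id", "cv", "wi", "wi_predicted"),
               drop = FALSE]
  lines <- c(
    sprintf("cohort of %d neurons; rate %.1f-%.1f sp/s; CV %.2f-%.2f",
            nrow(tab), min(tab$rate), max(tab$rate), min(tab$cv), max(tab$cv)),
    sprintf("whitening index: %.2f-%.2f (Spearman vs CV: %+.2f)",
            min(tab$wi), max(tab$wi),
            trends$spearman[trends$metric == "wi"]),
    sprintf("coding fraction: %.2f-%.2f (Spearman vs CV: %+.2f)",
            min(tab$cf), max(tab$cf),
            trends$spearman[trends$metric == "cf"]),
    sprintf("information rate: %.1f-%.1f bits/s (Spearman vs CV: %+.2f)",
            min(tab$mi_rate), max(tab$mi_rate),
            trends$spearman[trends$metric == "mi_rate"]),
    sprintf("matching index: %.2f-%.2f (Spearman vs CV: %+.2f)",
            min(tab$matching_index), max(tab$matching_index),
            trends$spearman[trends$metric == "matching_index"]),
    sprintf("LN whitening prediction: mean |wi - wi_pred| = %.3f; %d/%d within %.2f",
            mean(dev), sum(dev <= wi_tol), nrow(tab), wi_tol))
  if (nrow(flags) > 0)
    lines <- c(lines,
               sprintf("FLAG: %s |wi - wi_pred| > %.2f (wi %.2f vs predicted %.2f)",
                       flags$neuron_id, wi_tol, flags$wi, flags$wi_predicted))
  structure(list(summary = lines, flags = flags, trends = trends),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  writeLines(x$summary)
  invisible(x)
}
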