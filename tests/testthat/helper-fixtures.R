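# Shared fixtures, built once per test run.  All are generated in code
# from seeded simulations; the heavier ones are memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# dense, nearly noiseless time-on-study study: good for recovery oracles
dense_study <- function() fixture("dense_study", function() {
  simulate_scenario(sim_config(n_subjects = 400, noise_sd = 0.01,
                               censoring = "none", seed = 101))
})

# dense noisy study at the configured noise level, median censoring
noisy_study <- function() fixture("noisy_study", function() {
  simulate_scenario(scenario_config(2, n_subjects = 400, seed = 202))
})

# small age-at-observation study
age_study <- function() fixture("age_study", function() {
  simulate_scenario(scenario_config(5, n_subjects = 300, seed = 303))
})

# mFPCA fit on the dense study (study-time scale)
dense_fit <- function() fixture("dense_fit", function() {
  fit_mfpca(dense_study()$dataset, time_scale = "study", pve_target = 0.95)
})

# a tiny hand-made dataset: 3 subjects, one variable, 3 planned visits
toy_dataset <- function() {
  long <- expand.grid(id = c("a", "b", "c"), time = c(0, 1, 2),
                      stringsAsFactors = FALSE)
  long$variable <- "v"
  long$value <- seq_len(nrow(long))
  baseline <- data.frame(id = c("a", "b", "c"), age = c(50, 60, 70),
                         time = c(1, 2, 3), event = c(1, 1, 0))
  longitudinal_dataset(long, baseline, grid = c(0, 1, 2))
}

# prediction_result wrapper around an arbitrary probability matrix
as_prediction <- function(ids, t_LM, horizon, prob) {
  structure(list(subject_ids = as.character(ids), landmark_time = t_LM,
                 horizon_times = horizon,
                 probabilities = matrix(prob, nrow = length(ids))),
            class = "prediction_result")
}
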