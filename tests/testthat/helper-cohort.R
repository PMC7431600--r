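# Shared fixtures: parameter sets used across test files.

# noiseless, instantaneous-onset group: downstream profiles equal the
# generative curve exactly
noiseless_params <- function(label = "noiseless", a = 0.2, lambda = 200,
                             n = 5, d0 = 25,
                             len_min = 200, len_max = 400) {
  group_params(label, n_vessels = n,
               true_local_constriction = a,
               true_length_constant = lambda,
               baseline_diameter_mean = d0, baseline_diameter_sd = 0,
               traceable_length_min = len_min, traceable_length_max = len_max,
               constriction_onset_tau = 0, recovery_tau = 5,
               vasomotion_sd = 0, measurement_noise_sd = 0)
}

noiseless_pool <- function(..., seed = 1) {
  coh <- generate_cohort(noiseless_params(...), seed = seed)
  pool_group(lapply(coh, build_profile))
}

# hand-built recording on the default grid: diameters given per position as
# baseline/stimulation/recovery triples
manual_recording <- function(diams, positions = (seq_along(diams) - 1) * 50,
                             vessel_id = "m1", group = "manual") {
  stopifnot(all(lengths(diams) == 9))
  m <- do.call(rbind, diams)
  dimnames(m) <- list(position = positions, time = seq(10, 90, 10))
  structure(list(vessel_id = vessel_id, group_label = group,
                 positions = positions, times = seq(10, 90, 10),
                 phases = rep(c("baseline", "stimulation", "recovery"),
                              each = 3),
                 diameters = m,
                 baseline_diameter = mean(m[1, 1:3]),
                 traceable_length = max(positions)),
            class = "vessel_recording")
}
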