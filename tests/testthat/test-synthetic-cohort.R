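test_that("default protocol matches the experimental design", {
  p <- default_protocol()
  expect_equal(p$baseline_duration, 30)
  expect_equal(p$stimulation_duration, 30)
  expect_equal(p$recovery_duration, 30)
  expect_equal(p$sampling_interval, 10)
  expect_equal(p$position_spacing, 50)
})

test_that("protocol validation rejects inconsistent timing", {
  expect_error(stim_protocol(baseline_duration = -5), "> 0")
  expect_error(stim_protocol(baseline_duration = 25), "integer multiples")
  expect_error(stim_protocol(position_spacing = 0), "position_spacing")
  expect_error(stim_protocol(baseline_duration = Inf), "finite")
})

test_that("group parameter validation enforces the documented invariants", {
  expect_error(group_params("g", 5, 1.2, 200), "\\[0, 1\\)")
  expect_error(group_params("g", 5, 0.2, -10), "true_length_constant")
  expect_error(group_params("g", 0, 0.2, 200), "n_vessels")
  expect_error(group_params("g", 5, 0.2, 200, vasomotion_sd = -1),
               "standard deviations")
  expect_error(group_params("g", 5, 0.2, 200,
                            traceable_length_min = 300,
                            traceable_length_max = 200), "<=")
  expect_error(group_params("g", 5, NaN, 200), "finite")
})

test_that("default group parameters carry the published group values", {
  ko45 <- default_group_params("Cx45 KO")
  expect_equal(ko45$true_local_constriction, 0.17)
  expect_equal(ko45$n_vessels, 11)

  ko40 <- default_group_params("Cx40 KO")
  expect_equal(ko40$baseline_diameter_mean, 15.5)
  expect_equal(ko40$true_length_constant, 1 / 5.6e-3)

  wt45 <- default_group_params("Cx45 WT")
  expect_equal(wt45$true_length_constant, 455)
  expect_equal(wt45$baseline_diameter_mean, 30.6)

  # the Cx40 WT length constant derives from its decay rate
  expect_equal(default_group_params("Cx40 WT")$true_length_constant,
               1 / 3.8e-3)

  expect_error(default_group_params("Cx43 WT"), "Cx40 WT")
})

test_that("noiseless generated diameters follow the generative formula", {
  p <- default_protocol()
  gp <- group_params("g", 1, true_local_constriction = 0.40,
                     true_length_constant = 300,
                     baseline_diameter_mean = 20, baseline_diameter_sd = 0,
                     traceable_length_min = 200, traceable_length_max = 200,
                     constriction_onset_tau = 10, recovery_tau = 5,
                     vasomotion_sd = 0, measurement_noise_sd = 0)
  rec <- generate_vessel(gp, p, seed = 1)
  # at x = 0, end of stimulation: diameter ~ 0.60 * baseline, short of it
  # only by the onset residual exp(-30/tau)
  d_end <- rec$diameters["0", "60"]
  expect_equal(d_end, 20 * (1 - 0.40 * (1 - exp(-30 / 10))), tolerance = 1e-12)
  expect_lt(abs(d_end / 20 - 0.60), 0.40 * exp(-30 / 10) + 1e-12)
  # baseline samples untouched
  expect_equal(unname(rec$diameters[, "10"]), rep(20, length(rec$positions)))
  # spatial profile scales as exp(-x/lambda) at fixed time
  c_x <- 1 - rec$diameters[, "60"] / 20
  expect_equal(unname(c_x / c_x[1]), exp(-rec$positions / 300),
               tolerance = 1e-12)
})

test_that("null-effect vessels stay at baseline", {
  gp <- noiseless_params(a = 0, lambda = 200, n = 1)
  rec <- generate_vessel(gp, default_protocol(), seed = 4)
  expect_true(all(rec$diameters == 25))
})

test_that("generation is seed-deterministic", {
  gp <- default_group_params("Cx40 WT")
  p <- default_protocol()
  r1 <- generate_vessel(gp, p, seed = 123)
  r2 <- generate_vessel(gp, p, seed = 123)
  expect_identical(r1, r2)
  expect_false(identical(r1$diameters,
                         generate_vessel(gp, p, seed = 124)$diameters))

  gs <- list(default_group_params("Cx40 WT"), default_group_params("Cx40 KO"))
  c1 <- generate_cohort(gs, p, seed = 99)
  c2 <- generate_cohort(gs, p, seed = 99)
  expect_identical(c1, c2)
})

test_that("cohorts have the requested sizes and appending a group leaves earlier draws intact", {
  p <- default_protocol()
  gs <- list(default_group_params("Cx40 WT"), default_group_params("Cx40 KO"))
  coh <- generate_cohort(gs, p, seed = 7)
  expect_length(coh, 15)
  labs <- vapply(coh, function(r) r$group_label, character(1))
  expect_equal(unname(table(labs)[c("Cx40 WT", "Cx40 KO")]),
               c(8L, 7L), ignore_attr = TRUE)

  coh3 <- generate_cohort(c(gs, list(default_group_params("Cx45 WT"))),
                          p, seed = 7)
  expect_identical(coh3[1:15], coh[1:15])

  expect_error(generate_cohort(list(gs[[1]], gs[[1]]), p, seed = 1),
               "distinct")
  expect_error(group_params("g", 0, 0.2, 200), "n_vessels")
})

test_that("traceable lengths stay on the position grid within the group range", {
  gp <- default_group_params("Cx45 KO")
  lens <- vapply(1:40, function(s)
    generate_vessel(gp, default_protocol(), seed = s)$traceable_length,
    numeric(1))
  expect_true(all(lens >= 100 & lens <= 500))
  expect_true(all(lens %% 50 == 0))
  expect_gt(length(unique(lens)), 3) # actually varies
})

test_that("mean measured local constriction converges to the generative value", {
  # instantaneous onset so the 10/20/30-s window reads the plateau; noise
  # at the default magnitudes averages out across vessels
  gp <- group_params("conv", n_vessels = 200,
                     true_local_constriction = 0.23,
                     true_length_constant = 455,
                     baseline_diameter_mean = 30.6, baseline_diameter_sd = 8.1,
                     traceable_length_min = 200, traceable_length_max = 500,
                     constriction_onset_tau = 0, recovery_tau = 5)
  coh <- generate_cohort(gp, seed = 2024)
  locals <- vapply(coh, function(r) {
    relative_constriction(resting_diameter(r, 0), stimulation_diameter(r, 0))
  }, numeric(1))
  se <- sd(locals) / sqrt(length(locals))
  expect_lt(abs(mean(locals) - 0.23), 3 * se)
})

test_that("recordings round-trip through the tidy CSV dialect", {
  coh <- generate_cohort(list(default_group_params("Cx40 WT"),
                              default_group_params("Cx40 KO")), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recordings(coh, f)
  df <- read.csv(f, na.strings = "")
  expect_named(df, c("vessel_id", "group", "position_um", "time_s", "phase",
                     "diameter_um"))
  coh2 <- read_recordings(f)
  expect_length(coh2, length(coh))
  for (i in seq_along(coh)) {
    expect_equal(coh2[[i]]$positions, coh[[i]]$positions)
    expect_equal(unname(coh2[[i]]$diameters), unname(coh[[i]]$diameters),
                 tolerance = 1e-12)
    expect_equal(coh2[[i]]$phases, coh[[i]]$phases)
  }
})

test_that("malformed recordings CSVs are rejected with a row number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vessel_id,group,position_um,time_s,phase,diameter_um",
               "v1,g,0,10,baseline,20",
               "v1,g,0,20,baseline,-3"), f)
  expect_error(read_recordings(f), "row 2")
  writeLines(c("vessel_id,group,position_um,time_s,diameter_um",
               "v1,g,0,10,20"), f)
  expect_error(read_recordings(f), "missing column")
  writeLines(c("vessel_id,group,position_um,time_s,phase,diameter_um",
               "v1,g,0,10,lunch,20"), f)
  expect_error(read_recordings(f), "phase at data row 1")
})
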