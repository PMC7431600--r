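test_that("resting diameter is the baseline-phase mean", {
  rec <- manual_recording(list(c(19, 20, 21, 16, 15, 14, 18, 19, 20)))
  expect_equal(resting_diameter(rec, 0), 20)
  rec2 <- manual_recording(list(rep(28.7, 9)))
  expect_equal(resting_diameter(rec2, 0), 28.7)
  expect_error(resting_diameter(rec, 50), "not present")
})

test_that("stimulation diameter averages the 10/20/30-s samples", {
  rec <- manual_recording(list(c(20, 20, 20, 16, 15, 14, 18, 19, 20)))
  expect_equal(stimulation_diameter(rec, 0), 15)
  recd <- manual_recording(list(c(20, 20, 20, 17, 17, 17, 19, 20, 20)))
  expect_equal(stimulation_diameter(recd, 0), 17)
})

test_that("missing stimulation samples raise an error naming the time", {
  rec <- manual_recording(list(c(20, 20, 20, 16, NA, 14, 18, 19, 20)))
  expect_error(stimulation_diameter(rec, 0), "t = 50")
})

test_that("relative constriction is the fractional diameter reduction", {
  expect_equal(relative_constriction(20, 16), 0.20)
  expect_equal(relative_constriction(17.3, 17.3), 0)
  expect_equal(relative_constriction(20, 22), -0.10)
  expect_error(relative_constriction(0, 5), "positive")
  expect_error(relative_constriction(20, -1), ">= 0")
  # inverse property: constricting by c and measuring recovers c
  for (c in c(0.01, 0.3, 0.85)) {
    expect_equal(relative_constriction(24, 24 * (1 - c)), c)
  }
})

test_that("zero-truncation zeroes everything from the first non-positive value", {
  expect_equal(as.numeric(truncate_profile(c(0.20, 0.10, -0.02, 0.05))),
               c(0.20, 0.10, 0, 0))
  expect_equal(attr(truncate_profile(c(0.20, 0.10, -0.02, 0.05)),
                    "truncated_from"), 3L)
  v <- c(0.3, 0.2, 0.1)
  expect_equal(as.numeric(truncate_profile(v)), v)
  expect_true(is.na(attr(truncate_profile(v), "truncated_from")))
  expect_equal(as.numeric(truncate_profile(c(-0.1, 0.2, 0.3))), c(0, 0, 0))
})

test_that("zero-truncation is idempotent and order-preserving before the cut", {
  set.seed(42)
  for (i in 1:25) {
    v <- round(rnorm(sample(3:10, 1), 0.1, 0.12), 3)
    t1 <- as.numeric(truncate_profile(v))
    expect_identical(as.numeric(truncate_profile(t1)), t1)
    cut <- attr(truncate_profile(v), "truncated_from")
    keep <- if (is.na(cut)) seq_along(v) else seq_len(cut - 1L)
    expect_identical(t1[keep], v[keep])
  }
})

test_that("noiseless profiles reproduce the generative curve exactly", {
  gp <- noiseless_params(a = 0.26, lambda = 263, n = 1,
                         len_min = 300, len_max = 300)
  rec <- generate_vessel(gp, default_protocol(), seed = 1)
  prof <- build_profile(rec)
  expect_equal(prof$raw_constriction,
               0.26 * exp(-prof$distances / 263), tolerance = 1e-12)
  expect_equal(prof$constriction, prof$raw_constriction, tolerance = 1e-12)
  expect_length(prof$distances, 7)
})

test_that("null-effect vessels give all-zero truncated profiles", {
  gp <- noiseless_params(a = 0, n = 1, len_min = 200, len_max = 200)
  prof <- build_profile(generate_vessel(gp, default_protocol(), seed = 1))
  expect_true(all(prof$constriction == 0))
  expect_equal(prof$truncated_from, 1L)
})

test_that("inclusion criteria match the study rules", {
  # criterion 1: local constriction below 5%
  weak <- manual_recording(list(c(20, 20, 20, 19.2, 19.2, 19.2, 20, 20, 20),
                                c(20, 20, 20, 19.5, 19.5, 19.5, 20, 20, 20),
                                c(20, 20, 20, 19.8, 19.8, 19.8, 20, 20, 20)))
  d <- apply_inclusion_criteria(build_profile(weak), weak)
  expect_false(d$included)
  expect_named(d$failed_criteria, "local_constriction_min")
  expect_equal(d$failed_criteria$local_constriction_min, 0.04)

  # criterion 2: poor recovery
  stuck <- manual_recording(list(c(20, 20, 20, 14, 14, 14, 9, 9, 9),
                                 c(20, 20, 20, 16, 16, 16, 9, 9, 9),
                                 c(20, 20, 20, 18, 18, 18, 9, 9, 9)))
  d <- apply_inclusion_criteria(build_profile(stuck), stuck)
  expect_false(d$included)
  expect_named(d$failed_criteria, "recovery_min")
  expect_equal(d$failed_criteria$recovery_min, 0.45)

  # criterion 3: fewer than three measurable positions
  short <- manual_recording(list(c(20, 20, 20, 14, 14, 14, 19, 19, 19),
                                 c(20, 20, 20, 16, 16, 16, 19, 19, 19)))
  d <- apply_inclusion_criteria(build_profile(short), short)
  expect_false(d$included)
  expect_named(d$failed_criteria, "position_min")
  expect_equal(d$failed_criteria$position_min, 2)

  # all pass
  good <- manual_recording(list(c(20, 20, 20, 16, 16, 16, 18, 19, 20),
                                c(20, 20, 20, 17, 17, 17, 19, 20, 20),
                                c(20, 20, 20, 18, 18, 18, 19, 20, 20),
                                c(20, 20, 20, 19, 19, 19, 20, 20, 20),
                                c(20, 20, 20, 19.5, 19.5, 19.5, 20, 20, 20)))
  d <- apply_inclusion_criteria(build_profile(good), good)
  expect_true(d$included)
  expect_length(d$failed_criteria, 0)
})

test_that("pooling summarises per distance with the sample SEM", {
  p1 <- build_profile(manual_recording(
    list(c(20, 20, 20, 16, 16, 16, 19, 19, 19),
         c(20, 20, 20, 17, 17, 17, 19, 19, 19),
         c(20, 20, 20, 18, 18, 18, 19, 19, 19)), vessel_id = "a"))
  p2 <- build_profile(manual_recording(
    list(c(20, 20, 20, 14, 14, 14, 19, 19, 19),
         c(20, 20, 20, 16, 16, 16, 19, 19, 19)), vessel_id = "b"))
  pooled <- pool_group(list(p1, p2), label = "manual")
  at0 <- pooled$per_distance[pooled$per_distance$distance == 0, ]
  expect_equal(at0$mean, 0.25)
  expect_equal(at0$sem, 0.05)
  expect_equal(at0$n, 2L)
  # distance 100 has a single vessel: SEM undefined
  at100 <- pooled$per_distance[pooled$per_distance$distance == 100, ]
  expect_equal(at100$n, 1L)
  expect_true(is.na(at100$sem))
  expect_error(pool_group(list()), "no profiles")
})

test_that("pooled means equal direct enumeration and counts never increase with distance", {
  coh <- generate_cohort(default_group_params("Cx40 WT"), seed = 31)
  profs <- lapply(coh, build_profile)
  pooled <- pool_group(profs)
  # direct enumeration oracle
  all_pts <- do.call(rbind, lapply(profs, function(p)
    data.frame(d = p$distances, y = p$constriction)))
  for (d in unique(all_pts$d)) {
    expect_equal(pooled$per_distance$mean[pooled$per_distance$distance == d],
                 mean(all_pts$y[all_pts$d == d]))
  }
  expect_true(all(diff(pooled$per_distance$n) <= 0))
})
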