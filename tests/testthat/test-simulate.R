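test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_trial(coordination_preset("expert_like"), n_cycles = 2,
                      seed = 99)
  b <- simulate_trial(coordination_preset("expert_like"), n_cycles = 2,
                      seed = 99)
  expect_identical(a$trial$positions, b$trial$positions)
  expect_identical(a$truth$theta, b$truth$theta)
  c <- simulate_trial(coordination_preset("expert_like"), n_cycles = 2,
                      seed = 100)
  expect_false(identical(a$trial$positions, c$trial$positions))
})

test_that("zero-amplitude profiles yield static trials with no strokes", {
  prof <- coordination_profile(marker_noise_sd = 0)
  sim <- simulate_trial(prof, n_cycles = 2, seed = 1)
  expect_lt(max(apply(sim$trial$positions, 2:3, function(x) diff(range(x)))),
            1e-9)
  kin <- bow_kinematics(sim$trial)
  expect_equal(nrow(detect_strokes(kin$velocity, 60)$strokes), 0)
})

test_that("presets are named and validated", {
  expect_s3_class(coordination_preset("expert_like"), "coordination_profile")
  expect_error(coordination_preset("virtuoso"))
  expect_error(coordination_profile(plateau = 1.2), "plateau")
  expect_error(coordination_profile(shoulder_amp = -1), ">= 0")
  expect_error(coordination_profile(joint_noise_sd = c(0.1, 0.1)),
               "length 1 or 3")
})

test_that("noise-free presets segment into ~2 n_cycles strokes of 0.75 s", {
  for (name in c("expert_like", "novice_like")) {
    sim <- simulate_trial(noise_free(name), n_cycles = 10, seed = 3)
    kin <- bow_kinematics(sim$trial)
    ss <- detect_strokes(kin$velocity, sim$trial$rate_hz)
    expect_gte(nrow(ss$strokes), 2 * 10 - 3)
    expect_lte(nrow(ss$strokes), 2 * 10)
    expect_true(all(abs(ss$strokes$duration_s - 0.75) <= 0.05))
  }
})

test_that("expert velocity shaping is more rectangular than novice", {
  res <- lapply(c("expert_like", "novice_like"), function(name) {
    sim <- simulate_trial(noise_free(name), n_cycles = 4, seed = 5)
    kin <- bow_kinematics(sim$trial)
    ss <- detect_strokes(kin$velocity, sim$trial$rate_hz)
    an <- select_analyzed(ss, rep(FALSE, nrow(kin)), 3)
    m <- trial_measures(kin, an)
    # normalize by squared amplitude so only the profile shape matters
    wv <- m$value[m$measure == "within_bow_var"]
    amp <- m$value[m$measure == "amplitude"]
    mean(wv) / mean(amp)^2
  })
  expect_lt(res[[1]], res[[2]])
})

test_that("programmed bow amplitude is recovered by the measures module", {
  sim <- simulate_trial(noise_free("novice_like"), n_cycles = 4, seed = 6)
  kin <- bow_kinematics(sim$trial)
  ss <- detect_strokes(kin$velocity, sim$trial$rate_hz)
  an <- select_analyzed(ss, rep(FALSE, nrow(kin)), 3)
  st <- an$strokes
  for (i in seq_len(nrow(st))) {
    measured <- measure_amplitude(kin$position, st$start[i], st$end[i])
    programmed <- diff(range(sim$truth$contact_mm[st$start[i]:st$end[i]]))
    expect_equal(measured, programmed, tolerance = 1e-9)
  }
})

test_that("sharper reversals produce larger reversal accelerations", {
  peak_for <- function(plateau) {
    prof <- noise_free("expert_like")
    prof$plateau <- plateau
    sim <- simulate_trial(prof, n_cycles = 4, seed = 7)
    kin <- bow_kinematics(sim$trial)
    ss <- detect_strokes(kin$velocity, sim$trial$rate_hz)
    an <- select_analyzed(ss, rep(FALSE, nrow(kin)), 3)
    m <- trial_measures(kin, an)
    mean(m$value[m$measure == "accel_amp"])
  }
  p0 <- peak_for(0)
  p5 <- peak_for(0.5)
  p8 <- peak_for(0.8)
  expect_lt(p0, p5)
  expect_lt(p5, p8)
})

test_that("injected angle noise is recovered by the angle-SD measure", {
  # wrist angle noise maps 1:1 onto bow-angle deviations (in degrees)
  prof <- coordination_profile(shoulder_amp = 0, plateau = 0,
                               joint_noise_sd = c(0, 0, 2 * pi / 180),
                               joint_noise_cutoff_hz = 8,
                               marker_noise_sd = 0)
  sim <- simulate_trial(prof, n_cycles = 10, seed = 8)
  kin <- bow_kinematics(sim$trial)
  sd_meas <- pop_sd(kin$angle_deg)
  expect_equal(sd_meas, 2, tolerance = 0.25)
})

test_that("the cohort generator reproduces the two-lab design", {
  cohort <- simulate_cohort(3, 4, seed = 2, n_cycles = 2)
  expect_length(cohort, 7)
  groups <- vapply(cohort, function(x) x$trial$meta$group, character(1))
  labs <- vapply(cohort, function(x) x$trial$meta$lab, character(1))
  rates <- vapply(cohort, function(x) x$trial$rate_hz, numeric(1))
  expect_equal(sum(groups == "expert"), 3)
  expect_true(all(rates[labs == "A"] == 120))
  expect_true(all(rates[labs == "B"] == 60))
  # deterministic under the master seed
  cohort2 <- simulate_cohort(3, 4, seed = 2, n_cycles = 2)
  expect_identical(cohort[[5]]$trial$positions,
                   cohort2[[5]]$trial$positions)
})
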