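test_that("bow angle follows the axis geometry", {
  expect_equal(bow_angle(c(0, 1, 0), c(1, 0, 0)), 90)
  expect_equal(bow_angle(c(1, 0, 0), c(2, 0, 0)), 0)
  # axes at 60 degrees by construction
  expect_equal(bow_angle(c(cos(pi / 3), sin(pi / 3), 0), c(1, 0, 0)), 60,
               tolerance = 1e-9)
})

test_that("the bowing coordinate tracks translation along the bow axis", {
  nf <- 20
  rate <- 60
  # bow translating purely along its own axis (+y) at 100 mm/frame
  prox <- matrix(rest_pose()$bow_proximal, nf, 3, byrow = TRUE)
  prox[, 2] <- prox[, 2] + 100 * (seq_len(nf) - 1)
  tip <- prox
  tip[, 2] <- tip[, 2] + 217
  tr <- make_static_trial(nf = nf, rate_hz = rate,
                          overrides = list(bow_proximal = prox,
                                           bow_tip = tip))
  kin <- bow_kinematics(tr)
  expect_true(all(kin$ok))
  # contact point is fixed in the lab, so the coordinate changes by -100/frame
  expect_equal(diff(kin$position), rep(-100, nf - 1), tolerance = 1e-9)
  interior <- 2:(nf - 1)
  expect_equal(kin$velocity[interior], rep(-100 * rate, nf - 2),
               tolerance = 1e-9)
  expect_equal(kin$angle_deg, rep(90, nf), tolerance = 1e-9)

  # stationary bow: zero velocity and acceleration
  st <- make_static_trial(nf = nf, rate_hz = rate)
  ks <- bow_kinematics(st)
  expect_equal(ks$velocity[interior], rep(0, nf - 2), tolerance = 1e-9)
  expect_equal(ks$acceleration[interior], rep(0, nf - 2), tolerance = 1e-9)

  # bow parallel to the string: contact point undefined, frame flagged
  par_tip <- matrix(rest_pose()$bow_proximal + c(217, 0, 0), nf, 3,
                    byrow = TRUE)
  pp <- make_static_trial(nf = nf, overrides = list(bow_tip = par_tip))
  kp <- bow_kinematics(pp)
  expect_false(any(kp$ok))
})

test_that("the bowing coordinate matches the generator's programmed contact", {
  sim <- simulate_trial(noise_free("expert_like"), n_cycles = 2, seed = 2)
  kin <- bow_kinematics(sim$trial)
  expect_lt(max(abs(kin$position - sim$truth$contact_mm)), 1e-6)
  expect_lt(max(abs(kin$angle_deg - sim$truth$angle_deg)), 1e-9)
})

test_that("stroke detection recovers sinusoidal strokes and filters durations", {
  rate <- 60
  t <- seq(0, 30, by = 1 / rate)
  v <- sin(2 * pi * t / 1.5)
  ss <- detect_strokes(v, rate)
  expect_gte(nrow(ss$strokes), 38)
  expect_lte(nrow(ss$strokes), 40)
  expect_true(all(abs(ss$strokes$duration_s - 0.75) <= 0.02))
  # strokes alternate direction
  expect_true(all(ss$strokes$direction[-1] != head(ss$strokes$direction, -1)))
  # 45-sample windows at 60 Hz
  expect_equal(ss$span, 45)
  expect_true(all(ss$reversals$wend - ss$reversals$wstart + 1 == 45))

  # constant velocity: no reversals, no strokes
  expect_equal(nrow(detect_strokes(rep(5, 600), rate)$strokes), 0)

  # an injected 0.4 s segment is rejected by the duration filter
  seg <- function(dur, s) s * sin(pi * seq(0, 1, length.out = round(dur * rate)))
  v2 <- c(seg(0.75, 1), seg(0.75, -1), seg(0.4, 1), seg(0.75, -1),
          seg(0.75, 1), seg(0.75, -1))
  ss2 <- detect_strokes(v2, rate)
  expect_true(all(ss2$strokes$duration_s >= 0.5))
  expect_false(any(abs(ss2$strokes$duration_s - 0.4) < 0.05))
})

test_that("analyzed-stroke selection skips contaminated strokes and promotes later ones", {
  sim <- simulate_trial(coordination_preset("novice_like"), seed = 13)
  tr <- preprocess_trial(sim$trial)
  kin <- bow_kinematics(tr)
  ss <- detect_strokes(kin$velocity, tr$rate_hz)
  bad <- rep(FALSE, nrow(kin))

  all_clean <- select_analyzed(ss, bad, n_per_dir = 10)
  expect_equal(sum(all_clean$strokes$direction == "up"), 10)
  expect_equal(sum(all_clean$strokes$direction == "down"), 10)

  # contaminate the 3rd up-bow: it must be skipped and a later one promoted
  ups <- ss$strokes[ss$strokes$direction == "up", ]
  bad[ups$start[3] + 5] <- TRUE
  sel <- select_analyzed(ss, bad, n_per_dir = 10)
  expect_equal(sum(sel$strokes$direction == "up"), 10)
  expect_false(ups$start[3] %in% sel$strokes$start)
  expect_true(ups$start[11] %in% sel$strokes$start)

  # everything contaminated: empty set with warnings for both directions
  w <- capture_warnings(empty <- select_analyzed(ss, rep(TRUE, nrow(kin))))
  expect_gte(length(w), 2)
  expect_equal(nrow(empty$strokes), 0)
})

test_that("central_fraction trims symmetrically with inward rounding", {
  # 45-frame stroke keeps 37 frames (~82%)
  r <- central_fraction(1, 45, 0.8)
  expect_equal(r, c(5, 41))
  expect_equal(r[2] - r[1] + 1, 37)
  expect_equal(central_fraction(10, 20, 1.0), c(10, 20))
  expect_error(central_fraction(1, 4), "too short")
})

test_that("performance measures match closed forms", {
  # amplitude: linear ramp and constant
  expect_equal(measure_amplitude(seq(0, 600, length.out = 50), 1, 50), 600)
  expect_equal(measure_amplitude(rep(3, 50), 1, 50), 0)

  # angle SD: constant angle and an alternating 89/91 sequence (pop SD 1)
  expect_equal(measure_angle_sd(rep(90, 50), 1, 50), 0)
  alt <- rep(c(89, 91), 25)
  expect_equal(measure_angle_sd(alt, 1, 50, fraction = 1), 1)

  # within-bow variance: rectangular profile is 0; half-sine of equal
  # amplitude is strictly larger (bell-shaped profiles score worse)
  n <- 100
  rect <- rep(300, n)
  half_sine <- 300 * sin(pi * seq(0, 1, length.out = n))
  expect_equal(measure_within_bow_var(rect, 1, n), 0)
  expect_gt(measure_within_bow_var(half_sine, 1, n),
            measure_within_bow_var(rect, 1, n))
  # closed form for the full half-sine: var = A^2 (1/2 - 4/pi^2)
  # (fine grid so discretization is negligible)
  hs_fine <- 300 * sin(pi * seq(0, 1, length.out = 2000))
  v <- measure_within_bow_var(hs_fine, 1, 2000, fraction = 1)
  expect_equal(v, 300^2 * (1 / 2 - 4 / pi^2), tolerance = 2e-3)

  # between-bow variance: identical strokes give 0; a +10 mm/s offset
  # between two strokes gives pop variance 25
  vel <- c(half_sine, half_sine + 10)
  strokes <- data.frame(start = c(1, n + 1), end = c(n, 2 * n))
  expect_equal(measure_between_bow_var(c(half_sine, half_sine), strokes), 0)
  expect_equal(measure_between_bow_var(vel, strokes), 25, tolerance = 1e-9)
  expect_error(measure_between_bow_var(vel, strokes[1, ]), "at least 2")

  # i.i.d. per-point noise: between-bow variance estimates sigma^2.
  # 124-frame strokes give a 100-frame central portion, so the resampling
  # grid coincides with the samples and no interpolation smoothing occurs.
  set.seed(77)
  m <- 40
  len <- 124
  base <- 300 * sin(pi * seq(0, 1, length.out = len))
  noisy <- as.vector(t(matrix(rep(base, m), m, len, byrow = TRUE) +
                         rnorm(m * len, 0, 5)))
  strokes_m <- data.frame(start = (0:(m - 1)) * len + 1, end = (1:m) * len)
  bv <- measure_between_bow_var(noisy, strokes_m)
  expect_gt(bv, 25 * 0.8)
  expect_lt(bv, 25 * 1.25)
})

test_that("reversal acceleration amplitude matches the analytic derivative", {
  rate <- 600  # fine grid so the discrete peak sits on the analytic one
  T_ <- 1.5
  V <- 400
  t <- seq(0, 3, by = 1 / rate)
  pos <- -V * T_ / (2 * pi) * sin(2 * pi * t / T_)  # velocity = -V cos(...)
  acc <- central_diff(central_diff(pos, rate, 1), rate, 1)
  # reversal (velocity zero) at t = T/4
  cen <- which.min(abs(t - T_ / 4))
  w <- c(cen - 20, cen + 20)
  peak <- measure_accel_amplitude(acc, w[1], w[2])
  expect_equal(peak, V * 2 * pi / T_, tolerance = 1e-3)
  # static bow: zero
  expect_equal(measure_accel_amplitude(rep(0, 100), 10, 50), 0)
  # peak-to-peak mode is the max - min range
  expect_equal(measure_accel_amplitude(c(-3, 4, 1), 1, 3, "peak_to_peak"), 7)
})

test_that("measures are invariant under global rigid transforms and scale correctly", {
  set.seed(21)
  sim <- simulate_trial(noise_free("expert_like"), n_cycles = 3, seed = 14)
  tr <- sim$trial
  kin <- bow_kinematics(tr)
  ss <- detect_strokes(kin$velocity, tr$rate_hz)
  an <- suppressWarnings(select_analyzed(ss, rep(FALSE, nrow(kin)), 2))
  m0 <- trial_measures(kin, an)

  tr2 <- apply_rigid(tr, random_rotation(), c(-500, 200, 900))
  m1 <- trial_measures(bow_kinematics(tr2), an)
  expect_equal(m1$value, m0$value, tolerance = 1e-6)

  # uniform spatial scaling: amplitudes linear, variances quadratic
  tr3 <- tr
  tr3$positions <- tr3$positions * 2
  m2 <- trial_measures(bow_kinematics(tr3), an)
  amp0 <- m0$value[m0$measure == "amplitude"]
  amp2 <- m2$value[m2$measure == "amplitude"]
  expect_equal(amp2, 2 * amp0, tolerance = 1e-6)
  wv0 <- m0$value[m0$measure == "within_bow_var"]
  wv2 <- m2$value[m2$measure == "within_bow_var"]
  expect_equal(wv2, 4 * wv0, tolerance = 1e-6)
  aa0 <- m0$value[m0$measure == "accel_amp"]
  aa2 <- m2$value[m2$measure == "accel_amp"]
  expect_equal(aa2, 2 * aa0, tolerance = 1e-6)
})
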