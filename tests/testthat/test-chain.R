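test_that("gram_schmidt_frame builds right-handed orthonormal bases", {
  expect_equal(gram_schmidt_frame(c(1, 0, 0), c(0, 1, 0)), diag(3))
  expect_error(gram_schmidt_frame(c(1, 0, 0), c(2, 0, 0)), "collinear")
  expect_error(gram_schmidt_frame(c(0, 0, 0), c(1, 0, 0)), "zero")

  B <- gram_schmidt_frame(c(1, 1, 0), c(0, 3, 0))
  expect_equal(crossprod(B), diag(3), tolerance = 1e-12)
  expect_equal(det(B), 1, tolerance = 1e-12)
  expect_equal(B[, 1], c(1, 1, 0) / sqrt(2), tolerance = 1e-12)

  # property: random valid vector pairs always give orthonormal det=+1 bases
  set.seed(31)
  for (i in 1:25) {
    B <- gram_schmidt_frame(rnorm(3), rnorm(3))
    expect_equal(crossprod(B), diag(3), tolerance = 1e-9)
    expect_equal(det(B), 1, tolerance = 1e-9)
  }
})

test_that("joint-center estimation approximates the generator's true centers", {
  prof <- noise_free("novice_like")
  with_centers <- simulate_trial(prof, n_cycles = 2, seed = 9)
  without <- simulate_trial(prof, n_cycles = 2, seed = 9,
                            emit_joint_centers = FALSE)
  anthro <- anthropometrics()
  est <- estimate_joint_centers(without$trial, anthro)

  for (role in c("elbow_jc", "wrist_jc")) {
    err <- row_norms(get_marker(est, role) -
                       get_marker(with_centers$trial, role))
    # recovered centers lie within the anthropometric offset scale
    expect_lt(max(err), anthro$elbow_width_mm)
  }
  # shoulder default: the acromion itself
  expect_equal(get_marker(est, "shoulder_jc"),
               get_marker(est, "acromion"), tolerance = 1e-12)

  # a second offsetting pass must refuse
  expect_error(estimate_joint_centers(est, anthro), "already present")
  expect_error(anthropometrics(elbow_width_mm = 0), "positive")
})

test_that("decompose/reconstruct round-trips markers exactly", {
  sim <- simulate_trial(coordination_preset("expert_like"), n_cycles = 3,
                        seed = 3)
  tr <- sim$trial
  rec <- reconstruct(decompose(tr))
  expect_lt(max(abs(rec$positions - tr$positions)), 1e-6)
  expect_identical(rec$labels, tr$labels)

  # a static chain reconstructs static markers
  prof <- noise_free("novice_like")
  prof$shoulder_amp <- 0
  st <- simulate_trial(prof, n_cycles = 2, seed = 1)$trial
  ch <- decompose(st)
  expect_lt(max(abs(sweep(ch$shoulder$t, 2, ch$shoulder$t[1, ]))), 1e-9)
  expect_lt(max(abs(ch$shoulder$R - array(ch$shoulder$R[, , 1],
                                          dim(ch$shoulder$R)))), 1e-9)
})

test_that("joint motions are invariant under global rigid transforms", {
  set.seed(12)
  sim <- simulate_trial(noise_free("expert_like"), n_cycles = 2, seed = 8)
  tr <- sim$trial
  ch0 <- decompose(tr)

  # vertical-preserving transform (rotation about gravity + translation):
  # every joint motion is invariant, only the root pose changes. The
  # scapula frame references the global vertical, so this is the full
  # invariance class.
  a <- runif(1, 0, 2 * pi)
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ch1 <- decompose(apply_rigid(tr, Rz, c(250, -80, 1200)))
  for (j in c("shoulder", "elbow", "wrist", "hand_to_bow")) {
    expect_lt(max(abs(ch0[[j]]$R - ch1[[j]]$R)), 1e-9)
    expect_lt(max(abs(ch0[[j]]$t - ch1[[j]]$t)), 1e-6)
  }
  expect_gt(max(abs(ch0$root$t - ch1$root$t)), 100)

  # under an arbitrary rotation the vertical reference moves, which can
  # only affect the scapula frame (hence the shoulder joint): all joints
  # distal to it remain invariant
  ch2 <- decompose(apply_rigid(tr, random_rotation(), c(10, 20, 30)))
  for (j in c("elbow", "wrist", "hand_to_bow")) {
    expect_lt(max(abs(ch0[[j]]$R - ch2[[j]]$R)), 1e-9)
    expect_lt(max(abs(ch0[[j]]$t - ch2[[j]]$t)), 1e-6)
  }
})

test_that("decomposition recovers the programmed joint rotations", {
  sim <- simulate_trial(noise_free("novice_like"), n_cycles = 3, seed = 4)
  ch <- decompose(sim$trial)
  nf <- dim(ch$shoulder$R)[3]
  recovered <- vapply(seq_len(nf), function(i) {
    rotation_angle(ch$shoulder$R[, , i] %*% t(ch$shoulder$R[, , 1]))
  }, numeric(1))
  programmed <- abs(sim$truth$theta$shoulder - sim$truth$theta$shoulder[1])
  expect_lt(max(abs(recovered - programmed)), 1e-6)

  # distal joints were programmed constant and decompose as constant
  for (j in c("elbow", "wrist")) {
    expect_lt(max(abs(ch[[j]]$R - array(ch[[j]]$R[, , 1], dim(ch[[j]]$R)))),
              1e-9)
    expect_lt(max(abs(sweep(ch[[j]]$t, 2, ch[[j]]$t[1, ]))), 1e-9)
  }
})

test_that("shoulder-only motion moves bow markers on circles about the axis", {
  sim <- simulate_trial(noise_free("novice_like"), n_cycles = 2, seed = 6)
  tip <- get_marker(sim$trial, "bow_tip")
  # rotation is about the vertical through the shoulder: planar radius constant
  r <- sqrt(tip[, 1]^2 + tip[, 2]^2)
  expect_lt(max(r) - min(r), 1e-6)
  expect_lt(max(tip[, 3]) - min(tip[, 3]), 1e-9)
})

test_that("degenerate (collinear) segment constructions flag frames as bad", {
  nf <- 5
  line <- function(p) matrix(p, nf, 3, byrow = TRUE)
  tr <- make_static_trial(nf = nf, extra = list(
    shoulder_jc = line(c(0, 0, 0)),
    elbow_jc = line(c(100, 0, 0)),    # collinear with shoulder and wrist:
    wrist_jc = line(c(200, 0, 0)),    # upper-arm secondary axis vanishes
    hand_ref = line(c(260, 10, -10))))
  ch <- decompose(tr)
  expect_true(all(ch$bad))
})

test_that("chain audit export round-trips the joint poses", {
  sim <- simulate_trial(coordination_preset("novice_like"), n_cycles = 2,
                        seed = 10)
  ch <- decompose(sim$trial)
  path <- tempfile(fileext = ".tsv")
  write_chain(ch, path)
  back <- read_chain(path)
  for (p in c("root", "shoulder", "elbow", "wrist", "hand_to_bow")) {
    expect_lt(max(abs(back[[p]]$R - ch[[p]]$R)), 1e-9)
    expect_lt(max(abs(back[[p]]$t - ch[[p]]$t)), 1e-9)
  }
})
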