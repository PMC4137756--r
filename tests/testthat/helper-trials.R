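# Shared fixture builders: all fixtures are constructed in code.

# a static, geometrically valid rest pose covering all 14 marker roles (mm)
rest_pose <- function() {
  list(sternum = c(-180, 100, -150),
       c7 = c(-160, -40, 20),
       acromion = c(0, 0, 0),
       elbow_lateral = c(125, 170, -200),
       lowerarm = c(230, 230, -160),
       wrist_radial = c(381, 215, -130),
       wrist_ulnar = c(376, 230, -182),
       mcp1 = c(455, 253, -162),
       pip1 = c(488, 264, -166),
       cello_scroll = c(5, 150, -217),
       cello_tailpiece = c(905, 150, -217),
       cello_body = c(455, 150, -350),
       bow_tip = c(455, 510, -197),
       bow_proximal = c(455, 293, -197))
}

# trial with every role static except explicit per-frame overrides
# (overrides: named list of nf x 3 matrices)
make_static_trial <- function(nf = 10, rate_hz = 60, overrides = list(),
                              extra = list(), meta = list()) {
  pose <- rest_pose()
  markers <- lapply(pose, function(p) matrix(p, nf, 3, byrow = TRUE))
  for (nm in names(overrides)) markers[[nm]] <- overrides[[nm]]
  for (nm in names(extra)) markers[[nm]] <- extra[[nm]]
  labels <- names(markers)
  pos <- array(NA_real_, c(nf, length(labels), 3))
  for (j in seq_along(labels)) pos[, j, ] <- markers[[j]]
  trial_recording(pos, rate_hz, labels, stats::setNames(labels, labels),
                  meta = meta)
}

# noise-free variant of a preset profile
noise_free <- function(name) {
  prof <- coordination_preset(name)
  prof$marker_noise_sd <- 0
  prof$joint_noise_sd[] <- 0
  prof
}

# random rigid transform (rotation + translation) applied to a whole trial
apply_rigid <- function(trial, R, t) {
  nf <- dim(trial$positions)[1]
  for (m in seq_len(dim(trial$positions)[2])) {
    xyz <- trial$positions[, m, ]
    trial$positions[, m, ] <- xyz %*% t(R) + matrix(t, nf, 3, byrow = TRUE)
  }
  trial
}

random_rotation <- function() {
  a <- stats::rnorm(3)
  b <- stats::rnorm(3)
  gram_schmidt_frame(a, b)
}
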