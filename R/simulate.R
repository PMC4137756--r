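# Joint-space synthetic bowing generator. Markers are synthesized through
# the same forward model the analysis inverts, so decomposition,
# reconstruction and freezing have exact ground truth.

# fixed adult-scale geometry (mm): a 4-segment right arm with the trunk
# (scapula) static, plus a bow held rigidly in the hand and a static cello.
# Transport rotations are about the lab vertical (+Z), so the arm sweeps the
# bow horizontally along its own axis across a horizontal string.
sim_geometry <- function() {
  u0 <- 300 * unitize(c(0.35, 0.65, -0.67))   # shoulder -> elbow, rest
  f0 <- 280 * unitize(c(0.85, 0.10, 0.15))    # elbow -> wrist, rest
  h0 <- 80 * unitize(c(0.90, 0.30, -0.10))    # wrist -> mcp1, rest
  shoulder <- c(0, 0, 0)
  elbow0 <- shoulder + u0
  wrist0 <- elbow0 + f0
  mcp0 <- wrist0 + h0
  bow_prox_off <- h0 + c(0, 40, -35)          # in hand frame (rest pose)
  bow_dir0 <- c(0, 1, 0)                      # bow long axis at rest
  bow_marker_sep <- 217                       # proximal marker -> tip (mm)
  prox0 <- wrist0 + bow_prox_off
  string_z <- prox0[3] - 20                   # string passes 20 mm under bow
  string_y <- 150
  list(shoulder = shoulder, u0 = u0, f0 = f0, h0 = h0,
       sternum = c(-180, 100, -150), c7 = c(-160, -40, 20),
       elbow_lat_off = 35 * unitize(cross3(unitize(u0), c(0, 0, 1))),
       lowerarm_off = 0.5 * f0 + c(-10, 25, 20),
       # wrist marker line parallel to the rotation axis, so it is rigid in
       # both forearm and hand frames and the marker-derived hand LCS is
       # exactly rigid with the hand (and the bow it holds)
       wrist_half = 25 * c(0, 0, 1),
       pip_scale = 115 / 80,                  # pip1 along the finger axis
       hand_ref_off = h0 + c(5, 10, -15),
       bow_prox_off = bow_prox_off, bow_dir0 = bow_dir0,
       bow_marker_sep = bow_marker_sep,
       cello_scroll = c(prox0[1] - 450, string_y, string_z),
       cello_tailpiece = c(prox0[1] + 450, string_y, string_z),
       cello_body = c(prox0[1], string_y, string_z - 130))
}

#' Inter-joint coordination profile for the generator
#'
#' Parameterizes the joint-angle programs of a simulated bowing trial.
#' Transport is a shared periodic waveform (0.75 s per bow by default) whose
#' velocity shape interpolates between sinusoidal (`plateau = 0`,
#' bell-shaped, point-to-point-like) and rectangular with sharp reversals
#' (`plateau` near 1, the expert hallmark). Each joint rotates about the
#' vertical with its own amplitude and phase; in `"compensatory"` coupling
#' the wrist additionally counter-rotates against the summed shoulder+elbow
#' rotation — `angle_compensation_gain` cancels the bow-angle deviation the
#' proximal transport would otherwise cause (and thereby brakes transport:
#' the counter-movement), and `wrist_counter_gain` adds pure extra braking.
#' Smooth independent per-joint angle noise and i.i.d. Gaussian marker noise
#' complete the model.
#'
#' @param shoulder_amp,elbow_amp,wrist_amp transport rotation amplitudes
#'   (rad) about the vertical.
#' @param shoulder_phase,elbow_phase,wrist_phase waveform phases (rad).
#' @param plateau velocity plateau fraction in [0, 0.95]: fraction of each
#'   stroke spent above 90% of peak speed.
#' @param angle_compensation_gain in [0, 1]: fraction of the proximal
#'   rotation the wrist cancels (compensatory coupling only).
#' @param wrist_counter_gain extra wrist counter-rotation gain.
#' @param joint_noise_sd SD (rad) of smooth independent angle noise; either
#'   a single value for all joints or a length-3 vector (shoulder, elbow,
#'   wrist). The bow-transport lever shrinks from proximal to distal, so
#'   distal-dominant noise perturbs bow angle much more than bow velocity.
#' @param joint_noise_cutoff_hz low-pass cutoff of the angle noise (Hz).
#' @param marker_noise_sd i.i.d. Gaussian marker noise SD per coordinate
#'   (mm); 0.5 is motion-capture-realistic.
#' @param coupling_mode `"independent"` (wrist follows its own program) or
#'   `"compensatory"` (wrist counter-rotates against shoulder+elbow).
#' @return an object of class `coordination_profile`.
#' @export
coordination_profile <- function(shoulder_amp = 0, elbow_amp = 0,
                                 wrist_amp = 0,
                                 shoulder_phase = 0, elbow_phase = 0,
                                 wrist_phase = 0,
                                 plateau = 0,
                                 angle_compensation_gain = 0,
                                 wrist_counter_gain = 0,
                                 joint_noise_sd = 0,
                                 joint_noise_cutoff_hz = 5,
                                 marker_noise_sd = 0.5,
                                 coupling_mode = c("independent",
                                                   "compensatory")) {
  coupling_mode <- match.arg(coupling_mode)
  if (min(shoulder_amp, elbow_amp, wrist_amp) < 0) {
    stop("rotation amplitudes must be >= 0")
  }
  if (plateau < 0 || plateau >= 1) stop("plateau must lie in [0, 1)")
  if (angle_compensation_gain < 0 || angle_compensation_gain > 1) {
    stop("angle_compensation_gain must lie in [0, 1]")
  }
  if (any(joint_noise_sd < 0) || marker_noise_sd < 0) {
    stop("noise SDs must be >= 0")
  }
  if (!length(joint_noise_sd) %in% c(1, 3)) {
    stop("joint_noise_sd must have length 1 or 3 (shoulder, elbow, wrist)")
  }
  joint_noise_sd <- rep(joint_noise_sd, length.out = 3)
  names(joint_noise_sd) <- c("shoulder", "elbow", "wrist")
  structure(list(shoulder_amp = shoulder_amp, elbow_amp = elbow_amp,
                 wrist_amp = wrist_amp,
                 shoulder_phase = shoulder_phase, elbow_phase = elbow_phase,
                 wrist_phase = wrist_phase,
                 plateau = plateau,
                 angle_compensation_gain = angle_compensation_gain,
                 wrist_counter_gain = wrist_counter_gain,
                 joint_noise_sd = joint_noise_sd,
                 joint_noise_cutoff_hz = joint_noise_cutoff_hz,
                 marker_noise_sd = marker_noise_sd,
                 coupling_mode = coupling_mode),
            class = "coordination_profile")
}

#' Named coordination presets
#'
#' Documented parameterizations of the generator:
#' * `expert_like`: shoulder and elbow share transport in phase with a
#'   rectangular velocity profile (plateau 0.8, sharp reversals); the wrist
#'   cancels 90% of the proximal rotation (stabilizing bow angle) plus a
#'   small extra counter-movement, so freezing the wrist increases both
#'   transport amplitude and bow-angle variability.
#' * `novice_like`: shoulder-only sinusoidal transport (bell-shaped
#'   velocity), no compensation, nearly rigid distal joints.
#' * `independent_noise`: shoulder transport plus mutually independent
#'   smooth angle noise at every joint — the no-coordination null, under
#'   which freezing a joint can only remove variance.
#' * `compensatory`: shoulder transport with the wrist cancelling 90% of
#'   the bow-angle deviation, so freezing the wrist removes coordination
#'   and increases angle variability.
#'
#' @param name preset name.
#' @return a `coordination_profile`.
#' @export
coordination_preset <- function(name = c("expert_like", "novice_like",
                                         "independent_noise",
                                         "compensatory")) {
  name <- match.arg(name)
  switch(name,
    expert_like = coordination_profile(
      shoulder_amp = 0.28, elbow_amp = 0.28, plateau = 0.8,
      angle_compensation_gain = 0.9, wrist_counter_gain = 0.05,
      joint_noise_sd = 0.01, marker_noise_sd = 0.5,
      coupling_mode = "compensatory"),
    novice_like = coordination_profile(
      shoulder_amp = 0.25, plateau = 0,
      joint_noise_sd = 0.005, marker_noise_sd = 0.5,
      coupling_mode = "independent"),
    independent_noise = coordination_profile(
      shoulder_amp = 0.15, plateau = 0,
      joint_noise_sd = c(0.01, 0.02, 0.12), joint_noise_cutoff_hz = 2.5,
      marker_noise_sd = 0.5,
      coupling_mode = "independent"),
    compensatory = coordination_profile(
      shoulder_amp = 0.25, plateau = 0,
      angle_compensation_gain = 0.9,
      joint_noise_sd = c(0.01, 0.01, 0.02), joint_noise_cutoff_hz = 2,
      marker_noise_sd = 0.5,
      coupling_mode = "compensatory"))
}

# solve the velocity-shape parameter k of v ~ tanh(sin(w t)/k)/tanh(1/k)
# such that |v| >= 0.9 * peak for the requested fraction of each stroke
plateau_to_k <- function(plateau) {
  if (plateau <= 0) return(Inf)
  target <- cos(pi * plateau / 2)
  f <- function(k) k * atanh(0.9 * tanh(1 / k)) - target
  stats::uniroot(f, c(1e-4, 50), tol = 1e-12)$root
}

# transport waveform: position-like G(t) in [-1, 1] and its raw velocity
# shape; one full cycle = one up-bow + one down-bow
transport_wave <- function(t, period_s, plateau, phase = 0) {
  w <- 2 * pi / period_s
  k <- plateau_to_k(plateau)
  v <- if (is.infinite(k)) sin(w * t + phase) else
    tanh(sin(w * t + phase) / k) / tanh(1 / k)
  dt <- t[2] - t[1]
  g <- cumsum(v) * dt
  g <- g - mean(g)
  g / max(abs(g))
}

# smooth zero-mean angle noise: low-passed white noise rescaled to sd
smooth_noise <- function(n, rate_hz, sd, cutoff_hz) {
  if (sd <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  bf <- signal::butter(2, min(0.99, cutoff_hz / (rate_hz / 2)), type = "low")
  y <- filtfilt_refl(x, bf$b, bf$a)
  y <- y - mean(y)
  y * sd / stats::sd(y)
}

rot_z_apply <- function(theta, v) {
  cbind(cos(theta) * v[1] - sin(theta) * v[2],
        sin(theta) * v[1] + cos(theta) * v[2],
        rep(v[3], length(theta)))
}

#' Simulate a marker-level bowing trial
#'
#' Generates a complete trial of metronome-paced bowing (default 20 cycles
#' of 1.5 s, i.e. 0.75 s per bow) from a [coordination_profile()]: joint
#' rotations about the vertical at shoulder, elbow and wrist drive a
#' 4-segment arm (upper arm 300 mm, lower arm 280 mm, hand 80 mm) holding a
#' bow rigidly, sweeping it along its own axis across a static string; all
#' 14 marker roles are emitted, plus (by default) the exact joint centers as
#' virtual markers, with i.i.d. Gaussian marker noise on the physical
#' markers. The returned ground truth carries the programmed joint angles,
#' the noise-free bow contact trajectory and bow angle.
#'
#' @param profile a `coordination_profile`.
#' @param n_cycles number of bowing cycles.
#' @param rate_hz sampling rate (60 or 120 Hz in the emulated labs).
#' @param bow_period_s duration of one full cycle (up + down bow), s.
#' @param seed RNG seed; a fixed seed makes the trial bit-identical across
#'   runs.
#' @param emit_joint_centers if `TRUE`, the true joint centers are included
#'   as noise-free virtual markers; if `FALSE`, only the 14 physical
#'   markers are emitted and [estimate_joint_centers()] must be used.
#' @param meta trial metadata (participant_id, group, lab).
#' @param contact_tolerance_mm simulation sanity bound: maximal admissible
#'   distance between bow axis and string axis.
#' @return list with `trial` (a `trial_recording`) and `truth` (programmed
#'   joint angles, hand orientation, true contact coordinate and bow angle,
#'   profile and seed).
#' @export
simulate_trial <- function(profile, n_cycles = 20, rate_hz = 60,
                           bow_period_s = 1.5, seed = NULL,
                           emit_joint_centers = TRUE,
                           meta = list(participant_id = "sim",
                                       group = "novice", lab = "A"),
                           contact_tolerance_mm = 60) {
  stopifnot(inherits(profile, "coordination_profile"))
  if (!is.null(seed)) set.seed(seed)
  geo <- sim_geometry()
  nf <- as.integer(round(n_cycles * bow_period_s * rate_hz))
  t <- (seq_len(nf) - 1) / rate_hz

  g_s <- transport_wave(t, bow_period_s, profile$plateau,
                        profile$shoulder_phase)
  g_e <- transport_wave(t, bow_period_s, profile$plateau,
                        profile$elbow_phase)
  g_w <- transport_wave(t, bow_period_s, profile$plateau,
                        profile$wrist_phase)
  n_s <- smooth_noise(nf, rate_hz, profile$joint_noise_sd[["shoulder"]],
                      profile$joint_noise_cutoff_hz)
  n_e <- smooth_noise(nf, rate_hz, profile$joint_noise_sd[["elbow"]],
                      profile$joint_noise_cutoff_hz)
  n_w <- smooth_noise(nf, rate_hz, profile$joint_noise_sd[["wrist"]],
                      profile$joint_noise_cutoff_hz)

  theta_s <- profile$shoulder_amp * g_s + n_s
  theta_e <- profile$elbow_amp * g_e + n_e
  tau <- theta_s + theta_e
  theta_w <- if (profile$coupling_mode == "compensatory") {
    -(profile$angle_compensation_gain + profile$wrist_counter_gain) * tau +
      profile$wrist_amp * g_w + n_w
  } else {
    profile$wrist_amp * g_w + n_w
  }
  psi <- tau + theta_w   # hand (and bow) orientation about the vertical

  S <- geo$shoulder
  E <- matrix(S, nf, 3, byrow = TRUE) + rot_z_apply(theta_s, geo$u0)
  W <- E + rot_z_apply(tau, geo$f0)
  mcp <- W + rot_z_apply(psi, geo$h0)
  pip <- W + rot_z_apply(psi, geo$h0 * geo$pip_scale)
  hand_ref <- W + rot_z_apply(psi, geo$hand_ref_off)
  elbow_lat <- E + rot_z_apply(theta_s, geo$elbow_lat_off)
  lowerarm <- E + rot_z_apply(tau, geo$lowerarm_off)
  wrist_r <- W + rot_z_apply(tau, geo$wrist_half)
  wrist_u <- W + rot_z_apply(tau, -geo$wrist_half)
  bow_prox <- W + rot_z_apply(psi, geo$bow_prox_off)
  bow_tip <- W + rot_z_apply(psi, geo$bow_prox_off +
                               geo$bow_marker_sep * geo$bow_dir0)

  static <- function(p) matrix(p, nf, 3, byrow = TRUE)
  markers <- list(sternum = static(geo$sternum),
                  c7 = static(geo$c7),
                  acromion = static(S),
                  elbow_lateral = elbow_lat,
                  lowerarm = lowerarm,
                  wrist_radial = wrist_r,
                  wrist_ulnar = wrist_u,
                  mcp1 = mcp,
                  pip1 = pip,
                  cello_scroll = static(geo$cello_scroll),
                  cello_tailpiece = static(geo$cello_tailpiece),
                  cello_body = static(geo$cello_body),
                  bow_tip = bow_tip,
                  bow_proximal = bow_prox)

  # ground truth from the noise-free geometry
  us <- matrix(unitize(geo$cello_tailpiece - geo$cello_scroll), nf, 3,
               byrow = TRUE)
  ub <- rot_z_apply(psi, geo$bow_dir0)
  contact <- line_contact_coordinate(static(geo$cello_scroll), us,
                                     bow_prox, ub)
  angle_true <- acos(pmin(1, pmax(-1, rowSums(ub * us)))) * 180 / pi
  # distance between bow axis and string axis (self-consistency guard)
  nvec <- row_cross(us, ub)
  gapd <- abs(rowSums((bow_prox - static(geo$cello_scroll)) * nvec)) /
    row_norms(nvec)
  if (any(is.finite(gapd) & gapd > contact_tolerance_mm)) {
    stop("simulation error: bow leaves the string-axis vicinity (",
         round(max(gapd), 1), " mm)")
  }

  if (profile$marker_noise_sd > 0) {
    for (m in names(markers)) {
      markers[[m]] <- markers[[m]] +
        matrix(stats::rnorm(nf * 3, 0, profile$marker_noise_sd), nf, 3)
    }
  }
  if (emit_joint_centers) {
    markers$shoulder_jc <- static(S)
    markers$elbow_jc <- E
    markers$wrist_jc <- W
    markers$hand_ref <- hand_ref
  }

  labels <- names(markers)
  pos <- array(NA_real_, c(nf, length(labels), 3))
  for (j in seq_along(labels)) pos[, j, ] <- markers[[j]]
  trial <- trial_recording(pos, rate_hz, labels,
                           stats::setNames(labels, labels),
                           meta = meta)
  truth <- list(t_s = t,
                theta = data.frame(shoulder = theta_s, elbow = theta_e,
                                   wrist = theta_w),
                psi = psi,
                contact_mm = contact,
                angle_deg = angle_true,
                profile = profile,
                seed = seed,
                rate_hz = rate_hz)
  list(trial = trial, truth = truth)
}

#' Simulate a two-group, two-lab cohort
#'
#' Emulates the study design: experts and novices split across two labs
#' (lab A records at 120 Hz, lab B at 60 Hz; the default counts follow the
#' 8/12 split with 2 experts + 6 novices in A and 8 experts + 4 novices in
#' B). Participant-level variation jitters the preset amplitudes
#' (multiplicative log-normal, 8% SD); each participant gets a
#' deterministic sub-seed from `seed`.
#'
#' @param n_expert,n_novice group sizes.
#' @param seed cohort master seed.
#' @param n_cycles bowing cycles per trial.
#' @param expert_profile,novice_profile base profiles.
#' @param amp_jitter_sd SD of the log-normal amplitude jitter.
#' @return list of `simulate_trial()` results (fields `trial`, `truth`).
#' @export
simulate_cohort <- function(n_expert = 10, n_novice = 10, seed = 1,
                            n_cycles = 20,
                            expert_profile = coordination_preset("expert_like"),
                            novice_profile = coordination_preset("novice_like"),
                            amp_jitter_sd = 0.08) {
  set.seed(seed)
  n <- n_expert + n_novice
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- c(rep("expert", n_expert), rep("novice", n_novice))
  labs <- c(rep("A", min(2, n_expert)),
            rep("B", max(0, n_expert - 2)),
            rep("A", min(6, n_novice)),
            rep("B", max(0, n_novice - 6)))
  jit <- exp(stats::rnorm(n, 0, amp_jitter_sd))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- if (groups[i] == "expert") expert_profile else novice_profile
    prof$shoulder_amp <- prof$shoulder_amp * jit[i]
    prof$elbow_amp <- prof$elbow_amp * jit[i]
    rate <- if (labs[i] == "A") 120 else 60
    out[[i]] <- simulate_trial(prof, n_cycles = n_cycles, rate_hz = rate,
                               seed = sub_seeds[i],
                               meta = list(participant_id = sprintf("P%02d", i),
                                           group = groups[i], lab = labs[i]))
  }
  out
}
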