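# Virtual joint centers, segment coordinate systems, and the rigid-body
# decomposition/reconstruction of the marker data.

#' Estimate virtual joint-center markers
#'
#' Adds approximate joint centers as virtual markers, offsetting surface
#' markers by half the corresponding anthropometric thickness:
#' * `shoulder_jc`: the acromion, lowered along -Z by `shoulder_offset_mm`
#'   (default 0, i.e. the acromion itself);
#' * `elbow_jc`: the lateral epicondyle marker offset by half the elbow
#'   width along the local medial direction (the component of the vector
#'   toward the sternum orthogonal to the upper-arm long axis);
#' * `wrist_jc`: the midpoint of the radial/ulnar wrist markers offset by
#'   half the wrist width along the palmar-normal estimate (cross product of
#'   the forearm axis with the wrist marker line);
#' * `hand_ref`: the first metacarpophalangeal marker offset by half the
#'   hand thickness along the same palmar normal.
#'
#' The offset constructions are approximations exposed through the
#' arguments; the synthetic generator can alternatively emit exact centers.
#'
#' @param trial a `trial_recording` without virtual roles.
#' @param anthro an [anthropometrics()] object.
#' @param shoulder_offset_mm downward offset of the shoulder center from the
#'   acromion (mm).
#' @param palmar_sign +1 or -1, fixing the sign convention of the palmar
#'   normal.
#' @return the trial with four additional virtual markers and updated roles.
#' @export
estimate_joint_centers <- function(trial, anthro = anthropometrics(),
                                   shoulder_offset_mm = 0, palmar_sign = 1) {
  stopifnot(inherits(trial, "trial_recording"),
            inherits(anthro, "anthropometrics"))
  present <- intersect(virtual_roles(), names(trial$roles))
  if (length(present) > 0) {
    stop("virtual roles already present: ", paste(present, collapse = ", "))
  }
  acr <- get_marker(trial, "acromion")
  stern <- get_marker(trial, "sternum")
  elb <- get_marker(trial, "elbow_lateral")
  wr <- get_marker(trial, "wrist_radial")
  wu <- get_marker(trial, "wrist_ulnar")
  mcp <- get_marker(trial, "mcp1")

  shoulder_jc <- acr
  shoulder_jc[, 3] <- shoulder_jc[, 3] - shoulder_offset_mm

  u_axis <- elb - shoulder_jc
  u_axis <- u_axis / row_norms(u_axis)
  toward_trunk <- stern - elb
  medial <- toward_trunk - rowSums(toward_trunk * u_axis) * u_axis
  medial <- medial / row_norms(medial)
  elbow_jc <- elb + (anthro$elbow_width_mm / 2) * medial

  wrist_mid <- (wr + wu) / 2
  forearm <- wrist_mid - elbow_jc
  forearm <- forearm / row_norms(forearm)
  wline <- wu - wr
  wline <- wline / row_norms(wline)
  palmar <- row_cross(forearm, wline)
  palmar <- palmar_sign * palmar / row_norms(palmar)
  wrist_jc <- wrist_mid + (anthro$wrist_width_mm / 2) * palmar
  hand_ref <- mcp + (anthro$hand_thickness_mm / 2) * palmar

  add_virtual_markers(trial, list(shoulder_jc = shoulder_jc,
                                  elbow_jc = elbow_jc,
                                  wrist_jc = wrist_jc,
                                  hand_ref = hand_ref))
}

# append virtual markers (named list of T x 3 matrices) to a trial
add_virtual_markers <- function(trial, centers) {
  nf <- n_frames(trial)
  nm <- dim(trial$positions)[2]
  kk <- length(centers)
  pos <- array(NA_real_, c(nf, nm + kk, 3))
  pos[, seq_len(nm), ] <- trial$positions
  miss <- cbind(trial$missing, matrix(FALSE, nf, kk))
  src_miss <- apply(trial$missing[, match(trial$roles[marker_model()],
                                          trial$labels), drop = FALSE],
                    1, any)
  for (j in seq_len(kk)) {
    pos[, nm + j, ] <- centers[[j]]
    miss[, nm + j] <- src_miss | apply(!is.finite(centers[[j]]), 1, any)
    if (any(miss[, nm + j])) pos[miss[, nm + j], nm + j, ] <- NA_real_
  }
  labels <- c(trial$labels, names(centers))
  roles <- c(trial$roles, stats::setNames(names(centers), names(centers)))
  trial_recording(pos, trial$rate_hz, labels, roles, miss, trial$meta)
}

# marker ownership along the chain (roles; anything else lives in the lab
# frame, notably the cello markers)
segment_roles <- function() {
  list(scapula = c("sternum", "c7", "acromion", "shoulder_jc"),
       upper_arm = c("elbow_lateral", "elbow_jc"),
       lower_arm = c("lowerarm", "wrist_radial", "wrist_ulnar", "wrist_jc"),
       hand = c("mcp1", "pip1", "hand_ref"),
       bow = c("bow_tip", "bow_proximal"))
}

#' Build per-frame segment coordinate systems
#'
#' Constructs the five local coordinate systems (scapula, upper arm, lower
#' arm, hand, bow) frame by frame via [gram_schmidt_frame()] on the segment
#' definition vectors:
#' * scapula: primary sternum -> shoulder center, secondary = global
#'   vertical x primary; origin shoulder center;
#' * upper arm: primary shoulder -> elbow center, secondary = primary x
#'   lower-arm primary (requires a flexed elbow); origin shoulder center;
#' * lower arm: primary elbow -> wrist center, secondary = primary x wrist
#'   marker line; origin elbow center;
#' * hand: primary wrist center -> first metacarpophalangeal marker,
#'   secondary = primary x wrist marker line; origin wrist center;
#' * bow: primary proximal -> tip bow marker, secondary vector from the
#'   proximal bow marker to the distal finger marker; origin at the proximal
#'   bow marker.
#'
#' @param trial a `trial_recording` carrying the virtual joint-center roles.
#' @return a list with one `pose_series` per segment and a logical `bad`
#'   vector flagging frames where any construction is degenerate or has
#'   missing input markers.
#' @export
build_segment_frames <- function(trial) {
  need <- c("shoulder_jc", "elbow_jc", "wrist_jc")
  if (!has_roles(trial, need)) {
    stop("virtual joint-center markers required; run estimate_joint_centers()")
  }
  nf <- n_frames(trial)
  stern <- get_marker(trial, "sternum")
  sj <- get_marker(trial, "shoulder_jc")
  ej <- get_marker(trial, "elbow_jc")
  wj <- get_marker(trial, "wrist_jc")
  wr <- get_marker(trial, "wrist_radial")
  wu <- get_marker(trial, "wrist_ulnar")
  mcp <- get_marker(trial, "mcp1")
  pip <- get_marker(trial, "pip1")
  bp <- get_marker(trial, "bow_proximal")
  bt <- get_marker(trial, "bow_tip")

  vertical <- matrix(c(0, 0, 1), nf, 3, byrow = TRUE)
  wline <- wu - wr
  la_primary <- wj - ej

  scap <- row_frames(sj - stern, row_cross(vertical, sj - stern))
  ua <- row_frames(ej - sj, row_cross(ej - sj, la_primary))
  la <- row_frames(la_primary, row_cross(la_primary, wline))
  hand <- row_frames(mcp - wj, row_cross(mcp - wj, wline))
  bow <- row_frames(bt - bp, pip - bp)

  bad <- scap$bad | ua$bad | la$bad | hand$bad | bow$bad
  list(scapula = pose_series(scap$R, sj),
       upper_arm = pose_series(ua$R, sj),
       lower_arm = pose_series(la$R, ej),
       hand = pose_series(hand$R, wj),
       bow = pose_series(bow$R, bp),
       bad = bad)
}

#' Decompose a trial into per-joint rigid-body motions
#'
#' Expresses each distal segment's coordinate system in its proximal
#' neighbour's frame along the chain lab -> scapula -> upper arm -> lower
#' arm -> hand -> bow, yielding per-frame rigid motions for the shoulder,
#' elbow and wrist joints plus the hand-to-bow grip and the scapula root
#' pose. Marker positions are stored as per-frame offsets in their owning
#' segment's frame (so soft-tissue wobble is preserved exactly and
#' [reconstruct()] of an unmodified chain reproduces the trial to numerical
#' precision); markers not on the chain (the cello markers) are kept in lab
#' coordinates.
#'
#' @param trial a `trial_recording` with virtual joint-center roles.
#' @return an object of class `chain_series`.
#' @export
decompose <- function(trial) {
  sf <- build_segment_frames(trial)
  root <- sf$scapula
  shoulder <- ps_rel(sf$scapula, sf$upper_arm)
  elbow <- ps_rel(sf$upper_arm, sf$lower_arm)
  wrist <- ps_rel(sf$lower_arm, sf$hand)
  hand_to_bow <- ps_rel(sf$hand, sf$bow)

  nf <- n_frames(trial)
  segroles <- segment_roles()
  owned_roles <- intersect(unlist(segroles), names(trial$roles))
  owned_labels <- unname(trial$roles[owned_roles])
  lab_labels <- setdiff(trial$labels, owned_labels)

  locals <- list()
  for (seg in names(segroles)) {
    roles <- intersect(segroles[[seg]], names(trial$roles))
    if (length(roles) == 0) next
    pts <- array(NA_real_, c(nf, length(roles), 3),
                 dimnames = list(NULL, unname(trial$roles[roles]), NULL))
    for (j in seq_along(roles)) pts[, j, ] <- get_marker(trial, roles[j])
    locals[[seg]] <- ps_localize(sf[[seg]], pts)
  }
  lab_markers <- NULL
  if (length(lab_labels) > 0) {
    lab_markers <- trial$positions[, match(lab_labels, trial$labels), ,
                                   drop = FALSE]
    dimnames(lab_markers) <- list(NULL, lab_labels, NULL)
  }

  structure(list(root = root,
                 shoulder = shoulder,
                 elbow = elbow,
                 wrist = wrist,
                 hand_to_bow = hand_to_bow,
                 locals = locals,
                 lab_markers = lab_markers,
                 labels = trial$labels,
                 roles = trial$roles,
                 rate_hz = trial$rate_hz,
                 meta = trial$meta,
                 missing = trial$missing,
                 bad = sf$bad,
                 frozen = character(0)),
            class = "chain_series")
}

#' @export
print.chain_series <- function(x, ...) {
  cat(sprintf("<chain_series> %d frames @ %g Hz; %d degenerate frame(s)\n",
              ps_nframes(x$root), x$rate_hz, sum(x$bad)))
  if (length(x$frozen) > 0) {
    cat("  frozen joints:", paste(names(x$frozen), "@", x$frozen,
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruct marker positions from a chain
#'
#' Composes the lab-frame pose of every segment along the chain and places
#' each marker at its stored per-frame local offset; cello/lab markers are
#' restored unchanged. For an unmodified chain this reproduces the input
#' trial's marker positions to numerical precision; for a chain modified by
#' [freeze_joint()] it yields the surrogate trial.
#'
#' @param chain a `chain_series`.
#' @return a `trial_recording` with the same labels, roles and metadata as
#'   the decomposed trial.
#' @export
reconstruct <- function(chain) {
  stopifnot(inherits(chain, "chain_series"))
  nf <- ps_nframes(chain$root)
  poses <- list(scapula = chain$root,
                upper_arm = ps_compose(chain$root, chain$shoulder))
  poses$lower_arm <- ps_compose(poses$upper_arm, chain$elbow)
  poses$hand <- ps_compose(poses$lower_arm, chain$wrist)
  poses$bow <- ps_compose(poses$hand, chain$hand_to_bow)

  positions <- array(NA_real_, c(nf, length(chain$labels), 3))
  dimnames(positions) <- list(NULL, chain$labels, c("x", "y", "z"))
  for (seg in names(chain$locals)) {
    glob <- ps_globalize(poses[[seg]], chain$locals[[seg]])
    for (lbl in dimnames(glob)[[2]]) {
      positions[, lbl, ] <- glob[, lbl, ]
    }
  }
  if (!is.null(chain$lab_markers)) {
    for (lbl in dimnames(chain$lab_markers)[[2]]) {
      positions[, lbl, ] <- chain$lab_markers[, lbl, ]
    }
  }
  missing <- chain$missing | matrix(chain$bad, nf, length(chain$labels))
  positions[array(missing, dim(positions))] <- NA_real_
  trial_recording(positions, chain$rate_hz, chain$labels, chain$roles,
                  missing, chain$meta)
}

#' Export chain poses for audit
#'
#' Writes one row per frame with each pose (root, shoulder, elbow, wrist,
#' hand-to-bow) as a unit quaternion (w, x, y, z) plus translation (mm).
#' This is an audit/replay export of the joint trajectories; per-frame
#' marker offsets are not included, so it does not substitute for the trial
#' file.
#'
#' @param chain a `chain_series`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "chain_series"))
  parts <- c("root", "shoulder", "elbow", "wrist", "hand_to_bow")
  nf <- ps_nframes(chain$root)
  out <- list(frame = seq_len(nf) - 1L)
  for (p in parts) {
    ps <- chain[[p]]
    q <- t(vapply(seq_len(nf), function(i) rot_to_quat(ps$R[, , i]),
                  numeric(4)))
    for (j in 1:4) out[[paste0(p, "_q", c("w", "x", "y", "z")[j])]] <- q[, j]
    for (j in 1:3) out[[paste0(p, "_t", c("x", "y", "z")[j])]] <- ps$t[, j]
  }
  df <- as.data.frame(out)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chain poses written by [write_chain()]
#'
#' @param path TSV path.
#' @return a named list of `pose_series` (root, shoulder, elbow, wrist,
#'   hand_to_bow).
#' @export
read_chain <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  parts <- c("root", "shoulder", "elbow", "wrist", "hand_to_bow")
  nf <- nrow(df)
  out <- list()
  for (p in parts) {
    R <- array(NA_real_, c(3, 3, nf))
    q <- as.matrix(df[paste0(p, "_q", c("w", "x", "y", "z"))])
    tt <- as.matrix(df[paste0(p, "_t", c("x", "y", "z"))])
    for (i in seq_len(nf)) R[, , i] <- quat_to_rot(q[i, ])
    colnames(tt) <- NULL
    out[[p]] <- pose_series(R, tt)
  }
  out
}
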