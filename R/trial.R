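# Trial container, marker model, and the wide-TSV + YAML exchange format.

#' Required marker roles
#'
#' The marker model: trunk (sternum, C7), right arm (acromion, lateral
#' epicondyle of the elbow, lower arm, radial/ulnar wrist), right hand (first
#' metacarpophalangeal and first proximal interphalangeal joints), cello
#' (scroll and tailpiece defining the string axis, plus a body marker), and
#' bow (tip, and a proximal marker about two-thirds of the way from frog to
#' tip).
#'
#' @return character vector of the 14 required role names.
#' @export
marker_model <- function() {
  c("sternum", "c7", "acromion", "elbow_lateral", "lowerarm",
    "wrist_radial", "wrist_ulnar", "mcp1", "pip1",
    "cello_scroll", "cello_tailpiece", "cello_body",
    "bow_tip", "bow_proximal")
}

#' Virtual joint-center roles
#'
#' Roles added by [estimate_joint_centers()] (or emitted directly by the
#' synthetic generator): approximate shoulder, elbow and wrist joint centers
#' plus a hand reference point.
#'
#' @return character vector of virtual role names.
#' @export
virtual_roles <- function() c("shoulder_jc", "elbow_jc", "wrist_jc", "hand_ref")

#' Anthropometric measures
#'
#' Segment thicknesses (mm) used to offset surface markers to approximate
#' joint centers. Defaults are adult-scale values; measured per-participant
#' values should be supplied when available.
#'
#' @param elbow_width_mm,wrist_width_mm,hand_thickness_mm strictly positive
#'   lengths in mm.
#' @return an object of class `anthropometrics`.
#' @export
anthropometrics <- function(elbow_width_mm = 70,
                            wrist_width_mm = 55,
                            hand_thickness_mm = 28) {
  vals <- c(elbow_width_mm, wrist_width_mm, hand_thickness_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("anthropometric measures must be strictly positive")
  }
  structure(list(elbow_width_mm = elbow_width_mm,
                 wrist_width_mm = wrist_width_mm,
                 hand_thickness_mm = hand_thickness_mm),
            class = "anthropometrics")
}

#' Construct a validated trial recording
#'
#' The canonical in-memory container for a motion-capture trial: a
#' frames x markers x 3 position array (mm), the sampling rate, marker
#' labels, a role-to-label map covering the marker model, a missing-sample
#' mask, and trial metadata (participant, group, lab).
#'
#' @param positions numeric array, frames x markers x 3, in mm.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param labels character vector of marker labels, one per marker column.
#' @param roles named character vector mapping role -> label; must cover
#'   [marker_model()] with distinct labels present in `labels`.
#' @param missing logical frames x markers mask; defaults to marking frames
#'   with any non-finite coordinate.
#' @param meta list of trial metadata; `participant_id`, `group`
#'   (`"expert"`/`"novice"`) and `lab` are carried into result tables.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(positions, rate_hz, labels, roles,
                            missing = NULL, meta = list()) {
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3) {
    stop("positions must be a frames x markers x 3 array")
  }
  n_frames <- dim(positions)[1]
  n_markers <- dim(positions)[2]
  if (n_frames < 2) stop("a trial needs at least 2 frames")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  if (length(labels) != n_markers) {
    stop("labels length must match the number of marker columns")
  }
  if (anyDuplicated(labels)) stop("marker labels must be distinct")
  roles <- unlist(roles)
  if (is.null(names(roles)) || any(names(roles) == "")) {
    stop("roles must be a named role -> label map")
  }
  req <- marker_model()
  missing_roles <- setdiff(req, names(roles))
  if (length(missing_roles) > 0) {
    stop("role-mapping error: required roles absent: ",
         paste(missing_roles, collapse = ", "))
  }
  if (anyDuplicated(names(roles)) || anyDuplicated(roles)) {
    stop("role-mapping error: roles and their labels must be distinct")
  }
  unknown <- setdiff(roles, labels)
  if (length(unknown) > 0) {
    stop("role-mapping error: role labels not present in trial: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(missing)) {
    missing <- apply(!is.finite(positions), c(1, 2), any)
  }
  if (!is.logical(missing) || !all(dim(missing) == c(n_frames, n_markers))) {
    stop("missing must be a logical frames x markers matrix")
  }
  if (any(!is.finite(positions) & array(!missing, dim(positions)))) {
    stop("positions must be finite wherever missing is FALSE")
  }
  dimnames(positions) <- list(NULL, labels, c("x", "y", "z"))
  structure(list(positions = positions,
                 rate_hz = rate_hz,
                 labels = labels,
                 roles = roles,
                 missing = missing,
                 meta = meta),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d frames x %d markers @ %g Hz (%.2f s)\n",
              dim(x$positions)[1], dim(x$positions)[2], x$rate_hz,
              dim(x$positions)[1] / x$rate_hz))
  if (length(x$meta) > 0) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  cat(sprintf("  missing samples: %d\n", sum(x$missing)))
  invisible(x)
}

n_frames <- function(trial) dim(trial$positions)[1]

has_roles <- function(trial, roles) all(roles %in% names(trial$roles))

#' Extract one marker's trajectory by role
#'
#' @param trial a `trial_recording`.
#' @param role a role name present in `trial$roles`.
#' @return a frames x 3 numeric matrix (mm).
#' @export
get_marker <- function(trial, role) {
  if (!role %in% names(trial$roles)) {
    stop("role not present in trial: ", role)
  }
  idx <- match(trial$roles[[role]], trial$labels)
  m <- trial$positions[, idx, , drop = FALSE]
  dim(m) <- c(dim(trial$positions)[1], 3)
  m
}

#' Write a trial to the wide-TSV exchange format
#'
#' One row per frame with columns `<label>_X`, `<label>_Y`, `<label>_Z` in
#' mm; missing samples are written as empty fields. A YAML sidecar
#' (`<path>.yaml`) stores the sampling rate, role map, and metadata.
#' Positions round-trip through [read_trial()] to better than 1e-9 mm.
#'
#' @param trial a valid `trial_recording`.
#' @param path output TSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  nf <- n_frames(trial)
  nm <- length(trial$labels)
  cols <- vector("list", nm * 3)
  nms <- character(nm * 3)
  for (m in seq_len(nm)) {
    for (k in 1:3) {
      v <- trial$positions[, m, k]
      v[trial$missing[, m]] <- NA_real_
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- ""
      cols[[(m - 1) * 3 + k]] <- s
      nms[(m - 1) * 3 + k] <- paste0(trial$labels[m], "_", c("X", "Y", "Z")[k])
    }
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(nms, collapse = "\t"), con)
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(body, con)
  sidecar <- list(rate_hz = trial$rate_hz,
                  roles = as.list(trial$roles),
                  meta = trial$meta)
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  bf_log("wrote trial (%d frames, %d markers) to %s", nf, nm, path)
  invisible(path)
}

#' Read a trial from the wide-TSV exchange format
#'
#' Inverse of [write_trial()]. Unparseable or empty coordinate fields become
#' missing samples; validation enforces the marker model, so a file lacking a
#' required role raises a role-mapping error.
#'
#' @param path TSV path written by [write_trial()] (or conforming to its
#'   dialect).
#' @param sidecar YAML sidecar path; defaults to `<path>.yaml`.
#' @return a validated `trial_recording`.
#' @export
read_trial <- function(path, sidecar = paste0(path, ".yaml")) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  cn <- colnames(raw)
  coord_cols <- grepl("_[XYZ]$", cn)
  if (!all(coord_cols)) {
    stop("format error: non-coordinate columns in trial file: ",
         paste(cn[!coord_cols], collapse = ", "))
  }
  labels <- unique(sub("_[XYZ]$", "", cn))
  expected <- as.vector(t(outer(labels, c("_X", "_Y", "_Z"), paste0)))
  if (!setequal(cn, expected) || length(cn) != length(expected)) {
    stop("format error: each marker needs exactly _X, _Y, _Z columns")
  }
  nf <- nrow(raw)
  nm <- length(labels)
  positions <- array(NA_real_, c(nf, nm, 3))
  for (m in seq_len(nm)) {
    for (k in 1:3) {
      col <- paste0(labels[m], "_", c("X", "Y", "Z")[k])
      v <- suppressWarnings(as.numeric(raw[[col]]))
      positions[, m, k] <- v
    }
  }
  side <- yaml::read_yaml(sidecar)
  if (is.null(side$rate_hz)) stop("sidecar must provide rate_hz")
  missing <- apply(!is.finite(positions), c(1, 2), any)
  positions[array(missing, dim(positions))] <- NA_real_
  trial <- trial_recording(positions,
                           rate_hz = side$rate_hz,
                           labels = labels,
                           roles = unlist(side$roles),
                           missing = missing,
                           meta = if (is.null(side$meta)) list() else side$meta)
  bf_log("read trial %s: %d frames, %d markers, %d missing samples",
         path, nf, nm, sum(missing))
  trial
}
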