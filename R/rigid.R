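# Rigid-body and orthonormal-frame primitives used by the kinematic chain.
# Conventions: right-handed lab frame, millimetres, rotations as 3x3 matrices
# with columns = frame axes; a pose maps segment-local coordinates into the
# parent frame, x_parent = R %*% x_local + t.

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise helpers for T x 3 matrices of per-frame vectors.
row_norms <- function(m) sqrt(rowSums(m * m))

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build a right-handed orthonormal basis from two vectors
#'
#' Gram-Schmidt construction of a segment-fixed coordinate frame: the first
#' column is the normalized `primary` vector, the second the normalized
#' component of `secondary` orthogonal to it, and the third their cross
#' product, so the basis is always right-handed.
#'
#' @param primary,secondary numeric length-3 vectors; must be nonzero and not
#'   (near-)collinear.
#' @param tol collinearity tolerance: an error is raised when the
#'   orthogonalized secondary retains less than `tol` of its original norm.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @examples
#' gram_schmidt_frame(c(1, 0, 0), c(0, 1, 0))
#' @export
gram_schmidt_frame <- function(primary, secondary, tol = 1e-6) {
  stopifnot(length(primary) == 3, length(secondary) == 3)
  np <- vnorm(primary)
  ns <- vnorm(secondary)
  if (np < 1e-12 || ns < 1e-12) {
    stop("gram_schmidt_frame: zero-length input vector")
  }
  e1 <- primary / np
  s_perp <- secondary - sum(secondary * e1) * e1
  nsp <- vnorm(s_perp)
  if (nsp < tol * ns) {
    stop("gram_schmidt_frame: near-collinear input vectors (degenerate frame)")
  }
  e2 <- s_perp / nsp
  cbind(e1, e2, cross3(e1, e2), deparse.level = 0)
}

# Vectorized frame construction over frames. primary/secondary: T x 3.
# Returns list(R = 3x3xT array, bad = logical T); degenerate or non-finite
# frames are flagged rather than raising, so callers can mark frames missing.
row_frames <- function(primary, secondary, tol = 1e-6) {
  np <- row_norms(primary)
  ns <- row_norms(secondary)
  bad <- !is.finite(np) | !is.finite(ns) | np < 1e-12 | ns < 1e-12
  np[bad] <- NA_real_
  e1 <- primary / np
  sp <- secondary - rowSums(secondary * e1) * e1
  nsp <- row_norms(sp)
  bad <- bad | !is.finite(nsp) | nsp < tol * ns
  e2 <- sp / nsp
  e3 <- row_cross(e1, e2)
  n <- nrow(primary)
  R <- array(NA_real_, c(3, 3, n))
  R[, 1, ] <- t(e1)
  R[, 2, ] <- t(e2)
  R[, 3, ] <- t(e3)
  list(R = R, bad = bad)
}

# ---- pose series: per-frame rigid motions -----------------------------------

#' Per-frame rigid motion series
#'
#' Internal container for a time series of rigid-body motions: `R` is a
#' 3x3xT rotation array, `t` a T x 3 translation matrix (mm).
#'
#' @param R 3x3xT array of rotation matrices.
#' @param t T x 3 matrix of translations.
#' @return an object of class `pose_series`.
#' @keywords internal
#' @export
pose_series <- function(R, t) {
  stopifnot(length(dim(R)) == 3, dim(R)[1] == 3, dim(R)[2] == 3,
            is.matrix(t), ncol(t) == 3, dim(R)[3] == nrow(t))
  structure(list(R = R, t = t), class = "pose_series")
}

ps_nframes <- function(p) dim(p$R)[3]

# relative pose: inv(a) o b, frame by frame
ps_rel <- function(a, b) {
  n <- ps_nframes(a)
  stopifnot(ps_nframes(b) == n)
  R <- array(NA_real_, c(3, 3, n))
  tt <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    Ra <- a$R[, , i]
    R[, , i] <- crossprod(Ra, b$R[, , i])
    tt[i, ] <- crossprod(Ra, b$t[i, ] - a$t[i, ])
  }
  pose_series(R, tt)
}

ps_compose <- function(a, b) {
  n <- ps_nframes(a)
  stopifnot(ps_nframes(b) == n)
  R <- array(NA_real_, c(3, 3, n))
  tt <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    Ra <- a$R[, , i]
    R[, , i] <- Ra %*% b$R[, , i]
    tt[i, ] <- Ra %*% b$t[i, ] + a$t[i, ]
  }
  pose_series(R, tt)
}

# hold every frame at the pose of frame `at`
ps_const <- function(p, at) {
  n <- ps_nframes(p)
  stopifnot(at >= 1, at <= n)
  R <- array(p$R[, , at], c(3, 3, n))
  tt <- matrix(p$t[at, ], n, 3, byrow = TRUE)
  pose_series(R, tt)
}

# express lab-frame points (T x k x 3) in the pose's local frame
ps_localize <- function(p, pts) {
  n <- ps_nframes(p)
  k <- dim(pts)[2]
  out <- array(NA_real_, dim(pts), dimnames = dimnames(pts))
  for (i in seq_len(n)) {
    m <- t(pts[i, , , drop = TRUE])
    if (k == 1) m <- matrix(pts[i, 1, ], 3, 1)
    out[i, , ] <- t(crossprod(p$R[, , i], m - p$t[i, ]))
  }
  out
}

# map local points (T x k x 3) into the parent frame
ps_globalize <- function(p, loc) {
  n <- ps_nframes(p)
  k <- dim(loc)[2]
  out <- array(NA_real_, dim(loc), dimnames = dimnames(loc))
  for (i in seq_len(n)) {
    m <- t(loc[i, , , drop = TRUE])
    if (k == 1) m <- matrix(loc[i, 1, ], 3, 1)
    out[i, , ] <- t(p$R[, , i] %*% m + p$t[i, ])
  }
  out
}

# rotation angle (rad) of a single 3x3 rotation matrix
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

# ---- quaternion helpers (chain audit export) --------------------------------

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
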