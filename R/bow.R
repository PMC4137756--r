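# Bow kinematics: the scalar bowing coordinate, bow-string angle, stroke
# segmentation, reversal windows, and the five performance measures.

# closest-point coordinate of the bow line to the string line, per frame.
# Returns the signed arc-length along the bow axis (proximal -> tip) from
# the proximal bow marker of the common-perpendicular foot.
line_contact_coordinate <- function(string_p, string_dir, bow_p, bow_dir) {
  b <- rowSums(string_dir * bow_dir)
  denom <- 1 - b^2
  w0 <- bow_p - string_p
  s <- (b * rowSums(w0 * string_dir) - rowSums(w0 * bow_dir)) / denom
  s[!is.finite(denom) | denom < 1e-12] <- NA_real_
  s
}

#' Compute bow kinematics from a trial
#'
#' Derives, per frame, the scalar bowing coordinate (the signed arc-length
#' position, along the bow's long axis from the proximal bow marker, of the
#' point on the bow axis closest to the string axis), its first and second
#' central-difference derivatives (bow velocity, mm/s, and acceleration,
#' mm/s^2), and the bow-string angle in degrees (0-180 between the oriented
#' bow axis, proximal to tip, and the oriented string axis, scroll to
#' tailpiece; orthogonal bowing gives 90). Frames where the bow axis is
#' (near-)parallel to the string axis, or where any needed marker is
#' missing, are flagged.
#'
#' @param trial a `trial_recording` (original or reconstructed surrogate).
#' @return a data frame with columns `position`, `velocity`, `acceleration`,
#'   `angle_deg`, and logical `ok`.
#' @export
bow_kinematics <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  bp <- get_marker(trial, "bow_proximal")
  bt <- get_marker(trial, "bow_tip")
  cs <- get_marker(trial, "cello_scroll")
  ct <- get_marker(trial, "cello_tailpiece")

  bow_axis <- bt - bp
  bn <- row_norms(bow_axis)
  string_axis <- ct - cs
  sn <- row_norms(string_axis)
  degen <- !is.finite(bn) | !is.finite(sn) | bn < 1e-9 | sn < 1e-9
  ub <- bow_axis / bn
  us <- string_axis / sn

  pos <- line_contact_coordinate(cs, us, bp, ub)
  ang <- acos(pmin(1, pmax(-1, rowSums(ub * us)))) * 180 / pi

  miss_roles <- c("bow_proximal", "bow_tip", "cello_scroll", "cello_tailpiece")
  idx <- match(trial$roles[miss_roles], trial$labels)
  miss <- apply(trial$missing[, idx, drop = FALSE], 1, any)
  ok <- !degen & !miss & is.finite(pos)
  pos[!ok] <- NA_real_
  ang[degen | miss] <- NA_real_

  data.frame(position = pos,
             velocity = central_diff(pos, trial$rate_hz, 1),
             acceleration = central_diff(pos, trial$rate_hz, 2),
             angle_deg = ang,
             ok = ok)
}

# central differences (one-sided at the ends); order 1 = velocity,
# order 2 = acceleration
central_diff <- function(x, rate_hz, order = 1) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (order == 1) {
    out[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate_hz / 2
    out[1] <- (x[2] - x[1]) * rate_hz
    out[n] <- (x[n] - x[n - 1]) * rate_hz
  } else {
    out[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * rate_hz^2
  }
  out
}

#' Bow-string angle
#'
#' Angle in degrees between an oriented bow axis and an oriented string
#' axis; thin wrapper over the computation used by [bow_kinematics()] for a
#' single pair of direction vectors.
#'
#' @param bow_axis,string_axis numeric length-3 direction vectors.
#' @return angle in degrees in [0, 180].
#' @export
bow_angle <- function(bow_axis, string_axis) {
  ub <- unitize(bow_axis)
  us <- unitize(string_axis)
  acos(min(1, max(-1, sum(ub * us)))) * 180 / pi
}

#' Detect bow strokes from the velocity trace
#'
#' A reversal is a zero crossing of bow velocity, detected with hysteresis:
#' velocity states (+/-) are only entered when |velocity| exceeds
#' `hysteresis_frac` of the trial's median absolute velocity for at least
#' `min_run` consecutive samples, and the reversal frame is the
#' minimum-|velocity| sample between opposite states. Movements between
#' consecutive reversals with a duration inside
#' `[min_stroke_s, max_stroke_s]` are scored as strokes; positive velocity
#' is a down-bow. Reversal windows of `round(reversal_window_s * rate_hz)`
#' samples (45 at 60 Hz) are attached to each reversal that fits inside the
#' trial.
#'
#' @param velocity numeric per-frame bow velocity (mm/s).
#' @param rate_hz sampling rate (Hz).
#' @param params pipeline parameters from [freeze_params()].
#' @return an object of class `stroke_set`: list with data frames `strokes`
#'   (`direction`, `start`, `end`, `duration_s`; frame indices 1-based,
#'   inclusive) and `reversals` (`center`, `kind`, `wstart`, `wend`).
#' @export
detect_strokes <- function(velocity, rate_hz, params = freeze_params()) {
  n <- length(velocity)
  v <- velocity
  thr <- params$hysteresis_frac * stats::median(abs(v), na.rm = TRUE)
  state <- integer(n)
  state[which(v > thr)] <- 1L
  state[which(v < -thr)] <- -1L

  # drop supra-threshold runs shorter than min_run (jitter suppression)
  r <- rle(state)
  r$values[r$values != 0L & r$lengths < params$min_run] <- 0L
  state <- inverse.rle(r)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0L
  run_val <- r$values[keep]
  run_start <- starts[keep]
  run_end <- ends[keep]

  centers <- integer(0)
  if (length(run_val) >= 2) {
    for (i in seq_len(length(run_val) - 1)) {
      if (run_val[i] != run_val[i + 1]) {
        gap <- run_end[i]:run_start[i + 1]
        av <- abs(v[gap])
        av[!is.finite(av)] <- Inf
        centers <- c(centers, gap[which.min(av)])
      }
    }
  }

  strokes <- data.frame(direction = character(0), start = integer(0),
                        end = integer(0), duration_s = numeric(0),
                        stringsAsFactors = FALSE)
  span <- as.integer(round(params$reversal_window_s * rate_hz))
  half <- (span - 1L) %/% 2L
  reversals <- data.frame(center = integer(0), kind = character(0),
                          wstart = integer(0), wend = integer(0),
                          stringsAsFactors = FALSE)
  if (length(centers) == 0) {
    bf_log("no bow reversals detected")
    return(structure(list(strokes = strokes, reversals = reversals,
                          rate_hz = rate_hz, span = span),
                     class = "stroke_set"))
  }

  if (length(centers) >= 2) {
    for (i in seq_len(length(centers) - 1)) {
      s0 <- centers[i]
      s1 <- centers[i + 1]
      dur <- (s1 - s0) / rate_hz
      if (dur < params$min_stroke_s || dur > params$max_stroke_s) next
      vseg <- v[s0:s1]
      dirsign <- sign(sum(vseg[is.finite(vseg)]))
      if (dirsign == 0) next
      strokes <- rbind(strokes,
                       data.frame(direction = if (dirsign > 0) "down" else "up",
                                  start = s0, end = s1,
                                  duration_s = dur,
                                  stringsAsFactors = FALSE))
    }
  }

  for (cen in centers) {
    before <- v[max(1, cen - 3):cen]
    after <- v[cen:min(n, cen + 3)]
    kind <- if (mean(before, na.rm = TRUE) < mean(after, na.rm = TRUE)) {
      "up_down"   # velocity goes negative -> positive: up-bow ends, down starts
    } else {
      "down_up"
    }
    ws <- cen - half
    we <- ws + span - 1L
    if (ws < 1 || we > n) next
    reversals <- rbind(reversals,
                       data.frame(center = cen, kind = kind,
                                  wstart = ws, wend = we,
                                  stringsAsFactors = FALSE))
  }
  structure(list(strokes = strokes, reversals = reversals,
                 rate_hz = rate_hz, span = span),
            class = "stroke_set")
}

#' @export
print.stroke_set <- function(x, ...) {
  cat(sprintf("<stroke_set> %d strokes (%d up, %d down), %d reversal windows\n",
              nrow(x$strokes), sum(x$strokes$direction == "up"),
              sum(x$strokes$direction == "down"), nrow(x$reversals)))
  invisible(x)
}

#' Select the analyzed strokes and reversals
#'
#' Keeps the first `n_per_dir` up-bow and down-bow strokes containing no
#' invalid frames, together with the adjacent reversals whose full analysis
#' windows are clean; later clean strokes are promoted when earlier ones are
#' contaminated. A warning is issued when fewer than `n_per_dir` clean
#' strokes exist for a direction.
#'
#' @param ss a `stroke_set` from [detect_strokes()].
#' @param bad_frames logical per-frame vector; `TRUE` marks frames that may
#'   not enter the analysis (missing samples, degenerate geometry).
#' @param n_per_dir analyzed strokes per direction.
#' @return a `stroke_set` containing only the analyzed strokes/reversals.
#' @export
select_analyzed <- function(ss, bad_frames, n_per_dir = 10) {
  stopifnot(inherits(ss, "stroke_set"))
  st <- ss$strokes
  clean <- function(i0, i1) !any(bad_frames[i0:i1])
  keep <- logical(nrow(st))
  taken <- c(up = 0L, down = 0L)
  for (i in seq_len(nrow(st))) {
    d <- st$direction[i]
    if (taken[[d]] >= n_per_dir) next
    if (clean(st$start[i], st$end[i])) {
      keep[i] <- TRUE
      taken[[d]] <- taken[[d]] + 1L
    }
  }
  for (d in c("up", "down")) {
    if (taken[[d]] < n_per_dir) {
      warning(sprintf("only %d clean %s-bow strokes available (requested %d)",
                      taken[[d]], d, n_per_dir))
    }
  }
  st <- st[keep, , drop = FALSE]
  rev <- ss$reversals
  if (nrow(rev) > 0 && nrow(st) > 0) {
    adjacent <- rev$center %in% c(st$start, st$end)
    wclean <- vapply(seq_len(nrow(rev)),
                     function(i) clean(rev$wstart[i], rev$wend[i]),
                     logical(1))
    rev <- rev[adjacent & wclean, , drop = FALSE]
  } else {
    rev <- rev[0, , drop = FALSE]
  }
  structure(list(strokes = st, reversals = rev,
                 rate_hz = ss$rate_hz, span = ss$span),
            class = "stroke_set")
}

#' Central fraction of a stroke
#'
#' Symmetric trimming used to exclude bow reversals from the variability
#' measures: `floor(n * (1 - fraction) / 2)` frames are removed from each
#' end of an n-frame stroke.
#'
#' @param start,end 1-based inclusive frame indices of the stroke.
#' @param fraction retained central fraction (default 0.8).
#' @return integer vector `c(start, end)` of the retained range.
#' @export
central_fraction <- function(start, end, fraction = 0.8) {
  n <- end - start + 1
  if (n < 5) stop("stroke too short for central-fraction trimming")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- floor(n * (1 - fraction) / 2)
  c(start + k, end - k)
}

# ---- performance measures ---------------------------------------------------

#' Bow movement amplitude of one stroke
#'
#' Range (max - min, mm) of the bowing coordinate over the full stroke.
#'
#' @param position per-frame bowing coordinate (mm).
#' @param start,end stroke frame range (1-based, inclusive).
#' @return amplitude in mm.
#' @export
measure_amplitude <- function(position, start, end) {
  x <- position[start:end]
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  max(x) - min(x)
}

#' Bow-angle variability of one stroke
#'
#' Population standard deviation (degrees) of the bow-string angle over the
#' central fraction of the stroke.
#'
#' @param angle_deg per-frame bow angle (degrees).
#' @param start,end stroke frame range.
#' @param fraction central fraction retained (1 = full stroke).
#' @return SD in degrees.
#' @export
measure_angle_sd <- function(angle_deg, start, end, fraction = 0.8) {
  r <- central_fraction(start, end, fraction)
  pop_sd(angle_deg[r[1]:r[2]])
}

#' Within-bow velocity variance of one stroke
#'
#' Population variance ((mm/s)^2) of bow velocity over the central fraction
#' of a stroke; low values indicate a rectangular (constant-speed) velocity
#' profile.
#'
#' @param velocity per-frame bow velocity (mm/s).
#' @param start,end stroke frame range.
#' @param fraction central fraction retained.
#' @return variance in (mm/s)^2.
#' @export
measure_within_bow_var <- function(velocity, start, end, fraction = 0.8) {
  r <- central_fraction(start, end, fraction)
  pop_var(velocity[r[1]:r[2]])
}

#' Between-bow velocity variance across strokes
#'
#' Each stroke's central-fraction velocity profile is linearly resampled to
#' `n_points` normalized time points; the population variance across strokes
#' is taken at each point and averaged over points. Low values indicate
#' consistent stroke-to-stroke velocity profiles.
#'
#' @param velocity per-frame bow velocity (mm/s).
#' @param strokes data frame with `start`, `end` columns (same direction).
#' @param fraction central fraction retained.
#' @param n_points resampling grid size.
#' @return variance in (mm/s)^2.
#' @export
measure_between_bow_var <- function(velocity, strokes, fraction = 0.8,
                                    n_points = 100) {
  if (nrow(strokes) < 2) {
    stop("between-bow variance needs at least 2 strokes")
  }
  grid <- seq(0, 1, length.out = n_points)
  prof <- matrix(NA_real_, nrow(strokes), n_points)
  for (i in seq_len(nrow(strokes))) {
    r <- central_fraction(strokes$start[i], strokes$end[i], fraction)
    idx <- r[1]:r[2]
    tt <- seq(0, 1, length.out = length(idx))
    prof[i, ] <- stats::approx(tt, velocity[idx], xout = grid)$y
  }
  mean(apply(prof, 2, pop_var))
}

#' Reversal acceleration amplitude
#'
#' Maximum absolute bow acceleration (mm/s^2) inside one reversal window
#' (optionally the peak-to-peak range instead).
#'
#' @param acceleration per-frame bow acceleration (mm/s^2).
#' @param wstart,wend window frame range.
#' @param mode `"max_abs"` (default) or `"peak_to_peak"`.
#' @return acceleration amplitude in mm/s^2.
#' @export
measure_accel_amplitude <- function(acceleration, wstart, wend,
                                    mode = c("max_abs", "peak_to_peak")) {
  mode <- match.arg(mode)
  a <- acceleration[wstart:wend]
  a <- a[is.finite(a)]
  if (length(a) == 0) return(NA_real_)
  if (mode == "max_abs") max(abs(a)) else max(a) - min(a)
}

#' All performance measures for one trial
#'
#' Computes the five dependent measures from a bow-kinematics table and the
#' analyzed stroke set: bow movement amplitude, bow-angle SD, within-bow
#' velocity variance, and between-bow velocity variance per bow direction
#' (up/down; per-stroke values averaged across the analyzed strokes of that
#' direction), plus reversal acceleration amplitude per reversal kind
#' (up-down / down-up; averaged across windows).
#'
#' @param kin data frame from [bow_kinematics()].
#' @param analyzed a `stroke_set` from [select_analyzed()].
#' @param params pipeline parameters.
#' @return a tidy data frame with columns `measure`, `direction`, `value`.
#' @export
trial_measures <- function(kin, analyzed, params = freeze_params()) {
  st <- analyzed$strokes
  rv <- analyzed$reversals
  frac <- params$central_fraction
  afrac <- if (params$angle_full_stroke) 1 else frac
  rows <- list()
  for (d in c("up", "down")) {
    sd_ <- st[st$direction == d, , drop = FALSE]
    if (nrow(sd_) == 0) next
    amp <- mean(vapply(seq_len(nrow(sd_)), function(i) {
      measure_amplitude(kin$position, sd_$start[i], sd_$end[i])
    }, numeric(1)), na.rm = TRUE)
    asd <- mean(vapply(seq_len(nrow(sd_)), function(i) {
      measure_angle_sd(kin$angle_deg, sd_$start[i], sd_$end[i], afrac)
    }, numeric(1)), na.rm = TRUE)
    wv <- mean(vapply(seq_len(nrow(sd_)), function(i) {
      measure_within_bow_var(kin$velocity, sd_$start[i], sd_$end[i], frac)
    }, numeric(1)), na.rm = TRUE)
    bv <- if (nrow(sd_) >= 2) {
      measure_between_bow_var(kin$velocity, sd_, frac, params$n_points)
    } else {
      NA_real_
    }
    rows[[length(rows) + 1]] <- data.frame(
      measure = c("amplitude", "angle_sd", "within_bow_var", "between_bow_var"),
      direction = d,
      value = c(amp, asd, wv, bv),
      stringsAsFactors = FALSE)
  }
  for (k in c("up_down", "down_up")) {
    rk <- rv[rv$kind == k, , drop = FALSE]
    if (nrow(rk) == 0) next
    aa <- mean(vapply(seq_len(nrow(rk)), function(i) {
      measure_accel_amplitude(kin$acceleration, rk$wstart[i], rk$wend[i],
                              params$accel_peak)
    }, numeric(1)), na.rm = TRUE)
    rows[[length(rows) + 1]] <- data.frame(measure = "accel_amp",
                                           direction = k, value = aa,
                                           stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(measure = character(0), direction = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
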