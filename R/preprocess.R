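# Zero-phase low-pass filtering and sampling-rate harmonization.

# start/end indices of runs of TRUE
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# Forward filter with DC-offset initialization: filtering (x - x[1]) with
# zero initial conditions and restoring the DC term keeps the startup
# transient proportional to local deviations only.
filt_dc <- function(x, b, a) {
  x0 <- x[1]
  as.numeric(signal::filter(b, a, x - x0)) + x0 * sum(b) / sum(a)
}

# Zero-phase (forward-backward) filtering with odd-reflection end padding,
# so both ends are extended smoothly before the bidirectional pass.
filtfilt_refl <- function(x, b, a) {
  n <- length(x)
  padlen <- min(n - 1, 3 * (length(a) + length(b)))
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xp <- c(pre, x, post)
  y <- filt_dc(xp, b, a)
  y <- rev(filt_dc(rev(y), b, a))
  y[(padlen + 1):(padlen + n)]
}

#' Low-pass filter a trial (zero phase)
#'
#' Applies a bidirectional (forward and backward, hence zero-phase)
#' Butterworth low-pass to every marker coordinate. Each contiguous block of
#' non-missing frames is filtered independently; blocks shorter than three
#' times the filter order are passed through unchanged and logged. The
#' missing mask is unchanged.
#'
#' @param trial a `trial_recording`.
#' @param cutoff_hz cutoff frequency (Hz); must be below Nyquist.
#' @param order filter order for each pass.
#' @return the filtered `trial_recording`.
#' @export
lowpass_filter <- function(trial, cutoff_hz = 20, order = 5) {
  stopifnot(inherits(trial, "trial_recording"))
  nyq <- trial$rate_hz / 2
  if (cutoff_hz >= nyq) {
    stop("cutoff_hz must be below the Nyquist frequency (", nyq, " Hz)")
  }
  if (cutoff_hz <= 0 || order < 1) stop("invalid filter parameters")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  min_len <- max(3 * order, 2 * (length(bf$a) + length(bf$b)))
  pos <- trial$positions
  nm <- dim(pos)[2]
  for (m in seq_len(nm)) {
    ok <- !trial$missing[, m]
    if (!any(ok)) next
    runs <- logical_runs(ok)
    for (r in seq_len(nrow(runs))) {
      i0 <- runs[r, 1]
      i1 <- runs[r, 2]
      if (i1 - i0 + 1 < min_len) {
        bf_log("marker %s: block %d-%d shorter than filter warm-up; left unfiltered",
               trial$labels[m], i0, i1)
        next
      }
      for (k in 1:3) {
        pos[i0:i1, m, k] <- filtfilt_refl(pos[i0:i1, m, k], bf$b, bf$a)
      }
    }
  }
  trial$positions <- pos
  trial
}

#' Decimate a trial to a target rate
#'
#' Keeps every (rate/target)-th sample; intended to be applied after
#' [lowpass_filter()], whose 20 Hz default already prevents aliasing at a
#' 60 Hz target (Nyquist 30 Hz). The rate must be an integer multiple of the
#' target.
#'
#' @param trial a `trial_recording`.
#' @param target_hz target sampling rate (Hz).
#' @return the decimated `trial_recording` (identity if already at target).
#' @export
decimate_to <- function(trial, target_hz = 60) {
  stopifnot(inherits(trial, "trial_recording"))
  ratio <- trial$rate_hz / target_hz
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1) {
    stop("rate_hz (", trial$rate_hz,
         ") is not an integer multiple of target_hz (", target_hz, ")")
  }
  k <- as.integer(round(ratio))
  if (k == 1L) return(trial)
  idx <- seq(1L, n_frames(trial), by = k)
  trial$positions <- trial$positions[idx, , , drop = FALSE]
  trial$missing <- trial$missing[idx, , drop = FALSE]
  trial$rate_hz <- target_hz
  bf_log("decimated by %d to %g Hz (%d frames)", k, target_hz, length(idx))
  trial
}

#' Filter and rate-harmonize a trial
#'
#' Convenience wrapper: [lowpass_filter()] followed by [decimate_to()], the
#' order of operations used throughout the analysis.
#'
#' @param trial a `trial_recording`.
#' @param params pipeline parameters from [freeze_params()].
#' @return the preprocessed `trial_recording` at `params$target_hz`.
#' @export
preprocess_trial <- function(trial, params = freeze_params()) {
  trial <- lowpass_filter(trial, params$cutoff_hz, params$filter_order)
  decimate_to(trial, params$target_hz)
}
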