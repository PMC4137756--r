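# Logging and shared pipeline parameters.

bf_log <- function(...) {
  if (isTRUE(getOption("bowfreeze.verbose", FALSE))) {
    message("[bowfreeze] ", sprintf(...))
  }
  invisible(NULL)
}

#' Pipeline parameters
#'
#' Collects every tunable of the analysis pipeline with its default. Defaults
#' reproduce the study conditions: a bidirectional 5th-order Butterworth
#' low-pass at 20 Hz, harmonization to 60 Hz, strokes of 0.5-1 s (instructed
#' 0.75 s), 45-sample (0.75 s) reversal windows, the central 80% of each
#' stroke for the velocity/angle variability measures, and the first ten
#' clean strokes per direction.
#'
#' @param cutoff_hz low-pass cutoff frequency (Hz).
#' @param filter_order Butterworth order (applied forward and backward).
#' @param target_hz analysis sampling rate; trials at integer multiples are
#'   decimated after filtering.
#' @param min_stroke_s,max_stroke_s admissible stroke durations (s).
#' @param reversal_window_s reversal analysis window length (s); the span in
#'   samples is `round(reversal_window_s * rate_hz)`.
#' @param central_fraction fraction of each stroke retained (centred) for the
#'   variability measures.
#' @param n_strokes number of analyzed strokes per bow direction.
#' @param hysteresis_frac reversal-detection hysteresis: a velocity
#'   zero-crossing counts only if |velocity| exceeds this fraction of the
#'   trial's median absolute velocity on both sides.
#' @param min_run minimum number of consecutive supra-threshold samples for a
#'   velocity sign state to count in reversal detection.
#' @param n_points number of normalized-time points used when resampling
#'   stroke velocity profiles for the between-bow variance.
#' @param accel_peak one of "max_abs" (default) or "peak_to_peak": the
#'   operationalization of reversal acceleration amplitude.
#' @param angle_full_stroke if `TRUE`, bow-angle SD uses full strokes instead
#'   of the central fraction.
#' @param ratio_eps effects are undefined (NA) when the original measure
#'   falls below this guard, so ratios are never infinite.
#' @return a named list of parameters.
#' @export
freeze_params <- function(cutoff_hz = 20,
                          filter_order = 5,
                          target_hz = 60,
                          min_stroke_s = 0.5,
                          max_stroke_s = 1.0,
                          reversal_window_s = 0.75,
                          central_fraction = 0.8,
                          n_strokes = 10,
                          hysteresis_frac = 0.05,
                          min_run = 3,
                          n_points = 100,
                          accel_peak = c("max_abs", "peak_to_peak"),
                          angle_full_stroke = FALSE,
                          ratio_eps = 1e-12) {
  list(cutoff_hz = cutoff_hz,
       filter_order = filter_order,
       target_hz = target_hz,
       min_stroke_s = min_stroke_s,
       max_stroke_s = max_stroke_s,
       reversal_window_s = reversal_window_s,
       central_fraction = central_fraction,
       n_strokes = n_strokes,
       hysteresis_frac = hysteresis_frac,
       min_run = min_run,
       n_points = n_points,
       accel_peak = match.arg(accel_peak),
       angle_full_stroke = angle_full_stroke,
       ratio_eps = ratio_eps)
}

# population variance / sd (divide by n); measures are compared as ratios so
# the convention cancels, but it is fixed for reproducibility
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

# md5 of a small R object via its YAML rendering (provenance stamping)
config_hash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}
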