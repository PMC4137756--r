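# Frozen-joint surrogates and log10 freezing-effect ratios.

#' Freeze one joint of a chain
#'
#' Replaces the named joint's full 6-DoF rigid motion (rotation and
#' translation) at every frame by its value at `ref_frame`, leaving all
#' other joints, the root pose, the hand-bow grip, and the per-frame marker
#' offsets untouched. Reconstructing the result yields the surrogate trial
#' that differs from the original only through the frozen joint.
#'
#' @param chain a `chain_series` from [decompose()].
#' @param joint one of `"shoulder"`, `"elbow"`, `"wrist"`.
#' @param ref_frame 1-based frame index at which the joint configuration is
#'   held (stroke midpoint for movement measures, first analyzed reversal
#'   for acceleration).
#' @return the modified `chain_series`.
#' @export
freeze_joint <- function(chain, joint = c("shoulder", "elbow", "wrist"),
                         ref_frame) {
  stopifnot(inherits(chain, "chain_series"))
  joint <- match.arg(joint)
  nf <- ps_nframes(chain$root)
  if (!is.numeric(ref_frame) || length(ref_frame) != 1 ||
      ref_frame < 1 || ref_frame > nf) {
    stop("ref_frame must be a frame index inside the trial")
  }
  ref_frame <- as.integer(ref_frame)
  chain[[joint]] <- ps_const(chain[[joint]], ref_frame)
  chain$frozen <- c(chain$frozen, stats::setNames(ref_frame, joint))
  chain
}

# reference frames for the two surrogate families
midpoint_frame <- function(analyzed) {
  st <- analyzed$strokes
  if (nrow(st) == 0) stop("no analyzed strokes: freezing reference undefined")
  first <- st[which.min(st$start), ]
  as.integer(floor((first$start + first$end) / 2))
}

first_reversal_frame <- function(analyzed) {
  rv <- analyzed$reversals
  if (nrow(rv) == 0) stop("no analyzed reversals: freezing reference undefined")
  as.integer(min(rv$center))
}

# log10 surrogate/original with an epsilon guard; undefined ratios are NA
log_ratio <- function(surrogate, original, eps = 1e-12) {
  ifelse(is.finite(original) & is.finite(surrogate) & original > eps &
           surrogate > eps,
         log10(surrogate / original), NA_real_)
}

#' Run the complete freezing analysis on one trial
#'
#' The full per-participant pipeline: preprocess (zero-phase low-pass,
#' decimation to the analysis rate), ensure virtual joint centers, compute
#' bow kinematics, segment strokes and select the analyzed set, decompose
#' into the kinematic chain, and for each joint build two surrogates — one
#' frozen at the midpoint of the first analyzed stroke (for the movement
#' measures) and one frozen at the first analyzed reversal (for the
#' acceleration measure). Surrogate measures are computed on the identical
#' stroke/reversal windows taken from the original segmentation (surrogate
#' velocity may no longer cross zero, e.g. under a full freeze, so the
#' comparison must use identical time windows). The freezing effect is the
#' log10 ratio of surrogate to original measure; positive values are
#' relative increases.
#'
#' @param trial a `trial_recording` (raw; preprocessing is applied here).
#' @param anthro anthropometrics used if joint centers must be estimated.
#' @param params pipeline parameters from [freeze_params()].
#' @return a list with `effects` (data frame: `joint`, `measure`,
#'   `direction`, `original`, `surrogate`, `log10_ratio`, plus any
#'   participant metadata), `measures` (original measure table), `analyzed`
#'   (the stroke set), `kin`, `chain`, and the preprocessed `trial`.
#' @export
run_freezing_analysis <- function(trial, anthro = anthropometrics(),
                                  params = freeze_params()) {
  stopifnot(inherits(trial, "trial_recording"))
  trial <- preprocess_trial(trial, params)
  if (!has_roles(trial, c("shoulder_jc", "elbow_jc", "wrist_jc"))) {
    trial <- estimate_joint_centers(trial, anthro)
  }
  kin <- bow_kinematics(trial)
  chain <- decompose(trial)
  bad <- chain$bad | !kin$ok | apply(trial$missing, 1, any)
  ss <- detect_strokes(kin$velocity, trial$rate_hz, params)
  analyzed <- select_analyzed(ss, bad, params$n_strokes)
  original <- trial_measures(kin, analyzed, params)

  mid <- midpoint_frame(analyzed)
  rev1 <- first_reversal_frame(analyzed)
  movement_measures <- c("amplitude", "angle_sd", "within_bow_var",
                         "between_bow_var")
  rows <- list()
  for (joint in c("shoulder", "elbow", "wrist")) {
    for (ref in c("stroke_midpoint", "first_reversal")) {
      ref_frame <- if (ref == "stroke_midpoint") mid else rev1
      surro <- reconstruct(freeze_joint(chain, joint, ref_frame))
      skin <- bow_kinematics(surro)
      smeas <- trial_measures(skin, analyzed, params)
      wanted <- if (ref == "stroke_midpoint") movement_measures else "accel_amp"
      o <- original[original$measure %in% wanted, , drop = FALSE]
      s <- smeas[smeas$measure %in% wanted, , drop = FALSE]
      m <- merge(o, s, by = c("measure", "direction"),
                 suffixes = c("_original", "_surrogate"))
      if (nrow(m) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        joint = joint,
        measure = m$measure,
        direction = m$direction,
        original = m$value_original,
        surrogate = m$value_surrogate,
        log10_ratio = log_ratio(m$value_surrogate, m$value_original,
                                params$ratio_eps),
        stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, rows)
  for (field in c("participant_id", "group", "lab")) {
    if (!is.null(trial$meta[[field]])) effects[[field]] <- trial$meta[[field]]
  }
  ord <- order(match(effects$joint, c("shoulder", "elbow", "wrist")),
               match(effects$measure, c(movement_measures, "accel_amp")),
               effects$direction)
  effects <- effects[ord, , drop = FALSE]
  rownames(effects) <- NULL
  list(effects = effects,
       measures = original,
       analyzed = analyzed,
       kin = kin,
       chain = chain,
       trial = trial)
}
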