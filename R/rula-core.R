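#' Posture inputs for a single RULA assessment
#'
#' Bundles every quantity the RULA scheme scores for one observed posture:
#' joint angles in degrees, the worksheet's "+1" posture flags, and the
#' muscle-use / force-load increments added to the posture table scores.
#'
#' Angle sign conventions: flexion is positive, extension negative (upper
#' arm and neck); wrist deviation is signed degrees from the neutral
#' hand-forearm alignment.  The defaults describe a neutral seated working
#' posture (arm hanging, elbow at 80 degrees so the forearm sits in its
#' low-risk 60--100 degree band, wrist/neck/trunk neutral, legs supported)
#' with the fixed modifiers used for static seated work: muscle use +1 for
#' both score groups and force/load 0 (no loads over 2 kg are handled).
#'
#' @param upper_arm_flexion Shoulder flexion/extension, degrees.
#' @param shoulder_raised Is the shoulder raised? (+1)
#' @param upper_arm_abducted Is the upper arm abducted? (+1)
#' @param arm_supported Is the arm supported / person leaning? (-1)
#' @param lower_arm_flexion Elbow flexion, degrees.
#' @param arm_across_midline_or_out Arm working across the body midline or
#'   out to the side. (+1)
#' @param wrist_deviation Wrist bend from neutral, signed degrees.
#' @param wrist_bent_from_midline Wrist bent away from the midline? (+1)
#' @param wrist_twist_near_end_range Forearm rotation near end of range?
#' @param neck_flexion Neck flexion (positive) or extension (negative),
#'   degrees.
#' @param neck_twist,neck_side_tilt Neck posture flags. (+1 each)
#' @param trunk_flexion Trunk flexion from upright, degrees.
#' @param trunk_twist,trunk_side_tilt Trunk posture flags. (+1 each)
#' @param legs_supported Legs and feet supported and balanced?
#' @param muscle_use_arm,muscle_use_trunk Muscle-use increments added to
#'   the posture A / posture B table values (default +1, static posture).
#' @param force_load_arm,force_load_trunk Force/load increments (default 0).
#'
#' @return An object of class `rula_inputs` (a named list).
#' @seealso [score_posture()]
#' @export
#' @examples
#' rula_inputs()                      # neutral seated posture
#' rula_inputs(upper_arm_flexion = 70, shoulder_raised = TRUE)
rula_inputs <- function(upper_arm_flexion = 0, shoulder_raised = FALSE,
                        upper_arm_abducted = FALSE, arm_supported = FALSE,
                        lower_arm_flexion = 80,
                        arm_across_midline_or_out = FALSE,
                        wrist_deviation = 0, wrist_bent_from_midline = FALSE,
                        wrist_twist_near_end_range = FALSE,
                        neck_flexion = 0, neck_twist = FALSE,
                        neck_side_tilt = FALSE,
                        trunk_flexion = 0, trunk_twist = FALSE,
                        trunk_side_tilt = FALSE,
                        legs_supported = TRUE,
                        muscle_use_arm = 1, muscle_use_trunk = 1,
                        force_load_arm = 0, force_load_trunk = 0) {
  x <- list(upper_arm_flexion = upper_arm_flexion,
            shoulder_raised = shoulder_raised,
            upper_arm_abducted = upper_arm_abducted,
            arm_supported = arm_supported,
            lower_arm_flexion = lower_arm_flexion,
            arm_across_midline_or_out = arm_across_midline_or_out,
            wrist_deviation = wrist_deviation,
            wrist_bent_from_midline = wrist_bent_from_midline,
            wrist_twist_near_end_range = wrist_twist_near_end_range,
            neck_flexion = neck_flexion, neck_twist = neck_twist,
            neck_side_tilt = neck_side_tilt,
            trunk_flexion = trunk_flexion, trunk_twist = trunk_twist,
            trunk_side_tilt = trunk_side_tilt,
            legs_supported = legs_supported,
            muscle_use_arm = muscle_use_arm,
            muscle_use_trunk = muscle_use_trunk,
            force_load_arm = force_load_arm,
            force_load_trunk = force_load_trunk)
  validate_rula_inputs(x)
  structure(x, class = "rula_inputs")
}

.rula_angle_fields <- c("upper_arm_flexion", "lower_arm_flexion",
                        "wrist_deviation", "neck_flexion", "trunk_flexion")
.rula_flag_fields <- c("shoulder_raised", "upper_arm_abducted",
                       "arm_supported", "arm_across_midline_or_out",
                       "wrist_bent_from_midline",
                       "wrist_twist_near_end_range", "neck_twist",
                       "neck_side_tilt", "trunk_twist", "trunk_side_tilt",
                       "legs_supported")
.rula_increment_fields <- c("muscle_use_arm", "muscle_use_trunk",
                            "force_load_arm", "force_load_trunk")
.rula_input_fields <- c(.rula_angle_fields, .rula_flag_fields,
                        .rula_increment_fields)

validate_rula_inputs <- function(x) {
  missing <- setdiff(.rula_input_fields, names(x))
  if (length(missing))
    stop(input_error(paste0("missing RULA input field(s): ",
                            paste(missing, collapse = ", "))))
  for (f in .rula_angle_fields)
    if (!is.numeric(x[[f]]) || any(!is.finite(x[[f]])))
      stop(input_error(paste0("angle field '", f, "' must be finite numeric")))
  for (f in .rula_flag_fields)
    if (!is.logical(x[[f]]) || any(is.na(x[[f]])))
      stop(input_error(paste0("flag field '", f, "' must be TRUE/FALSE")))
  for (f in .rula_increment_fields)
    if (!is.numeric(x[[f]]) || any(!is.finite(x[[f]])) || any(x[[f]] < 0))
      stop(input_error(paste0("increment field '", f,
                              "' must be a non-negative number")))
  invisible(x)
}

input_error <- function(msg) {
  errorCondition(msg, class = c("rulagree_input_error", "error", "condition"))
}

.check_finite_angle <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(input_error(paste0(what, " must be finite numeric")))
  x
}

#' Body-region RULA sub-scores
#'
#' Each function maps one body region's posture (an angle in degrees plus
#' the worksheet's modifier flags) to its RULA sub-score.  Band boundaries
#' follow the published worksheet, with boundary values assigned to the
#' lower-scoring band:
#' \itemize{
#'   \item upper arm: within +-20 deg = 1; extension beyond 20 deg or
#'     flexion 20--45 = 2; 45--90 = 3; above 90 = 4; then +1 if the
#'     shoulder is raised, +1 if abducted, -1 if the arm is supported
#'     (floored at 1).
#'   \item lower arm: elbow flexion 60--100 deg = 1, otherwise 2; +1 if the
#'     arm works across the midline or out to the side.
#'   \item wrist: neutral = 1; within +-15 deg = 2; beyond = 3; +1 if bent
#'     from the midline.
#'   \item wrist twist: 1 mid-range, 2 near end of range.
#'   \item neck: 0--10 deg = 1; 10--20 = 2; above 20 = 3; any extension
#'     (negative angle) = 4; +1 twist, +1 side tilt.
#'   \item trunk: seated, well supported (within `neutral_tol` of upright)
#'     = 1; up to 20 deg = 2; 20--60 = 3; above 60 = 4; +1 twist, +1 side
#'     tilt.  Extension beyond the neutral tolerance scores as the 0--20
#'     band.
#'   \item legs: 1 if legs and feet are supported, else 2.
#' }
#' All functions are vectorised and deterministic.
#'
#' @param flexion Angle in degrees (signed where the region admits
#'   extension).
#' @param raised,abducted,supported,across_or_out,bent_from_midline,twist,side_tilt,near_end_range,supported_legs
#'   Logical modifier flags (see above).
#' @param deviation Wrist deviation from neutral, signed degrees.
#' @param neutral_tol Half-width (degrees) of the upright trunk band that
#'   scores 1 for a seated, well-supported trunk.  Default 2.
#' @return Integer sub-score vector.
#' @name rula_subscores
#' @export
score_upper_arm <- function(flexion, raised = FALSE, abducted = FALSE,
                            supported = FALSE) {
  .check_finite_angle(flexion, "upper arm flexion")
  base <- ifelse(flexion < -20, 2L,
          ifelse(flexion <= 20, 1L,
          ifelse(flexion <= 45, 2L,
          ifelse(flexion <= 90, 3L, 4L))))
  pmax(1L, base + as.integer(raised) + as.integer(abducted) -
         as.integer(supported))
}

#' @rdname rula_subscores
#' @export
score_lower_arm <- function(flexion, across_or_out = FALSE) {
  .check_finite_angle(flexion, "lower arm flexion")
  base <- ifelse(flexion >= 60 & flexion <= 100, 1L, 2L)
  base + as.integer(across_or_out)
}

#' @rdname rula_subscores
#' @export
score_wrist <- function(deviation, bent_from_midline = FALSE,
                        neutral_tol = 1e-9) {
  .check_finite_angle(deviation, "wrist deviation")
  # the worksheet's "neutral" band is a single position; a tiny numerical
  # tolerance keeps geometrically measured zeros in it
  base <- ifelse(abs(deviation) <= neutral_tol, 1L,
          ifelse(abs(deviation) <= 15, 2L, 3L))
  base + as.integer(bent_from_midline)
}

#' @rdname rula_subscores
#' @export
score_wrist_twist <- function(near_end_range = FALSE) {
  1L + as.integer(near_end_range)
}

#' @rdname rula_subscores
#' @export
score_neck <- function(flexion, twist = FALSE, side_tilt = FALSE) {
  .check_finite_angle(flexion, "neck flexion")
  base <- ifelse(flexion < 0, 4L,
          ifelse(flexion <= 10, 1L,
          ifelse(flexion <= 20, 2L, 3L)))
  base + as.integer(twist) + as.integer(side_tilt)
}

#' @rdname rula_subscores
#' @export
score_trunk <- function(flexion, twist = FALSE, side_tilt = FALSE,
                        neutral_tol = 2) {
  .check_finite_angle(flexion, "trunk flexion")
  base <- ifelse(abs(flexion) <= neutral_tol, 1L,
          ifelse(flexion <= 20, 2L,
          ifelse(flexion <= 60, 3L, 4L)))
  base + as.integer(twist) + as.integer(side_tilt)
}

#' @rdname rula_subscores
#' @export
score_legs <- function(supported_legs = TRUE) {
  ifelse(supported_legs, 1L, 2L)
}

#' RULA posture lookup tables
#'
#' `lookup_posture_a()` returns the arm-and-wrist posture score (table A),
#' `lookup_posture_b()` the neck-trunk-legs posture score (table B), and
#' `grand_score()` the final 1--7 score (table C).  Table C inputs above
#' its last row/column are clamped to the published "8+" row and "7+"
#' column, so any valid score A/B pair maps into 1--7.
#'
#' @param ua,la,wrist,twist Sub-scores for upper arm (1--6), lower arm
#'   (1--3), wrist (1--4) and wrist twist (1--2).
#' @param neck,trunk,legs Sub-scores for neck (1--6), trunk (1--6) and legs
#'   (1--2).
#' @param score_a,score_b Score A and score B (posture table value plus
#'   muscle-use and force/load increments), each >= 1.
#' @return Integer posture/grand score.
#' @export
#' @examples
#' lookup_posture_a(1, 1, 1, 1)  # 1
#' lookup_posture_b(6, 6, 2)     # 9
#' grand_score(8, 8)             # 7
lookup_posture_a <- function(ua, la, wrist, twist) {
  .check_index(ua, 6L, "upper arm score")
  .check_index(la, 3L, "lower arm score")
  .check_index(wrist, 4L, "wrist score")
  .check_index(twist, 2L, "wrist twist score")
  .rula_table_a[cbind(ua, la, wrist, twist)]
}

#' @rdname lookup_posture_a
#' @export
lookup_posture_b <- function(neck, trunk, legs) {
  .check_index(neck, 6L, "neck score")
  .check_index(trunk, 6L, "trunk score")
  .check_index(legs, 2L, "legs score")
  .rula_table_b[cbind(neck, trunk, legs)]
}

#' @rdname lookup_posture_a
#' @export
grand_score <- function(score_a, score_b) {
  if (any(score_a < 1) || any(score_b < 1) ||
      any(score_a != round(score_a)) || any(score_b != round(score_b)))
    stop(input_error("score_a and score_b must be integers >= 1"))
  .rula_table_c[cbind(pmin(as.integer(score_a), 8L),
                      pmin(as.integer(score_b), 7L))]
}

.check_index <- function(x, hi, what) {
  if (any(!is.finite(x)) || any(x != round(x)) || any(x < 1) || any(x > hi))
    stop(input_error(paste0(what, " out of range 1..", hi)))
  invisible(x)
}

# Vectorised scoring over a data.frame holding one RulaInputs field per
# column and one posture per row.  Workhorse behind score_posture(),
# score_stream() and the cohort simulator.
.score_frames <- function(df, trunk_neutral_tol = 2) {
  ua <- score_upper_arm(df$upper_arm_flexion, df$shoulder_raised,
                        df$upper_arm_abducted, df$arm_supported)
  la <- score_lower_arm(df$lower_arm_flexion, df$arm_across_midline_or_out)
  wr <- score_wrist(df$wrist_deviation, df$wrist_bent_from_midline)
  wt <- score_wrist_twist(df$wrist_twist_near_end_range)
  nk <- score_neck(df$neck_flexion, df$neck_twist, df$neck_side_tilt)
  tr <- score_trunk(df$trunk_flexion, df$trunk_twist, df$trunk_side_tilt,
                    neutral_tol = trunk_neutral_tol)
  lg <- score_legs(df$legs_supported)
  pa <- lookup_posture_a(ua, la, wr, wt)
  pb <- lookup_posture_b(nk, tr, lg)
  sa <- pa + df$muscle_use_arm + df$force_load_arm
  sb <- pb + df$muscle_use_trunk + df$force_load_trunk
  data.frame(upper_arm_score = ua, lower_arm_score = la, wrist_score = wr,
             wrist_twist_score = wt, neck_score = nk, trunk_score = tr,
             legs_score = lg, posture_a = pa, posture_b = pb,
             score_a = sa, score_b = sb, grand = grand_score(sa, sb))
}

#' Score one posture with the full RULA chain
#'
#' Composes the body-region sub-scores, the A and B posture tables, the
#' muscle-use and force/load increments, and the grand-score table into a
#' complete RULA result for one posture.  Deterministic: identical inputs
#' always give identical results.
#'
#' @param inputs A [rula_inputs()] object.
#' @param trunk_neutral_tol Degrees of trunk flexion still treated as
#'   "seated, well supported" (sub-score 1).  Default 2.
#' @return An object of class `rula_result`: a list with the seven region
#'   sub-scores, `posture_a`, `posture_b`, `score_a`, `score_b` and the
#'   `grand` score (1--7).
#' @export
#' @examples
#' score_posture(rula_inputs())$grand   # 2: neutral posture + static muscle use
score_posture <- function(inputs, trunk_neutral_tol = 2) {
  if (!inherits(inputs, "rula_inputs")) {
    validate_rula_inputs(inputs)
  }
  res <- .score_frames(as.data.frame(unclass(inputs)[.rula_input_fields]),
                       trunk_neutral_tol = trunk_neutral_tol)
  structure(as.list(res[1L, ]), class = "rula_result")
}

#' @export
print.rula_result <- function(x, ...) {
  cat("RULA result: grand score", x$grand, "\n")
  cat(sprintf("  score A %d (posture A %d)  |  score B %d (posture B %d)\n",
              x$score_a, x$posture_a, x$score_b, x$posture_b))
  cat(sprintf(paste0("  upper arm %d  lower arm %d  wrist %d  ",
                     "wrist twist %d  neck %d  trunk %d  legs %d\n"),
              x$upper_arm_score, x$lower_arm_score, x$wrist_score,
              x$wrist_twist_score, x$neck_score, x$trunk_score,
              x$legs_score))
  invisible(x)
}

#' @export
print.rula_inputs <- function(x, ...) {
  cat("RULA posture inputs\n")
  ang <- unlist(x[.rula_angle_fields])
  cat("  angles (deg):",
      paste(sprintf("%s=%.1f", sub("_flexion|_deviation", "",
                                   names(ang)), ang), collapse = "  "), "\n")
  on <- .rula_flag_fields[unlist(x[.rula_flag_fields])]
  cat("  flags set:", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
  cat(sprintf("  increments: muscle arm/trunk %g/%g, force arm/trunk %g/%g\n",
              x$muscle_use_arm, x$muscle_use_trunk, x$force_load_arm,
              x$force_load_trunk))
  invisible(x)
}
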