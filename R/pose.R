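#' The 17 keypoint names of the COCO / MoveNet skeleton layout
#' @export
keypoint_names <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
                    "left_shoulder", "right_shoulder", "left_elbow",
                    "right_elbow", "left_wrist", "right_wrist",
                    "left_hip", "right_hip", "left_knee", "right_knee",
                    "left_ankle", "right_ankle")

#' A single-plane 2D skeleton snapshot
#'
#' Seventeen named keypoints (MoveNet/COCO layout) with per-keypoint
#' confidences, in image coordinates (pixels, y increases downward), for
#' one anatomical plane (frontal or sagittal camera view).
#'
#' @param plane `"frontal"` or `"sagittal"`.
#' @param keypoints A 17 x 2 numeric matrix of (x, y) image coordinates
#'   with rownames exactly [keypoint_names] (any order).
#' @param confidence Named numeric vector of per-keypoint confidences in
#'   \[0, 1\]; defaults to 1 for all keypoints.
#' @return Object of class `skeleton2d`.
#' @export
skeleton2d <- function(plane, keypoints, confidence = NULL) {
  plane <- match.arg(plane, c("frontal", "sagittal"))
  if (is.null(confidence))
    confidence <- stats::setNames(rep(1, 17L), keypoint_names)
  kp <- as.matrix(keypoints)
  if (is.null(rownames(kp)))
    stop(schema_error("keypoints matrix must have keypoint rownames"))
  unknown <- setdiff(rownames(kp), keypoint_names)
  if (length(unknown))
    stop(schema_error(paste0("unknown keypoint name(s): ",
                             paste(unknown, collapse = ", "))))
  missing <- setdiff(keypoint_names, rownames(kp))
  if (length(missing))
    stop(schema_error(paste0("missing keypoint(s): ",
                             paste(missing, collapse = ", "))))
  kp <- kp[keypoint_names, , drop = FALSE]
  if (ncol(kp) != 2L || !is.numeric(kp) || any(!is.finite(kp)))
    stop(schema_error("keypoint coordinates must be a finite n x 2 matrix"))
  colnames(kp) <- c("x", "y")
  conf <- confidence[keypoint_names]
  if (any(is.na(conf)) || any(conf < 0) || any(conf > 1))
    stop(schema_error("confidence must cover all keypoints, each in [0, 1]"))
  structure(list(plane = plane, keypoints = kp,
                 confidence = stats::setNames(as.numeric(conf),
                                              keypoint_names)),
            class = "skeleton2d")
}

#' @export
print.skeleton2d <- function(x, ...) {
  cat("skeleton2d (", x$plane, " plane): 17 keypoints, mean confidence ",
      sprintf("%.2f", mean(x$confidence)), "\n", sep = "")
  invisible(x)
}

#' Manual annotations for transverse-plane RULA items
#'
#' Neither a 2D camera snapshot nor the geometric extraction can observe
#' rotations about the body's long axes, so the twist flags, the hand
#' alignment, and arm support are supplied by the assessor.
#'
#' @param neck_twist,trunk_twist,wrist_twist_near_end_range,wrist_bent_from_midline,arm_supported
#'   Logical flags (defaults `FALSE`).
#' @param hand_direction Optional named list of per-plane 2D unit vectors
#'   (image coordinates) giving the direction of the hand, e.g.
#'   `list(sagittal = c(0, 1))`; used to measure wrist deviation against
#'   the elbow-wrist line.  Each vector must have unit norm within 1e-6.
#' @return Object of class `manual_annotations`.
#' @export
manual_annotations <- function(neck_twist = FALSE, trunk_twist = FALSE,
                               wrist_twist_near_end_range = FALSE,
                               wrist_bent_from_midline = FALSE,
                               arm_supported = FALSE,
                               hand_direction = NULL) {
  for (f in c("neck_twist", "trunk_twist", "wrist_twist_near_end_range",
              "wrist_bent_from_midline", "arm_supported")) {
    v <- get(f)
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      stop(schema_error(paste0("annotation '", f, "' must be TRUE/FALSE")))
  }
  if (!is.null(hand_direction)) {
    if (!is.list(hand_direction) || is.null(names(hand_direction)))
      stop(schema_error("hand_direction must be a named list of 2D vectors"))
    for (pl in names(hand_direction)) {
      v <- hand_direction[[pl]]
      if (length(v) != 2L || any(!is.finite(v)) ||
          abs(sqrt(sum(v^2)) - 1) > 1e-6)
        stop(schema_error(paste0("hand_direction$", pl,
                                 " must be a finite 2D unit vector")))
    }
  }
  structure(list(neck_twist = neck_twist, trunk_twist = trunk_twist,
                 wrist_twist_near_end_range = wrist_twist_near_end_range,
                 wrist_bent_from_midline = wrist_bent_from_midline,
                 arm_supported = arm_supported,
                 hand_direction = hand_direction),
            class = "manual_annotations")
}

#' Configuration for two-plane pose extraction
#'
#' @param facing Direction the subject faces in the sagittal image
#'   (`"right"` = anterior is +x in the image).
#' @param side Which body side is scored (default `"right"`, one-sided
#'   assessment).
#' @param abduction_threshold_deg Frontal hip-shoulder vs shoulder-elbow
#'   angle beyond which the upper arm counts as abducted.  Default 20.
#' @param shoulder_raise_threshold_deg Frontal shoulder-line inclination
#'   (from horizontal) beyond which a shoulder counts as raised.  Default 5.
#' @param confidence_min Keypoints below this confidence are treated as
#'   occluded and raise an occlusion error when required.  Default 0.3.
#' @param eye_tilt_tolerance_deg Frontal eye-line inclinations up to this
#'   value still count as level (guards the "over 0 degrees" side-tilt rule
#'   against pixel noise; the eye keypoints sit close together, so their
#'   line is the noisiest of the frontal landmarks).  Default 3.
#' @param trunk_side_tilt_threshold_deg Frontal inclination of the
#'   hip-midpoint to shoulder-midpoint line beyond which the trunk counts
#'   as side-tilted.  Default 10.
#' @param trunk_neutral_tol_deg Sagittal trunk flexions within this band
#'   score as seated upright.  Default 2.
#' @param allow_annotation_only_wrist If `TRUE`, a missing annotated hand
#'   direction yields wrist deviation 0 (flags still scored) instead of an
#'   error.  Default `FALSE`.
#' @return Object of class `pose_config`.
#' @export
pose_config <- function(facing = c("right", "left"),
                        side = c("right", "left"),
                        abduction_threshold_deg = 20,
                        shoulder_raise_threshold_deg = 5,
                        confidence_min = 0.3,
                        eye_tilt_tolerance_deg = 3,
                        trunk_side_tilt_threshold_deg = 10,
                        trunk_neutral_tol_deg = 2,
                        allow_annotation_only_wrist = FALSE) {
  structure(list(facing = match.arg(facing), side = match.arg(side),
                 abduction_threshold_deg = abduction_threshold_deg,
                 shoulder_raise_threshold_deg = shoulder_raise_threshold_deg,
                 confidence_min = confidence_min,
                 eye_tilt_tolerance_deg = eye_tilt_tolerance_deg,
                 trunk_side_tilt_threshold_deg = trunk_side_tilt_threshold_deg,
                 trunk_neutral_tol_deg = trunk_neutral_tol_deg,
                 allow_annotation_only_wrist = allow_annotation_only_wrist),
            class = "pose_config")
}

#' Unsigned angle between two 2D line segments
#'
#' Returns the angle in degrees, in \[0, 180\], between the direction of
#' segment `p1 -> p2` and the direction of segment `q1 -> q2`.
#'
#' @param p1,p2,q1,q2 Numeric length-2 points.
#' @return Angle in degrees.
#' @export
#' @examples
#' line_angle(c(0, 0), c(0, 1), c(0, 0), c(1, 0))  # 90
line_angle <- function(p1, p2, q1, q2) {
  u <- p2 - p1
  v <- q2 - q1
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop(geometry_error("coincident points define no line direction"))
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# signed angle (degrees) from u to v, positive counter-clockwise, in
# y-UP (mathematical) coordinates
.signed_angle <- function(u, v) {
  atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
}

geometry_error <- function(msg) {
  errorCondition(msg,
                 class = c("rulagree_geometry_error", "error", "condition"))
}

occlusion_error <- function(keypoint, plane) {
  errorCondition(paste0("required keypoint '", keypoint, "' (", plane,
                        " plane) is occluded or below the confidence ",
                        "threshold"),
                 class = c("rulagree_occlusion_error", "error", "condition"))
}

# keypoint in y-up coordinates after confidence gating
.kp <- function(skel, name, cfg) {
  if (skel$confidence[[name]] < cfg$confidence_min)
    stop(occlusion_error(name, skel$plane))
  p <- skel$keypoints[name, ]
  c(p[["x"]], -p[["y"]])
}

#' Extract RULA inputs from two-plane keypoint snapshots
#'
#' Converts a sagittal and a frontal 17-keypoint skeleton, plus the manual
#' transverse-plane annotations, into the full set of [rula_inputs()] for
#' the configured body side.  Angle rules:
#' \itemize{
#'   \item upper arm flexion: sagittal angle between the shoulder-hip line
#'     and the shoulder-elbow axis (signed, extension negative);
#'   \item lower arm flexion: sagittal shoulder-elbow vs elbow-wrist;
#'   \item neck flexion: sagittal shoulder-hip line (extended upward) vs
#'     shoulder-ear axis;
#'   \item trunk flexion: sagittal hip-to-shoulder line vs the image
#'     vertical (the standardized camera makes image-vertical
#'     gravity-aligned);
#'   \item wrist deviation: sagittal elbow-wrist line vs the annotated
#'     hand direction;
#'   \item abduction flag: frontal hip-shoulder vs shoulder-elbow angle
#'     over the configured threshold;
#'   \item shoulder raised: frontal shoulder-line inclination over the
#'     configured threshold;
#'   \item arm across midline / out to side: the scored wrist's frontal x
#'     crosses the vertical through the hip midpoint;
#'   \item neck side tilt: frontal eye-line inclination over 0 (plus
#'     tolerance); trunk side tilt: frontal hip-midpoint to
#'     shoulder-midpoint inclination over its threshold.
#' }
#' All geometry is scale- and translation-invariant.  Twist flags, wrist
#' midline bend and arm support come from the annotations.  The fixed
#' modifiers for static seated work are applied: muscle use +1 on both
#' score groups, force/load 0, legs supported.
#'
#' @param sagittal,frontal [skeleton2d()] snapshots of the two planes.
#' @param ann [manual_annotations()].
#' @param cfg [pose_config()].
#' @return A [rula_inputs()] object.
#' @export
extract_rula_inputs <- function(sagittal, frontal,
                                ann = manual_annotations(),
                                cfg = pose_config()) {
  stopifnot(inherits(sagittal, "skeleton2d"), inherits(frontal, "skeleton2d"))
  if (sagittal$plane != "sagittal" || frontal$plane != "frontal")
    stop(schema_error("skeleton planes do not match the arguments"))
  if (!inherits(ann, "manual_annotations"))
    stop(schema_error("ann must be a manual_annotations object"))
  side <- cfg$side
  fx <- if (cfg$facing == "right") 1 else -1
  kn <- function(part) paste0(side, "_", part)

  ## --- sagittal angles -------------------------------------------------
  hip <- .kp(sagittal, kn("hip"), cfg)
  sh  <- .kp(sagittal, kn("shoulder"), cfg)
  el  <- .kp(sagittal, kn("elbow"), cfg)
  wr  <- .kp(sagittal, kn("wrist"), cfg)
  ear <- .kp(sagittal, kn("ear"), cfg)

  trunk_flexion <- -fx * .signed_angle(c(0, 1), sh - hip)
  upper_arm_flexion <- fx * .signed_angle(hip - sh, el - sh)
  lower_arm_flexion <- fx * .signed_angle(el - sh, wr - el)
  neck_flexion <- -fx * .signed_angle(sh - hip, ear - sh)

  if (!is.null(ann$hand_direction) &&
      !is.null(ann$hand_direction$sagittal)) {
    hd <- ann$hand_direction$sagittal
    hd <- c(hd[1], -hd[2])            # image -> y-up
    wrist_deviation <- fx * .signed_angle(wr - el, hd)
  } else if (cfg$allow_annotation_only_wrist) {
    wrist_deviation <- 0
  } else {
    stop(errorCondition(
      paste0("wrist unmeasurable: no annotated hand direction for the ",
             "sagittal plane (set allow_annotation_only_wrist to score ",
             "wrist flags only)"),
      class = c("rulagree_wrist_error", "error", "condition")))
  }

  ## --- frontal flags ---------------------------------------------------
  f_lsh <- .kp(frontal, "left_shoulder", cfg)
  f_rsh <- .kp(frontal, "right_shoulder", cfg)
  f_lhip <- .kp(frontal, "left_hip", cfg)
  f_rhip <- .kp(frontal, "right_hip", cfg)
  f_sh  <- .kp(frontal, kn("shoulder"), cfg)
  f_hip <- .kp(frontal, kn("hip"), cfg)
  f_el  <- .kp(frontal, kn("elbow"), cfg)
  f_wr  <- .kp(frontal, kn("wrist"), cfg)
  f_leye <- .kp(frontal, "left_eye", cfg)
  f_reye <- .kp(frontal, "right_eye", cfg)

  abd_angle <- abs(.signed_angle(f_hip - f_sh, f_el - f_sh))
  upper_arm_abducted <- abd_angle > cfg$abduction_threshold_deg

  dsh <- f_rsh - f_lsh
  shoulder_incl <- abs(atan2(dsh[2], abs(dsh[1])) * 180 / pi)
  shoulder_raised <- shoulder_incl > cfg$shoulder_raise_threshold_deg

  deye <- f_reye - f_leye
  eye_incl <- abs(atan2(deye[2], abs(deye[1])) * 180 / pi)
  neck_side_tilt <- eye_incl > cfg$eye_tilt_tolerance_deg

  hip_mid <- (f_lhip + f_rhip) / 2
  sh_mid <- (f_lsh + f_rsh) / 2
  dtr <- sh_mid - hip_mid
  trunk_incl <- abs(atan2(abs(dtr[1]), dtr[2]) * 180 / pi)
  trunk_side_tilt <- trunk_incl > cfg$trunk_side_tilt_threshold_deg

  side_sign <- sign(f_hip[1] - hip_mid[1])
  wrist_off <- f_wr[1] - hip_mid[1]
  arm_across <- side_sign != 0 && wrist_off * side_sign < 0

  rula_inputs(upper_arm_flexion = upper_arm_flexion,
              shoulder_raised = shoulder_raised,
              upper_arm_abducted = upper_arm_abducted,
              arm_supported = ann$arm_supported,
              lower_arm_flexion = lower_arm_flexion,
              arm_across_midline_or_out = arm_across,
              wrist_deviation = wrist_deviation,
              wrist_bent_from_midline = ann$wrist_bent_from_midline,
              wrist_twist_near_end_range = ann$wrist_twist_near_end_range,
              neck_flexion = neck_flexion,
              neck_twist = ann$neck_twist,
              neck_side_tilt = neck_side_tilt,
              trunk_flexion = trunk_flexion,
              trunk_twist = ann$trunk_twist,
              trunk_side_tilt = trunk_side_tilt,
              legs_supported = TRUE,
              muscle_use_arm = 1, muscle_use_trunk = 1,
              force_load_arm = 0, force_load_trunk = 0)
}

#' Score a two-plane pose capture
#'
#' [extract_rula_inputs()] followed by [score_posture()]; deterministic.
#'
#' @inheritParams extract_rula_inputs
#' @return A `rula_result`.
#' @export
score_pose_capture <- function(sagittal, frontal,
                               ann = manual_annotations(),
                               cfg = pose_config()) {
  inputs <- extract_rula_inputs(sagittal, frontal, ann, cfg)
  score_posture(inputs, trunk_neutral_tol = cfg$trunk_neutral_tol_deg)
}
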