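test_that("line_angle measures unsigned angles between segments", {
  expect_equal(line_angle(c(0, 0), c(0, 1), c(0, 0), c(0, 1)), 0)
  expect_equal(line_angle(c(0, 0), c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_equal(line_angle(c(0, 0), c(1, 1), c(0, 0), c(1, 0)), 45)
  expect_error(line_angle(c(0, 0), c(0, 0), c(0, 0), c(1, 0)),
               class = "rulagree_geometry_error")
})

test_that("skeleton validation names missing and unknown keypoints", {
  kp <- skeleton_from_angles(rula_inputs(), plane = "frontal")$keypoints
  expect_error(skeleton2d("frontal", kp[-match("left_hip", rownames(kp)), ]),
               "left_hip", class = "rulagree_schema_error")
  bad <- rbind(kp, pelvis = c(0, 0))
  expect_error(skeleton2d("frontal", bad), "pelvis",
               class = "rulagree_schema_error")
  expect_error(skeleton2d("frontal", kp,
                          confidence = setNames(rep(2, 17),
                                                keypoint_names)),
               class = "rulagree_schema_error")
})

test_that("render then extract recovers the generating angles at zero noise", {
  # neutral posture: all plane-measured angles return their defaults
  tp0 <- rula_inputs()
  ex0 <- render_and_extract(tp0)
  expect_equal(ex0$upper_arm_flexion, 0, tolerance = 1e-6)
  expect_equal(ex0$lower_arm_flexion, 80, tolerance = 1e-6)
  expect_equal(ex0$neck_flexion, 0, tolerance = 1e-6)
  expect_equal(ex0$trunk_flexion, 0, tolerance = 1e-6)
  expect_equal(ex0$wrist_deviation, 0, tolerance = 1e-6)
  expect_false(ex0$shoulder_raised)
  expect_false(ex0$upper_arm_abducted)
  expect_false(ex0$arm_across_midline_or_out)
  expect_false(ex0$neck_side_tilt)
  expect_false(ex0$trunk_side_tilt)
  # a specific working posture
  tp <- rula_inputs(upper_arm_flexion = 70, lower_arm_flexion = 30,
                    neck_flexion = 25, trunk_flexion = 10,
                    wrist_deviation = 12)
  ex <- render_and_extract(tp)
  for (f in c("upper_arm_flexion", "lower_arm_flexion", "neck_flexion",
              "trunk_flexion", "wrist_deviation"))
    expect_equal(ex[[f]], tp[[f]], tolerance = 1e-6)
})

test_that("round-trip recovery holds across random postures and flag patterns", {
  set.seed(11)
  for (i in 1:200) {
    tp <- random_renderable_inputs()
    ex <- render_and_extract(tp)
    for (f in c("upper_arm_flexion", "lower_arm_flexion", "neck_flexion",
                "trunk_flexion", "wrist_deviation"))
      expect_equal(ex[[f]], tp[[f]], tolerance = 1e-6)
    for (f in c("shoulder_raised", "upper_arm_abducted",
                "arm_across_midline_or_out", "neck_side_tilt",
                "trunk_side_tilt", "neck_twist", "trunk_twist",
                "wrist_bent_from_midline", "wrist_twist_near_end_range",
                "arm_supported"))
      expect_identical(ex[[f]], tp[[f]])
  }
})

test_that("extracted angles and flags are scale- and translation-invariant", {
  set.seed(12)
  tp <- random_renderable_inputs()
  sag <- skeleton_from_angles(tp, plane = "sagittal")
  fro <- skeleton_from_angles(tp, plane = "frontal")
  ann <- manual_annotations(
    hand_direction = list(sagittal = hand_direction_from_angles(tp)),
    neck_twist = tp$neck_twist, trunk_twist = tp$trunk_twist,
    wrist_twist_near_end_range = tp$wrist_twist_near_end_range,
    wrist_bent_from_midline = tp$wrist_bent_from_midline,
    arm_supported = tp$arm_supported)
  ref <- extract_rula_inputs(sag, fro, ann)
  for (s in c(0.25, 3)) for (shift in list(c(0, 0), c(-140, 260))) {
    tsag <- skeleton2d("sagittal", sag$keypoints * s +
                         rep(shift, each = 17), sag$confidence)
    tfro <- skeleton2d("frontal", fro$keypoints * s +
                         rep(shift, each = 17), fro$confidence)
    got <- extract_rula_inputs(tsag, tfro, ann)
    expect_equal(unclass(got), unclass(ref), tolerance = 1e-9)
  }
})

test_that("an occluded required keypoint raises an error naming it", {
  tp <- rula_inputs()
  sag <- skeleton_from_angles(tp, plane = "sagittal")
  fro <- skeleton_from_angles(tp, plane = "frontal")
  ann <- manual_annotations(
    hand_direction = list(sagittal = hand_direction_from_angles(tp)))
  for (kp in c("right_shoulder", "right_elbow", "right_wrist",
               "right_hip", "right_ear")) {
    hidden <- sag
    hidden$confidence[[kp]] <- 0.1
    expect_error(extract_rula_inputs(hidden, fro, ann), kp,
                 class = "rulagree_occlusion_error")
  }
  hidden <- fro
  hidden$confidence[["left_eye"]] <- 0
  expect_error(extract_rula_inputs(sag, hidden, ann), "left_eye",
               class = "rulagree_occlusion_error")
})

test_that("shoulder-raise detection follows the inclination threshold", {
  # 3 cm offset over a ~38 cm shoulder width is ~4.5 deg: below the 5 deg
  # threshold; 5 cm (~7.5 deg) is above it
  tp <- rula_inputs()
  fro <- skeleton_from_angles(tp, plane = "frontal", px_per_cm = 1)
  sag <- skeleton_from_angles(tp, plane = "sagittal", px_per_cm = 1)
  ann <- manual_annotations(
    hand_direction = list(sagittal = hand_direction_from_angles(tp)))
  raise <- function(cm) {
    kp <- fro$keypoints
    kp["right_shoulder", "y"] <- kp["right_shoulder", "y"] - cm
    skeleton2d("frontal", kp, fro$confidence)
  }
  expect_false(extract_rula_inputs(sag, raise(3), ann)$shoulder_raised)
  expect_true(extract_rula_inputs(sag, raise(5), ann)$shoulder_raised)
})

test_that("wrist scoring without a hand annotation fails loudly unless permitted", {
  tp <- rula_inputs(wrist_deviation = 20)
  sag <- skeleton_from_angles(tp, plane = "sagittal")
  fro <- skeleton_from_angles(tp, plane = "frontal")
  expect_error(extract_rula_inputs(sag, fro, manual_annotations()),
               "wrist unmeasurable", class = "rulagree_wrist_error")
  ex <- extract_rula_inputs(sag, fro,
                            manual_annotations(wrist_bent_from_midline = TRUE),
                            pose_config(allow_annotation_only_wrist = TRUE))
  expect_equal(ex$wrist_deviation, 0)
  expect_true(ex$wrist_bent_from_midline)
})

test_that("pose captures score through the full RULA chain deterministically", {
  tp0 <- rula_inputs()
  sag <- skeleton_from_angles(tp0, plane = "sagittal")
  fro <- skeleton_from_angles(tp0, plane = "frontal")
  ann <- manual_annotations(
    hand_direction = list(sagittal = hand_direction_from_angles(tp0)))
  r <- score_pose_capture(sag, fro, ann)
  expect_equal(r$grand, 2L)
  expect_identical(r, score_pose_capture(sag, fro, ann))

  hi <- rula_inputs(upper_arm_flexion = 70, shoulder_raised = TRUE,
                    lower_arm_flexion = 30, wrist_deviation = 20,
                    wrist_bent_from_midline = TRUE,
                    wrist_twist_near_end_range = TRUE,
                    neck_flexion = 25, neck_twist = TRUE,
                    trunk_flexion = 30, trunk_twist = TRUE)
  expect_equal(render_and_extract(hi)$trunk_flexion, 30, tolerance = 1e-6)
  r7 <- score_pose_capture(
    skeleton_from_angles(hi, plane = "sagittal"),
    skeleton_from_angles(hi, plane = "frontal"),
    manual_annotations(
      neck_twist = TRUE, trunk_twist = TRUE,
      wrist_twist_near_end_range = TRUE, wrist_bent_from_midline = TRUE,
      hand_direction = list(sagittal = hand_direction_from_angles(hi))))
  expect_equal(r7$grand, 7L)
})
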