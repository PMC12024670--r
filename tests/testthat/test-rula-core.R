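test_that("body-region sub-scores match the worksheet examples", {
  # upper arm: band, raised, supported floor
  expect_equal(score_upper_arm(10), 1L)
  expect_equal(score_upper_arm(70, raised = TRUE), 4L)
  expect_equal(score_upper_arm(10, supported = TRUE), 1L)
  # lower arm: mid band low risk, outside band, midline flag
  expect_equal(score_lower_arm(80), 1L)
  expect_equal(score_lower_arm(30), 2L)
  expect_equal(score_lower_arm(80, across_or_out = TRUE), 2L)
  # wrist: neutral, small deviation, beyond band + bend flag
  expect_equal(score_wrist(0), 1L)
  expect_equal(score_wrist(10), 2L)
  expect_equal(score_wrist(20, bent_from_midline = TRUE), 4L)
  # wrist twist
  expect_equal(score_wrist_twist(FALSE), 1L)
  expect_equal(score_wrist_twist(TRUE), 2L)
  expect_equal(score_wrist_twist(FALSE), 1L)
  # neck: slight flexion, extension band, flexed + both flags
  expect_equal(score_neck(5), 1L)
  expect_equal(score_neck(-5), 4L)
  expect_equal(score_neck(25, twist = TRUE, side_tilt = TRUE), 5L)
  # trunk: seated upright, slight flexion, flexed + twist
  expect_equal(score_trunk(0), 1L)
  expect_equal(score_trunk(10), 2L)
  expect_equal(score_trunk(30, twist = TRUE), 4L)
  # legs
  expect_equal(score_legs(TRUE), 1L)
  expect_equal(score_legs(FALSE), 2L)
  expect_equal(score_legs(TRUE), 1L)
})

test_that("non-finite angles are rejected as input errors", {
  expect_error(score_upper_arm(NaN), class = "rulagree_input_error")
  expect_error(score_lower_arm(Inf), class = "rulagree_input_error")
  expect_error(score_wrist(NA_real_), class = "rulagree_input_error")
  expect_error(score_neck(Inf), class = "rulagree_input_error")
  expect_error(score_trunk(-Inf), class = "rulagree_input_error")
})

test_that("posture lookup tables match the worksheet examples", {
  expect_equal(lookup_posture_a(1, 1, 1, 1), 1L)
  expect_equal(lookup_posture_a(6, 3, 4, 2), 9L)
  expect_equal(lookup_posture_a(2, 2, 2, 1), 3L)
  expect_equal(lookup_posture_b(1, 1, 1), 1L)
  expect_equal(lookup_posture_b(6, 6, 2), 9L)
  expect_equal(lookup_posture_b(3, 2, 1), 3L)
  expect_equal(grand_score(1, 1), 1L)
  expect_equal(grand_score(8, 8), 7L)
  expect_equal(grand_score(2, 2), 2L)
  # clamping of the C table beyond its last row/column
  expect_equal(grand_score(12, 9), 7L)
  expect_error(lookup_posture_a(0, 1, 1, 1), class = "rulagree_input_error")
  expect_error(lookup_posture_b(1, 7, 1), class = "rulagree_input_error")
})

test_that("all three lookup tables equal the transcribed worksheet cell-for-cell", {
  expect_equal(
    lookup_posture_a(oracle_table_a$ua, oracle_table_a$la,
                     oracle_table_a$wrist, oracle_table_a$twist),
    oracle_table_a$score)
  expect_equal(
    lookup_posture_b(oracle_table_b$neck, oracle_table_b$trunk,
                     oracle_table_b$legs),
    oracle_table_b$score)
  expect_equal(grand_score(oracle_table_c$a, oracle_table_c$b),
               oracle_table_c$score)
})

test_that("sub-score bands match the worksheet oracle on a dense angle grid", {
  grid <- seq(-60, 150, by = 0.5)
  expect_equal(score_upper_arm(grid),
               vapply(grid, oracle_ua_band, integer(1)))
  expect_equal(score_lower_arm(grid),
               vapply(grid, oracle_la_band, integer(1)))
  wgrid <- seq(-50, 50, by = 0.25)
  expect_equal(score_wrist(wgrid),
               vapply(wgrid, oracle_wrist_band, integer(1)))
  expect_equal(score_neck(grid),
               vapply(grid, oracle_neck_band, integer(1)))
  expect_equal(score_trunk(grid),
               vapply(grid, function(f) oracle_trunk_band(f), integer(1)))
})

test_that("every grand score over a dense input grid lies in 1..7 with sub-scores in range", {
  angles <- list(ua = seq(-40, 120, by = 20), la = seq(-20, 150, by = 34),
                 wr = seq(-30, 30, by = 15), nk = seq(-30, 60, by = 15),
                 tr = seq(-10, 80, by = 18))
  flag_sets <- list(rep(FALSE, 11), rep(TRUE, 11))
  fl <- c("shoulder_raised", "upper_arm_abducted", "arm_supported",
          "arm_across_midline_or_out", "wrist_bent_from_midline",
          "wrist_twist_near_end_range", "neck_twist", "neck_side_tilt",
          "trunk_twist", "trunk_side_tilt", "legs_supported")
  grid <- expand.grid(ua = angles$ua, la = angles$la, wr = angles$wr,
                      nk = angles$nk, tr = angles$tr, flags = 1:2)
  df <- data.frame(upper_arm_flexion = grid$ua,
                   lower_arm_flexion = grid$la,
                   wrist_deviation = grid$wr, neck_flexion = grid$nk,
                   trunk_flexion = grid$tr)
  for (i in seq_along(fl)) df[[fl[i]]] <-
    vapply(grid$flags, function(k) flag_sets[[k]][i], logical(1))
  df$muscle_use_arm <- 1; df$muscle_use_trunk <- 1
  df$force_load_arm <- 0; df$force_load_trunk <- 0
  sc <- rulagree:::.score_frames(df)
  expect_true(all(sc$grand >= 1 & sc$grand <= 7))
  expect_true(all(sc$upper_arm_score >= 1 & sc$upper_arm_score <= 6))
  expect_true(all(sc$lower_arm_score >= 1 & sc$lower_arm_score <= 3))
  expect_true(all(sc$wrist_score >= 1 & sc$wrist_score <= 4))
  expect_true(all(sc$wrist_twist_score %in% 1:2))
  expect_true(all(sc$neck_score >= 1 & sc$neck_score <= 6))
  expect_true(all(sc$trunk_score >= 1 & sc$trunk_score <= 6))
  expect_true(all(sc$legs_score %in% 1:2))
  expect_equal(sc$score_a, sc$posture_a + 1)
  expect_equal(sc$score_b, sc$posture_b + 1)
})

test_that("lookup tables are monotone in every coordinate", {
  # raising any single sub-score never lowers the table value
  for (ua in 1:5) for (la in 1:3) for (w in 1:4) for (tw in 1:2)
    expect_gte(lookup_posture_a(ua + 1, la, w, tw),
               lookup_posture_a(ua, la, w, tw))
  for (ua in 1:6) for (la in 1:2) for (w in 1:4) for (tw in 1:2)
    expect_gte(lookup_posture_a(ua, la + 1, w, tw),
               lookup_posture_a(ua, la, w, tw))
  for (ua in 1:6) for (la in 1:3) for (w in 1:3) for (tw in 1:2)
    expect_gte(lookup_posture_a(ua, la, w + 1, tw),
               lookup_posture_a(ua, la, w, tw))
  for (ua in 1:6) for (la in 1:3) for (w in 1:4)
    expect_gte(lookup_posture_a(ua, la, w, 2),
               lookup_posture_a(ua, la, w, 1))
  for (nk in 1:5) for (tr in 1:6) for (lg in 1:2)
    expect_gte(lookup_posture_b(nk + 1, tr, lg),
               lookup_posture_b(nk, tr, lg))
  for (nk in 1:6) for (tr in 1:5) for (lg in 1:2)
    expect_gte(lookup_posture_b(nk, tr + 1, lg),
               lookup_posture_b(nk, tr, lg))
  for (nk in 1:6) for (tr in 1:6)
    expect_gte(lookup_posture_b(nk, tr, 2), lookup_posture_b(nk, tr, 1))
  for (a in 1:7) for (b in 1:7)
    expect_gte(grand_score(a + 1, b), grand_score(a, b))
  for (a in 1:8) for (b in 1:6)
    expect_gte(grand_score(a, b + 1), grand_score(a, b))
})

test_that("setting any +1 flag never decreases any downstream score", {
  set.seed(41)
  up_flags <- c("shoulder_raised", "upper_arm_abducted",
                "arm_across_midline_or_out", "wrist_bent_from_midline",
                "wrist_twist_near_end_range", "neck_twist",
                "neck_side_tilt", "trunk_twist", "trunk_side_tilt")
  for (rep in 1:60) {
    base <- random_inputs()
    r0 <- score_posture(base)
    for (f in up_flags) {
      if (isTRUE(base[[f]])) next
      mod <- unclass(base); mod[[f]] <- TRUE
      r1 <- score_posture(mod)
      expect_gte(r1$grand, r0$grand)
      expect_gte(r1$score_a, r0$score_a)
      expect_gte(r1$score_b, r0$score_b)
    }
  }
})

test_that("the full chain reproduces the worksheet walk-throughs", {
  # neutral static seated posture with the fixed modifiers
  r <- score_posture(rula_inputs())
  expect_equal(r$posture_a, 1L)
  expect_equal(r$score_a, 2)
  expect_equal(r$posture_b, 1L)
  expect_equal(r$score_b, 2)
  expect_equal(r$grand, 2L)
  # stripping the muscle increments gives the all-minimum chain
  r0 <- score_posture(rula_inputs(muscle_use_arm = 0,
                                  muscle_use_trunk = 0))
  expect_equal(r0$grand, 1L)
  # a high-risk posture saturates the scale
  r7 <- score_posture(rula_inputs(
    upper_arm_flexion = 70, shoulder_raised = TRUE,
    lower_arm_flexion = 30, wrist_deviation = 20,
    wrist_bent_from_midline = TRUE, wrist_twist_near_end_range = TRUE,
    neck_flexion = 25, neck_twist = TRUE,
    trunk_flexion = 30, trunk_twist = TRUE))
  expect_equal(r7$grand, 7L)
})

test_that("scoring is deterministic for identical inputs", {
  set.seed(7)
  for (i in 1:25) {
    tp <- random_inputs()
    expect_identical(score_posture(tp), score_posture(tp))
  }
})
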