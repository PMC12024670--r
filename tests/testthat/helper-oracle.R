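# Independent transcription of the published RULA worksheet, kept in the
# worksheet's own visual layout (row strings), plus brute-force reference
# implementations used as oracles.

# Table A: rows upper-arm x lower-arm; 8 columns = wrist 1..4, each with
# wrist-twist 1 | 2
.oracle_a_rows <- c(
  "1 1 | 1 2  2 2  2 3  3 3",
  "1 2 | 2 2  2 2  3 3  3 3",
  "1 3 | 2 3  3 3  3 3  4 4",
  "2 1 | 2 3  3 3  3 4  4 4",
  "2 2 | 3 3  3 3  3 4  4 4",
  "2 3 | 3 4  4 4  4 4  5 5",
  "3 1 | 3 3  4 4  4 4  5 5",
  "3 2 | 3 4  4 4  4 4  5 5",
  "3 3 | 4 4  4 4  4 5  5 5",
  "4 1 | 4 4  4 4  4 5  5 5",
  "4 2 | 4 4  4 4  4 5  5 5",
  "4 3 | 4 4  4 5  5 5  6 6",
  "5 1 | 5 5  5 5  5 6  6 7",
  "5 2 | 5 6  6 6  6 7  7 7",
  "5 3 | 6 6  6 7  7 7  7 8",
  "6 1 | 7 7  7 7  7 8  8 9",
  "6 2 | 8 8  8 8  8 9  9 9",
  "6 3 | 9 9  9 9  9 9  9 9")

oracle_table_a <- local({
  out <- expand.grid(ua = 1:6, la = 1:3, wrist = 1:4, twist = 1:2)
  out$score <- NA_integer_
  for (row in .oracle_a_rows) {
    parts <- strsplit(row, "\\|")[[1]]
    idx <- as.integer(strsplit(trimws(parts[1]), "\\s+")[[1]])
    vals <- as.integer(strsplit(trimws(parts[2]), "\\s+")[[1]])
    stopifnot(length(vals) == 8L)
    for (w in 1:4) for (tw in 1:2) {
      sel <- out$ua == idx[1] & out$la == idx[2] & out$wrist == w &
        out$twist == tw
      out$score[sel] <- vals[(w - 1L) * 2L + tw]
    }
  }
  out
})

# Table B: rows neck; 12 columns = trunk 1..6, each with legs 1 | 2
.oracle_b_rows <- c(
  "1 | 1 3  2 3  3 4  5 5  6 6  7 7",
  "2 | 2 3  2 3  4 5  5 5  6 7  7 7",
  "3 | 3 3  3 4  4 5  5 6  6 7  7 7",
  "4 | 5 5  5 6  6 7  7 7  7 7  8 8",
  "5 | 7 7  7 7  7 8  8 8  8 8  8 8",
  "6 | 8 8  8 8  8 8  8 9  9 9  9 9")

oracle_table_b <- local({
  out <- expand.grid(neck = 1:6, trunk = 1:6, legs = 1:2)
  out$score <- NA_integer_
  for (row in .oracle_b_rows) {
    parts <- strsplit(row, "\\|")[[1]]
    nk <- as.integer(trimws(parts[1]))
    vals <- as.integer(strsplit(trimws(parts[2]), "\\s+")[[1]])
    stopifnot(length(vals) == 12L)
    for (tr in 1:6) for (lg in 1:2) {
      sel <- out$neck == nk & out$trunk == tr & out$legs == lg
      out$score[sel] <- vals[(tr - 1L) * 2L + lg]
    }
  }
  out
})

# Table C: rows score A 1..8+, columns score B 1..7+
.oracle_c_rows <- c(
  "1 | 1 2 3 3 4 5 5",
  "2 | 2 2 3 4 4 5 5",
  "3 | 3 3 3 4 4 5 6",
  "4 | 3 3 3 4 5 6 6",
  "5 | 4 4 4 5 6 7 7",
  "6 | 4 4 5 6 6 7 7",
  "7 | 5 5 6 6 7 7 7",
  "8 | 5 5 6 7 7 7 7")

oracle_table_c <- local({
  out <- expand.grid(a = 1:8, b = 1:7)
  out$score <- NA_integer_
  for (row in .oracle_c_rows) {
    parts <- strsplit(row, "\\|")[[1]]
    a <- as.integer(trimws(parts[1]))
    vals <- as.integer(strsplit(trimws(parts[2]), "\\s+")[[1]])
    for (b in 1:7) out$score[out$a == a & out$b == b] <- vals[b]
  }
  out
})

# worksheet angle bands, written independently of the package's ifelse
# chains (boundaries belong to the lower-scoring band)
oracle_ua_band <- function(f) {
  if (f >= -20 && f <= 20) return(1L)
  if (f < -20 || f <= 45) return(2L)
  if (f <= 90) return(3L)
  4L
}
oracle_la_band <- function(f) if (f >= 60 && f <= 100) 1L else 2L
oracle_wrist_band <- function(d) {
  if (d == 0) 1L else if (d >= -15 && d <= 15) 2L else 3L
}
oracle_neck_band <- function(f) {
  if (f < 0) return(4L)
  if (f <= 10) 1L else if (f <= 20) 2L else 3L
}
oracle_trunk_band <- function(f, tol = 2) {
  if (abs(f) <= tol) return(1L)
  if (f <= 20) 2L else if (f <= 60) 3L else 4L
}

# brute-force weighted kappa: observed agreement over pairs, expected
# agreement over the full n^2 cross product of observations
bf_weighted_kappa <- function(x, y, k, scheme = "linear") {
  w <- matrix(NA_real_, k, k)
  for (i in 1:k) for (j in 1:k) {
    d <- abs(i - j) / (k - 1)
    w[i, j] <- if (scheme == "linear") 1 - d else 1 - d^2
  }
  n <- length(x)
  po <- mean(w[cbind(x, y)])
  pe <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) pe <- pe + w[x[i], y[j]]
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# brute-force rank-biserial: favorable minus unfavorable pairs
bf_rank_biserial <- function(x, y) {
  fav <- 0; unf <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) fav <- fav + 1
    if (xi < yj) unf <- unf + 1
  }
  list(U = fav + sum(outer(x, y, "==")) / 2,
       r_rb = (fav - unf) / (length(x) * length(y)))
}

# random valid posture over the full scoring domain
random_inputs <- function() {
  rula_inputs(
    upper_arm_flexion = stats::runif(1, -40, 120),
    shoulder_raised = stats::runif(1) < 0.5,
    upper_arm_abducted = stats::runif(1) < 0.5,
    arm_supported = stats::runif(1) < 0.5,
    lower_arm_flexion = stats::runif(1, -20, 150),
    arm_across_midline_or_out = stats::runif(1) < 0.5,
    wrist_deviation = stats::runif(1, -45, 45),
    wrist_bent_from_midline = stats::runif(1) < 0.5,
    wrist_twist_near_end_range = stats::runif(1) < 0.5,
    neck_flexion = stats::runif(1, -30, 60),
    neck_twist = stats::runif(1) < 0.5,
    neck_side_tilt = stats::runif(1) < 0.5,
    trunk_flexion = stats::runif(1, -15, 75),
    trunk_twist = stats::runif(1) < 0.5,
    trunk_side_tilt = stats::runif(1) < 0.5,
    legs_supported = stats::runif(1) < 0.5)
}

# posture within the ranges the two-plane renderer expects (static seated
# work), for render -> extract round trips
random_renderable_inputs <- function() {
  rula_inputs(
    upper_arm_flexion = stats::runif(1, -30, 110),
    shoulder_raised = stats::runif(1) < 0.5,
    upper_arm_abducted = stats::runif(1) < 0.5,
    arm_supported = stats::runif(1) < 0.5,
    lower_arm_flexion = stats::runif(1, -30, 140),
    arm_across_midline_or_out = stats::runif(1) < 0.5,
    wrist_deviation = stats::runif(1, -45, 45),
    wrist_bent_from_midline = stats::runif(1) < 0.5,
    wrist_twist_near_end_range = stats::runif(1) < 0.5,
    neck_flexion = stats::runif(1, -35, 55),
    neck_twist = stats::runif(1) < 0.5,
    neck_side_tilt = stats::runif(1) < 0.5,
    trunk_flexion = stats::runif(1, -15, 55),
    trunk_twist = stats::runif(1) < 0.5,
    trunk_side_tilt = stats::runif(1) < 0.5)
}

render_and_extract <- function(tp, jitter = 0, anthro = anthropometry(),
                               px_per_cm = 2) {
  sag <- skeleton_from_angles(tp, anthro, plane = "sagittal",
                              jitter_sd_px = jitter,
                              px_per_cm = px_per_cm)
  fro <- skeleton_from_angles(tp, anthro, plane = "frontal",
                              jitter_sd_px = jitter,
                              px_per_cm = px_per_cm)
  ann <- manual_annotations(
    neck_twist = tp$neck_twist, trunk_twist = tp$trunk_twist,
    wrist_twist_near_end_range = tp$wrist_twist_near_end_range,
    wrist_bent_from_midline = tp$wrist_bent_from_midline,
    arm_supported = tp$arm_supported,
    hand_direction = list(sagittal = hand_direction_from_angles(tp,
                                                                anthro)))
  extract_rula_inputs(sag, fro, ann)
}
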