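# RULA posture lookup tables, transcribed from the published worksheet
# (McAtamney & Corlett's Rapid Upper Limb Assessment).
#
# Table A: arm & wrist posture score, indexed [upper_arm, lower_arm,
# wrist, wrist_twist].  Table B: neck/trunk/legs, indexed
# [neck, trunk, legs].  Table C: grand score, indexed [score_a, score_b]
# with score_a clamped to 8+ and score_b to 7+.

.rula_table_a <- local({
  # one row per (upper_arm, lower_arm); 8 cells = wrist 1..4 x twist 1..2
  rows <- rbind(
    c(1, 2, 2, 2, 2, 3, 3, 3),  # ua1 la1
    c(2, 2, 2, 2, 3, 3, 3, 3),  # ua1 la2
    c(2, 3, 3, 3, 3, 3, 4, 4),  # ua1 la3
    c(2, 3, 3, 3, 3, 4, 4, 4),  # ua2 la1
    c(3, 3, 3, 3, 3, 4, 4, 4),  # ua2 la2
    c(3, 4, 4, 4, 4, 4, 5, 5),  # ua2 la3
    c(3, 3, 4, 4, 4, 4, 5, 5),  # ua3 la1
    c(3, 4, 4, 4, 4, 4, 5, 5),  # ua3 la2
    c(4, 4, 4, 4, 4, 5, 5, 5),  # ua3 la3
    c(4, 4, 4, 4, 4, 5, 5, 5),  # ua4 la1
    c(4, 4, 4, 4, 4, 5, 5, 5),  # ua4 la2
    c(4, 4, 4, 5, 5, 5, 6, 6),  # ua4 la3
    c(5, 5, 5, 5, 5, 6, 6, 7),  # ua5 la1
    c(5, 6, 6, 6, 6, 7, 7, 7),  # ua5 la2
    c(6, 6, 6, 7, 7, 7, 7, 8),  # ua5 la3
    c(7, 7, 7, 7, 7, 8, 8, 9),  # ua6 la1
    c(8, 8, 8, 8, 8, 9, 9, 9),  # ua6 la2
    c(9, 9, 9, 9, 9, 9, 9, 9))  # ua6 la3
  a <- array(NA_integer_, dim = c(6L, 3L, 4L, 2L),
             dimnames = list(upper_arm = 1:6, lower_arm = 1:3,
                             wrist = 1:4, wrist_twist = 1:2))
  r <- 0L
  for (ua in 1:6) for (la in 1:3) {
    r <- r + 1L
    for (w in 1:4) for (tw in 1:2) a[ua, la, w, tw] <- rows[r, (w - 1L) * 2L + tw]
  }
  a
})

.rula_table_b <- local({
  # one row per neck score; 12 cells = trunk 1..6 x legs 1..2
  rows <- rbind(
    c(1, 3, 2, 3, 3, 4, 5, 5, 6, 6, 7, 7),  # neck 1
    c(2, 3, 2, 3, 4, 5, 5, 5, 6, 7, 7, 7),  # neck 2
    c(3, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 7),  # neck 3
    c(5, 5, 5, 6, 6, 7, 7, 7, 7, 7, 8, 8),  # neck 4
    c(7, 7, 7, 7, 7, 8, 8, 8, 8, 8, 8, 8),  # neck 5
    c(8, 8, 8, 8, 8, 8, 8, 9, 9, 9, 9, 9))  # neck 6
  b <- array(NA_integer_, dim = c(6L, 6L, 2L),
             dimnames = list(neck = 1:6, trunk = 1:6, legs = 1:2))
  for (nk in 1:6) for (tr in 1:6) for (lg in 1:2)
    b[nk, tr, lg] <- rows[nk, (tr - 1L) * 2L + lg]
  b
})

.rula_table_c <- local({
  # rows = score A 1..8+ ; columns = score B 1..7+
  m <- rbind(
    c(1, 2, 3, 3, 4, 5, 5),
    c(2, 2, 3, 4, 4, 5, 5),
    c(3, 3, 3, 4, 4, 5, 6),
    c(3, 3, 3, 4, 5, 6, 6),
    c(4, 4, 4, 5, 6, 7, 7),
    c(4, 4, 5, 6, 6, 7, 7),
    c(5, 5, 6, 6, 7, 7, 7),
    c(5, 5, 6, 7, 7, 7, 7))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(score_a = 1:8, score_b = 1:7)
  m
})
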