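#' A joint-angle time series at a fixed sampling rate
#'
#' Represents the output of an IMU motion-capture session: one complete
#' set of RULA inputs per frame, sampled at `rate` Hz over a capture
#' window (30 s in a typical static-task protocol).
#'
#' @param frames A data.frame with one row per frame and one column per
#'   [rula_inputs()] field.
#' @param rate Sampling rate in Hz (> 0).
#' @return Object of class `angle_stream` with elements `rate`, `frames`
#'   and `duration` (seconds).
#' @export
angle_stream <- function(frames, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0)
    stop(schema_error("rate must be a single positive number (Hz)"))
  frames <- as.data.frame(frames)
  if (nrow(frames) < 1L)
    stop(schema_error("an angle stream needs at least one frame"))
  missing <- setdiff(.rula_input_fields, names(frames))
  if (length(missing))
    stop(schema_error(paste0("stream is missing column(s): ",
                             paste(missing, collapse = ", "))))
  frames <- frames[, .rula_input_fields]
  structure(list(rate = rate, frames = frames,
                 duration = nrow(frames) / rate),
            class = "angle_stream")
}

#' @export
print.angle_stream <- function(x, ...) {
  cat(sprintf("angle_stream: %d frames at %g Hz (%.1f s)\n",
              nrow(x$frames), x$rate, x$duration))
  invisible(x)
}

#' Score every frame of an angle stream
#'
#' Applies the full RULA chain to each frame independently
#' (order-preserving elementwise map).  Frames that fail validation abort
#' with an error naming the frame index.
#'
#' @param stream An [angle_stream()].
#' @param trunk_neutral_tol Passed to the trunk sub-score; see
#'   [score_posture()].
#' @return A data.frame with one row per frame: all region sub-scores,
#'   posture/score A and B, and the `grand` score.
#' @export
score_stream <- function(stream, trunk_neutral_tol = 2) {
  if (!inherits(stream, "angle_stream"))
    stop(schema_error("stream must be an angle_stream"))
  fr <- stream$frames
  bad <- !stats::complete.cases(fr) |
    !apply(sapply(fr[.rula_angle_fields], is.finite), 1L, all)
  if (any(bad))
    stop(input_error(paste0("invalid frame(s) at index: ",
                            paste(utils::head(which(bad), 5L),
                                  collapse = ", "))))
  .score_frames(fr, trunk_neutral_tol = trunk_neutral_tol)
}

#' Relative time spent in each RULA level
#'
#' Summarises per-frame RULA results into the fraction of frames (i.e. of
#' capture time, at a fixed sampling rate) spent at each grand-score level
#' 1--7, together with the mean of every region sub-score.
#'
#' @param scores Per-frame results from [score_stream()] (a data.frame
#'   with at least a `grand` column and the region sub-score columns).
#' @return Object of class `score_distribution`: `level_fraction` (named
#'   numeric, levels "1".."7", sums to 1) and `per_region_mean`.
#' @export
time_distribution <- function(scores) {
  scores <- as.data.frame(scores)
  if (nrow(scores) < 1L)
    stop(input_error("cannot summarise an empty score sequence"))
  lf <- tabulate(scores$grand, nbins = 7L) / nrow(scores)
  names(lf) <- as.character(1:7)
  regions <- c("upper_arm_score", "lower_arm_score", "wrist_score",
               "wrist_twist_score", "neck_score", "trunk_score",
               "legs_score")
  structure(list(level_fraction = lf,
                 per_region_mean = vapply(scores[regions], mean,
                                          numeric(1))),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("RULA level occupancy:\n")
  occ <- x$level_fraction[x$level_fraction > 0]
  for (k in names(occ))
    cat(sprintf("  level %s: %5.1f%%\n", k, 100 * occ[[k]]))
  cat(sprintf("time-weighted overall score: %.2f\n",
              aggregate_rula(x)$overall))
  invisible(x)
}

#' Time-weighted aggregate RULA scores
#'
#' Reduces a level-occupancy distribution to continuous scores: the
#' overall score is the time-weighted mean over levels,
#' `sum(level * fraction)`, which equals the arithmetic mean of the
#' per-frame grand scores; region scores are the per-frame sub-score
#' means.  Continuous values (e.g. an overall 4.82) are the natural
#' output of aggregating a 30 s capture.
#'
#' @param dist A [time_distribution()] result.
#' @return List with `overall` (in \[1, 7\]) and `per_region` (named
#'   numeric).
#' @export
aggregate_rula <- function(dist) {
  if (!inherits(dist, "score_distribution"))
    stop(schema_error("dist must be a score_distribution"))
  lf <- dist$level_fraction
  list(overall = sum(as.numeric(names(lf)) * lf),
       per_region = dist$per_region_mean)
}
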