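# File readers and writers for the formats the two scoring branches
# exchange: keypoint snapshots (JSON or CSV), manual annotations (JSON),
# angle-stream CSVs with a rate sidecar, paired-score CSVs and agreement
# reports (JSON).  Every reader validates against the same schema its
# writer produces and fails with a named schema error.

schema_error <- function(msg) {
  errorCondition(msg, class = c("rulagree_schema_error", "error",
                                "condition"))
}

#' Read and write 2D keypoint snapshots
#'
#' JSON layout: `{"plane": "...", "keypoints": {"nose": [x, y,
#' confidence], ...}}`.  CSV layout: columns `name,x,y,confidence`, one
#' file per plane (the plane is then supplied by the caller).  Unknown or
#' missing keypoint names, non-finite coordinates and out-of-range
#' confidences are rejected with a schema error naming the offending
#' field.
#'
#' @param path File path (`.json` or `.csv`).
#' @param plane Plane for CSV input (ignored for JSON, which embeds it).
#' @param skeleton A [skeleton2d()] to write.
#' @return `read_keypoints()`: a [skeleton2d()].
#' @export
read_keypoints <- function(path, plane = NULL) {
  if (!file.exists(path))
    stop(schema_error(paste0("keypoint file not found: ", path)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$plane) || is.null(obj$keypoints))
      stop(schema_error("keypoint JSON needs 'plane' and 'keypoints'"))
    kp_list <- obj$keypoints
    .skeleton_from_triplets(names(kp_list),
                            do.call(rbind, kp_list), obj$plane)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "confidence")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop(schema_error(paste0("keypoint CSV missing column(s): ",
                               paste(missing, collapse = ", "))))
    if (is.null(plane))
      stop(schema_error("plane must be supplied when reading CSV keypoints"))
    .skeleton_from_triplets(df$name,
                            cbind(df$x, df$y, df$confidence), plane)
  }
}

.skeleton_from_triplets <- function(names, xyz, plane) {
  if (is.null(dim(xyz)) || ncol(xyz) != 3L)
    stop(schema_error("each keypoint needs [x, y, confidence]"))
  if (!is.numeric(xyz) || any(!is.finite(xyz)))
    stop(schema_error("malformed keypoint coordinate or confidence"))
  kp <- xyz[, 1:2, drop = FALSE]
  rownames(kp) <- names
  skeleton2d(plane, kp, confidence = stats::setNames(xyz[, 3], names))
}

#' @rdname read_keypoints
#' @export
write_keypoints <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "skeleton2d"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    kp <- lapply(keypoint_names, function(nm)
      c(skeleton$keypoints[nm, ], skeleton$confidence[[nm]]))
    names(kp) <- keypoint_names
    jsonlite::write_json(list(plane = skeleton$plane, keypoints = kp),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(name = keypoint_names,
                                x = skeleton$keypoints[, "x"],
                                y = skeleton$keypoints[, "y"],
                                confidence = skeleton$confidence),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write manual annotations (JSON)
#'
#' @param path File path.
#' @param ann A [manual_annotations()] to write.
#' @return `read_annotations()`: a [manual_annotations()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop(schema_error(paste0("annotation file not found: ", path)))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hd <- obj$hand_direction
  if (!is.null(hd)) hd <- lapply(hd, as.numeric)
  manual_annotations(
    neck_twist = isTRUE(obj$neck_twist),
    trunk_twist = isTRUE(obj$trunk_twist),
    wrist_twist_near_end_range = isTRUE(obj$wrist_twist_near_end_range),
    wrist_bent_from_midline = isTRUE(obj$wrist_bent_from_midline),
    arm_supported = isTRUE(obj$arm_supported),
    hand_direction = hd)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "manual_annotations"))
  jsonlite::write_json(unclass(ann)[!vapply(unclass(ann), is.null,
                                            logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write angle-stream CSVs
#'
#' One row per frame, one column per [rula_inputs()] field; the sampling
#' rate lives in a JSON sidecar (`<stem>_meta.json`, key `rate_hz`) or is
#' passed explicitly.  Angles are degrees.
#'
#' @param path CSV path.
#' @param rate_hz Sampling rate override; if `NULL`, the sidecar is read.
#' @param stream An [angle_stream()] to write.
#' @return `read_angle_stream()`: an [angle_stream()].
#' @export
read_angle_stream <- function(path, rate_hz = NULL) {
  if (!file.exists(path))
    stop(schema_error(paste0("stream file not found: ", path)))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop(schema_error(paste0("stream file is empty: ", path)))
  missing <- setdiff(.rula_input_fields, names(df))
  if (length(missing))
    stop(schema_error(paste0("stream missing column(s): ",
                             paste(missing, collapse = ", "))))
  for (f in c(.rula_angle_fields, .rula_increment_fields)) {
    if (!is.numeric(df[[f]]) || any(!is.finite(df[[f]])))
      stop(schema_error(paste0("non-numeric cell in stream column '", f,
                               "' (first bad row: ",
                               which(!is.finite(suppressWarnings(
                                 as.numeric(df[[f]]))))[1], ")")))
  }
  for (f in .rula_flag_fields) df[[f]] <- as.logical(df[[f]])
  if (is.null(rate_hz)) {
    side <- paste0(sub("\\.csv$", "", path, ignore.case = TRUE),
                   "_meta.json")
    if (!file.exists(side))
      stop(schema_error(paste0("no rate_hz given and no sidecar found: ",
                               side)))
    rate_hz <- jsonlite::read_json(side)$rate_hz
  }
  if (is.null(rate_hz) || !is.numeric(rate_hz) || rate_hz <= 0)
    stop(schema_error("rate_hz must be a positive number"))
  angle_stream(df, rate = rate_hz)
}

#' @rdname read_angle_stream
#' @export
write_angle_stream <- function(stream, path) {
  stopifnot(inherits(stream, "angle_stream"))
  utils::write.csv(stream$frames, path, row.names = FALSE)
  side <- paste0(sub("\\.csv$", "", path, ignore.case = TRUE), "_meta.json")
  jsonlite::write_json(list(rate_hz = stream$rate), side,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Materialises a complete, self-describing dataset consumable by the two
#' scoring branches: per participant, a frontal and a sagittal keypoint
#' JSON (pose branch, with observation noise applied), an angle-stream
#' CSV with rate sidecar (IMU branch), and an annotation JSON; plus
#' `truth.csv` (true angles, flags and true RULA scores, for recovery
#' tests) and `cohort_config.json`.
#'
#' @param cfg A [cohort_config()]; set `cfg$seed` for a reproducible
#'   tree.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest list of the written paths by
#'   participant.
#' @export
generate_cohort <- function(cfg = cohort_config(), dir) {
  validate_cohort_config(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    stop(schema_error(paste0("cannot create output directory: ", dir)))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_participants
  truth <- sample_true_postures(cfg, n = n)
  manifest <- list()
  for (i in seq_len(n)) {
    id <- truth$participant[i]
    tp <- as.list(truth[i, .rula_input_fields])
    stream <- render_imu_stream(tp, cfg)
    obs <- .pose_observed_angles(tp, cfg)
    sag <- skeleton_from_angles(obs, plane = "sagittal",
                                jitter_sd_px = cfg$pose_noise$keypoint_jitter_px)
    fro <- skeleton_from_angles(obs, plane = "frontal",
                                jitter_sd_px = cfg$pose_noise$keypoint_jitter_px)
    ann <- manual_annotations(
      neck_twist = obs$neck_twist, trunk_twist = obs$trunk_twist,
      wrist_twist_near_end_range = obs$wrist_twist_near_end_range,
      wrist_bent_from_midline = obs$wrist_bent_from_midline,
      arm_supported = obs$arm_supported,
      hand_direction = list(sagittal = hand_direction_from_angles(obs)))
    paths <- list(
      stream = file.path(dir, paste0("stream_", id, ".csv")),
      sagittal = file.path(dir, paste0("keypoints_sagittal_", id, ".json")),
      frontal = file.path(dir, paste0("keypoints_frontal_", id, ".json")),
      annotations = file.path(dir, paste0("annotations_", id, ".json")))
    write_angle_stream(stream, paths$stream)
    write_keypoints(sag, paths$sagittal)
    write_keypoints(fro, paths$frontal)
    write_annotations(ann, paths$annotations)
    manifest[[id]] <- paths
  }
  truth_out <- cbind(truth, .score_frames(truth[.rula_input_fields]))
  utils::write.csv(truth_out, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg_plain <- unclass(cfg)
  cfg_plain$posture <- lapply(cfg_plain$posture, as.list)
  jsonlite::write_json(cfg_plain, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dir = dir, participants = manifest,
                 truth = file.path(dir, "truth.csv")))
}

#' Run the full dual-technology analysis pipeline
#'
#' Either simulates a cohort (when `input_dir` is `NULL`) or reads one
#' from disk, scores every participant with both branches (IMU:
#' per-frame RULA and time-weighted aggregation; pose: two-plane
#' geometric extraction and single-posture RULA), writes the paired-score
#' CSV, the agreement report JSON and a Bland-Altman plot, and returns
#' the [rula_agreement()] fit.
#'
#' @param cfg A [cohort_config()] used for simulation (and recorded in
#'   the report).
#' @param out_dir Output directory for the report artifacts.
#' @param input_dir Optional directory holding a cohort written by
#'   [generate_cohort()]; when given, files are read instead of
#'   simulated in memory.
#' @param weights,bonferroni_m,alpha Passed to [rula_agreement()].
#' @param plot Write `bland_altman.png`?  Default `TRUE`.
#' @return The `rula_agreement` fit (invisibly the written paths as
#'   attribute `paths`).
#' @export
run_pipeline <- function(cfg = cohort_config(), out_dir,
                         input_dir = NULL,
                         weights = "linear", bonferroni_m = NULL,
                         alpha = 0.05, plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(input_dir)) {
    sim <- simulate_cohort(cfg)
    imu <- sim$imu; pose <- sim$pose
  } else {
    scored <- score_cohort_dir(input_dir)
    imu <- scored$imu; pose <- scored$pose
  }
  paired <- data.frame(participant = imu$participant)
  for (f in names(.rula_family_levels)) {
    paired[[paste0("imu_", f)]] <- imu[[f]]
    paired[[paste0("pose_", f)]] <- pose[[f]]
  }
  paired_path <- file.path(out_dir, "paired_scores.csv")
  utils::write.csv(paired, paired_path, row.names = FALSE)

  fit <- rula_agreement(imu[names(.rula_family_levels)],
                        pose[names(.rula_family_levels)],
                        method_names = c("imu", "pose"),
                        weights = weights, bonferroni_m = bonferroni_m,
                        alpha = alpha)
  report_path <- file.path(out_dir, "agreement_report.json")
  write_agreement_report(fit, report_path, seed = cfg$seed)
  plot_path <- NULL
  if (plot) {
    plot_path <- file.path(out_dir, "bland_altman.png")
    grDevices::png(plot_path, width = 720, height = 540)
    plot(fit, family = "overall")
    grDevices::dev.off()
  }
  attr(fit, "paths") <- list(paired = paired_path, report = report_path,
                             plot = plot_path)
  fit
}

#' Score a cohort directory with both branches
#'
#' Reads every participant written by [generate_cohort()] and produces
#' the same paired per-participant score tables as [simulate_cohort()].
#'
#' @param dir Cohort directory.
#' @param cfg_pose A [pose_config()] for the extraction.
#' @return List with `imu` and `pose` score data.frames.
#' @export
score_cohort_dir <- function(dir, cfg_pose = pose_config()) {
  streams <- sort(list.files(dir, pattern = "^stream_.*\\.csv$",
                             full.names = TRUE))
  if (!length(streams))
    stop(schema_error(paste0("no stream files found under ", dir)))
  ids <- sub("^stream_(.*)\\.csv$", "\\1", basename(streams))
  imu_rows <- list(); pose_rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    st <- read_angle_stream(streams[i])
    sc <- score_stream(st)
    agg <- aggregate_rula(time_distribution(sc))
    imu_rows[[id]] <- data.frame(
      participant = id, overall = agg$overall,
      upper_arm = agg$per_region[["upper_arm_score"]],
      lower_arm = agg$per_region[["lower_arm_score"]],
      wrist = agg$per_region[["wrist_score"]],
      neck = agg$per_region[["neck_score"]],
      trunk = agg$per_region[["trunk_score"]])
    sag <- read_keypoints(file.path(dir, paste0("keypoints_sagittal_", id,
                                                ".json")))
    fro <- read_keypoints(file.path(dir, paste0("keypoints_frontal_", id,
                                                ".json")))
    ann <- read_annotations(file.path(dir, paste0("annotations_", id,
                                                  ".json")))
    r <- score_pose_capture(sag, fro, ann, cfg_pose)
    pose_rows[[id]] <- data.frame(
      participant = id, overall = r$grand, upper_arm = r$upper_arm_score,
      lower_arm = r$lower_arm_score, wrist = r$wrist_score,
      neck = r$neck_score, trunk = r$trunk_score)
  }
  list(imu = do.call(rbind, c(imu_rows, make.row.names = FALSE)),
       pose = do.call(rbind, c(pose_rows, make.row.names = FALSE)))
}

#' Write an agreement report as JSON
#'
#' @param fit A [rula_agreement()] fit.
#' @param path Output path.
#' @param seed Seed recorded for provenance (optional).
#' @export
write_agreement_report <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "rula_agreement"))
  fam <- lapply(fit$families, function(f) {
    list(kappa = if (is.null(f$kappa)) NULL else
           list(estimate = f$kappa$kappa, ci = f$kappa$ci,
                p = f$kappa$p_value, p_bonferroni = f$kappa_p_bonferroni),
         bland_altman = list(mean_diff = f$bland_altman$mean_diff,
                             sd_diff = f$bland_altman$sd_diff,
                             loa = f$bland_altman$loa),
         mannwhitney = list(U = f$mannwhitney$U,
                            p = f$mannwhitney$p_value,
                            p_bonferroni = f$mannwhitney_p_bonferroni,
                            rank_biserial = f$mannwhitney$rank_biserial),
         shapiro_p = f$shapiro$p_value)
  })
  jsonlite::write_json(
    list(methods = fit$method_names, n = fit$n, weights = fit$weights,
         bonferroni_m = fit$bonferroni_m, alpha = fit$alpha,
         power = fit$power, power_effect_size = fit$power_effect_size,
         seed = seed, families = fam),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Configuration keys mirror [cohort_config()] plus `weights`,
#' `bonferroni_m` and `alpha`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(schema_error(paste0("config file not found: ", path)))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}
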