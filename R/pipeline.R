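#' Pipeline configuration
#'
#' Declarative configuration of a full validation run.  Every protocol
#' parameter is exposed here with its validated default — Hampel
#' half-window 4 and threshold 1 robust SD, 3 Hz markerless / 5 Hz
#' marker-stream cutoffs, order 2, 30 Hz capture — nothing is hard-coded
#' in the run itself.
#'
#' @param fixture_dir Input directory (layout written by
#'   [make_fixtures()]: `segments.csv`, `swaps.csv`, and
#'   `<participant>/<hand>/pose/*.json` + `markers.tsv`).
#' @param out_dir Output directory for the report CSVs.
#' @param markerless_filter [filter_config()] for the markerless stream.
#' @param marker_filter [filter_config()] for the projected marker
#'   stream.
#' @param proj [projection()] used to take 3D markers to the image
#'   plane.
#' @param participants Optional character vector restricting the run to
#'   a subset of participant ids.
#' @param filter_target `"coordinates"` (default: clean the x/y keypoint
#'   series, then compute angles) or `"angles"` (compute angles from raw
#'   keypoints, then clean the angle series).
#' @param vertex_at_wrist Alternative inter-digit convention, see
#'   [inter_digit_angle()].
#' @param write_angles Also write the full per-frame angle table
#'   (`angles.csv`; large).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fixture_dir, out_dir,
                            markerless_filter = filter_config(
                              butter_cutoff = 3, use_hampel = TRUE),
                            marker_filter = filter_config(
                              butter_cutoff = 5, use_hampel = FALSE),
                            proj = projection(scale = 1),
                            participants = NULL,
                            filter_target = c("coordinates", "angles"),
                            vertex_at_wrist = FALSE,
                            write_angles = FALSE) {
  filter_target <- match.arg(filter_target)
  structure(list(fixture_dir = fixture_dir, out_dir = out_dir,
                 markerless_filter = markerless_filter,
                 marker_filter = marker_filter, proj = proj,
                 participants = participants,
                 filter_target = filter_target,
                 vertex_at_wrist = vertex_at_wrist,
                 write_angles = write_angles),
            class = "pipeline_config")
}

#' Write a complete synthetic fixture tree
#'
#' Simulates `n_participants` two-handed sessions and writes every
#' stream in the plain-text dialects the pipeline reads: per-frame
#' pose-JSON files, one marker TSV per hand, and the shared
#' `segments.csv` / `swaps.csv` annotations.  Re-running with the same
#' seed reproduces the tree byte for byte.
#'
#' @param out_dir Output directory (created).
#' @param n_participants Number of simulated participants.
#' @param seed Master seed; per-session seeds are derived from it.
#' @param ... Passed to [simulate_session()] (e.g. `cycle_s`,
#'   `jitter_sd`, `outlier_rate`).
#' @return Invisibly, a manifest list with `participants`, `segments`,
#'   `swaps` and the ground truth per session.
#' @export
make_fixtures <- function(out_dir, n_participants = 1, seed = 1, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- sprintf("P%02d", seq_len(n_participants))
  all_segments <- list(); all_swaps <- list(); truth <- list()
  for (i in seq_along(ids)) {
    for (hand in c("right", "left")) {
      s <- seed + 7919L * i + 3571L * (hand == "left")
      ses <- simulate_session(ids[i], hand, seed = s, ...)
      hand_dir <- file.path(out_dir, ids[i], hand)
      write_pose_json(ses$track, file.path(hand_dir, "pose"))
      write_marker_tsv(ses$markers, file.path(hand_dir, "markers.tsv"))
      all_segments[[paste(ids[i], hand)]] <- ses$segments
      all_swaps[[paste(ids[i], hand)]] <- ses$swaps
      truth[[paste(ids[i], hand, sep = "_")]] <- ses$truth
    }
  }
  segments <- activity_segments(do.call(rbind, all_segments))
  swaps <- do.call(rbind, all_swaps)
  rownames(swaps) <- NULL
  write_segments(segments, file.path(out_dir, "segments.csv"))
  write_swap_annotations(swaps, file.path(out_dir, "swaps.csv"))
  invisible(list(participants = ids, segments = segments, swaps = swaps,
                 truth = truth))
}

# stage wrapper: prefix errors with the failing stage's name
pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full validation pipeline
#'
#' Executes read -> project -> swap-correct -> gap-interpolate -> Hampel
#' -> Butterworth -> angle catalogs -> TAF -> agreement on a fixture
#' tree, and writes the report CSVs: `series_index.csv` (one row per
#' extracted angle series per source), `taf.csv`, `rmse.csv`,
#' `rmse_by_digit.csv`, `agreement_ba.csv`, `agreement_regression.csv`
#' and a deterministic `log.txt` with per-stage counts.  The run is
#' deterministic given its inputs; report files are removed if any stage
#' fails.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the report tables (`series_index`,
#'   `taf`, `rmse`, `report` from [aggregate_report()]), the per-session
#'   filter reports, and `out_dir`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fx <- config$fixture_dir
  segments <- pipeline_stage("read_segments",
    read_segments(file.path(fx, "segments.csv")))
  swap_path <- file.path(fx, "swaps.csv")
  swaps <- if (file.exists(swap_path))
    pipeline_stage("read_swaps", read_swap_annotations(swap_path))
  else NULL
  ids <- unique(segments$participant)
  if (!is.null(config$participants))
    ids <- intersect(ids, config$participants)
  if (!length(ids)) stop("pipeline stage [setup]: no participants to run")

  idx_rows <- list(); taf_rows <- list(); rmse_rows <- list()
  angle_rows <- list(); filter_reports <- list(); log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))

  for (id in ids) {
    for (hand in c("right", "left")) {
      hand_dir <- file.path(fx, id, hand)
      if (!dir.exists(hand_dir)) next
      key <- paste(id, hand, sep = "_")
      seg <- segments[segments$participant == id & segments$hand == hand, ]
      if (!nrow(seg)) next

      paths <- sort(list.files(file.path(hand_dir, "pose"),
                               pattern = "\\.json$", full.names = TRUE))
      ml_raw <- pipeline_stage("read_pose",
        read_pose_json(paths, hand_side = hand))
      logf("%s: read %d markerless frames", key, n_frames(ml_raw))

      sw <- if (!is.null(swaps))
        swaps[swaps$participant == id & swaps$hand == hand, ]
      else NULL
      ml_raw <- pipeline_stage("swap_correction",
        apply_swap_correction(ml_raw, sw))
      logf("%s: applied %d swap correction(s)", key,
           if (is.null(sw)) 0L else nrow(sw))

      markers <- pipeline_stage("read_markers",
        read_marker_tsv(file.path(hand_dir, "markers.tsv")))
      mk_raw <- pipeline_stage("project_markers",
        project_markers(markers, config$proj, hand_side = hand))
      logf("%s: projected %d marker frames", key, n_frames(mk_raw))

      if (config$filter_target == "coordinates") {
        mlf <- pipeline_stage("filter_markerless",
          filter_track(ml_raw, config$markerless_filter))
        mkf <- pipeline_stage("filter_markers",
          filter_track(mk_raw, config$marker_filter))
        ml <- mlf$track; mk <- mkf$track
        filter_reports[[key]] <- list(markerless = mlf$report,
                                      marker = mkf$report)
        logf("%s: flagged %d outlier sample(s), interpolated %d gap sample(s)",
             key, mlf$report$n_outliers, mlf$report$n_interpolated)
      } else {
        ml <- ml_raw; mk <- mk_raw
      }

      for (act in unique(seg$activity)) {
        cat_ <- build_angle_catalog(act, hand)
        a_ml <- pipeline_stage("angles",
          compute_catalog_angles(ml, cat_, config$vertex_at_wrist))
        a_mk <- pipeline_stage("angles",
          compute_catalog_angles(mk, cat_, config$vertex_at_wrist))
        if (config$filter_target == "angles") {
          a_ml <- apply(a_ml, 2L, clean_angle_series,
                        config = config$markerless_filter)
          a_mk <- apply(a_mk, 2L, clean_angle_series,
                        config = config$marker_filter)
        }
        for (r in which(seg$activity == act)) {
          s <- seg[r, ]
          rows <- (s$start_frame + 1L):s$end_frame
          for (src in c("markerless", "projected_marker")) {
            a <- if (src == "markerless") a_ml else a_mk
            sub <- a[rows, , drop = FALSE]
            idx_rows[[length(idx_rows) + 1L]] <- data.frame(
              participant = id, hand = hand, activity = act,
              repetition = s$repetition, angle_name = cat_$name,
              source = src, n_frames = nrow(sub),
              n_missing = colSums(is.na(sub)))
            taf_rows[[length(taf_rows) + 1L]] <- data.frame(
              participant = id, hand = hand, activity = act,
              repetition = s$repetition, angle_name = cat_$name,
              source = src,
              taf = apply(sub, 2L, function(v)
                suppressWarnings(total_active_flexion(v))))
            if (config$write_angles)
              angle_rows[[length(angle_rows) + 1L]] <- data.frame(
                participant = id, hand = hand, activity = act,
                repetition = s$repetition,
                angle_name = rep(cat_$name, each = nrow(sub)),
                source = src,
                frame = rep(rows - 1L, times = ncol(sub)),
                value_deg = as.vector(sub))
          }
          ag <- lapply(seq_len(nrow(cat_)), function(j)
            suppressWarnings(
              series_agreement(a_ml[rows, j], a_mk[rows, j])))
          rmse_rows[[length(rmse_rows) + 1L]] <- data.frame(
            participant = id, hand = hand, activity = act,
            repetition = s$repetition, angle_name = cat_$name,
            rmse = vapply(ag, `[[`, numeric(1L), "rmse"),
            mean_abs_diff = vapply(ag, `[[`, numeric(1L), "mean_abs_diff"),
            n = vapply(ag, `[[`, integer(1L), "n"))
        }
      }
    }
  }

  idx_all <- do.call(rbind, idx_rows)
  # one index row per extracted time series: an angle of one activity,
  # hand, participant and source (repetition segments pooled)
  series_index <- stats::aggregate(
    cbind(n_frames, n_missing) ~ participant + hand + activity +
      angle_name + source, data = idx_all, FUN = sum)
  n_reps <- stats::aggregate(
    repetition ~ participant + hand + activity + angle_name + source,
    data = idx_all, FUN = length)
  names(n_reps)[names(n_reps) == "repetition"] <- "n_reps"
  series_index <- merge(series_index, n_reps)
  series_index <- series_index[order(series_index$participant,
                                     series_index$hand,
                                     match(series_index$activity,
                                           activity_levels()),
                                     series_index$angle_name,
                                     series_index$source), ]
  rownames(series_index) <- NULL
  taf <- do.call(rbind, taf_rows); rownames(taf) <- NULL
  rmse <- do.call(rbind, rmse_rows); rownames(rmse) <- NULL
  logf("extracted %d angle series (%d per source)",
       nrow(series_index), nrow(series_index) %/% 2L)
  dropped <- sum(series_index$n_missing == series_index$n_frames)
  logf("series with all frames missing: %d", dropped)
  report <- pipeline_stage("aggregate", aggregate_report(rmse, taf))

  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  tryCatch({
    wr(series_index, "series_index.csv")
    wr(taf, "taf.csv")
    wr(rmse, "rmse.csv")
    wr(report$rmse_by_digit, "rmse_by_digit.csv")
    wr(report$bland_altman, "agreement_ba.csv")
    wr(report$regression, "agreement_regression.csv")
    if (config$write_angles)
      wr(do.call(rbind, angle_rows), "angles.csv")
    writeLines(log_lines, file.path(out, "log.txt"))
    written <- c(written, file.path(out, "log.txt"))
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage [write_report]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(list(series_index = series_index, taf = taf, rmse = rmse,
                 report = report, filter_reports = filter_reports,
                 log = log_lines, out_dir = out))
}

# gap-interpolate, optional Hampel, zero-phase smooth one angle series
clean_angle_series <- function(v, config) {
  v <- interpolate_gaps(v, config$max_gap)
  if (config$use_hampel && sum(!is.na(v)) > 2L * config$hampel_half_window)
    v <- hampel_filter(v, config$hampel_half_window, config$hampel_k)$filtered
  for (r in contiguous_runs(!is.na(v))) {
    if (length(r) > 3L * config$butter_order + 2L)
      v[r] <- butterworth_lowpass(v[r], config$butter_cutoff, config$fps,
                                  config$butter_order)
  }
  v
}
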