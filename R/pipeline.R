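# ---- file formats -----------------------------------------------------------

#' Write / read a marker track CSV
#'
#' Plain CSV, one row per frame, columns `frame,time_s,<MARKER>_x,<MARKER>_y`
#' (plus `_z` for 3D tracks), with `# key=value` comment headers recording
#' the frame rate and units. Frame numbers are 0-based; y increases upward.
#'
#' @param track Data frame as produced by [simulate_trial()].
#' @param path Output file.
#' @param fps Frame rate recorded in the header.
#' @param units `"m"` or `"px"`.
#' @export
write_marker_csv <- function(track, path, fps, units = c("m", "px")) {
  units <- match.arg(units)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fps=%g", fps), sprintf("# units=%s", units),
               "# frames=0-based, y-up"), con)
  cols <- c("frame", "time_s",
            intersect(unlist(lapply(.all_markers, function(m)
              paste0(m, c("_x", "_y", "_z")))), names(track)))
  utils::write.csv(track[cols], con, row.names = FALSE)
}

#' @rdname write_marker_csv
#' @return `read_marker_csv()`: the track data frame with attributes
#'   `fps` and `units`.
#' @export
read_marker_csv <- function(path) {
  hdr <- .read_hash_headers(path)
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "fps") <- as.numeric(hdr[["fps"]])
  attr(df, "units") <- hdr[["units"]]
  df
}

#' Write / read a vertical force CSV (`time_s,fz_n`, `# rate=` header)
#'
#' @param grf Output of [synth_grf()] (or a `force_signal`).
#' @param path File path.
#' @export
write_force_csv <- function(grf, path) {
  sig <- if (inherits(grf, "force_signal")) grf else grf$signal
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%g", sig$rate), con)
  tt <- (seq_along(sig$samples) - 1) / sig$rate
  utils::write.csv(data.frame(time_s = tt, fz_n = sig$samples), con,
                   row.names = FALSE)
}

#' @rdname write_force_csv
#' @return `read_force_csv()`: a `force_signal`.
#' @export
read_force_csv <- function(path) {
  hdr <- .read_hash_headers(path)
  df <- utils::read.csv(path, comment.char = "#")
  force_signal(df$fz_n, as.numeric(hdr[["rate"]]))
}

#' Write / read the long-format cohort angle table
#' @param cohort Data frame from [simulate_cohort()].
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(cohort, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  utils::write.csv(cohort, con, row.names = FALSE)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  hdr <- .read_hash_headers(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!is.null(hdr[["seed"]])) attr(df, "seed") <- as.integer(hdr[["seed"]])
  df
}

.read_hash_headers <- function(path) {
  out <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      k <- sub("=.*$", "", kv)
      out[[k]] <- sub("^[^=]*=", "", kv)
    }
  }
  out
}

# ---- run configuration ------------------------------------------------------

#' Study run configuration
#'
#' Bundles the cohort design, error model, camera, contrasts and
#' aggregation rule into one reproducible run description.
#'
#' @param cohort A `cohort_config`.
#' @param error An `error_model`.
#' @param camera A `camera_model`.
#' @param contrasts Character subset of `"intra_rater"`, `"inter_rater"`,
#'   `"system"`.
#' @param aggregation How repetitions are collapsed per design cell before
#'   reliability analysis: `"mean"` (default) or `"first"`.
#' @param inter_session Which session the inter-rater and system contrasts
#'   use (default 1).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), error = error_model(),
                       camera = camera_model(),
                       contrasts = c("intra_rater", "inter_rater", "system"),
                       aggregation = c("mean", "first"), inter_session = 1) {
  aggregation <- match.arg(aggregation)
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  if (length(contrasts) < 1) stop("run_config(): need at least one contrast")
  structure(list(cohort = cohort, error = error, camera = camera,
                 contrasts = contrasts, aggregation = aggregation,
                 inter_session = as.integer(inter_session)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the `cohort` / `error` / `camera` constructor arguments
#' plus `contrasts`, `aggregation` and `seed` at the top level.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  co <- do.call(cohort_config, as.list(y$cohort %||% list()))
  if (!is.null(y$seed)) co$seed <- as.integer(y$seed)
  errargs <- lapply(y$error %||% list(), function(v) {
    if (is.list(v)) unlist(v) else v
  })
  er <- do.call(error_model, errargs)
  camargs <- lapply(y$camera %||% list(), function(v) {
    if (is.list(v)) unlist(v) else v
  })
  cm <- do.call(camera_model, camargs)
  run_config(cohort = co, error = er, camera = cm,
             contrasts = y$contrasts %||% c("intra_rater", "inter_rater", "system"),
             aggregation = y$aggregation %||% "mean",
             inter_session = y$inter_session %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- aggregation and contrasts ---------------------------------------------

#' Collapse repetitions to one value per design cell
#'
#' @param cohort Long-format cohort table.
#' @param rule `"mean"` (average of the repetitions, default) or `"first"`.
#' @return Data frame `subject, session, observer, system, joint, angle_deg`.
#' @export
aggregate_repetitions <- function(cohort, rule = c("mean", "first")) {
  rule <- match.arg(rule)
  f <- if (rule == "mean") mean else function(x) x[1]
  stats::aggregate(angle_deg ~ subject + session + observer + system + joint,
                   data = cohort, FUN = f)
}

# subjects x 2 matrix for one contrast of the aggregated table
.contrast_matrix <- function(agg, joint, contrast, observer = 1, session = 1) {
  a <- agg[agg$joint == joint, ]
  pick <- switch(contrast,
    intra_rater = {
      a <- a[a$system == "video" & a$observer == observer, ]
      list(split_by = "session", levels = c(1, 2))
    },
    inter_rater = {
      a <- a[a$system == "video" & a$session == session, ]
      list(split_by = "observer", levels = c(1, 2))
    },
    system = {
      a <- a[a$observer == observer & a$session == session, ]
      list(split_by = "system", levels = c("video", "reference"))
    },
    stop("unknown contrast: ", contrast))
  x <- a[a[[pick$split_by]] == pick$levels[1], ]
  y <- a[a[[pick$split_by]] == pick$levels[2], ]
  x <- x[order(x$subject), ]; y <- y[order(y$subject), ]
  stopifnot(nrow(x) == nrow(y), all(x$subject == y$subject))
  m <- cbind(x$angle_deg, y$angle_deg)
  colnames(m) <- as.character(pick$levels)
  rownames(m) <- x$subject
  m
}

# ---- study orchestration ----------------------------------------------------

#' Run the full simulate -> extract -> aggregate -> agreement pipeline
#'
#' Simulates a cohort under the configured design, collapses repetitions,
#' and evaluates every configured contrast (intra-rater per observer,
#' inter-rater, video vs reference system) per joint: ICC (both single-
#' measures forms) with 95% CI and interpretation band, Bland-Altman bias
#' and limits of agreement, and a paired t test. Difference orders are
#' fixed: session1 - session2, observer1 - observer2, video - reference.
#'
#' @param config A `run_config`.
#' @param outdir Optional directory; when given, report CSVs, a JSON
#'   summary, Bland-Altman plot data and a YAML config echo are written.
#' @return List of class `study_report`.
#' @export
run_study <- function(config = run_config(), outdir = NULL) {
  cohort <- simulate_cohort(config$cohort, config$error, config$camera)
  agg <- aggregate_repetitions(cohort, config$aggregation)

  results <- list()
  ba_points <- list()
  specs <- list()
  if ("intra_rater" %in% config$contrasts) {
    for (o in seq_len(config$cohort$n_observers)) {
      specs[[length(specs) + 1L]] <- list(contrast = "intra_rater", observer = o)
    }
  }
  if ("inter_rater" %in% config$contrasts) {
    specs[[length(specs) + 1L]] <- list(contrast = "inter_rater", observer = NA)
  }
  if ("system" %in% config$contrasts) {
    specs[[length(specs) + 1L]] <- list(contrast = "system", observer = 1)
  }

  for (sp in specs) {
    for (j in .joints) {
      m <- .contrast_matrix(agg, j, sp$contrast,
                            observer = if (is.na(sp$observer)) 1 else sp$observer,
                            session = config$inter_session)
      icc_a <- icc_single(m, "absolute_agreement")
      icc_c <- icc_single(m, "consistency")
      ba <- bland_altman(m[, 1], m[, 2])
      tt <- paired_t(m[, 1], m[, 2])
      key <- paste0(sp$contrast,
                    if (sp$contrast == "intra_rater") paste0("_obs", sp$observer) else "",
                    ".", j)
      results[[key]] <- list(
        contrast = sp$contrast, observer = sp$observer, joint = j,
        mean_a = mean(m[, 1]), sd_a = stats::sd(m[, 1]),
        mean_b = mean(m[, 2]), sd_b = stats::sd(m[, 2]),
        icc = icc_a, icc_consistency = icc_c,
        bland_altman = ba, paired_t = tt)
      ba_points[[key]] <- ba$points
    }
  }

  report <- structure(list(results = results, config = config,
                           seed = config$cohort$seed,
                           n_rows = nrow(cohort),
                           package_version = as.character(
                             utils::packageVersion("gaitagree"))),
                      class = "study_report")
  if (!is.null(outdir)) {
    .write_report(report, cohort, ba_points, outdir)
  }
  report
}

.report_table <- function(report) {
  rows <- lapply(report$results, function(r) {
    data.frame(contrast = r$contrast,
               observer = ifelse(is.na(r$observer), NA_integer_, r$observer),
               joint = r$joint,
               mean_a = r$mean_a, sd_a = r$sd_a,
               mean_b = r$mean_b, sd_b = r$sd_b,
               icc = r$icc$estimate, ci_low = r$icc$ci_low,
               ci_high = r$icc$ci_high, band = r$icc$band,
               icc_consistency = r$icc_consistency$estimate,
               md = r$paired_t$md, md_ci_low = r$paired_t$ci_low,
               md_ci_high = r$paired_t$ci_high, p = r$paired_t$p,
               bias = r$bland_altman$bias, loa_low = r$bland_altman$loa_low,
               loa_high = r$bland_altman$loa_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate a study report
#' @param report A `study_report`.
#' @return One row per contrast x joint with ICC, Bland-Altman and paired-t
#'   columns.
#' @export
report_table <- function(report) .report_table(report)

.write_report <- function(report, cohort, ba_points, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfgfile <- file.path(outdir, "config.yaml")
  .write_config_yaml(report$config, cfgfile)
  cfg_hash <- unname(tools::md5sum(cfgfile))

  write_cohort_csv(cohort, file.path(outdir, "cohort.csv"))
  tab <- .report_table(report)
  utils::write.csv(tab, file.path(outdir, "agreement_tables.csv"),
                   row.names = FALSE)
  badir <- file.path(outdir, "bland_altman")
  dir.create(badir, showWarnings = FALSE)
  for (key in names(ba_points)) {
    r <- report$results[[key]]$bland_altman
    f <- file.path(badir, paste0(key, ".csv"))
    con <- file(f, "w")
    writeLines(sprintf("# bias=%.10g sd_diff=%.10g loa_low=%.10g loa_high=%.10g",
                       r$bias, r$sd_diff, r$loa_low, r$loa_high), con)
    utils::write.csv(ba_points[[key]], con, row.names = FALSE)
    close(con)
  }
  summary <- list(seed = report$seed, config_hash = cfg_hash,
                  package_version = report$package_version,
                  n_rows = report$n_rows,
                  results = lapply(report$results, function(r) list(
                    contrast = r$contrast, joint = r$joint,
                    icc = r$icc$estimate,
                    icc_ci = c(r$icc$ci_low, r$icc$ci_high),
                    band = r$icc$band,
                    icc_consistency = r$icc_consistency$estimate,
                    md = r$paired_t$md, p = r$paired_t$p,
                    loa = c(r$bland_altman$loa_low, r$bland_altman$loa_high))))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.write_config_yaml <- function(config, path) {
  y <- list(
    seed = config$cohort$seed,
    cohort = unclass(config$cohort),
    error = lapply(unclass(config$error), function(v)
      if (!is.null(names(v))) as.list(v) else v),
    camera = unclass(config$camera),
    contrasts = config$contrasts,
    aggregation = config$aggregation,
    inter_session = config$inter_session)
  yaml::write_yaml(y, path)
}

#' Write a small packaged mini-cohort for tests and examples
#'
#' Emits a 5-subject cohort table (default noise), one noise-free
#' orthographic demonstration trial (3D ground-truth marker CSV, digitized
#' 2D marker CSV, force CSV) and a JSON manifest of the trial's ground-truth
#' angles and event indices, against which the extraction pipeline can be
#' round-tripped.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Base seed.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(outdir, seed = 42) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort_config(n_subjects = 5, seed = seed)
  cohort <- simulate_cohort(cfg, error_model(), camera_model())
  write_cohort_csv(cohort, file.path(outdir, "mini_cohort.csv"))

  cam <- camera_model(projection = "orthographic")
  subj <- sample_subject(cfg, error_model_zero(), 1)
  trial <- simulate_trial(subj, NULL, error_model_zero(), cam,
                          seed = .substream(seed, 1, 1, tag = 500))
  write_marker_csv(trial$gt_track, file.path(outdir, "trial_markers_3d.csv"),
                   fps = cam$fps, units = "m")
  write_marker_csv(trial$observers[[1]]$track,
                   file.path(outdir, "trial_markers_2d.csv"),
                   fps = cam$fps, units = "m")
  write_force_csv(trial$force, file.path(outdir, "trial_force.csv"))
  manifest <- list(seed = seed,
                   true_ic_frame = trial$true_ic_frame,
                   true_crossing_sample = trial$force$true_crossing_sample,
                   true_angles_ic = as.list(trial$true_angles_ic),
                   fps = cam$fps, force_rate = trial$force$signal$rate,
                   subject_height_m = subj$seg$height)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
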