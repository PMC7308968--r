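#' Camera model for the video system
#'
#' Pinhole camera placed lateral to the sagittal plane of progression,
#' looking perpendicular to it. World coordinates: x = direction of
#' progression, y = up, z = mediolateral toward the camera (sagittal plane
#' at z = 0). Perspective projection returns pixel coordinates with y
#' measured upward; orthographic projection returns scaled in-plane
#' coordinates (metres at `ortho_scale = 1`) and is the `lateral_distance ->
#' Inf` limit of the perspective model.
#'
#' @param lateral_distance Camera distance from the sagittal plane, m.
#' @param height Camera height above the floor, m.
#' @param fps Video frame rate, frames/s.
#' @param resolution Pixel resolution `c(width, height)`.
#' @param focal_length Focal length in pixels.
#' @param projection `"perspective"` or `"orthographic"`.
#' @param axis_x World x where the principal axis crosses the plane, m.
#' @param ortho_scale Scale for orthographic output (default 1).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(lateral_distance = 2.5, height = 1.0, fps = 50,
                         resolution = c(1280, 720), focal_length = 1000,
                         projection = c("perspective", "orthographic"),
                         axis_x = 0, ortho_scale = 1) {
  projection <- match.arg(projection)
  stopifnot(fps > 0, lateral_distance > 0, focal_length > 0)
  structure(list(lateral_distance = lateral_distance, height = height,
                 fps = fps, resolution = resolution,
                 focal_length = focal_length, projection = projection,
                 axis_x = axis_x, ortho_scale = ortho_scale),
            class = "camera_model")
}

#' Project 3D marker positions to the camera image
#'
#' @param points3d Numeric matrix with columns x, y, z (world metres), or a
#'   length-3 vector.
#' @param cam A `camera_model`.
#' @return Matrix with columns `u`, `v` (pixels for perspective, in-plane
#'   units for orthographic; v increases upward in both).
#' @export
project_markers <- function(points3d, cam) {
  p <- if (is.null(dim(points3d))) matrix(points3d, ncol = 3) else as.matrix(points3d)
  if (cam$projection == "orthographic") {
    out <- cbind(u = cam$ortho_scale * (p[, 1]),
                 v = cam$ortho_scale * (p[, 2]))
    return(out)
  }
  depth <- cam$lateral_distance - p[, 3]
  if (any(depth <= 1e-6)) stop("project_markers(): point at or behind the camera plane")
  cx <- cam$resolution[1] / 2
  cy <- cam$resolution[2] / 2
  cbind(u = cam$focal_length * (p[, 1] - cam$axis_x) / depth + cx,
        v = cam$focal_length * (p[, 2] - cam$height) / depth + cy)
}

#' Measurement error model for the synthetic cohort
#'
#' Variance components of the simulated study design. All SDs must be
#' non-negative; with every SD and bias set to zero (and an orthographic
#' camera) the simulated measurements equal the ground truth exactly.
#'
#' @param sd_subject Between-subject SD of the initial-contact angles, deg;
#'   named per joint or scalar. Defaults to the observed spread of healthy
#'   adults (hip 5.7, knee 3.8, ankle 3.7).
#' @param ic_mean Population mean initial-contact angles, deg
#'   (hip 33.06, knee 4.55, ankle -7.77).
#' @param sd_session Marker re-placement SD between sessions, metres, named
#'   per marker (re-palpation error is landmark-dependent) or scalar.
#'   Resampled per session, fixed within a session.
#' @param sd_observer_frame SD of the observer's initial-contact frame
#'   selection error, frames.
#' @param sd_digitize SD of the observer's marker-click jitter, pixels.
#' @param system_bias Additive per-joint offset of the emulated reference
#'   system relative to ground truth, deg; the realized video-minus-reference
#'   bias is this plus the perspective-projection contribution (about +0.4
#'   to +0.7 deg per joint with the default camera).
#' @param sd_system Reference-system trial noise SD, deg.
#' @param sd_system_subject Subject-level SD of the video-vs-reference
#'   disagreement, deg (model-definition differences vary with anatomy).
#' @param sd_residual Stride-to-stride SD of the true IC angles, deg.
#' @param sd_force Force-plate noise SD, N.
#' @return Object of class `error_model`.
#' @export
error_model <- function(
    sd_subject = c(hip = 5.7, knee = 3.8, ankle = 3.7),
    ic_mean = c(hip = 33.06, knee = 4.55, ankle = -7.77),
    sd_session = c(ASIS = 0.0035, PSIS = 0.0035, GT = 0.006, THI = 0.008,
                   LFC = 0.0045, TIB = 0.008, LM = 0.004, CAL = 0.002,
                   MT2 = 0.002),
    sd_observer_frame = 0.5,
    sd_digitize = 1.0,
    system_bias = c(hip = 0.4, knee = 1.6, ankle = -2.0),
    sd_system = 1.0,
    sd_system_subject = 1.2,
    sd_residual = 1.2,
    sd_force = 1.0) {
  sd_subject <- .per_joint(sd_subject)
  ic_mean <- .per_joint(ic_mean)
  system_bias <- .per_joint(system_bias)
  sd_session <- .per_marker(sd_session)
  sds <- c(sd_subject, sd_session, sd_observer_frame, sd_digitize,
           sd_system, sd_system_subject, sd_residual, sd_force)
  if (any(sds < 0)) stop("error_model(): all SDs must be >= 0")
  structure(list(sd_subject = sd_subject, ic_mean = ic_mean,
                 sd_session = sd_session,
                 sd_observer_frame = sd_observer_frame,
                 sd_digitize = sd_digitize, system_bias = system_bias,
                 sd_system = sd_system,
                 sd_system_subject = sd_system_subject,
                 sd_residual = sd_residual, sd_force = sd_force),
            class = "error_model")
}

#' Zero-noise error model (all SDs and biases zero)
#' @return An `error_model` whose measurements reproduce ground truth.
#' @export
error_model_zero <- function() {
  error_model(sd_subject = c(hip = 5.7, knee = 3.8, ankle = 3.7),
              sd_session = 0, sd_observer_frame = 0, sd_digitize = 0,
              system_bias = c(hip = 0, knee = 0, ankle = 0),
              sd_system = 0, sd_system_subject = 0, sd_residual = 0,
              sd_force = 0)
}

.joints <- c("hip", "knee", "ankle")

.per_joint <- function(x) {
  if (length(x) == 1 && is.null(names(x))) x <- rep(x, 3)
  if (is.null(names(x))) names(x) <- .joints
  stopifnot(all(.joints %in% names(x)))
  x[.joints]
}

.per_marker <- function(x) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- stats::setNames(rep(x, length(.all_markers)), .all_markers)
  }
  stopifnot(all(.all_markers %in% names(x)))
  x[.all_markers]
}

#' Cohort design configuration
#'
#' @param n_subjects,n_sessions,n_repetitions,n_observers Design counts
#'   (defaults 50, 2, 5, 2: the reliability-study design this generator
#'   emulates).
#' @param systems Measurement systems (video = 2D digitized, reference =
#'   emulated 3D optical system).
#' @param seed Base RNG seed; identical seed gives a bit-identical cohort.
#'   Hierarchical substreams per subject/session mean that adding subjects
#'   does not perturb existing ones.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50, n_sessions = 2, n_repetitions = 5,
                          n_observers = 2, systems = c("video", "reference"),
                          seed = 1) {
  counts <- c(n_subjects, n_sessions, n_repetitions, n_observers)
  if (any(counts < 1)) stop("cohort_config(): all counts must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_repetitions = as.integer(n_repetitions),
                 n_observers = as.integer(n_observers),
                 systems = systems, seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic substream seed (kept below 2^31)
.substream <- function(base, i = 0, s = 0, tag = 0) {
  as.integer((as.numeric(base) + i * 100003 + s * 1013 + tag * 7919) %% 2147483629)
}

# --- gait angle profiles -----------------------------------------------------

# Coarse normative sagittal profiles over the gait cycle (t = 0 at initial
# contact), degrees; smoothed by a two-harmonic least-squares fit. Shapes
# only: each subject's curve is shifted to pass exactly through the drawn
# initial-contact targets.
.base_profiles <- list(
  t = seq(0, 0.9, by = 0.1),
  hip   = c(30, 26, 17, 7, -3, -9, -5, 10, 25, 30),
  knee  = c(5, 15, 15, 8, 4, 8, 35, 60, 45, 15),
  ankle = c(0, -5, 3, 7, 9, 6, -12, -8, -2, 0),
  tilt  = c(1, 0.5, -0.5, -1, 0, 1, 0.5, -0.5, -1, 0)
)

.harm_basis <- function(t) {
  cbind(1, cos(2 * pi * t), sin(2 * pi * t), cos(4 * pi * t), sin(4 * pi * t))
}

.harm_fit <- function(t, y) {
  X <- .harm_basis(t)
  qr.solve(X, y)
}

.harm_eval <- function(coef, t) drop(.harm_basis(t %% 1) %*% coef)

#' Subject-level gait angle profile
#'
#' Continuous periodic hip/knee/ankle/pelvic-tilt curves over the normalized
#' gait cycle (phase 0 = initial contact), built as two-harmonic fits to a
#' coarse normative shape and shifted additively so that each joint curve
#' passes exactly through the subject's drawn initial-contact targets.
#'
#' @param ic_targets Named vector `c(hip=, knee=, ankle=)`, deg.
#' @param mean_tilt Mean anterior pelvic tilt, deg (ASIS below PSIS).
#' @return Object of class `gait_profile` with `$angle(joint, t)`.
#' @export
gait_profile <- function(ic_targets, mean_tilt = 10) {
  ic_targets <- .per_joint(ic_targets)
  coefs <- list(
    hip = .harm_fit(.base_profiles$t, .base_profiles$hip),
    knee = .harm_fit(.base_profiles$t, .base_profiles$knee),
    ankle = .harm_fit(.base_profiles$t, .base_profiles$ankle),
    tilt = .harm_fit(.base_profiles$t, .base_profiles$tilt)
  )
  shift <- c(hip = unname(ic_targets["hip"] - .harm_eval(coefs$hip, 0)),
             knee = unname(ic_targets["knee"] - .harm_eval(coefs$knee, 0)),
             ankle = unname(ic_targets["ankle"] - .harm_eval(coefs$ankle, 0)),
             tilt = mean_tilt)
  obj <- list(ic_targets = ic_targets, t_ic = 0, coefs = coefs, shift = shift)
  obj$angle <- function(joint, t) .harm_eval(coefs[[joint]], t) + shift[[joint]]
  structure(obj, class = "gait_profile")
}

# --- segments ----------------------------------------------------------------

#' Segment geometry of the modelled left lower limb
#'
#' Lengths in metres; `marker_z` gives each marker's fixed mediolateral
#' offset toward the camera (lateral markers sit closer to the camera than
#' medial ones, which is what makes perspective projection distort the
#' sagittal geometry).
#'
#' @param height Subject stature, m.
#' @return Object of class `segment_model`.
#' @export
segment_model <- function(height = 1.67) {
  stopifnot(height > 0)
  structure(list(
    height = height,
    pelvis_depth = 0.10 * height,      # ASIS-PSIS sagittal separation
    thigh_length = 0.245 * height,
    shank_length = 0.246 * height,
    heel_offset = 0.05,                # CAL behind the ankle, along foot line
    toe_offset = 0.14,                 # MT2 in front of the ankle
    foot_drop = 0.04,                  # ankle-to-foot-line offset along shank
    pelvis_marker_up = 0.085,          # ASIS/PSIS height above GT, pelvis frame
    gt_height = 0.53 * height,         # greater trochanter standing height
    marker_z = c(ASIS = 0.10, PSIS = 0.04, GT = 0.09, THI = 0.07,
                 LFC = 0.05, TIB = 0.045, LM = 0.04, CAL = 0.035, MT2 = 0.03)
  ), class = "segment_model")
}

.rot <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# guard ranges for anatomically plausible sagittal angles (deg)
.angle_guard <- list(hip = c(-40, 70), knee = c(-15, 100), ankle = c(-50, 45),
                     tilt = c(-20, 30))

#' Forward kinematics: marker positions for a gait phase
#'
#' Planar linkage realizing the sagittal angle conventions: the thigh hangs
#' from the greater trochanter at `hip` degrees anterior of the pelvis
#' perpendicular, the shank flexes posteriorly by `knee`, and the foot line
#' rotates `ankle` degrees of dorsiflexion off the shank perpendicular.
#' During early stance the whole body is lowered so that the heel stays on
#' the floor (foot-flat), emulating ground contact without altering any
#' joint angle. Recomputing the three angle constructions from the returned
#' noise-free markers reproduces the profile angles exactly.
#'
#' @param profile A `gait_profile`.
#' @param seg A `segment_model`.
#' @param t Gait-cycle phases in `[0, 1)` (vectorized).
#' @param placement Optional named list of per-marker placement offsets
#'   `c(parallel, perpendicular)` in metres, applied in each marker's
#'   segment frame (skin-fixed marker placement error).
#' @param x_offset Forward translation per phase (recycled), m.
#' @param angle_shift Optional named per-joint additive shift, deg (trial
#'   stride-to-stride deviation).
#' @param guard Check angles against anatomical guard ranges (default TRUE).
#' @return Data frame with `t` and `<MARKER>_x/_y/_z` columns (metres).
#' @export
pose_leg <- function(profile, seg, t, placement = NULL, x_offset = 0,
                     angle_shift = NULL, guard = TRUE) {
  stopifnot(all(t >= 0), all(t < 1))
  x_offset <- rep_len(x_offset, length(t))
  shift <- c(hip = 0, knee = 0, ankle = 0)
  if (!is.null(angle_shift)) shift[names(angle_shift)] <- angle_shift

  hip <- profile$angle("hip", t) + shift["hip"]
  knee <- profile$angle("knee", t) + shift["knee"]
  ankle <- profile$angle("ankle", t) + shift["ankle"]
  tilt <- profile$angle("tilt", t)
  if (guard) {
    vals <- list(hip = hip, knee = knee, ankle = ankle, tilt = tilt)
    for (j in names(vals)) {
      g <- .angle_guard[[j]]
      if (any(vals[[j]] < g[1] | vals[[j]] > g[2])) {
        stop(sprintf("pose_leg(): %s angle outside anatomical guard [%g, %g] deg",
                     j, g[1], g[2]))
      }
    }
  }

  n <- length(t)
  out <- data.frame(t = t)
  pos <- list()
  for (m in .all_markers) pos[[m]] <- matrix(0, n, 2)

  # heel-clamp references: heel height at initial contact and at the start
  # of terminal descent, computed without placement error
  base_cal_y <- .heel_y_raw(profile, seg, 0, shift)
  desc_cal_y <- max(.heel_y_raw(profile, seg, .descent_start, shift), base_cal_y)

  for (i in seq_len(n)) {
    th <- tilt[i]
    p_dir <- .rot(-th) %*% c(1, 0)          # pelvis line, anterior
    perp_up <- .rot(-th) %*% c(0, 1)
    caudal <- -perp_up
    gt <- c(0, seg$gt_height)
    mid <- gt + seg$pelvis_marker_up * perp_up
    asis <- mid + 0.5 * seg$pelvis_depth * p_dir
    psis <- mid - 0.5 * seg$pelvis_depth * p_dir
    thigh_dir <- .rot(hip[i]) %*% caudal
    lfc <- gt + seg$thigh_length * thigh_dir
    shank_dir <- .rot(-knee[i]) %*% thigh_dir
    lm <- lfc + seg$shank_length * shank_dir
    foot_dir <- .rot(ankle[i]) %*% (.rot(90) %*% shank_dir)
    foot_origin <- lm + seg$foot_drop * shank_dir
    cal <- foot_origin - seg$heel_offset * foot_dir
    mt2 <- foot_origin + seg$toe_offset * foot_dir
    thi <- gt + 0.5 * seg$thigh_length * thigh_dir
    tib <- lfc + 0.5 * seg$shank_length * shank_dir

    # ground-contact emulation: translate the whole body vertically so that
    # the heel (i) stays on the floor through foot-flat (phase 0 to 0.34,
    # cosine release), (ii) never drops below the floor in stance, and
    # (iii) descends smoothly onto the floor through terminal swing with
    # zero vertical velocity at contact. Translation only: no joint angle
    # is altered.
    heel_target <- .heel_target(t[i], cal[2], base_cal_y, desc_cal_y)
    dy <- cal[2] - heel_target
    dv <- c(x_offset[i], -dy)

    frames <- list(ASIS = asis, PSIS = psis, GT = gt, THI = thi, LFC = lfc,
                   TIB = tib, LM = lm, CAL = cal, MT2 = mt2)
    dirs <- list(ASIS = p_dir, PSIS = p_dir, GT = p_dir, THI = thigh_dir,
                 LFC = thigh_dir, TIB = shank_dir, LM = shank_dir,
                 CAL = foot_dir, MT2 = foot_dir)
    for (m in .all_markers) {
      p <- frames[[m]] + dv
      if (!is.null(placement) && !is.null(placement[[m]])) {
        d <- dirs[[m]]
        off <- placement[[m]]
        p <- p + off[1] * d + off[2] * (.rot(90) %*% d)
      }
      pos[[m]][i, ] <- p
    }
  }
  for (m in .all_markers) {
    out[[paste0(m, "_x")]] <- pos[[m]][, 1]
    out[[paste0(m, "_y")]] <- pos[[m]][, 2]
    out[[paste0(m, "_z")]] <- rep(seg$marker_z[[m]], n)
  }
  out
}

.descent_start <- 0.75   # phase where terminal heel descent begins

# desired heel height at phase t given the raw (unclamped) height `raw`,
# the contact height `base` and the height at descent start `desc`
.heel_target <- function(t, raw, base, desc) {
  if (t <= 0.34) return(base)                       # foot-flat plateau
  if (t < 0.44) {                                   # cosine release
    w <- 0.5 * (1 + cos(pi * (t - 0.34) / 0.10))
    return(base + (1 - w) * max(raw - base, 0))
  }
  if (t < .descent_start) return(max(raw, base))    # swing, floor-limited
  u <- (1 - t) / (1 - .descent_start)               # terminal descent
  base + (desc - base) * u^2 * (3 - 2 * u)          # smoothstep to floor
}

# raw heel height (no clamp, no placement) at a phase
.heel_y_raw <- function(profile, seg, t, angle_shift = NULL) {
  shift <- c(hip = 0, knee = 0, ankle = 0)
  if (!is.null(angle_shift)) shift[names(angle_shift)] <- angle_shift
  hip <- profile$angle("hip", t) + shift[["hip"]]
  knee <- profile$angle("knee", t) + shift[["knee"]]
  ankle <- profile$angle("ankle", t) + shift[["ankle"]]
  tilt <- profile$angle("tilt", t)
  caudal <- .rot(-tilt) %*% c(0, -1)
  thigh_dir <- .rot(hip) %*% caudal
  shank_dir <- .rot(-knee) %*% thigh_dir
  foot_dir <- .rot(ankle) %*% (.rot(90) %*% shank_dir)
  gt <- c(0, seg$gt_height)
  lm <- gt + seg$thigh_length * thigh_dir + seg$shank_length * shank_dir
  cal <- lm + seg$foot_drop * shank_dir - seg$heel_offset * foot_dir
  cal[2]
}

# --- subject and trial simulation -------------------------------------------

#' Draw one synthetic subject
#'
#' Anthropometry (height-scaled segment lengths) and subject-level initial-
#' contact angle targets drawn from the configured population model. Height
#' draws outside a plausible adult range are rejected and resampled.
#'
#' @param config A `cohort_config`.
#' @param err An `error_model`.
#' @param subject_id Integer subject index (drives the RNG substream).
#' @return List with `seg` (segment_model), `profile` (gait_profile),
#'   `ic_targets`, `cadence_s` (cycle duration), `speed_ms`, `mass_kg`,
#'   `system_offset` (subject-level video-vs-reference deviation, deg).
#' @export
sample_subject <- function(config, err = error_model(), subject_id = 1) {
  set.seed(.substream(config$seed, i = subject_id, tag = 1))
  height <- .truncated_normal(1.6749, 0.2557, 1.40, 2.00)
  mass <- .truncated_normal(65.74, 12.94, 40, 120)
  targets <- stats::rnorm(3, mean = err$ic_mean, sd = err$sd_subject)
  names(targets) <- .joints
  cadence <- .truncated_normal(1.05, 0.05, 0.9, 1.25)
  speed <- .truncated_normal(1.25 * height / 1.67, 0.1, 0.8, 1.8)
  sys_off <- stats::rnorm(3, 0, err$sd_system_subject)
  names(sys_off) <- .joints
  list(seg = segment_model(height), profile = gait_profile(targets),
       ic_targets = targets, cadence_s = cadence, speed_ms = speed,
       mass_kg = mass, system_offset = sys_off, subject_id = subject_id)
}

.truncated_normal <- function(mean, sd, lo, hi, max_tries = 200) {
  if (sd == 0) return(min(max(mean, lo), hi))
  rejected <- 0L
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) {
      if (rejected > 0) {
        .log_rejections(rejected)
      }
      return(x)
    }
    rejected <- rejected + 1L
  }
  stop("degenerate draw: no value inside [", lo, ", ", hi, "] after ",
       max_tries, " tries")
}

.rejection_env <- new.env(parent = emptyenv())
.rejection_env$n <- 0L
.log_rejections <- function(k) {
  .rejection_env$n <- .rejection_env$n + k
}

#' Draw the per-session marker placement offsets for one subject
#'
#' @param config A `cohort_config`.
#' @param err An `error_model`.
#' @param subject_id,session Integer indices.
#' @return Named list: marker -> `c(parallel, perpendicular)` offset, m.
#' @export
sample_session_placement <- function(config, err, subject_id, session) {
  set.seed(.substream(config$seed, i = subject_id, s = session, tag = 2))
  out <- list()
  for (m in .all_markers) {
    out[[m]] <- stats::rnorm(2, 0, err$sd_session[[m]])
  }
  out
}

#' Synthesize a vertical ground-reaction-force signal
#'
#' Zero through swing, rises steeply at contact to slightly above body
#' weight, plateaus through stance and unloads before toe-off. The
#' noise-free threshold-crossing sample (20 N) is recorded as ground truth.
#'
#' @param weight_n Body weight, N.
#' @param tc_time Contact time, s.
#' @param rate Sampling rate, Hz (default 1000).
#' @param duration Signal duration, s.
#' @param stance_s Stance duration, s.
#' @param sd_noise Additive Gaussian noise SD, N.
#' @param threshold Threshold whose crossing is recorded, N (default 20).
#' @return List: `signal` (a `force_signal`), `true_crossing_sample`
#'   (0-based, first noise-free sample >= threshold), `tc_time`.
#' @export
synth_grf <- function(weight_n, tc_time, rate = 1000, duration = 2.4,
                      stance_s = 0.7, sd_noise = 0, threshold = 20) {
  stopifnot(rate > 0, tc_time >= 0, tc_time < duration)
  tt <- seq(0, duration - 1 / rate, by = 1 / rate)
  u <- (tt - tc_time) / stance_s
  f <- ifelse(u > 0 & u < 1, 1.1 * weight_n * sin(pi * pmin(pmax(u, 0), 1))^0.7, 0)
  cross <- which(f >= threshold)
  if (length(cross) == 0) stop("synth_grf(): contact never reaches threshold")
  clean_cross <- cross[1] - 1L
  if (sd_noise > 0) f <- f + stats::rnorm(length(f), 0, sd_noise)
  list(signal = force_signal(f, rate), true_crossing_sample = clean_cross,
       tc_time = tc_time)
}

#' Simulate one recorded walking trial
#'
#' Produces the full trial dataset: noise-free 3D ground-truth marker track,
#' the marker track with this session's placement offsets, per-observer
#' digitized 2D tracks, the force signal, and the ground-truth angles and
#' event indices.
#'
#' @param subject Output of [sample_subject()].
#' @param placement Output of [sample_session_placement()] (session marker
#'   offsets; identical across the session's repetitions).
#' @param err An `error_model`.
#' @param cam A `camera_model`.
#' @param duration Trial length, s.
#' @param force_rate Force sampling rate, Hz.
#' @param seed RNG seed for the trial-level draws.
#' @return List of class `trial_dataset`.
#' @export
simulate_trial <- function(subject, placement, err, cam, duration = 2.4,
                           force_rate = 1000, seed = 1) {
  set.seed(seed)
  fps <- cam$fps
  n_frames <- as.integer(round(duration * fps))
  # trial-level stride deviation of the true IC angles
  delta <- stats::rnorm(3, 0, err$sd_residual)
  names(delta) <- .joints
  true_ic_frame <- as.integer(round(n_frames / 2)) +
    sample.int(11L, 1L) - 6L   # jitter -5..+5 frames
  tic_time <- true_ic_frame / fps
  tt <- (seq_len(n_frames) - 1) / fps
  phase <- ((tt - tic_time) / subject$cadence_s) %% 1
  x_off <- subject$speed_ms * (tt - tic_time)

  gt_track <- pose_leg(subject$profile, subject$seg, phase,
                       placement = NULL, x_offset = x_off,
                       angle_shift = delta)
  placed_track <- pose_leg(subject$profile, subject$seg, phase,
                           placement = placement, x_offset = x_off,
                           angle_shift = delta)
  gt_track$frame <- placed_track$frame <- seq_len(n_frames) - 1L
  gt_track$time_s <- placed_track$time_s <- tt

  true_angles <- subject$ic_targets + delta[.joints]
  names(true_angles) <- .joints

  grf <- synth_grf(subject$mass_kg * 9.81, tic_time, rate = force_rate,
                   duration = duration, sd_noise = err$sd_force)

  # per-observer digitized 2D tracks
  px_scale <- cam$focal_length / cam$lateral_distance   # px per metre
  observers <- list()
  for (o in 1:2) {
    frame_err <- as.integer(round(stats::rnorm(1, 0, err$sd_observer_frame)))
    obs <- .project_track(placed_track, cam)
    if (err$sd_digitize > 0) {
      jit_sd <- if (cam$projection == "perspective") err$sd_digitize
                else err$sd_digitize / px_scale
      for (m in .all_markers) {
        obs[[paste0(m, "_x")]] <- obs[[paste0(m, "_x")]] +
          stats::rnorm(nrow(obs), 0, jit_sd)
        obs[[paste0(m, "_y")]] <- obs[[paste0(m, "_y")]] +
          stats::rnorm(nrow(obs), 0, jit_sd)
      }
    }
    observers[[o]] <- list(track = obs, ic_frame = true_ic_frame + frame_err)
  }

  structure(list(gt_track = gt_track, placed_track = placed_track,
                 observers = observers, force = grf,
                 true_ic_frame = true_ic_frame,
                 true_angles_ic = true_angles,
                 fps = fps, duration = duration,
                 meta = list(subject = subject$subject_id)),
            class = "trial_dataset")
}

.project_track <- function(track, cam) {
  out <- data.frame(frame = track$frame, time_s = track$time_s)
  for (m in .all_markers) {
    p <- cbind(track[[paste0(m, "_x")]], track[[paste0(m, "_y")]],
               track[[paste0(m, "_z")]])
    uv <- project_markers(p, cam)
    out[[paste0(m, "_x")]] <- uv[, 1]
    out[[paste0(m, "_y")]] <- uv[, 2]
  }
  out
}

# fast path used by simulate_cohort: same generative model as
# simulate_trial, but poses are evaluated only at the frames actually
# digitized, and no force/track tables are materialized
.measure_trial <- function(subject, placement, err, cam, seed,
                           duration = 2.4) {
  set.seed(seed)
  fps <- cam$fps
  n_frames <- as.integer(round(duration * fps))
  delta <- stats::rnorm(3, 0, err$sd_residual)
  names(delta) <- .joints
  true_ic_frame <- as.integer(round(n_frames / 2)) + sample.int(11L, 1L) - 6L
  tic_time <- true_ic_frame / fps
  true_angles <- subject$ic_targets + delta[.joints]
  px_scale <- cam$focal_length / cam$lateral_distance

  video <- list()
  for (o in 1:2) {
    frame_err <- as.integer(round(stats::rnorm(1, 0, err$sd_observer_frame)))
    fr <- true_ic_frame + frame_err
    t_abs <- fr / fps
    ph <- ((t_abs - tic_time) / subject$cadence_s) %% 1
    pose <- pose_leg(subject$profile, subject$seg, ph, placement = placement,
                     x_offset = subject$speed_ms * (t_abs - tic_time),
                     angle_shift = delta)
    uvrow <- .project_track(cbind(pose, frame = fr, time_s = t_abs), cam)
    if (err$sd_digitize > 0) {
      jit_sd <- if (cam$projection == "perspective") err$sd_digitize
                else err$sd_digitize / px_scale
      for (m in .all_markers) {
        uvrow[[paste0(m, "_x")]] <- uvrow[[paste0(m, "_x")]] +
          stats::rnorm(1, 0, jit_sd)
        uvrow[[paste0(m, "_y")]] <- uvrow[[paste0(m, "_y")]] +
          stats::rnorm(1, 0, jit_sd)
      }
    }
    a <- angles_at_ic(frame_from_track(uvrow, 1), warn_guard = FALSE)
    video[[o]] <- c(hip = a$hip_deg, knee = a$knee_deg, ankle = a$ankle_deg)
  }
  ref <- true_angles - err$system_bias + subject$system_offset +
    stats::rnorm(3, 0, err$sd_system)
  names(ref) <- .joints
  list(video = video, reference = ref, true_angles = true_angles,
       true_ic_frame = true_ic_frame)
}

#' Simulate a full reliability-study cohort
#'
#' Runs the generative model over the whole design (subjects x sessions x
#' repetitions x observers x systems) and returns the long-format angle
#' table consumed by the agreement statistics. The reference system is
#' emulated as ground truth plus configured bias/noise and does not depend
#' on the observer; its rows are repeated per observer so the design stays
#' fully crossed.
#'
#' @param config A `cohort_config`.
#' @param err An `error_model`.
#' @param cam A `camera_model`.
#' @return Data frame `subject, session, observer, system, repetition,
#'   joint, angle_deg` with the config attached as attributes.
#' @export
simulate_cohort <- function(config = cohort_config(), err = error_model(),
                            cam = camera_model()) {
  .rejection_env$n <- 0L
  rows <- vector("list", config$n_subjects * config$n_sessions *
                   config$n_repetitions)
  idx <- 1L
  for (i in seq_len(config$n_subjects)) {
    subj <- sample_subject(config, err, i)
    for (s in seq_len(config$n_sessions)) {
      placement <- sample_session_placement(config, err, i, s)
      for (r in seq_len(config$n_repetitions)) {
        m <- .measure_trial(subj, placement, err, cam,
                            seed = .substream(config$seed, i, s, tag = 100 + r))
        blocks <- list()
        for (o in seq_len(config$n_observers)) {
          if ("video" %in% config$systems) {
            blocks[[length(blocks) + 1L]] <- data.frame(
              subject = i, session = s, observer = o, system = "video",
              repetition = r, joint = .joints,
              angle_deg = unname(m$video[[o]][.joints]))
          }
          if ("reference" %in% config$systems) {
            blocks[[length(blocks) + 1L]] <- data.frame(
              subject = i, session = s, observer = o, system = "reference",
              repetition = r, joint = .joints,
              angle_deg = unname(m$reference[.joints]))
          }
        }
        rows[[idx]] <- do.call(rbind, blocks)
        idx <- idx + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (.rejection_env$n > 0) {
    message("simulate_cohort(): ", .rejection_env$n,
            " out-of-range anthropometry draws were rejected and resampled")
  }
  attr(out, "seed") <- config$seed
  attr(out, "config") <- config
  out
}
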