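#' Unsigned angle at a vertex
#'
#' Inner angle between the rays `v -> a` and `v -> b`, in degrees, as a
#' manual video "angle tool" would report it. Computed with a two-argument
#' arctangent of the cross and dot products, which is numerically stable for
#' nearly collinear rays.
#'
#' @param a,v,b Numeric length-2 points; `v` is the vertex.
#' @return Angle in degrees in `[0, 180]`.
#' @examples
#' angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)) # 90
#' @export
angle_at_vertex <- function(a, v, b) {
  u <- as.numeric(a) - as.numeric(v)
  w <- as.numeric(b) - as.numeric(v)
  if (sum(u^2) == 0 || sum(w^2) == 0) {
    stop("angle_at_vertex(): a point coincides with the vertex")
  }
  cross <- u[1] * w[2] - u[2] * w[1]
  dot <- u[1] * w[1] + u[2] * w[2]
  atan2(abs(cross), dot) * 180 / pi
}

#' Signed planar angle from a reference direction to a target direction
#'
#' Counter-clockwise angle (degrees, in `(-180, 180]`) from `reference_dir`
#' to `target_dir`. With the package convention (x = direction of
#' progression, y = up), a caudally pointing reference rotated toward +x
#' (anteriorly) gives positive values, which is how the flexion-positive
#' signs of the joint angles are realized.
#'
#' @param reference_dir,target_dir Numeric length-2 nonzero vectors.
#' @return Signed angle in degrees.
#' @export
signed_angle_from <- function(reference_dir, target_dir) {
  u <- as.numeric(reference_dir)
  w <- as.numeric(target_dir)
  if (sum(u^2) == 0 || sum(w^2) == 0) stop("signed_angle_from(): zero vector")
  cross <- u[1] * w[2] - u[2] * w[1]
  dot <- u[1] * w[1] + u[2] * w[2]
  ang <- atan2(cross, dot) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Required markers for the three sagittal constructions. THI and TIB are
# carried in files but take no part in any angle.
.required_markers <- c("ASIS", "PSIS", "GT", "LFC", "LM", "CAL", "MT2")
.all_markers <- c("ASIS", "PSIS", "GT", "THI", "LFC", "TIB", "LM", "CAL", "MT2")

#' Assemble a single-frame marker set
#'
#' A `marker_frame` is a named list of 2D points (consistent units, metres or
#' pixels, y measured upward) for one video frame. If the pelvis markers show
#' the subject walking toward -x (ASIS behind PSIS), the frame is mirrored so
#' that progression is always +x; all signed angle conventions assume this.
#'
#' @param ... Named numeric length-2 points, e.g. `ASIS = c(x, y)`.
#' @param frame_index Optional 0-based frame number.
#' @param time_s Optional time stamp, seconds.
#' @param normalize Flip x so the subject faces +x (default `TRUE`).
#' @return Object of class `marker_frame`.
#' @export
marker_frame <- function(..., frame_index = NA_integer_, time_s = NA_real_,
                         normalize = TRUE) {
  pts <- list(...)
  missing <- setdiff(.required_markers, names(pts))
  if (length(missing) > 0) {
    stop("marker_frame(): missing markers: ", paste(missing, collapse = ", "))
  }
  pts <- lapply(pts, function(p) as.numeric(p)[1:2])
  if (!all(vapply(pts, function(p) all(is.finite(p)), logical(1)))) {
    stop("marker_frame(): non-finite marker coordinates")
  }
  if (normalize && pts$ASIS[1] < pts$PSIS[1]) {
    pts <- lapply(pts, function(p) c(-p[1], p[2]))
  }
  structure(list(markers = pts, frame_index = frame_index, time_s = time_s),
            class = "marker_frame")
}

.mk <- function(frame, name) frame$markers[[name]]

#' Sagittal hip angle from pelvis and thigh markers
#'
#' A line through ASIS and PSIS defines the pelvis; its perpendicular through
#' the greater trochanter (GT), taken caudally (pointing down the limb), is
#' the hip reference. The hip angle is the signed angle from that reference
#' to the GT->LFC thigh line: positive when the femoral condyle lies anterior
#' to the perpendicular (hip flexion), so a vertical thigh under a level
#' pelvis reads exactly 0.
#'
#' @param frame A `marker_frame`.
#' @return Hip angle, degrees, flexion positive.
#' @export
hip_angle <- function(frame) {
  asis <- .mk(frame, "ASIS"); psis <- .mk(frame, "PSIS")
  gt <- .mk(frame, "GT"); lfc <- .mk(frame, "LFC")
  pel <- asis - psis                      # points anteriorly
  if (sum(pel^2) == 0) stop("hip_angle(): ASIS and PSIS coincide")
  perp_caudal <- c(pel[2], -pel[1])       # pelvis line rotated -90 deg: down
  signed_angle_from(perp_caudal, lfc - gt)
}

#' Sagittal knee angle from thigh and shank markers
#'
#' The manual procedure measures the inner angle at the femoral condyle (LFC)
#' between the greater trochanter and the external malleolus and reports
#' `180 - angle`; a fully extended knee (GT, LFC, LM collinear) is 0. The
#' unsigned tool cannot distinguish flexion from hyperextension, so the side
#' of the malleolus relative to the extended thigh line assigns the sign:
#' shank posterior = flexion = positive, anterior = hyperextension = negative.
#'
#' @param frame A `marker_frame`.
#' @return Knee angle, degrees, flexion positive.
#' @export
knee_angle <- function(frame) {
  gt <- .mk(frame, "GT"); lfc <- .mk(frame, "LFC"); lm <- .mk(frame, "LM")
  inner <- angle_at_vertex(gt, lfc, lm)
  u <- lfc - gt                           # thigh direction, proximal->distal
  w <- lm - lfc                           # shank direction
  cross <- u[1] * w[2] - u[2] * w[1]
  # posterior shank (flexion) corresponds to a clockwise rotation of the
  # shank off the extended thigh line, i.e. negative cross product
  s <- if (cross <= 0) 1 else -1
  s * (180 - inner)
}

#' Sagittal ankle angle from foot and shank markers
#'
#' The foot line joins the calcaneus (CAL) to the 2nd metatarsal head (MT2);
#' the shank line joins the femoral condyle (LFC) to the malleolus (LM). The
#' manual procedure reports `90 - angle` with the angle measured between the
#' anterior foot ray (CAL->MT2) and the proximal shank ray (LM->LFC), so that
#' a foot perpendicular to the shank is 0, dorsiflexion (toes toward the
#' shin, angle closing below 90) is positive and plantar flexion negative.
#'
#' @param frame A `marker_frame`.
#' @return Ankle angle, degrees, dorsiflexion positive.
#' @export
ankle_angle <- function(frame) {
  cal <- .mk(frame, "CAL"); mt2 <- .mk(frame, "MT2")
  lfc <- .mk(frame, "LFC"); lm <- .mk(frame, "LM")
  if (all(cal == mt2)) stop("ankle_angle(): CAL and MT2 coincide")
  foot <- mt2 - cal                       # anterior foot ray
  shank_up <- lfc - lm                    # distal->proximal shank ray
  90 + signed_angle_from(shank_up, foot)
}

#' Hip, knee and ankle angles at an initial-contact frame
#'
#' Applies the three sagittal constructions to the marker frame selected as
#' initial contact and records which frame was used.
#'
#' @param frame A `marker_frame` (typically built from a track row at the
#'   detected initial-contact frame, see [frame_from_track()]).
#' @param warn_guard Warn if any |angle| exceeds 90 deg (implausible pose).
#' @return A list of class `joint_angles_ic` with `hip_deg`, `knee_deg`,
#'   `ankle_deg`, `frame_index`.
#' @export
angles_at_ic <- function(frame, warn_guard = TRUE) {
  out <- list(hip_deg = hip_angle(frame),
              knee_deg = knee_angle(frame),
              ankle_deg = ankle_angle(frame),
              frame_index = frame$frame_index)
  if (warn_guard &&
      any(abs(unlist(out[1:3])) >= 90)) {
    warning("angles_at_ic(): angle outside +/-90 deg plausibility guard")
  }
  structure(out, class = "joint_angles_ic")
}

#' Extract one frame of a marker track table as a `marker_frame`
#'
#' @param track Data frame with columns `<MARKER>_x`, `<MARKER>_y` (as
#'   written by [simulate_trial()] or read by [read_marker_csv()]).
#' @param i Row index (1-based) of the frame to extract.
#' @param normalize Passed to [marker_frame()].
#' @return A `marker_frame`.
#' @export
frame_from_track <- function(track, i, normalize = TRUE) {
  stopifnot(i >= 1, i <= nrow(track))
  args <- list()
  for (m in .all_markers) {
    xc <- paste0(m, "_x"); yc <- paste0(m, "_y")
    if (xc %in% names(track)) {
      args[[m]] <- c(track[[xc]][i], track[[yc]][i])
    }
  }
  args$frame_index <- if ("frame" %in% names(track)) track$frame[i] else i - 1L
  args$time_s <- if ("time_s" %in% names(track)) track$time_s[i] else NA_real_
  args$normalize <- normalize
  do.call(marker_frame, args)
}
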