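#' Published summary statistics of the motivating reliability study
#'
#' Summary tables from the 50-subject study of 2D video-based sagittal gait
#' angles at initial contact (two sessions one week apart, two observers
#' digitizing the same videos, video vs 3D optical reference) that this
#' package's synthetic cohort generator is calibrated to emulate. Angles in
#' degrees; `md` is the mean of the paired differences in the stated order
#' (session1 - session2, observer1 - observer2, video - reference).
#'
#' Note two internal inconsistencies carried over from the source tables,
#' relevant when checking reconstructions: the published hip video-vs-
#' reference `md` (0.80) does not equal the difference of the published
#' means (33.06 - 32.2 = 0.86), and the published hip and ankle limits of
#' agreement are not reproducible from their own `md` + CI via
#' [loa_from_summary()] (the knee row is).
#'
#' @return List of data frames: `intra_rater` (per observer and session),
#'   `inter_rater`, `system` (video vs reference with mean differences, CI
#'   and published limits of agreement), and `n_subjects`.
#' @export
reference_study_summaries <- function() {
  joints <- c("hip", "knee", "ankle")
  intra <- data.frame(
    joint = rep(joints, each = 2),
    observer = rep(1:2, 3),
    mean_s1 = c(33.06, 33.8, 4.55, 4.45, -7.77, -8.2),
    sd_s1 = c(5.7, 5.52, 3.8, 3.95, 3.7, 4.01),
    mean_s2 = c(33.4, 33.6, 4.36, 4.11, -8.86, -9.46),
    sd_s2 = c(4.87, 5.06, 3.5, 3.52, 3.6, 3.84),
    icc = c(0.886, 0.863, 0.859, 0.868, 0.875, 0.878),
    ci_low = c(0.799, 0.758, 0.751, 0.768, 0.780, 0.784),
    ci_high = c(0.935, 0.922, 0.920, 0.925, 0.929, 0.931),
    loa_low = c(-5.87, -6.17, -4.47, -4.21, -3.20, -3.02),
    loa_high = c(5.44, 6.52, 4.61, 4.82, 5.10, 4.97))
  inter <- data.frame(
    joint = joints,
    mean_obs1 = c(33.06, 4.55, -7.77),
    sd_obs1 = c(5.7, 3.8, 3.7),
    mean_obs2 = c(33.8, 4.45, -8.2),
    sd_obs2 = c(5.52, 3.95, 4.01),
    icc = c(0.962, 0.989, 0.973),
    ci_low = c(0.933, 0.981, 0.952),
    ci_high = c(0.978, 0.994, 0.984),
    loa_low = c(-3.05, -1.90, -2.18),
    loa_high = c(1.40, 2.09, 3.16))
  system <- data.frame(
    joint = joints,
    video_mean = c(33.06, 4.55, -7.77),
    video_sd = c(5.7, 3.8, 3.7),
    ref_mean = c(32.2, 2.53, -6.50),
    ref_sd = c(5.82, 3.93, 2.82),
    md = c(0.80, 2.02, -1.27),
    ci_low = c(0.12, 1.58, -2.03),
    ci_high = c(1.49, 2.45, -0.51),
    p = c(0.022, NA, NA),  # knee and ankle published only as p < 0.01
    loa_low = c(-3.58, -0.98, -6.09),
    loa_high = c(5.26, 5.01, 3.70))
  list(intra_rater = intra, inter_rater = inter, system = system,
       n_subjects = 50L)
}
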