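#' Vertical ground-reaction-force signal
#'
#' @param samples Numeric vector, vertical force in Newtons.
#' @param rate Sampling rate, Hz.
#' @return Object of class `force_signal`.
#' @export
force_signal <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("force_signal(): rate must be a positive scalar")
  }
  if (!all(is.finite(samples))) stop("force_signal(): non-finite samples")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "force_signal")
}

#' Detect initial contact from the vertical ground reaction force
#'
#' Implements the 20 N threshold rule used with force plates: initial
#' contact is the first sample at or above `threshold` that remains at or
#' above it for `min_above` consecutive samples. The dwell requirement
#' rejects isolated noise spikes before true contact; `min_above = 1`
#' reduces to the plain first-crossing rule.
#'
#' @param sig A `force_signal` (or numeric vector, with `rate` ignored).
#' @param threshold Force threshold in Newtons (default 20).
#' @param min_above Number of consecutive samples required at/above the
#'   threshold (default 10, i.e. 10 ms at 1000 Hz).
#' @return 0-based sample index of initial contact.
#' @export
detect_ic_force <- function(sig, threshold = 20, min_above = 10L) {
  x <- if (inherits(sig, "force_signal")) sig$samples else as.numeric(sig)
  min_above <- as.integer(min_above)
  stopifnot(min_above >= 1)
  above <- x >= threshold
  if (!any(above)) stop("detect_ic_force(): no contact (signal never reaches threshold)")
  # run-length scan: first run of >= min_above consecutive TRUE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_above)
  if (length(ok) == 0) stop("detect_ic_force(): no contact (no dwell of min_above samples)")
  starts[ok[1]] - 1L  # 0-based
}

#' Detect initial contact from heel-marker kinematics
#'
#' Automated surrogate for visual frame selection: initial contact is taken
#' as the first local minimum of the heel (CAL) marker height within the
#' search window. A frame `i` is a local minimum when the height strictly
#' decreased into it and does not decrease after it, which picks the first
#' frame of a flat foot-contact plateau.
#'
#' @param cal_y Numeric vector of heel heights per frame.
#' @param window Optional `c(first, last)` 0-based frame window to search.
#' @return 0-based frame index of the detected contact.
#' @export
detect_ic_kinematic <- function(cal_y, window = NULL) {
  y <- as.numeric(cal_y)
  n <- length(y)
  if (n < 5) stop("detect_ic_kinematic(): need at least 5 frames")
  lo <- 2L; hi <- n - 1L
  if (!is.null(window)) {
    lo <- max(lo, as.integer(window[1]) + 1L)
    hi <- min(hi, as.integer(window[2]) + 1L)
  }
  for (i in lo:hi) {
    if (y[i - 1] > y[i] && y[i + 1] >= y[i]) return(i - 1L)
  }
  stop("detect_ic_kinematic(): no local minimum of heel height in window")
}
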