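#' Ratings matrix for reliability analysis
#'
#' An n-subjects x k-measurements numeric matrix with no missing cells, the
#' input to the two-way ANOVA / ICC machinery. Columns are the repeated
#' measurements being compared (sessions, observers or systems).
#'
#' @param values Numeric matrix (or coercible), n >= 2 rows, k >= 2 columns.
#' @return Object of class `ratings_matrix`.
#' @export
ratings_matrix <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("ratings_matrix(): need at least 2 subjects and 2 measurements")
  }
  if (any(!is.finite(m))) stop("ratings_matrix(): missing or non-finite cells")
  structure(list(values = m, n = nrow(m), k = ncol(m)), class = "ratings_matrix")
}

.as_ratings <- function(m) {
  if (inherits(m, "ratings_matrix")) m else ratings_matrix(m)
}

#' Two-way ANOVA mean squares of a ratings matrix
#'
#' Decomposes the total sum of squares into rows (subjects), columns
#' (measurements) and residual, the decomposition underlying the single-
#' measures intraclass correlation coefficients.
#'
#' @param m A `ratings_matrix` or numeric matrix.
#' @return List of class `anova_components` with `ms_rows`, `ms_cols`,
#'   `ms_error`, the corresponding sums of squares and degrees of freedom,
#'   and `n`, `k`.
#' @export
two_way_anova <- function(m) {
  m <- .as_ratings(m)
  x <- m$values; n <- m$n; k <- m$k
  g <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm_ - g)^2)
  sst <- sum((x - g)^2)
  sse <- sst - ssr - ssc
  if (sse < 0) sse <- max(sse, 0)  # guard tiny negative rounding
  structure(list(
    ms_rows = ssr / (n - 1), ms_cols = ssc / (k - 1),
    ms_error = sse / ((n - 1) * (k - 1)),
    ss_rows = ssr, ss_cols = ssc, ss_error = sse, ss_total = sst,
    df_rows = n - 1, df_cols = k - 1, df_error = (n - 1) * (k - 1),
    n = n, k = k
  ), class = "anova_components")
}

#' Single-measures intraclass correlation coefficient
#'
#' Two forms are provided, both "single measures":
#' * `"absolute_agreement"` — ICC(A,1): penalizes systematic offsets between
#'   measurements; `r = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' * `"consistency"` — ICC(C,1): ignores column offsets;
#'   `r = (MSR - MSE) / (MSR + (k-1) MSE)`.
#'
#' 95% confidence intervals use the standard F-based formulas for each form
#' (Satterthwaite degrees of freedom for absolute agreement).
#'
#' @param m A `ratings_matrix` or numeric matrix.
#' @param model `"absolute_agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `model`, `band` (interpretation label), `n`, `k`, `degenerate`.
#' @export
icc_single <- function(m, model = c("absolute_agreement", "consistency"),
                       conf_level = 0.95) {
  model <- match.arg(model)
  an <- two_way_anova(m)
  n <- an$n; k <- an$k
  msr <- an$ms_rows; msc <- an$ms_cols; mse <- an$ms_error
  alpha <- 1 - conf_level

  degenerate <- FALSE
  if (model == "consistency") {
    den <- msr + (k - 1) * mse
    if (den <= 0) {
      degenerate <- TRUE; r <- NA_real_; lo <- NA_real_; hi <- NA_real_
    } else {
      r <- (msr - mse) / den
      if (mse == 0) {
        lo <- hi <- r
      } else {
        fobs <- msr / mse
        df2 <- (n - 1) * (k - 1)
        fl <- fobs / stats::qf(1 - alpha / 2, n - 1, df2)
        fu <- fobs * stats::qf(1 - alpha / 2, df2, n - 1)
        lo <- (fl - 1) / (fl + k - 1)
        hi <- (fu - 1) / (fu + k - 1)
      }
    }
  } else {
    den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    if (den <= 0) {
      degenerate <- TRUE; r <- NA_real_; lo <- NA_real_; hi <- NA_real_
    } else {
      r <- (msr - mse) / den
      if (mse == 0 && msc == 0) {
        lo <- hi <- r
      } else {
        a <- k * r / (n * (1 - r))
        b <- 1 + k * r * (n - 1) / (n * (1 - r))
        if (!is.finite(a) || !is.finite(b)) {
          lo <- hi <- r
        } else {
          v <- (a * msc + b * mse)^2 /
            ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
          fl <- stats::qf(1 - alpha / 2, n - 1, v)
          fu <- stats::qf(1 - alpha / 2, v, n - 1)
          lo <- n * (msr - fl * mse) /
            (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
          hi <- n * (fu * msr - mse) /
            (k * msc + (k * n - k - n) * mse + n * fu * msr)
        }
      }
    }
  }
  if (!degenerate) {
    lo <- max(-1, min(lo, r)); hi <- min(1, max(hi, r))
  }
  structure(list(estimate = r, ci_low = lo, ci_high = hi,
                 model = model, band = if (degenerate) NA_character_
                                 else interpret_icc(r),
                 n = n, k = k, degenerate = degenerate),
            class = "icc_result")
}

#' Interpretation band for an ICC point estimate
#'
#' Maps an ICC to the conventional labels: excellent (> 0.9),
#' good (0.76–0.9), moderate (0.5–0.75), poor (< 0.5). Values in the
#' unprinted gap (0.75, 0.76) are labelled "good"; exactly 0.9 is "good" and
#' exactly 0.75 is "moderate", following the band endpoints as printed.
#'
#' @param r Finite ICC estimate.
#' @return One of `"excellent"`, `"good"`, `"moderate"`, `"poor"`.
#' @export
interpret_icc <- function(r) {
  stopifnot(is.finite(r))
  if (r > 0.9) "excellent"
  else if (r > 0.75) "good"
  else if (r >= 0.5) "moderate"
  else "poor"
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of the paired differences `x - y`), the sample SD
#' of the differences and the 95% limits of agreement `bias +/- 1.96 SD`,
#' together with the per-pair means and differences for plotting.
#'
#' @param x,y Equal-length numeric vectors (paired measurements). The
#'   difference order `x - y` is the caller's contrast convention.
#' @return List of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and a data frame `points` with columns
#'   `mean` and `difference`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("bland_altman(): length mismatch")
  if (length(x) < 2) stop("bland_altman(): need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(d),
                 points = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman_result")
}

#' Reconstruct limits of agreement from a published summary
#'
#' Given a reported mean difference, its t-based 95% confidence interval and
#' the sample size, recovers the SD of the differences
#' (`sd = (CI half-width) / t_{0.975, n-1} * sqrt(n)`) and rebuilds the
#' Bland-Altman 95% limits of agreement `md +/- 1.96 sd`. Useful for
#' checking whether published limits are internally consistent with the
#' published mean difference and interval.
#'
#' @param md Reported mean difference.
#' @param ci_low,ci_high Reported 95% CI bounds of the mean difference.
#' @param n Number of pairs.
#' @return A `bland_altman_result` (without per-pair points).
#' @export
loa_from_summary <- function(md, ci_low, ci_high, n) {
  if (!(ci_low < ci_high)) stop("loa_from_summary(): invalid CI (ci_low >= ci_high)")
  if (n < 2) stop("loa_from_summary(): n must be >= 2")
  sdd <- ((ci_high - ci_low) / 2) / stats::qt(0.975, n - 1) * sqrt(n)
  structure(list(bias = md, sd_diff = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
                 n = n, points = NULL),
            class = "bland_altman_result")
}

#' Paired (dependent-samples) t test
#'
#' Mean difference `x - y` with a t-based 95% confidence interval and
#' two-sided p-value. With zero-variance differences the p-value is 1 when
#' the mean difference is 0 and is reported as below machine precision
#' (flagged) otherwise.
#'
#' @param x,y Equal-length numeric vectors.
#' @param conf_level Confidence level (default 0.95).
#' @param zero_tol Differences are treated as exactly zero when their
#'   largest magnitude is below this (default 1e-9, i.e. a nanodegree on
#'   the angle scale): floating-point residue from the extraction pipeline
#'   must not masquerade as a systematic effect.
#' @return List of class `paired_t_result`: `md`, `ci_low`, `ci_high`,
#'   `t_stat`, `df`, `p`, `zero_variance`.
#' @export
paired_t <- function(x, y, conf_level = 0.95, zero_tol = 1e-9) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("paired_t(): length mismatch")
  n <- length(x)
  if (n < 2) stop("paired_t(): need at least 2 pairs")
  d <- x - y
  if (max(abs(d)) <= zero_tol) d <- rep(0, n)
  md <- mean(d)
  sdd <- stats::sd(d)
  df <- n - 1
  zero_var <- sdd == 0
  if (zero_var) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(md) * Inf; p <- .Machine$double.xmin
    }
    ci <- c(md, md)
  } else {
    se <- sdd / sqrt(n)
    t_stat <- md / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    tq <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- c(md - tq * se, md + tq * se)
  }
  structure(list(md = md, ci_low = ci[1], ci_high = ci[2],
                 t_stat = t_stat, df = df, p = p, zero_variance = zero_var),
            class = "paired_t_result")
}

#' Reliability-study sample size for an ICC (Walter-Eliasziw-Donner)
#'
#' Closed-form number of subjects needed to show, with one-sided level
#' `alpha` and the stated power, that the ICC exceeds a minimally acceptable
#' value `rho0` when the true ICC is `rho1`, with `k` measurements per
#' subject:
#' `n0 = ceil(1 + 2k (z_a + z_b)^2 / ((k - 1) (ln C0)^2))` where
#' `C0 = (1 + k theta0) / (1 + k theta1)` and `theta = rho / (1 - rho)`.
#' The returned enrolment target inflates `n0` multiplicatively for the
#' expected attrition and rounds up.
#'
#' @param rho0 Minimally acceptable ICC (null), in `[0, 1)`.
#' @param rho1 Expected ICC (alternative), `rho0 < rho1 < 1`.
#' @param k Measurements per subject (default 2).
#' @param alpha One-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param attrition Expected drop-out fraction (default 0).
#' @return List with `n0` (evaluable subjects) and `n_inflated`
#'   (enrolment target after attrition inflation).
#' @examples
#' walter_sample_size(0.6, 0.8, k = 2, attrition = 0.10) # n0 = 39, 43 enrolled
#' @export
walter_sample_size <- function(rho0, rho1, k = 2, alpha = 0.05, power = 0.8,
                               attrition = 0) {
  stopifnot(rho0 >= 0, rho0 < 1, rho1 < 1, k >= 2,
            alpha > 0, alpha < 0.5, power > 0, power < 1,
            attrition >= 0, attrition < 1)
  if (rho0 >= rho1) stop("walter_sample_size(): need rho0 < rho1")
  theta0 <- rho0 / (1 - rho0)
  theta1 <- rho1 / (1 - rho1)
  c0 <- (1 + k * theta0) / (1 + k * theta1)
  za <- stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  n0 <- ceiling(1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2))
  list(n0 = as.integer(n0),
       n_inflated = as.integer(ceiling(n0 * (1 + attrition))))
}
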