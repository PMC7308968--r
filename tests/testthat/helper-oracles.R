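# Rotation-matrix oracle: builds a marker frame for given joint angles by
# composing absolute segment direction angles directly (independent of
# pose_leg and of the extraction code under test). dir(theta) is the unit
# vector theta degrees anterior of straight down.
oracle_dir <- function(theta_deg) {
  a <- theta_deg * pi / 180
  c(sin(a), -cos(a))
}

oracle_pose <- function(hip, knee, ankle, tilt = 0,
                        gt = c(0, 0.9), lengths = list(
                          pelvis = 0.17, pelvis_up = 0.08,
                          thigh = 0.41, shank = 0.41,
                          foot_drop = 0.04, heel = 0.05, toe = 0.14),
                        scale = 1, rotate = 0, translate = c(0, 0)) {
  # pelvis line: anterior direction tilted down by `tilt`
  pel_ant <- oracle_dir(90 - tilt)           # 90 deg anterior of down = +x
  perp_up <- oracle_dir(-tilt) * -1          # cephalad perpendicular
  mid <- gt + lengths$pelvis_up * perp_up
  asis <- mid + lengths$pelvis / 2 * pel_ant
  psis <- mid - lengths$pelvis / 2 * pel_ant
  thigh_d <- oracle_dir(hip - tilt)
  shank_d <- oracle_dir(hip - knee - tilt)
  foot_d <- oracle_dir(hip - knee - tilt + 90 + ankle)
  lfc <- gt + lengths$thigh * thigh_d
  lm <- lfc + lengths$shank * shank_d
  fo <- lm + lengths$foot_drop * shank_d
  cal <- fo - lengths$heel * foot_d
  mt2 <- fo + lengths$toe * foot_d
  thi <- gt + 0.5 * lengths$thigh * thigh_d
  tib <- lfc + 0.5 * lengths$shank * shank_d
  pts <- list(ASIS = asis, PSIS = psis, GT = gt, THI = thi, LFC = lfc,
              TIB = tib, LM = lm, CAL = cal, MT2 = mt2)
  R <- matrix(c(cos(rotate * pi / 180), sin(rotate * pi / 180),
                -sin(rotate * pi / 180), cos(rotate * pi / 180)), 2, 2)
  pts <- lapply(pts, function(p) as.numeric(R %*% (scale * p)) + translate)
  do.call(marker_frame, pts)
}

# Batched independent ICC reference (pingouin) for a list of matrices.
# Returns a data frame with icc_a / icc_c per matrix.
pingouin_icc_batch <- function(mats) {
  tmp <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  rows <- lapply(seq_along(mats), function(b) {
    m <- mats[[b]]
    data.frame(batch = b, subj = rep(seq_len(nrow(m)), ncol(m)),
               rater = rep(seq_len(ncol(m)), each = nrow(m)),
               y = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), tmp, row.names = FALSE)
  py <- c(
    "import pandas as pd, pingouin as pg",
    sprintf("df = pd.read_csv(%s)", shQuote(tmp)),
    "res = []",
    "for b, g in df.groupby('batch'):",
    "    icc = pg.intraclass_corr(g, 'subj', 'rater', 'y')",
    "    res.append({'batch': b,",
    "        'icc_a': icc.loc[icc.Type=='ICC(A,1)','ICC'].iloc[0],",
    "        'icc_c': icc.loc[icc.Type=='ICC(C,1)','ICC'].iloc[0]})",
    sprintf("pd.DataFrame(res).to_csv(%s, index=False)", shQuote(out)))
  pyf <- tempfile(fileext = ".py")
  writeLines(py, pyf)
  status <- system2("python", pyf, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out)) {
    stop("independent ICC reference (python/pingouin) failed to run")
  }
  utils::read.csv(out)
}

# accessor shortcut for marker coordinates in tests
.mk_test <- function(frame, name) frame$markers[[name]]

# small default-design cohort shared across tests
tiny_cohort_config <- function(n_subjects = 8, seed = 101) {
  cohort_config(n_subjects = n_subjects, seed = seed)
}
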