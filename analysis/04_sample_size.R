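#!/usr/bin/env Rscript
# Reliability-study sample-size planning (Walter-Eliasziw-Donner closed
# form) and the internal-consistency audit of the published summary tables.

suppressMessages(library(gaitagree))

ws <- walter_sample_size(rho0 = 0.6, rho1 = 0.8, k = 2, alpha = 0.05,
                         power = 0.8, attrition = 0.10)
cat(sprintf("Walter sample size (rho0 0.6, rho1 0.8, k 2, one-sided alpha 0.05, power 0.8):\n"))
cat(sprintf("  evaluable subjects n0 = %d; enrolment after 10%% attrition = %d\n\n",
            ws$n0, ws$n_inflated))

# Which published limits of agreement are reconstructible from their own
# mean difference + 95% CI?
ref <- reference_study_summaries()
sys <- ref$system
cat("Video-vs-reference rows: published LoA vs LoA rebuilt from MD + CI\n")
for (i in seq_len(nrow(sys))) {
  rec <- loa_from_summary(sys$md[i], sys$ci_low[i], sys$ci_high[i],
                          ref$n_subjects)
  consistent <- max(abs(c(rec$loa_low - sys$loa_low[i],
                          rec$loa_high - sys$loa_high[i]))) < 0.1
  cat(sprintf("  %-5s published (%+.2f, %+.2f)  rebuilt (%+.2f, %+.2f)  %s\n",
              sys$joint[i], sys$loa_low[i], sys$loa_high[i],
              rec$loa_low, rec$loa_high,
              if (consistent) "consistent" else "NOT consistent"))
}

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(list(n0 = ws$n0, n_enrolled = ws$n_inflated),
                     "results/sample_size.json", auto_unbox = TRUE)
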