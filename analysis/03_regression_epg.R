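#!/usr/bin/env Rscript

# Stage 2: which compounds shape the profile, and where? Phylogenetic
# GLS of the CLR profiles on the absolute compound abundances, marginal
# (type III) RRPP tests, then predicted profiles at the observed
# minimum/maximum of each flagged compound and localization of the
# responsive molecular-weight regions (log-linear synthetic kDa
# calibration, 250 down to 10 kDa).

library(glandcov)

report <- function(dir, out_dir, label) {
  ds <- load_dataset(dir)
  res <- run_full_analysis(ds, n_perm = 999, seed = 103, out_dir = out_dir)
  cat(sprintf("\n== %s ==\n", label))
  cat("Marginal (type III) tests of the 8 compounds on the profile:\n")
  print(res$pgls$table, row.names = FALSE, digits = 4)
  cat(sprintf("Flagged after Holm adjustment: %s\n",
              if (length(res$pgls$flagged))
                paste(res$pgls$flagged, collapse = ", ") else "(none)"))
  kda <- kda_calibration(ncol(ds$epg))
  for (tm in res$pgls$flagged) {
    pr <- res$pgls$predictions[[tm]]
    rg <- responsive_regions(pr[1, ], pr[2, ], kda = kda)
    cat(sprintf("Responsive regions for %s (bins, kDa):\n", tm))
    print(rg, row.names = FALSE, digits = 3)
  }
  invisible(res)
}

report("results/data", "results/regression",
       "moderate coupling (generator defaults)")
report("results/data_strong", "results/regression_strong",
       "strong isolated effect of compound 1 (bins 40-45)")
cat("\nTables written under results/regression/ and results/regression_strong/\n")
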