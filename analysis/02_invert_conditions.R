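#!/usr/bin/env Rscript
# Step 2: invert every simulated trace with the full processing protocol
# (phase correction, truncation where the acquisition used one, automated
# background determination, L-curve Tikhonov inversion with background-start
# consensus) and tabulate recovered vs true statistics.

suppressPackageStartupMessages(library(deerens))

bundles <- synth_study(default_conditions(seed = 1L))
dir.create("results", showWarnings = FALSE)

rows <- lapply(bundles, function(b) {
  inv <- invert_trace(b$trace, t_cut = if (!is.na(b$spec$t_cut)) b$spec$t_cut)
  write_distribution(inv$dist,
                     file.path("results", paste0(b$spec$label, "_dist.csv")))
  ts <- distribution_stats(b$truth)
  data.frame(condition = b$spec$label, site = b$spec$site,
             alpha = inv$alpha,
             modal_nm = inv$stats$modal, true_modal_nm = ts$modal,
             fwhm_nm = inv$stats$fwhm, true_fwhm_nm = ts$fwhm,
             sigma_nm = inv$stats$sigma, true_sigma_nm = ts$sigma)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/inversion_summary.csv", row.names = FALSE)

cat("Recovered vs true statistics (nm):\n")
print(tab[, c("condition", "modal_nm", "true_modal_nm", "sigma_nm",
              "true_sigma_nm")], row.names = FALSE, digits = 3)
cat(sprintf("\nLargest modal error: %.3f nm; largest relative width error: %.1f%%\n",
            max(abs(tab$modal_nm - tab$true_modal_nm)),
            100 * max(abs(tab$sigma_nm - tab$true_sigma_nm) /
                        tab$true_sigma_nm)))
cat("Per-condition distributions written to results/<condition>_dist.csv\n")
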