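#!/usr/bin/env Rscript
# Stage 3: microsecond-millisecond exchange from CPMG relaxation
# dispersion. Each residue's two-field curves are fitted with the
# Carver-Richards two-site model against a no-exchange alternative (AICc),
# and the exchange contribution Rex is extracted per field. The headline
# contrast: apo loop reporters disperse strongly (Rex > 5 s-1), the bound
# arm is flat.

library(colchidyn)

dir <- "results/synthetic_study"
if (!dir.exists(dir)) stop("run analysis/01_simulate_study.R first")
out <- "results/dispersion"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (arm in c("apo", "bound")) {
  curves <- read_dispersion(file.path(dir, paste0(arm, "_dispersion.tsv")))
  fits <- fit_all_residues(curves, n_boot = 200, seed = 2)
  write_fits_json(fits, file.path(out, paste0(arm, "_fits.json")))
  cat(arm, "arm:\n")
  for (r in names(fits)) {
    f <- fits[[r]]
    if (f$model == "exchange") {
      cat(sprintf(
        "  residue %-4s exchange: pA = %.3f, kex = %7.1f rad/s, dw = %5.2f ppm, Rex(950) = %5.1f s-1\n",
        r, f$pA, f$kex, f$dw_ppm, f$rex_by_field[["950"]]))
    } else {
      cat(sprintf("  residue %-4s no exchange contribution\n", r))
    }
  }
}
cat("fit records written to", out, "\n")
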