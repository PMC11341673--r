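#!/usr/bin/env Rscript
# Stage 3: stomatal and wax patterning between leaf sides.
#
# Per-leaf amphistomy (ASL) and amphiwaxy (AWL) levels; side-coupling
# regressions SD_ad ~ SD_ab (linear) and W_ad ~ W_ab (log10-linear) per
# species x light stratum and per species x age stratum; the potential
# (asymptotic) levels ASL_pot = k/(k+1) and AWL_pot at a reference
# adaxial coverage of 10 ug cm^-2; and ASL-on-polarity regressions whose
# intercepts estimate the amphistomy level at zero isotopic polarity.

suppressPackageStartupMessages(library(amphistomy))

in_dir <- "results/analysis"
leaves <- read_leaves(file.path(in_dir, "leaves.csv"))
pol <- read.csv(file.path(in_dir, "polarity.csv"))

pat <- patterning_summary(leaves)
write.csv(pat[c("leaf_id", "asl", "awl")],
          file.path(in_dir, "patterning.csv"), row.names = FALSE)

couple <- function(stratum_col) {
  rows <- list()
  for (sp in unique(leaves$species)) {
    for (g in unique(leaves[[stratum_col]])) {
      sub <- leaves[leaves$species == sp & leaves[[stratum_col]] == g, ]
      fsd <- fit_coupling(sub$sd_ab, sub$sd_ad, "identity")
      fw <- fit_coupling(sub$w_ab, sub$w_ad, "log10",
                         leaf_id = sub$leaf_id)
      rows[[paste(sp, g)]] <- data.frame(
        species = sp, stratum = g,
        sd_k = fsd$slope_k, sd_a = fsd$intercept_a,
        sd_r2 = fsd$r_squared, asl_pot = asl_pot(fsd),
        wax_k = fw$slope_k, wax_a = fw$intercept_a,
        wax_r2 = fw$r_squared, awl_pot = awl_pot(fw, 10)$awl_pot,
        n = nrow(sub))
    }
  }
  do.call(rbind, rows)
}

by_light <- couple("light")
by_age <- couple("age")
write.csv(by_light, file.path(in_dir, "coupling_by_light.csv"),
          row.names = FALSE)
write.csv(by_age, file.path(in_dir, "coupling_by_age.csv"),
          row.names = FALSE)
cat("Side couplings by light (slope k drives the asymptote):\n")
print(by_light, digits = 3, row.names = FALSE)
cat("\nSide couplings by age:\n")
print(by_age, digits = 3, row.names = FALSE)

merged <- merge(pat, pol[c("leaf_id", "polarity")], by = "leaf_id")
regr <- regress_asl_on_polarity(merged, group = "species")
attr(regr, "fits") <- NULL
write.csv(regr, file.path(in_dir, "asl_on_polarity.csv"),
          row.names = FALSE)
cat("\nASL on polarity; the intercept is the zero-polarity ASL:\n")
print(regr, digits = 3, row.names = FALSE)
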