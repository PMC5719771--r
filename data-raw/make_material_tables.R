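# Generates the packaged stopping-power and attenuation tables in
# inst/extdata/ from the analytic physics in R/physics.R.
# Run from the package root:  Rscript data-raw/make_material_tables.R

source("R/lungpdd-package.R")
source("R/physics.R")

grid <- exp(seq(log(0.01), log(20), length.out = 100))
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

for (mat in names(.compositions)) {
  sp <- .bethe_scol(grid, .compositions[[mat]], .sternheimer[[mat]])
  at <- .mu_over_rho(grid, .compositions[[mat]], "total")
  write.csv(data.frame(energy_MeV = signif(grid, 8), value = signif(sp, 8)),
            file.path("inst/extdata", paste0("stopping_power_", mat, ".csv")),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(energy_MeV = signif(grid, 8), value = signif(at, 8)),
            file.path("inst/extdata", paste0("attenuation_", mat, ".csv")),
            row.names = FALSE, quote = FALSE)
}
cat("wrote tables for:", paste(names(.compositions), collapse = ", "), "\n")
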