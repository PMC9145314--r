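#!/usr/bin/env Rscript
# Generate every input the downstream analyses need, with ground truth
# written beside each dataset: dose-response plates for the three particle
# shapes (viability and IL-1b endpoints), an ELISA calibration plate, and a
# feature-level expression experiment (8 conditions x 3 replicates) with
# spiked DEGs and pathway-coherent shifts.

suppressPackageStartupMessages(library(npinflam))

seed <- 20260927
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Dose-response truths per shape: the nanorod-like condition loses viability
# and gains IL-1b with dose, the star-like condition is flat in viability
# with a mild IL-1b decrease, the sphere-like condition loses viability
# without an IL-1b response.
truths <- list(
  viability_rod    = dr_model("exponential", 3, a = 100, b = -0.002, d = 1.5),
  viability_star   = dr_model("exponential", 1, a = 100),
  viability_sphere = dr_model("exponential", 2, a = 100, b = -0.012),
  il1b_rod         = dr_model("exponential", 3, a = 20, b = 0.03, d = 1),
  il1b_star        = dr_model("exponential", 2, a = 20, b = -0.008),
  il1b_sphere      = dr_model("exponential", 1, a = 20)
)

# Three independent experiments per endpoint, pooled for fitting with the
# experiment identifier retained (the reported dose-response tables pooled
# three replicate experiments the same way).
for (i in seq_along(truths)) {
  nm <- names(truths)[i]
  endpoint <- if (startsWith(nm, "viability")) "viability" else "IL-1b"
  exps <- lapply(1:3, function(e) {
    d <- gen_dose_response(truths[[i]], sd = 0.05, seed = seed + 10 * i + e,
                           endpoint = endpoint)
    d$experiment <- e
    d
  })
  pooled <- dr_dataset(
    dose = unlist(lapply(exps, `[[`, "dose")),
    response = unlist(lapply(exps, `[[`, "response")),
    replicate = unlist(lapply(exps, `[[`, "replicate")),
    experiment = unlist(lapply(exps, `[[`, "experiment")),
    endpoint = endpoint)
  attr(pooled, "truth") <- list(spec = truths[[i]], sd = 0.05,
                                seed = seed + 10 * i)
  write_dr_csv(pooled, file.path(out, paste0(nm, ".csv")))
  message(sprintf("wrote %s (%d observations, 3 experiments)", nm, nrow(pooled)))
}

# ELISA plate: a realistic IL-1b calibration curve plus three supernatants
# measured in 20-fold pre-dilution.
curve <- list(lower = 0.05, upper = 3.2, c = 120, b = 1.1, g = 0.9)
plate <- gen_elisa_plate(curve, c(rod = 45, star = 12, sphere = 18),
                         sd = 0.01, seed = seed + 10)
write.csv(plate, file.path(out, "elisa_plate.csv"), row.names = FALSE)
message("wrote elisa_plate.csv")

# Expression experiment with known spikes and set-level shifts.
n_genes <- 10246
shifts <- default_set_shifts(n_genes)
expr <- gen_expression(n_genes = n_genes, sd = 0.25,
                       spikes = default_spikes(n_genes),
                       set_shifts = shifts, probes_per_gene = 2,
                       flag_fail_rate = 0.02, control_fraction = 0.02,
                       seed = seed + 20)
write_feature_tables(expr, file.path(out, "expression"))
write_gmt(shifts$sets, file.path(out, "gene_sets.gmt"))
message(sprintf("wrote expression experiment (%d genes, %d samples)",
                n_genes, ncol(expr$intensity)))
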