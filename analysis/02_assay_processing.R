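#!/usr/bin/env Rscript
# Plate-assay arithmetic: 5PL ELISA calibration of the generated plate,
# endotoxin classification of the six reported dispersions, dose-metric
# conversions and particle surface-to-volume geometry.

suppressPackageStartupMessages(library(npinflam))

out <- "results/assays"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# ELISA: calibrate and invert the supernatants (20-fold pre-dilution).
plate <- read.csv("results/data/elisa_plate.csv")
res <- elisa_plate_analysis(plate, dilution_factor = 20)
message(sprintf("5PL calibration: lower %.3f, upper %.3f, c %.1f, b %.2f, g %.2f",
                res$curve$lower, res$curve$upper, res$curve$c,
                res$curve$b, res$curve$g))
write.table(res$samples, file.path(out, "cytokine_concentrations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(unclass(res$curve)[c("lower", "upper", "c", "b", "g", "rss")],
                     file.path(out, "elisa_calibration.json"),
                     auto_unbox = TRUE, digits = NA)

# Endotoxin content of 100 ug/mL dispersions against the 0.5 EU/mg limit
# (threshold 0.05 EU/mL); interference forces outcome C.
endo <- data.frame(
  gnp = paste0("GNP-", 1:6),
  shape = c("star", "star", "sphere", "sphere", "rod", "rod"),
  measured_EU_mL = c(0.030, 0.070, 1.667, 1.546, 0.436, 0.041),
  interference = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
endo$outcome <- mapply(endotoxin_classify, endo$measured_EU_mL, 100,
                       MoreArgs = list(limit = 0.5),
                       interference = endo$interference)
write.table(endo, file.path(out, "endotoxin_classification.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(paste("endotoxin outcomes:", paste(endo$outcome, collapse = " ")))

# Dose metrics: the 60 x 14 nm rod carries 1.324 ug/mL per nM, ten-fold the
# star (0.142) and sphere (0.123) factors.
rod <- particle_geometry("rod", radius = 7, length = 60, mass_per_nM = 1.324)
star <- particle_geometry("sphere", radius = 30, mass_per_nM = 0.142)
sphere <- particle_geometry("sphere", radius = 25, mass_per_nM = 0.123)
conv <- data.frame(
  particle = c("rod", "star", "sphere"),
  nM = 0.05,
  ug_mL = c(dose_convert(0.05, rod), dose_convert(0.05, star),
            dose_convert(0.05, sphere)))
conv$log2_ug_mL <- log2_dose(conv$ug_mL)
write.table(conv, file.path(out, "dose_conversions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# Geometry: surface-to-volume ratios and the rod/sphere fold difference.
sv <- data.frame(
  particle = c("rod_60x14", "sphere_30"),
  surface_to_volume_nm = c(surface_to_volume(rod),
                           surface_to_volume(particle_geometry("sphere", 15))))
sv_ratio <- sv$surface_to_volume_nm[1] / sv$surface_to_volume_nm[2]
message(sprintf("surface-to-volume: rod %.2f /nm, sphere %.2f /nm, ratio %.1f",
                sv$surface_to_volume_nm[1], sv$surface_to_volume_nm[2],
                sv_ratio))
write.table(sv, file.path(out, "surface_to_volume.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
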