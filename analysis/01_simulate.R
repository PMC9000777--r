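#!/usr/bin/env Rscript
# Generate the synthetic storage study: NIR spectra, electrolyte-leakage
# records and E-nose tables for 3 atmospheres x 6 checkpoints, with ground
# truth. Downstream scripts read these files only.

library(aquarocket)

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sc <- spectral_scenario(preset = "trial1", seed = 1)
print(sc)

gen <- generate_spectra(sc)
leak <- generate_leakage(sc, truth = gen$truth)
enose <- generate_enose(sc)

write_spectra(gen$ds, file.path(outdir, "spectra_reflectance.csv"), "wide_csv")
write.csv(leak, file.path(outdir, "leakage.csv"), row.names = FALSE)
write.csv(enose, file.path(outdir, "enose.csv"), row.names = FALSE)
jsonlite::write_json(list(bags = gen$truth$bags, bands = gen$truth$bands),
                     file.path(outdir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d spectra (%d wavelengths), %d leakage records, %d e-nose rows to %s\n",
            n_spectra(gen$ds), length(gen$ds$wavelengths), nrow(leak),
            nrow(enose), outdir))
cat(sprintf("latent damage at day 13 (bag means): A %.1f, B %.1f, C %.1f\n",
            mean(gen$truth$bags$damage[gen$truth$bags$treatment == "A" &
                                         gen$truth$bags$day == 13]),
            mean(gen$truth$bags$damage[gen$truth$bags$treatment == "B" &
                                         gen$truth$bags$day == 13]),
            mean(gen$truth$bags$damage[gen$truth$bags$treatment == "C" &
                                         gen$truth$bags$day == 13])))
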