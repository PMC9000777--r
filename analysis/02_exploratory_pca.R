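#!/usr/bin/env Rscript
# Exploratory PCA of the checkpoint-mean spectra after moving-average
# smoothing and the Norris gap first derivative, truncated to the first
# overtone of water (1300-1600 nm). Expectation from the storage model:
# checkpoints order along PC1 by storage day.

library(aquarocket)

outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ds <- read_spectra("results/data/spectra_reflectance.csv", "wide_csv",
                   mode = "reflectance")
absb <- reflectance_to_absorbance(ds)
prep <- apply_steps(checkpoint_means(absb), "pca_prep")$ds

pca <- fit_pca(prep, n_components = 3)
print(pca)

scores <- cbind(prep$samples[c("treatment", "day")], as.data.frame(pca$scores))
names(scores)[-(1:2)] <- paste0("PC", 1:3)
write.csv(scores, file.path(outdir, "pca_scores.csv"), row.names = FALSE)
write.csv(data.frame(wavelength = prep$wavelengths, pca$loadings),
          file.path(outdir, "pca_loadings.csv"), row.names = FALSE)

# day ordering along PC1
ord <- cor(scores$PC1, scores$day, method = "spearman")
cat(sprintf("PC1 explains %.1f%% of variance; Spearman(PC1, day) = %.2f\n",
            pca$explained_variance_pct[1], ord))
top <- prep$wavelengths[which.max(abs(pca$loadings[, 1]))]
cat(sprintf("largest |PC1 loading| at %.0f nm\n", top))

p <- ggplot2::ggplot(scores, ggplot2::aes(PC1, PC2, colour = factor(day),
                                          shape = treatment)) +
  ggplot2::geom_point(size = 2.5) +
  ggplot2::labs(colour = "storage day") +
  ggplot2::theme_minimal()
ggplot2::ggsave(file.path(outdir, "pca_scores.png"), p,
                width = 6, height = 4, dpi = 150)
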