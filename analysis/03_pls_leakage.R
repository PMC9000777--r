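#!/usr/bin/env Rscript
# PLS regression of the electrolyte-leakage index of leaf damage on
# SNV + second-derivative spectra, at bag level (spectra averaged per bag,
# leakage averaged per bag), with cross-validated component selection.

library(aquarocket)

outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ds <- read_spectra("results/data/spectra_reflectance.csv", "wide_csv",
                   mode = "reflectance")
leak <- read.csv("results/data/leakage.csv")

bag_ds <- average_by(reflectance_to_absorbance(ds),
                     c("treatment", "day", "bag"))
prep <- apply_steps(bag_ds, "pls_prep")$ds
ild_bag <- aggregate(ild ~ treatment + day + bag, data = leak, FUN = mean)
key <- function(d) paste(d$treatment, d$day, d$bag)
y <- ild_bag$ild[match(key(prep$samples), key(ild_bag))]

sel <- cross_validate(prep, y, max_components = 6)
write.csv(sel$table, file.path(outdir, "pls_component_selection.csv"),
          row.names = FALSE)
cat("component selection (one-SE rule):", sel$recommended, "LV\n")

fit <- fit_pls(prep, y, n_components = sel$recommended)
print(fit)
write.csv(data.frame(prep$samples[c("treatment", "day", "bag")], ild = y,
                     fitted = fit$fitted, cv_pred = fit$cv_pred),
          file.path(outdir, "pls_predictions.csv"), row.names = FALSE)
jsonlite::write_json(list(n_components = fit$n_components, r_cal = fit$r_cal,
                          r_cv = fit$r_cv, secv = fit$secv,
                          cv_scheme = fit$cv_scheme),
                     file.path(outdir, "pls_metrics.json"),
                     auto_unbox = TRUE, digits = NA)

df <- data.frame(observed = y, calibration = fit$fitted,
                 cross_validation = fit$cv_pred)
p <- ggplot2::ggplot(df, ggplot2::aes(observed)) +
  ggplot2::geom_point(ggplot2::aes(y = calibration), colour = "blue") +
  ggplot2::geom_point(ggplot2::aes(y = cross_validation), colour = "red") +
  ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
  ggplot2::labs(x = "observed leaf-damage index (%)", y = "predicted (%)") +
  ggplot2::theme_minimal()
ggplot2::ggsave(file.path(outdir, "pls_scatter.png"), p,
                width = 5, height = 4.5, dpi = 150)
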