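#!/usr/bin/env Rscript
# Group statistics: per-treatment one-way ANOVA + LSD of the leaf-damage
# index across storage days (bag means), per-sensor E-nose ANOVA + Tukey
# across days, and the E-nose PCA biplot table.

library(aquarocket)

outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

leak <- read.csv("results/data/leakage.csv")
enose <- read.csv("results/data/enose.csv")

## leaf-damage index: bag means, ANOVA + LSD across days per treatment
bag <- aggregate(ild ~ treatment + day + bag, data = leak, FUN = mean)
rows <- list()
for (tr in c("A", "B", "C")) {
  sub <- bag[bag$treatment == tr, ]
  ls <- lsd_test(sub$ild, sub$day)
  cat(sprintf("treatment %s: F = %.1f, p = %.2g, LSD = %.2f%%; day 13 mean %.1f%% vs day 0 %.1f%%\n",
              tr, ls$F, ls$p, ls$lsd_value,
              ls$means[["13"]], ls$means[["0"]]))
  rows[[tr]] <- data.frame(treatment = tr, ls$pairs)
}
write.csv(do.call(rbind, rows), file.path(outdir, "ild_lsd_pairs.csv"),
          row.names = FALSE)

# which atmosphere preserves freshness longest: first day whose mean
# leaves the day-0 LSD band
for (tr in c("A", "B", "C")) {
  sub <- bag[bag$treatment == tr, ]
  ls <- lsd_test(sub$ild, sub$day)
  vs0 <- ls$pairs[grepl("^0-", ls$pairs$pair), ]
  first <- suppressWarnings(min(as.numeric(sub("0-", "", vs0$pair[vs0$significant]))))
  cat(sprintf("treatment %s: first significant rise over day 0 at day %s\n",
              tr, if (is.finite(first)) first else "none"))
}

## E-nose: bag means, per-sensor ANOVA across days, Tukey on W5S
bagmeans <- aggregate(enose[enose_sensors()],
                      by = enose[c("treatment", "day", "bag")], FUN = mean)
res <- enose_anova(bagmeans)
write.csv(res, file.path(outdir, "enose_anova.csv"), row.names = FALSE)
sig <- res[res$significant, ]
cat("sensors with a storage-day effect:\n")
print(table(sig$treatment, sig$sensor))

subC <- bagmeans[bagmeans$treatment == "C", ]
tk <- tukey_hsd(subC$W5S, subC$day)
print(tk)

bp <- enose_pca(enose)
write.csv(bp$scores, file.path(outdir, "enose_pca_scores.csv"),
          row.names = FALSE)
write.csv(bp$loadings, file.path(outdir, "enose_pca_loadings.csv"),
          row.names = FALSE)
cat(sprintf("E-nose PCA: PC1 %.1f%%, PC2 %.1f%%\n",
            bp$pca$explained_variance_pct[1], bp$pca$explained_variance_pct[2]))
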