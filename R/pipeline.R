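# End-to-end orchestration of the three analysis chains (exploratory PCA,
# PLS vs the leaf-damage index, aquagrams) plus the leakage and E-nose
# statistics, from a single config. All quantitative artifacts are CSV or
# JSON; figures are side artifacts so downstream checks never parse images.

write_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write.csv(format(as.data.frame(df), digits = 17, trim = TRUE,
                   scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stable hash of the semantic config: serialised to canonical JSON first so
# field order and attribute noise cannot change the hash. The output
# directory is where results land, not what they are, so it is excluded.
config_hash <- function(cfg) {
  cfg$outdir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Default run configuration
#'
#' @param preset synthetic scenario preset (`"trial1"` or `"trial2"`).
#' @param seed scenario seed.
#' @param outdir output directory.
#' @param alpha significance level for the group statistics.
#' @param pls_components latent variables for the PLS model.
#' @param figures also render radar charts and score plots (PNG).
#' @return named list understood by [run_all()].
#' @export
run_config <- function(preset = "trial1", seed = 1, outdir = "results",
                       alpha = 0.05, pls_components = 2, figures = FALSE,
                       leakage = TRUE) {
  list(preset = preset, seed = seed, outdir = outdir, alpha = alpha,
       pls_components = pls_components, figures = figures, leakage = leakage)
}

#' Run the full monitoring analysis
#'
#' Generates the scenario data (spectra, leakage, E-nose), then runs the
#' three chains: (1) exploratory PCA on smoothed gap-derivative spectra in
#' the water first overtone; (2) PLS regression of the leaf-damage index
#' on SNV + second-derivative spectra at bag level; (3) aquagram
#' construction on the standardised second-derivative spectra; plus the
#' leakage ANOVA/LSD and the per-sensor E-nose ANOVA and PCA. Every
#' numeric artifact is written as CSV/JSON under `cfg$outdir`, and a
#' manifest records the config, its hash, seeds, artifact list and
#' per-stage timings. Re-running with the same config reproduces every
#' numeric artifact bit for bit.
#'
#' @param cfg configuration list from [run_config()] or a YAML file path.
#' @return the manifest, invisibly.
#' @export
run_all <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  defaults <- run_config()
  cfg <- utils::modifyList(defaults, cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   artifacts = character(), timings = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      # retain partial artifacts and mark the failed stage in the manifest
      manifest$failed_stage <- name
      jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(obj, file) {
    path <- file.path(cfg$outdir, file)
    if (is.data.frame(obj) || is.matrix(obj)) write_table(obj, path)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    manifest$artifacts <<- c(manifest$artifacts, file)
    path
  }

  # -- simulate ------------------------------------------------------------
  sim <- t_stage("simulate", {
    sc <- spectral_scenario(preset = cfg$preset, seed = cfg$seed)
    gen <- generate_spectra(sc)
    leak <- if (isTRUE(cfg$leakage)) generate_leakage(sc, truth = gen$truth)
            else NULL
    enose <- generate_enose(sc)
    list(sc = sc, gen = gen, leak = leak, enose = enose)
  })
  t_stage("simulate_write", {
    write_spectra(sim$gen$ds, file.path(cfg$outdir, "spectra_raw.csv"),
                  "wide_csv")
    manifest$artifacts <- c(manifest$artifacts, "spectra_raw.csv")
    if (!is.null(sim$leak))
      emit(sim$leak[, c("treatment", "day", "bag", "replicate", "ic", "fc",
                        "ild")], "leakage.csv")
    emit(sim$enose, "enose.csv")
    emit(list(bags = sim$gen$truth$bags, bands = sim$gen$truth$bands),
         "truth.json")
  })

  absb <- reflectance_to_absorbance(sim$gen$ds)

  # -- chain 1: exploratory PCA on checkpoint means ------------------------
  pca <- t_stage("pca", {
    prep <- apply_steps(checkpoint_means(absb), "pca_prep")$ds
    fit <- fit_pca(prep, n_components = min(4, n_spectra(prep) - 1))
    scores <- cbind(prep$samples[c("treatment", "day")],
                    as.data.frame(fit$scores))
    names(scores)[-(1:2)] <- paste0("PC", seq_len(ncol(fit$scores)))
    emit(scores, "pca_scores.csv")
    emit(data.frame(wavelength = prep$wavelengths, fit$loadings),
         "pca_loadings.csv")
    emit(list(explained_variance_pct = fit$explained_variance_pct),
         "pca_metrics.json")
    fit
  })

  # -- chain 2: PLS of the leaf-damage index on bag-mean spectra -----------
  pls <- if (cfg$pls_components < 1) NULL else t_stage("pls", {
    if (is.null(sim$leak))
      stop("PLS requested but the config provides no leakage input")
    bag_ds <- average_by(absb, c("treatment", "day", "bag"))
    prep <- apply_steps(bag_ds, "pls_prep")$ds
    ild_bag <- stats::aggregate(ild ~ treatment + day + bag,
                                data = sim$leak, FUN = mean)
    key <- function(d) paste(d$treatment, d$day, d$bag)
    m <- match(key(prep$samples), key(ild_bag))
    if (anyNA(m)) stop("leakage records do not cover every spectra bag")
    fit <- fit_pls(prep, ild_bag$ild[m], n_components = cfg$pls_components,
                   cv_seed = cfg$seed)
    emit(data.frame(prep$samples[c("treatment", "day", "bag")],
                    ild = ild_bag$ild[m], fitted = fit$fitted,
                    cv_pred = fit$cv_pred), "pls_predictions.csv")
    emit(list(n_components = fit$n_components, r_cal = fit$r_cal,
              r_cv = fit$r_cv, secv = fit$secv, cv_scheme = fit$cv_scheme),
         "pls_metrics.json")
    fit
  })

  # -- chain 3: aquagrams --------------------------------------------------
  aq <- t_stage("aquagram", {
    prep <- apply_steps(absb, "aqua_prep")$ds
    aq <- compute_aquagram(prep, default_wabs(), c("treatment", "day"))
    emit(as.data.frame(aq), "aquagram.csv")
    aq
  })

  # -- statistics ----------------------------------------------------------
  t_stage("stats", {
    if (!is.null(sim$leak)) {
      bag_means <- stats::aggregate(ild ~ treatment + day + bag,
                                    data = sim$leak, FUN = mean)
      rows <- lapply(sort(unique(bag_means$treatment)), function(tr) {
        sub <- bag_means[bag_means$treatment == tr, ]
        ls <- lsd_test(sub$ild, sub$day, alpha = cfg$alpha)
        data.frame(treatment = tr, F = ls$F, p = ls$p,
                   lsd = ls$lsd_value,
                   d13_vs_d0 = ls$pairs$significant[ls$pairs$pair == "0-13"])
      })
      emit(do.call(rbind, rows), "ild_anova.csv")
    }
    emit(enose_anova(sim$enose, alpha = cfg$alpha), "enose_anova.csv")
    ep <- enose_pca(sim$enose)
    emit(ep$scores, "enose_pca_scores.csv")
    emit(ep$loadings, "enose_pca_loadings.csv")
  })

  if (isTRUE(cfg$figures)) {
    t_stage("figures", {
      render_aquagram(aq, file.path(cfg$outdir, "aquagram.png"),
                      panel_by = "treatment")
      manifest$artifacts <- c(manifest$artifacts, "aquagram.png")
    })
  }

  manifest$summary <- c(
    list(pca_pc1_pct = pca$explained_variance_pct[1]),
    if (!is.null(pls)) list(pls_r_cal = pls$r_cal, pls_r_cv = pls$r_cv,
                            pls_secv = pls$secv)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
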