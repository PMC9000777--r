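# Electrolyte-leakage index and the group-comparison statistics used for
# the leakage and electronic-nose tables: one-way ANOVA, Fisher LSD and
# Tukey HSD. ANOVA goes through stats::aov; the LSD value is computed from
# the ANOVA mean squared error by the textbook formula.

#' Index of leaf damage from a conductivity pair
#'
#' `I_LD = 100 * IC / FC`: initial conductivity of the leaf-piece bath
#' relative to the final conductivity after freeze-thaw releases all
#' electrolytes. Proxies cell-membrane permeability, hence tissue damage.
#'
#' @param ic initial conductivity (uS/cm), >= 0. Vectorised.
#' @param fc final conductivity (uS/cm), > 0. Vectorised.
#' @return leakage index in percent. `ic > fc` triggers a warning (the
#'   index would exceed 100%, physically suspect).
#' @export
compute_ild <- function(ic, fc) {
  if (any(fc <= 0)) stop("compute_ild: final conductivity must be > 0")
  if (any(ic < 0)) stop("compute_ild: initial conductivity must be >= 0")
  if (any(ic > fc))
    warning("compute_ild: IC > FC for ", sum(ic > fc),
            " record(s); index exceeds 100%")
  100 * ic / fc
}

#' Attach the leakage index to a conductivity table
#'
#' @param df data frame with columns `ic` and `fc` (plus any metadata such
#'   as `treatment`, `day`, `replicate`).
#' @return `df` with an `ild` column appended.
#' @export
leakage_table <- function(df) {
  stopifnot(all(c("ic", "fc") %in% names(df)))
  df$ild <- compute_ild(df$ic, df$fc)
  df
}

as_group_list <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    if (is.null(names(values))) names(values) <- as.character(seq_along(values))
    return(values)
  }
  split(as.numeric(values), groups)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()]. The
#' degenerate case where every observation is identical is reported as
#' F = 0, p = 1 rather than an error.
#'
#' @param values list of per-group numeric vectors, or a numeric vector
#'   accompanied by `groups`.
#' @param groups optional grouping factor when `values` is a vector.
#' @return object of class `group_comparison` with `levels`, `F`, `p`,
#'   `df_between`, `df_within`, `mse`, `means`, `n`.
#' @export
anova_oneway <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  if (length(gl) < 2) stop("anova_oneway: need >= 2 groups")
  if (any(lengths(gl) < 2)) stop("anova_oneway: each group needs >= 2 observations")
  y <- unlist(gl, use.names = FALSE)
  g <- factor(rep(names(gl), lengths(gl)), levels = names(gl))
  if (length(unique(y)) == 1L) {      # documented degenerate limit
    return(structure(list(
      levels = names(gl), F = 0, p = 1,
      df_between = length(gl) - 1L, df_within = length(y) - length(gl),
      mse = 0, means = vapply(gl, mean, 0), n = lengths(gl)
    ), class = "group_comparison"))
  }
  tab <- anova(aov(y ~ g))
  Fstat <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(Fstat)) { Fstat <- 0; p <- 1 }
  structure(list(
    levels = names(gl),
    F = Fstat, p = p,
    df_between = tab$Df[1], df_within = tab$Df[2],
    mse = tab$`Mean Sq`[2],
    means = vapply(gl, mean, 0), n = lengths(gl)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  if (!is.null(x$pairs)) {
    sig <- x$pairs[x$pairs$significant, , drop = FALSE]
    cat("  significant pairs (", x$method, ", alpha = ", x$alpha, "): ",
        if (nrow(sig)) paste(sig$pair, collapse = ", ") else "none", "\n",
        sep = "")
  }
  invisible(x)
}

pairwise_frame <- function(levels) {
  idx <- utils::combn(seq_along(levels), 2)
  data.frame(i = idx[1, ], j = idx[2, ],
             pair = paste(levels[idx[1, ]], levels[idx[2, ]], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Fisher least significant difference post-hoc test
#'
#' After a one-way ANOVA, the LSD for a pair (i, j) is
#' `t(1 - alpha/2, df_within) * sqrt(MSE * (1/n_i + 1/n_j))`; a pair of
#' means differing by more than its LSD is declared significant at alpha.
#' For two groups this reduces exactly to the pooled-variance t-test.
#'
#' @inheritParams anova_oneway
#' @param alpha significance level.
#' @return `group_comparison` with a `pairs` data frame (`pair`, `diff`,
#'   `lsd`, `significant`) and `lsd_value` (the common LSD under balanced
#'   group sizes, else NA).
#' @export
lsd_test <- function(values, groups = NULL, alpha = 0.05) {
  an <- anova_oneway(values, groups)
  pr <- pairwise_frame(an$levels)
  tcrit <- qt(1 - alpha / 2, an$df_within)
  pr$diff <- abs(an$means[pr$i] - an$means[pr$j])
  pr$lsd <- tcrit * sqrt(an$mse * (1 / an$n[pr$i] + 1 / an$n[pr$j]))
  pr$significant <- pr$diff > pr$lsd
  an$pairs <- pr[, c("pair", "diff", "lsd", "significant")]
  an$lsd_value <- if (length(unique(an$n)) == 1L) pr$lsd[1] else NA_real_
  an$alpha <- alpha
  an$method <- "LSD"
  an
}

#' Tukey honestly significant difference post-hoc test
#'
#' Studentized-range-based pairwise comparisons (Tukey-Kramer for
#' unbalanced groups): critical difference for pair (i, j) is
#' `q(1 - alpha, k, df) / sqrt(2) * sqrt(MSE * (1/n_i + 1/n_j))`. For two
#' groups, `q = t * sqrt(2)` makes the decision identical to the pooled
#' t-test.
#'
#' @inheritParams lsd_test
#' @return `group_comparison` with `pairs` (`pair`, `diff`, `hsd`,
#'   `p_adj`, `significant`).
#' @export
tukey_hsd <- function(values, groups = NULL, alpha = 0.05) {
  an <- anova_oneway(values, groups)
  k <- length(an$levels)
  pr <- pairwise_frame(an$levels)
  qcrit <- qtukey(1 - alpha, k, an$df_within)
  pr$diff <- abs(an$means[pr$i] - an$means[pr$j])
  se <- sqrt(an$mse / 2 * (1 / an$n[pr$i] + 1 / an$n[pr$j]))
  pr$hsd <- qcrit * se
  pr$p_adj <- ptukey(pr$diff / se, k, an$df_within, lower.tail = FALSE)
  pr$significant <- pr$diff > pr$hsd
  an$pairs <- pr[, c("pair", "diff", "hsd", "p_adj", "significant")]
  an$alpha <- alpha
  an$method <- "Tukey HSD"
  an
}

# ---- electronic nose -----------------------------------------------------

#' Sensor names of the 10-channel MOS electronic nose
#' @return character vector of the ten sensor labels.
#' @export
enose_sensors <- function() {
  c("W1C", "W5S", "W3C", "W6S", "W5C", "W1S", "W1W", "W2S", "W2W", "W3S")
}

#' Per-sensor ANOVA across storage days
#'
#' For each treatment and each sensor, a one-way ANOVA (plus Tukey HSD)
#' of the conductivity ratio G/G0 across storage days, on replicate (bag)
#' means. Sensors are tested independently; no correction is applied
#' across sensors.
#'
#' @param df E-nose table: `treatment`, `day`, `replicate` and the ten
#'   sensor columns.
#' @param alpha significance level.
#' @return data frame with one row per (treatment, sensor): `F`, `p`,
#'   `significant`.
#' @export
enose_anova <- function(df, alpha = 0.05) {
  sensors <- enose_sensors()
  stopifnot(all(sensors %in% names(df)))
  out <- list()
  for (tr in sort(unique(df$treatment))) {
    sub <- df[df$treatment == tr, , drop = FALSE]
    for (s in sensors) {
      an <- anova_oneway(sub[[s]], sub$day)
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, sensor = s, F = an$F, p = an$p,
        significant = an$p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' PCA biplot data for the E-nose sensor table
#'
#' Standardised-column PCA of the (treatment, day) mean sensor table; the
#' biplot overlays sensor loadings on the checkpoint scores.
#'
#' @param df E-nose table as in [enose_anova()].
#' @param n_components components to keep.
#' @return list with `pca` (a `pca_result`), `scores` (data frame with
#'   treatment/day), `loadings` (data frame with sensor labels).
#' @export
enose_pca <- function(df, n_components = 2) {
  sensors <- enose_sensors()
  stopifnot(all(sensors %in% names(df)))
  agg <- stats::aggregate(df[sensors],
                          by = df[c("treatment", "day")], FUN = mean)
  pca <- fit_pca(as.matrix(agg[sensors]), n_components = n_components,
                 scale = TRUE)
  scores <- cbind(agg[c("treatment", "day")], as.data.frame(pca$scores))
  names(scores)[-(1:2)] <- paste0("PC", seq_len(n_components))
  loadings <- data.frame(sensor = sensors, pca$loadings)
  names(loadings)[-1] <- paste0("PC", seq_len(n_components))
  list(pca = pca, scores = scores, loadings = loadings)
}
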