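# Exploratory PCA and PLS regression of the leaf-damage index on spectra.
# PCA is a thin, sign-stabilised wrapper around the SVD; the PLS1 fit is a
# NIPALS implementation kept in-package so the cross-validation scheme and
# the SECV definition are fully under control.

#' Principal component analysis of a spectral dataset
#'
#' Column-mean-centred SVD. Loadings carry a deterministic sign convention:
#' the largest-magnitude element of each loading vector is positive, so
#' results are reproducible across platforms and runs.
#'
#' @param ds a `spectral_dataset` (or plain numeric matrix).
#' @param n_components number of components to keep;
#'   `<= min(n_samples - 1, n_wavelengths)`.
#' @param scale also scale columns to unit variance (used for the
#'   electronic-nose sensor table, where sensors live on different scales).
#' @return object of class `pca_result`: `scores` (n x k), `loadings`
#'   (p x k, orthonormal columns), `explained_variance_pct`, `center`,
#'   `scale`, `wavelengths` (NULL for non-spectral input).
#' @export
fit_pca <- function(ds, n_components = 2, scale = FALSE) {
  if (inherits(ds, "spectral_dataset")) {
    validate_spectral_dataset(ds)
    X <- ds$values
    wl <- ds$wavelengths
  } else {
    X <- as.matrix(ds)
    wl <- NULL
  }
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("fit_pca: need at least 2 samples")
  kmax <- min(n - 1, p)
  if (n_components > kmax)
    stop("fit_pca: n_components must be <= min(n_samples - 1, n_wavelengths)")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- rep(1, p)
  if (scale) {
    scl <- apply(X, 2L, sd)
    if (any(scl == 0)) stop("fit_pca: zero-variance column under scale = TRUE")
    Xc <- sweep(Xc, 2L, scl, "/")
  }
  sv <- svd(Xc, nu = kmax, nv = kmax)
  eig <- sv$d^2 / (n - 1)                      # covariance eigenvalues
  total <- sum(Xc^2) / (n - 1)
  load <- sv$v[, seq_len(n_components), drop = FALSE]
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {            # stabilise loading signs
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(
    scores = scores,
    loadings = load,
    explained_variance_pct = 100 * eig[seq_len(n_components)] / total,
    eigenvalues = eig[seq_len(kmax)],
    center = ctr, scale = scl, wavelengths = wl,
    samples = if (inherits(ds, "spectral_dataset")) ds$samples else NULL
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", ncol(x$scores), "components;",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$explained_variance_pct),
                     x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

# NIPALS PLS1 core: returns weights W, loadings P, scores T, y-loadings q
# and the regression vector in centred coordinates.
pls1_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ctr_x <- colMeans(X); ctr_y <- mean(y)
  E <- sweep(X, 2L, ctr_x, "-")
  f <- y - ctr_y
  W <- P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- as.vector(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * 1e3) {       # residual orthogonal to y
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      TT <- TT[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      break
    }
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    pvec <- as.vector(crossprod(E, t)) / tt
    qa <- sum(t * f) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; TT[, a] <- t; q[a] <- qa
  }
  ncomp_eff <- length(q)
  # regression vector: B = W (P'W)^-1 q
  B <- if (ncomp_eff)
    W %*% solve(crossprod(P, W), q) else matrix(0, p, 1)
  list(W = W, P = P, scores = TT, q = q, coef = as.vector(B),
       center_x = ctr_x, center_y = ctr_y, ncomp = ncomp_eff)
}

pls1_predict <- function(fit, Xnew) {
  as.vector(sweep(as.matrix(Xnew), 2L, fit$center_x, "-") %*% fit$coef) +
    fit$center_y
}

#' Cross-validation fold assignment
#'
#' Leave-one-out when `n <= loo_max`, otherwise `k` random segments drawn
#' reproducibly from `seed`.
#'
#' @param n number of samples.
#' @param scheme `"auto"`, `"loo"` or `"kfold"`.
#' @param k segment count for `"kfold"`.
#' @param loo_max largest n for which `"auto"` uses leave-one-out.
#' @param seed RNG seed for segment assignment.
#' @return list with `folds` (integer assignment per sample) and
#'   `description`.
#' @export
cv_folds <- function(n, scheme = c("auto", "loo", "kfold"), k = 10,
                     loo_max = 40, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "auto") scheme <- if (n <= loo_max) "loo" else "kfold"
  if (scheme == "loo") {
    list(folds = seq_len(n), description = "leave-one-out")
  } else {
    if (k < 2 || k > n) stop("cv_folds: need 2 <= k <= n")
    folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
    list(folds = folds,
         description = sprintf("%d random segments (seed %d)", k, seed))
  }
}

#' PLS regression of a response on spectra
#'
#' NIPALS PLS1 with calibration and cross-validated performance, as used to
#' link NIR spectra to the electrolyte-leakage index of leaf damage.
#' Reported `r_cal` and `r_cv` are Pearson correlations between predictions
#' and observations; `secv = sqrt(sum((yhat_cv - y)^2) / (n - 1))`, in the
#' units of `y` (percent for the leaf-damage index).
#'
#' @param ds a `spectral_dataset` or numeric matrix of predictors.
#' @param y numeric response, one value per spectrum.
#' @param n_components number of latent variables.
#' @param cv cross-validation scheme passed to [cv_folds()].
#' @param cv_k,cv_seed segment count and seed for k-fold CV.
#' @return object of class `pls_result`: `n_components`, `coefficients`
#'   (per wavelength, centred-data scale), `intercept`, `fitted`, `cv_pred`,
#'   `r_cal`, `r_cv`, `secv`, `factor_loadings`, `scores`, `cv_scheme`,
#'   `r_cal_ge_r_cv` (FALSE flags the unusual r_cv > r_cal case).
#' @export
fit_pls <- function(ds, y, n_components = 2, cv = "auto", cv_k = 10,
                    cv_seed = 1) {
  X <- if (inherits(ds, "spectral_dataset")) {
    validate_spectral_dataset(ds); ds$values
  } else as.matrix(ds)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("fit_pls: length(y) != number of spectra")
  if (sd(y) == 0) stop("fit_pls: constant response")
  if (n_components < 1) stop("fit_pls: n_components >= 1 required")

  fit <- pls1_nipals(X, y, n_components)
  fitted <- pls1_predict(fit, X)

  cvf <- cv_folds(n, cv, k = cv_k, seed = cv_seed)
  if (min(table(cvf$folds)) < 1) stop("fit_pls: empty CV fold")
  cv_pred <- numeric(n)
  for (f in unique(cvf$folds)) {
    hold <- which(cvf$folds == f)
    if (length(hold) >= n - 1) stop("fit_pls: CV fold leaves < 2 samples to fit")
    sub <- pls1_nipals(X[-hold, , drop = FALSE], y[-hold], n_components)
    cv_pred[hold] <- pls1_predict(sub, X[hold, , drop = FALSE])
  }
  r_cal <- stats::cor(fitted, y)
  r_cv <- stats::cor(cv_pred, y)
  secv <- sqrt(sum((cv_pred - y)^2) / (n - 1))
  structure(list(
    n_components = fit$ncomp,
    coefficients = fit$coef,
    intercept = fit$center_y - sum(fit$center_x * fit$coef),
    fitted = fitted, cv_pred = cv_pred, y = y,
    r_cal = r_cal, r_cv = r_cv, secv = secv,
    factor_loadings = fit$P, scores = fit$scores,
    wavelengths = if (inherits(ds, "spectral_dataset")) ds$wavelengths else NULL,
    cv_scheme = cvf$description,
    r_cal_ge_r_cv = r_cal >= r_cv
  ), class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf(
    "<pls_result> %d LV; r_cal = %.3f, r_cv = %.3f, SECV = %.3f (%s)\n",
    x$n_components, x$r_cal, x$r_cv, x$secv, x$cv_scheme))
  invisible(x)
}

#' Cross-validated component-count selection
#'
#' Fits PLS models with 1..max_components latent variables and tabulates
#' cross-validated correlation and SECV. The recommended component count is
#' chosen by the one-standard-error parsimony rule: the smallest count
#' whose SECV is within one standard error (of the per-sample squared CV
#' residuals) of the global SECV minimum.
#'
#' @inheritParams fit_pls
#' @param max_components largest component count to try.
#' @return list with `table` (data frame: n_components, r_cv, secv) and
#'   `recommended`.
#' @export
cross_validate <- function(ds, y, max_components = 10, cv = "auto",
                           cv_k = 10, cv_seed = 1) {
  if (max_components < 1) stop("cross_validate: max_components >= 1")
  X <- if (inherits(ds, "spectral_dataset")) ds$values else as.matrix(ds)
  max_components <- min(max_components, ncol(X), nrow(X) - 2)
  rows <- lapply(seq_len(max_components), function(k) {
    m <- fit_pls(ds, y, n_components = k, cv = cv, cv_k = cv_k,
                 cv_seed = cv_seed)
    list(n_components = k, r_cv = m$r_cv, secv = m$secv,
         se_secv = se_of_secv(m$cv_pred, m$y))
  })
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  best <- which.min(tab$secv)
  ok <- tab$secv <= tab$secv[best] + tab$se_secv[best]
  recommended <- tab$n_components[which(ok)[1]]
  list(table = tab[, c("n_components", "r_cv", "secv")],
       recommended = recommended)
}

# standard error of the SECV via the delta method on the mean squared
# CV residual
se_of_secv <- function(cv_pred, y) {
  e2 <- (cv_pred - y)^2
  n <- length(e2)
  mse <- sum(e2) / (n - 1)
  se_mse <- sd(e2) / sqrt(n)
  se_mse / (2 * sqrt(mse))
}
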