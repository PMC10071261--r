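# Deviance decomposition for soft-partitioned mixtures of GLMs.
#
# Every deviance here is twice a weighted log-likelihood difference taken at
# the fitted soft partition z-hat and at the fitted dispersions phi-hat, so
# that the measures isolate the fit due to the regressors.  The per-family
# closed forms below are algebraically identical to those differences; the
# identity is asserted by the test suite against the exact-density route.

# elementwise "pseudo log-likelihood core" (1/a) * [y * theta(mu) - b(theta)],
# dropping y-only terms (they cancel in every deviance difference); boundary
# means (mu = 0, mu = m) are allowed under the 0 * log(0) = 0 convention
dev_core <- function(y, mu, family, phi = 1) {
  switch(family$name,
    gaussian = (y * mu - mu^2 / 2) / phi,
    poisson  = xlogy(y, mu) - mu,
    binomial = xlogy(y, mu) + xlogy(family$m - y, family$m - mu)
  )
}

# x * log(y) with the 0 * log(0) := 0 limit
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

# weighted deviance 2 * sum(z * [core(better) - core(ref)]); `better` nests ref
wdev <- function(y, better, ref, z, family, phi = 1) {
  2 * sum(z * (dev_core(y, better, family, phi) -
                 dev_core(y, ref, family, phi)))
}

#' Local deviance components of a fitted mixture
#'
#' For each soft cluster `j` of a fitted mixture of GLMs, computes the local
#' null deviance `D_j` (saturated vs local intercept-only model with mean
#' `ybar_j`, the soft weighted response mean), the local residual deviance
#' `RD_j` (saturated vs fitted), the local explained deviance `ED_j`
#' (fitted vs local intercept-only), and the contribution `BD_j` of cluster
#' `j` to the between deviance (local intercept-only vs grand-mean model).
#' All are evaluated at the fitted soft partition and the fitted
#' dispersions, via family-specific closed forms: weighted standardized sums
#' of squares for Gaussian, and the familiar count-scale formulas for
#' Poisson and binomial.
#'
#' @param fit A `"mixglm"` fit.
#' @param method `"closed"` for the family closed forms (default) or
#'   `"loglik"` for the definition as twice a difference of exact weighted
#'   log-likelihoods (the slower, fully general route; the two agree to
#'   numerical precision).
#' @param offset_null If `TRUE` and the fit has a Poisson offset, the local
#'   null model is a weighted intercept-only GLM *with* the offset instead
#'   of the flat soft mean `ybar_j`.  Default `FALSE`: the local null is
#'   mean-based.
#' @return Tibble with one row per cluster: `cluster`, `soft_size`,
#'   `soft_mean`, `D`, `RD`, `ED`, `BD`.
#' @export
local_deviances <- function(fit, method = c("closed", "loglik"),
                            offset_null = FALSE) {
  stopifnot(inherits(fit, "mixglm"))
  method <- match.arg(method)
  fam <- fit$family
  y <- fit$y
  z <- fit$posteriors
  muhat <- fit$fitted_means
  ybar_j <- fit$soft_means
  ybar <- fit$grand_mean
  k <- fit$k

  if (fam$name %in% c("poisson", "binomial")) {
    bad <- which(ybar_j <= 0 | (fam$name == "binomial" & ybar_j >= fam$m))
    if (length(bad)) {
      stop(sprintf("cluster %d has its soft mean on the domain boundary",
                   bad[1]), call. = FALSE)
    }
  }

  # local null means: n x k matrix (constant columns unless offset-aware)
  null_mu <- matrix(rep(ybar_j, each = length(y)), ncol = k)
  if (offset_null && !is.null(fit$offset)) {
    for (j in seq_len(k)) {
      null_mu[, j] <- fit_weighted_glm(y, NULL, w = z[, j], family = fam,
                                       offset = fit$offset,
                                       intercept_only = TRUE)$fitted
    }
  }

  D <- RD <- ED <- BD <- numeric(k)
  for (j in seq_len(k)) {
    phi <- fit$params$phi[j]
    if (method == "closed") {
      D[j]  <- wdev(y, y, null_mu[, j], z[, j], fam, phi)
      RD[j] <- wdev(y, y, muhat[, j], z[, j], fam, phi)
      ED[j] <- wdev(y, muhat[, j], null_mu[, j], z[, j], fam, phi)
      BD[j] <- wdev(y, null_mu[, j], ybar, z[, j], fam, phi)
    } else {
      ll <- function(mu) weighted_loglik(y, mu, phi, z[, j], fam)
      ll_sat <- ll(y)
      ll_null <- ll(null_mu[, j])
      D[j]  <- 2 * (ll_sat - ll_null)
      RD[j] <- 2 * (ll_sat - ll(muhat[, j]))
      ED[j] <- 2 * (ll(muhat[, j]) - ll_null)
      BD[j] <- 2 * (ll_null - ll(rep(ybar, length(y))))
    }
  }
  tibble::tibble(cluster = seq_len(k), soft_size = fit$soft_sizes,
                 soft_mean = ybar_j, D = D, RD = RD, ED = ED, BD = BD)
}

#' Deviance decomposition and R-squared measures of a fitted mixture
#'
#' Assembles the full deviance decomposition of a fitted mixture of GLMs:
#'
#' * per cluster: `D_j = ED_j + RD_j`, the local deviance R-squared
#'   `R2_j = ED_j / D_j`, the weight `D_j / WD`, and the descriptive-only
#'   adjusted `R2bar_j`;
#' * totals: within `WD = sum(D_j)`, explained-within `EWD = sum(ED_j)`,
#'   residual-within `RWD = sum(RD_j)`, between `BD = sum(BD_j)`, and the
#'   total deviance `TD`, computed independently from the grand-mean null
#'   model and checked against `BD + EWD + RWD`;
#' * normalized shares `NBD + NEWD + NRWD = 1` and the explained share
#'   `NED = 1 - NRWD`;
#' * the overall deviance R-squared `R2 = EWD / WD`, a weighted average of
#'   the local `R2_j`;
#' * adjusted variants `R2bar_j` (dof `nhat_j - (d+1)` vs `nhat_j - 1`) and
#'   `R2bar` (dof `n - k(d+1)` vs `n - k`), flagged `descriptive_only`:
#'   they must not drive model or variable selection, because the soft
#'   partition (hence WD) changes with every refitted model.
#'
#' Undefined ratios (zero TD or zero `D_j`) are returned as `NA` with the
#' corresponding flag set, never silently coerced to 0 or 1.
#'
#' @inheritParams local_deviances
#' @return An object of class `"mixglm_deviance"`: list with `local`
#'   (tibble), `totals` (named list), `normalized`, `r2`, `adjusted`,
#'   `flags`, and the fit dimensions.
#' @examples
#' dat <- generate_mixture_data(simulation_condition("gaussian", 8), seed = 1)
#' fit <- mixglm(dat, y ~ x, family = "gaussian", k = 2,
#'               labels = "class", init = "true_labels")
#' deviance_decomposition(fit)
#' @export
deviance_decomposition <- function(fit, offset_null = FALSE) {
  stopifnot(inherits(fit, "mixglm"))
  loc <- local_deviances(fit, offset_null = offset_null)
  fam <- fit$family
  y <- fit$y
  z <- fit$posteriors
  ybar <- fit$grand_mean
  k <- fit$k
  n <- fit$n
  d <- fit$d

  WD <- sum(loc$D)
  EWD <- sum(loc$ED)
  RWD <- sum(loc$RD)
  BDt <- sum(loc$BD)
  # total deviance, computed independently: saturated vs grand-mean null,
  # each bracket at the fitted dispersion of its component
  TD <- sum(vapply(seq_len(k), function(j) {
    wdev(y, y, ybar, z[, j], fam, fit$params$phi[j])
  }, numeric(1)))

  rel <- abs(TD - (BDt + EWD + RWD)) / max(abs(TD), 1)
  if (is.finite(rel) && rel > 1e-8) {
    stop(sprintf("deviance decomposition identity violated (rel. error %.3g)",
                 rel), call. = FALSE)
  }

  flags <- list(td_zero = !(is.finite(TD) && TD > 0),
                dj_zero = which(!(loc$D > 0)),
                descriptive_only = TRUE)

  loc$R2 <- ifelse(loc$D > 0, loc$ED / loc$D, NA_real_)
  loc$weight <- if (WD > 0) loc$D / WD else rep(NA_real_, k)
  dof_r <- loc$soft_size - (d + 1)
  dof_n <- loc$soft_size - 1
  loc$R2bar <- ifelse(dof_r > 0 & dof_n > 0 & loc$D > 0,
                      1 - (loc$RD / dof_r) / (loc$D / dof_n), NA_real_)

  normalized <- if (!flags$td_zero) {
    list(NBD = BDt / TD, NEWD = EWD / TD, NRWD = RWD / TD,
         NED = 1 - RWD / TD)
  } else {
    list(NBD = NA_real_, NEWD = NA_real_, NRWD = NA_real_, NED = NA_real_)
  }
  R2 <- if (WD > 0) EWD / WD else NA_real_
  R2bar <- if (n - k * (d + 1) > 0 && n - k > 0 && WD > 0) {
    1 - (RWD / (n - k * (d + 1))) / (WD / (n - k))
  } else NA_real_

  structure(list(local = loc,
                 totals = list(WD = WD, BD = BDt, EWD = EWD, RWD = RWD,
                               TD = TD),
                 normalized = normalized,
                 r2 = R2,
                 adjusted = list(R2bar = R2bar, descriptive_only = TRUE),
                 flags = flags,
                 n = n, d = d, k = k, family = fam$name),
            class = "mixglm_deviance")
}

#' @export
print.mixglm_deviance <- function(x, digits = 4, ...) {
  cat(sprintf("Deviance decomposition (%s mixture, k = %d, n = %d)\n",
              x$family, x$k, x$n))
  print(as.data.frame(lapply(x$local, round, digits)), row.names = FALSE)
  with(x$totals, cat(sprintf(
    "WD %.4f  BD %.4f  EWD %.4f  RWD %.4f  TD %.4f\n", WD, BD, EWD, RWD, TD)))
  with(x$normalized, cat(sprintf(
    "NBD %.4f  NEWD %.4f  NRWD %.4f  NED %.4f\n", NBD, NEWD, NRWD, NED)))
  cat(sprintf("overall R2 %.4f   adjusted R2bar %.4f (descriptive only)\n",
              x$r2, x$adjusted$R2bar))
  invisible(x)
}

#' Adjusted deviance R-squared measures (descriptive only)
#'
#' Recomputes the degree-of-freedom-adjusted local and overall deviance
#' R-squared values from raw ingredients.  These are **descriptive-only**
#' diagnostics: because the soft partition, and with it the within deviance,
#' changes whenever the covariate set or the number of components changes,
#' they cannot be compared across models and must not be used for model or
#' variable selection.  A warning to that effect is emitted.
#'
#' @param RD,D Per-cluster residual and null deviances.
#' @param RWD,WD Overall residual-within and within deviances.
#' @param soft_sizes Soft cluster sizes `nhat_j`.
#' @param n,d,k Sample size, number of covariates, number of components.
#' @return List with `R2bar_j` (per cluster) and `R2bar`; both carry
#'   attribute `descriptive_only = TRUE`.  Nonpositive degrees of freedom
#'   yield `NA`.
#' @export
adjusted_r2 <- function(RD, D, RWD, WD, soft_sizes, n, d, k) {
  warning("adjusted deviance R-squared values are descriptive only; ",
          "do not use them for model or variable selection", call. = FALSE)
  dof_r <- soft_sizes - (d + 1)
  dof_n <- soft_sizes - 1
  r2j <- ifelse(dof_r > 0 & dof_n > 0 & D > 0,
                1 - (RD / dof_r) / (D / dof_n), NA_real_)
  r2 <- if (n - k * (d + 1) > 0 && n - k > 0 && WD > 0) {
    1 - (RWD / (n - k * (d + 1))) / (WD / (n - k))
  } else NA_real_
  structure(list(R2bar_j = r2j, R2bar = r2), descriptive_only = TRUE)
}
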