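#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted mixture of GLMs
#'
#' One row per component and coefficient, with standard errors from the
#' observed weighted Fisher information at convergence (the classical
#' soft-weighted GLM approximation; mixture-EM standard errors obtained this
#' way are approximate because they ignore the uncertainty of the
#' memberships).
#'
#' @param x A `"mixglm"` fit.
#' @param ... Unused.
#' @return Tibble with columns `component`, `term`, `estimate`,
#'   `std.error`, plus per-component `pi` and `phi`.
#' @method tidy mixglm
#' @export
tidy.mixglm <- function(x, ...) {
  k <- x$k
  terms <- c("(Intercept)", colnames(x$X))
  se <- component_standard_errors(x)
  purrr::map_dfr(seq_len(k), function(j) {
    tibble::tibble(component = j, term = terms,
                   estimate = x$params$beta[j, ],
                   std.error = se[j, ],
                   pi = x$params$pi[j],
                   phi = x$params$phi[j])
  })
}

# per-component Fisher information of the weighted GLM at convergence;
# canonical links, so the weight is z * Var(Y|mu) / a(phi)^ appropriate scale
component_standard_errors <- function(fit) {
  Xs <- cbind(1, fit$X)
  k <- fit$k
  se <- matrix(NA_real_, k, ncol(Xs))
  for (j in seq_len(k)) {
    w <- switch(fit$family$name,
      gaussian = fit$posteriors[, j] / fit$params$phi[j],
      poisson  = fit$posteriors[, j] * fit$fitted_means[, j],
      binomial = {
        p <- fit$fitted_means[, j] / fit$family$m
        fit$posteriors[, j] * fit$family$m * p * (1 - p)
      })
    info <- crossprod(Xs * sqrt(w))
    se[j, ] <- tryCatch(sqrt(diag(solve(info))),
                        error = function(e) rep(NA_real_, ncol(Xs)))
  }
  se
}

#' Glance at a fitted mixture of GLMs
#'
#' @param x A `"mixglm"` fit.
#' @param ... Unused.
#' @return One-row tibble: `k`, `n`, `d`, `logLik`, `n_params`, `BIC`,
#'   `ICL`, `converged`, `iterations`.
#' @method glance mixglm
#' @export
glance.mixglm <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, d = x$d, logLik = x$loglik,
                 n_params = x$n_params, BIC = x$BIC, ICL = x$ICL,
                 converged = x$converged, iterations = x$n_iter)
}

#' Augment data with mixture fit quantities
#'
#' @param x A `"mixglm"` fit.
#' @param ... Unused.
#' @return Tibble: the model frame plus `.class` (MAP label), `.fitted`
#'   (posterior-weighted mean), and one `.posterior_j` column per
#'   component.
#' @method augment mixglm
#' @export
augment.mixglm <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$X))
  out$y <- x$y
  out$.class <- x$map_labels
  out$.fitted <- rowSums(x$posteriors * x$fitted_means)
  z <- tibble::as_tibble(as.data.frame(x$posteriors),
                         .name_repair = ~ paste0(".posterior_", seq_along(.x)))
  dplyr::bind_cols(out, z)
}

#' Tidy a deviance decomposition
#'
#' @param x A `"mixglm_deviance"` object.
#' @param ... Unused.
#' @return The per-cluster tibble of local measures.
#' @method tidy mixglm_deviance
#' @export
tidy.mixglm_deviance <- function(x, ...) {
  x$local
}

#' Glance at a deviance decomposition
#'
#' @param x A `"mixglm_deviance"` object.
#' @param ... Unused.
#' @return One-row tibble with totals, normalized shares, the overall
#'   deviance R-squared and its descriptive-only adjusted variant.
#' @method glance mixglm_deviance
#' @export
glance.mixglm_deviance <- function(x, ...) {
  tibble::tibble(WD = x$totals$WD, BD = x$totals$BD, EWD = x$totals$EWD,
                 RWD = x$totals$RWD, TD = x$totals$TD,
                 NBD = x$normalized$NBD, NEWD = x$normalized$NEWD,
                 NRWD = x$normalized$NRWD, NED = x$normalized$NED,
                 R2 = x$r2, R2bar = x$adjusted$R2bar)
}
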