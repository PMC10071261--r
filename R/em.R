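#' Parameter set of a k-component mixture of GLMs
#'
#' @param pi Mixing weights (positive, summing to 1).
#' @param beta `k x (d+1)` coefficient matrix, intercept in the first column.
#' @param phi Length-`k` dispersion vector (`sigma_j^2` for Gaussian; 1
#'   otherwise).
#' @param family A [glm_family()] object.
#' @return An object of class `"mixglm_params"`.
#' @export
mixglm_params <- function(pi, beta, phi, family) {
  stopifnot(inherits(family, "mixglm_family"))
  beta <- rbind(beta)
  k <- length(pi)
  if (nrow(beta) != k || length(phi) != k) {
    stop("pi, beta and phi disagree on the number of components", call. = FALSE)
  }
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("mixing weights must be positive and sum to 1", call. = FALSE)
  }
  if (any(phi <= 0)) stop("dispersions must be positive", call. = FALSE)
  structure(list(k = k, pi = as.numeric(pi), beta = beta,
                 phi = as.numeric(phi), family = family),
            class = "mixglm_params")
}

# component mean matrix mu[i, j] from coefficients
component_means <- function(X, params, offset = NULL) {
  n <- if (is.null(X) || nrow(as.matrix(X)) == 0L) {
    stop("covariate matrix required", call. = FALSE)
  } else nrow(as.matrix(X))
  Xs <- cbind(1, as.matrix(X))
  eta <- Xs %*% t(params$beta)
  if (!is.null(offset)) eta <- eta + offset
  mu <- params$family$linkinv(eta)  # elementwise links preserve the shape
  matrix(mu, nrow = n, ncol = params$k)
}

#' E-step: posterior membership probabilities
#'
#' Computes \eqn{\hat z_{ij} \propto \pi_j f(y_i; \mu_{ij}, \phi_j)} with rows
#' normalized to 1, in log space with max-subtraction for numerical
#' stability.
#'
#' @param y Response vector.
#' @param X Covariate matrix (`n x d`, no intercept column).
#' @param params A [mixglm_params()] object.
#' @param offset Optional linear-predictor offset (Poisson only).
#' @return `n x k` posterior matrix.
#' @export
e_step <- function(y, X, params, offset = NULL) {
  fam <- params$family
  mu <- component_means(X, params, offset)
  k <- params$k
  L <- vapply(seq_len(k), function(j) {
    log(params$pi[j]) + log_density(y, mu[, j], params$phi[j], fam)
  }, numeric(length(y)))
  L <- rbind(L)  # keep matrix shape for n = 1
  mx <- apply(L, 1, max)
  if (any(!is.finite(mx))) {
    stop(sprintf("zero mixture density for observation(s) %s",
                 paste(which(!is.finite(mx)), collapse = ", ")),
         call. = FALSE)
  }
  z <- exp(L - mx)
  z / rowSums(z)
}

#' M-step: weighted maximization of the complete-data log-likelihood
#'
#' Mixing weights are the relative soft sizes \eqn{\hat\pi_j = \hat n_j / n};
#' component coefficients and dispersions come from [fit_weighted_glm()] and
#' [dispersion_mle()] with the posterior column as weights.  A component
#' whose soft size falls below `d + 2` aborts with a degenerate-component
#' error naming the component.
#'
#' @inheritParams e_step
#' @param z `n x k` posterior (or hard 0/1 membership) matrix.
#' @param family A [glm_family()] object.
#' @return A [mixglm_params()] object; component mean matrix in attribute
#'   `"mu"`.
#' @export
m_step <- function(y, X, z, family, offset = NULL) {
  z <- rbind(z)
  n <- nrow(z)
  k <- ncol(z)
  d <- ncol(as.matrix(X))
  nhat <- colSums(z)
  starving <- which(nhat < d + 2)
  if (length(starving)) {
    stop(sprintf("degenerate component %d: soft size %.3f below %d",
                 starving[1], nhat[starving[1]], d + 2),
         call. = FALSE)
  }
  pi <- nhat / n
  beta <- matrix(NA_real_, k, d + 1)
  phi <- numeric(k)
  mu <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    fit <- fit_weighted_glm(y, X, w = z[, j], family = family, offset = offset)
    beta[j, ] <- fit$coefficients
    mu[, j] <- fit$fitted
    phi[j] <- as.numeric(dispersion_mle(y, fit$fitted, z[, j], family))
  }
  out <- mixglm_params(pi, beta, phi, family)
  attr(out, "mu") <- mu
  out
}

#' EM control settings
#'
#' @param tol Relative observed-data log-likelihood change declaring
#'   convergence.
#' @param max_iter Maximum EM iterations.
#' @return A list of class `"mixglm_control"`.
#' @export
mixglm_control <- function(tol = 1e-8, max_iter = 500L) {
  stopifnot(tol >= 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter)),
            class = "mixglm_control")
}

# core EM loop on plain vectors/matrices; init is a hard label vector or an
# n x k membership matrix
em_core <- function(y, X, family, k, init, offset = NULL,
                    control = mixglm_control()) {
  n <- length(y)
  d <- ncol(as.matrix(X))
  z <- if (is.matrix(init)) {
    if (nrow(init) != n || ncol(init) != k) {
      stop("initial membership matrix must be n x k", call. = FALSE)
    }
    init / rowSums(init)
  } else {
    if (length(init) != n || !all(init %in% seq_len(k))) {
      stop("initial labels must be an n-vector in 1..k", call. = FALSE)
    }
    zz <- matrix(0, n, k)
    zz[cbind(seq_len(n), init)] <- 1
    zz
  }

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  params <- NULL
  for (iter in seq_len(control$max_iter)) {
    params <- m_step(y, X, z, family, offset)
    mu <- attr(params, "mu")
    # observed-data log-likelihood and new posteriors in one pass
    L <- vapply(seq_len(k), function(j) {
      log(params$pi[j]) + log_density(y, mu[, j], params$phi[j], family)
    }, numeric(n))
    L <- rbind(L)
    mx <- apply(L, 1, max)
    if (any(!is.finite(mx))) {
      stop(sprintf("zero mixture density for observation(s) %s",
                   paste(which(!is.finite(mx)), collapse = ", ")),
           call. = FALSE)
    }
    lse <- mx + log(rowSums(exp(L - mx)))
    ll <- sum(lse)
    z <- exp(L - lse)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < control$tol * (abs(ll_old) + control$tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  nhat <- colSums(z)
  list(params = params, posteriors = z,
       fitted_means = attr(params, "mu"),
       soft_sizes = nhat,
       soft_means = colSums(z * y) / nhat,
       grand_mean = mean(y),
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace,
       converged = converged,
       n_iter = length(loglik_trace),
       map_labels = map_classify(z))
}

#' Fit a finite mixture of generalized linear regressions
#'
#' EM estimation of a `k`-component clusterwise GLM
#' \eqn{f(y_i) = \sum_j \pi_j f(y_i; \mu_{ij}, \phi_j)} with canonical links
#' and component-specific coefficients (and, for Gaussian, variances).  Each
#' M-step solves weighted IRLS problems with the posterior memberships as
#' weights; iteration stops when the relative change in the observed-data
#' log-likelihood falls below `control$tol`.
#'
#' @param data A data frame.
#' @param formula Model formula, `response ~ covariates`.
#' @param family `"gaussian"`, `"poisson"`, `"binomial"`, or a
#'   [glm_family()] object.
#' @param k Number of mixture components.
#' @param trials Binomial trials `m` (binomial only).
#' @param offset Name of a log-scale offset column (Poisson only).
#' @param labels Name of a true-label column (used by label-based
#'   initializations and benchmarking).
#' @param init Initialization: a strategy name accepted by
#'   [initial_partition()] (default `"kmeans"`), a hard label vector, or an
#'   `n x k` membership matrix.
#' @param dgp Optional true [mixglm_params()] for the `"true_dgp_map"`
#'   strategy.
#' @param seed Seed for any initialization randomness; the EM itself is
#'   deterministic given the initial memberships.
#' @param control A [mixglm_control()] list.
#' @param ... Further arguments (`S`, `H`, `restarts`) passed to
#'   [initial_partition()].
#'
#' @return An object of class `"mixglm"`: the fitted parameters, the
#'   `n x k` posterior and fitted-mean matrices, soft sizes and soft means,
#'   the log-likelihood trace, MAP labels and information criteria.
#' @examples
#' set.seed(1)
#' dat <- generate_mixture_data(simulation_condition("gaussian", 8), seed = 1)
#' fit <- mixglm(dat, y ~ x, family = "gaussian", k = 2,
#'               labels = "class", init = "true_labels")
#' glance(fit)
#' @export
mixglm <- function(data, formula, family, k = 2L, trials = NULL,
                   offset = NULL, labels = NULL, init = "kmeans",
                   dgp = NULL, seed = NULL, control = mixglm_control(), ...) {
  data <- as.data.frame(data)
  if (!inherits(family, "mixglm_family")) {
    family <- glm_family(family, trials = trials)
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula, data = data), data)
  has_int <- "(Intercept)" %in% colnames(X)
  if (!has_int) stop("the model must include an intercept", call. = FALSE)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  off <- if (!is.null(offset)) {
    if (!offset %in% names(data)) {
      stop(sprintf("offset column '%s' not found", offset), call. = FALSE)
    }
    data[[offset]]
  }
  true_labels <- if (!is.null(labels)) {
    if (!labels %in% names(data)) {
      stop(sprintf("label column '%s' not found", labels), call. = FALSE)
    }
    as.integer(data[[labels]])
  }
  validate_regression_inputs(y, X, family, off, true_labels)

  if (is.character(init) && length(init) == 1L) {
    init <- initial_partition(y, X, k = k, strategy = init, family = family,
                              dgp = dgp, true_labels = true_labels,
                              offset = off, seed = seed, ...)
  }
  res <- em_core(y, X, family, k, init, offset = off, control = control)
  res$family <- family
  res$k <- as.integer(k)
  res$d <- ncol(X)
  res$n <- length(y)
  res$y <- y
  res$X <- X
  res$offset <- off
  res$true_labels <- true_labels
  res$call <- match.call()
  res$n_params <- (k - 1) + k * (res$d + 1) +
    if (family$dispersion_known) 0L else k
  class(res) <- "mixglm"
  ic <- information_criteria(res)
  res$BIC <- ic$BIC
  res$ICL <- ic$ICL
  res
}

#' @export
print.mixglm <- function(x, digits = 4, ...) {
  cat(sprintf("Mixture of %d %s regressions (n = %d, d = %d)\n",
              x$k, x$family$name, x$n, x$d))
  cat(sprintf("log-likelihood %.4f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("pi:  ", paste(round(x$params$pi, digits), collapse = "  "), "\n")
  cat("coefficients:\n")
  print(round(x$params$beta, digits))
  if (!x$family$dispersion_known) {
    cat("sigma:", paste(round(sqrt(x$params$phi), digits), collapse = "  "), "\n")
  }
  cat(sprintf("BIC %.3f   ICL %.3f\n", x$BIC, x$ICL))
  invisible(x)
}

#' MAP classification of a posterior matrix
#'
#' Assigns each observation to the component with the largest posterior
#' probability; ties are broken deterministically in favour of the lowest
#' component index.
#'
#' @param z `n x k` posterior matrix.
#' @return Integer label vector in `1..k`.
#' @export
map_classify <- function(z) {
  max.col(rbind(z), ties.method = "first")
}

#' BIC and ICL of a fitted mixture
#'
#' `BIC = -2 loglik + p log(n)` with
#' `p = (k - 1) + k (d + 1) + k` free dispersions for Gaussian components.
#' `ICL = BIC + 2 * entropy(posteriors)` where the entropy
#' \eqn{-\sum_{ij} \hat z_{ij} \log \hat z_{ij}} uses the `0 log 0 = 0`
#' convention; for a hard partition `ICL = BIC`.
#'
#' @param fit A `"mixglm"` fit.
#' @param n Sample size (taken from the fit by default).
#' @return List with elements `BIC` and `ICL`.
#' @export
information_criteria <- function(fit, n = fit$n) {
  bic <- -2 * fit$loglik + fit$n_params * log(n)
  z <- fit$posteriors
  ent <- -sum(ifelse(z > 0, z * log(z), 0))
  list(BIC = bic, ICL = bic + 2 * ent)
}
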