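#' Exponential-family specification for mixture-of-GLM modelling
#'
#' Builds the family object used throughout the package.  Three canonical-link
#' members are supported: Gaussian (identity link, unknown dispersion
#' \eqn{\phi = \sigma^2}), Poisson (log link, \eqn{\phi = 1}) and binomial with
#' a fixed number of trials `m` (logit link).  Binomial responses are stored
#' and modelled on the *count* scale, `y` in `{0, ..., m}`; the dispersion
#' function `a_phi()` still reports the proportion-scale constant `1/m`, while
#' the cumulant `b()` is parameterized on the count scale so that
#' `db/dtheta` evaluated at `theta_from_mu(mu)` returns the count-scale mean.
#'
#' @param name One of `"gaussian"`, `"poisson"`, `"binomial"`.
#' @param trials Number of binomial trials `m` (required for, and only
#'   allowed with, the binomial family).
#'
#' @return An object of class `"mixglm_family"`: a list with elements
#'   `name`, `m`, `linkfun` (mean to canonical parameter), `linkinv`
#'   (linear predictor to mean), `b` (cumulant), `a_phi` (dispersion
#'   function of Table-style form: \eqn{\sigma^2}, 1, or 1/m),
#'   `dispersion_known`, and `validate_y`.
#' @examples
#' fam <- glm_family("binomial", trials = 10)
#' fam$linkfun(5)   # logit(0.5) = 0
#' @export
glm_family <- function(name = c("gaussian", "poisson", "binomial"),
                       trials = NULL) {
  name <- match.arg(name)
  if (name == "binomial") {
    if (is.null(trials) || length(trials) != 1L || !is.finite(trials) ||
        trials < 1 || trials != round(trials)) {
      stop("binomial family requires a positive integer number of `trials`",
           call. = FALSE)
    }
    m <- as.integer(trials)
  } else {
    if (!is.null(trials)) {
      stop("`trials` is only meaningful for the binomial family", call. = FALSE)
    }
    m <- NA_integer_
  }

  fam <- switch(name,
    gaussian = list(
      name = "gaussian", m = NA_integer_,
      linkfun = function(mu) mu,
      linkinv = function(eta) eta,
      b = function(theta) theta^2 / 2,
      a_phi = function(phi) phi,
      dispersion_known = FALSE,
      mu_ok = function(mu) is.finite(mu),
      validate_y = function(y) all(is.finite(y))
    ),
    poisson = list(
      name = "poisson", m = NA_integer_,
      linkfun = function(mu) {
        if (any(mu <= 0)) stop("poisson mean must be positive", call. = FALSE)
        log(mu)
      },
      linkinv = function(eta) exp(eta),
      b = function(theta) exp(theta),
      a_phi = function(phi) 1,
      dispersion_known = TRUE,
      mu_ok = function(mu) is.finite(mu) & mu > 0,
      validate_y = function(y) {
        all(is.finite(y)) && all(y >= 0) && all(y == round(y))
      }
    ),
    binomial = list(
      name = "binomial", m = m,
      linkfun = function(mu) {
        if (any(mu <= 0 | mu >= m)) {
          stop("binomial mean must lie strictly between 0 and m", call. = FALSE)
        }
        stats::qlogis(mu / m)
      },
      linkinv = function(eta) m * stats::plogis(eta),
      b = function(theta) m * log1p(exp(theta)),
      a_phi = function(phi) 1 / m,
      dispersion_known = TRUE,
      mu_ok = function(mu) is.finite(mu) & mu > 0 & mu < m,
      validate_y = function(y) {
        all(is.finite(y)) && all(y >= 0) && all(y <= m) && all(y == round(y))
      }
    )
  )
  structure(fam, class = "mixglm_family")
}

#' @export
print.mixglm_family <- function(x, ...) {
  cat("<mixglm_family> ", x$name,
      if (x$name == "binomial") paste0(" (m = ", x$m, ")"), "\n", sep = "")
  invisible(x)
}

#' Canonical parameter of a mean value
#'
#' Maps a mean onto the canonical (natural) parameter of the family:
#' identity for Gaussian, `log(mu)` for Poisson and `logit(mu/m)` for the
#' binomial count scale.
#'
#' @param mu Mean value(s), in the family's mean domain.
#' @param family A [glm_family()] object.
#' @return Numeric vector of canonical parameters.
#' @examples
#' theta_from_mu(2.5, glm_family("gaussian"))
#' @export
theta_from_mu <- function(mu, family) {
  stopifnot(inherits(family, "mixglm_family"))
  family$linkfun(mu)
}

#' Weighted exponential-family log-likelihood
#'
#' Sum of weighted exact log-densities \eqn{\sum_i w_i \log f(y_i; \mu_i,
#' \phi)}, including the normalizing `c(y; phi)` term.  Saturated-model
#' evaluation (`mu = y`) is supported for every family through the usual
#' `0 * log(0) = 0` limit.
#'
#' @param y Response vector (counts for Poisson/binomial).
#' @param mu Mean vector, recycled if scalar.
#' @param phi Dispersion (`sigma^2` for Gaussian; ignored otherwise).
#' @param w Weight vector in `[0, 1]`, recycled if scalar.
#' @param family A [glm_family()] object.
#' @return A single number; `0` for zero-length input.
#' @examples
#' weighted_loglik(1, 1, phi = 1, w = 1, glm_family("poisson"))  # -1
#' @export
weighted_loglik <- function(y, mu, phi, w, family) {
  stopifnot(inherits(family, "mixglm_family"))
  if (length(y) == 0L) return(0)
  n <- length(y)
  mu <- rep_len(mu, n)
  w <- rep_len(w, n)
  ld <- log_density(y, mu, phi, family)
  # weights of exactly zero kill any -Inf saturated corner cases
  sum(ifelse(w == 0, 0, w * ld))
}

# exact elementwise log-density (count scale for binomial)
log_density <- function(y, mu, phi, family) {
  switch(family$name,
    gaussian = stats::dnorm(y, mean = mu, sd = sqrt(phi), log = TRUE),
    poisson  = stats::dpois(y, lambda = mu, log = TRUE),
    binomial = stats::dbinom(y, size = family$m, prob = mu / family$m,
                             log = TRUE)
  )
}

#' Weighted single-GLM fit (IRLS)
#'
#' Maximizes the weighted log-likelihood over regression coefficients with
#' canonical link, i.e. the M-step workhorse of the mixture EM.  Gaussian
#' fits use weighted least squares; Poisson and binomial fits use iteratively
#' reweighted least squares with the observation weights entering as prior
#' weights.  An additive offset on the linear-predictor scale is accepted for
#' the Poisson family only (the rate-model use case); requesting it elsewhere
#' is an error rather than a silent ignore.
#'
#' @param y Response vector (counts for Poisson/binomial).
#' @param X Covariate matrix (`n x d`, without intercept column); ignored
#'   when `intercept_only = TRUE`.
#' @param w Nonnegative weight vector.
#' @param family A [glm_family()] object.
#' @param offset Optional offset vector (Poisson only).
#' @param intercept_only If `TRUE`, fit only the intercept.
#' @return List with `coefficients` (intercept first), `fitted` (mean
#'   vector on the response/count scale), and `converged`.
#' @export
fit_weighted_glm <- function(y, X = NULL, w, family, offset = NULL,
                             intercept_only = FALSE) {
  stopifnot(inherits(family, "mixglm_family"))
  n <- length(y)
  w <- rep_len(w, n)
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (!is.null(offset) && family$name != "poisson") {
    stop("offsets are supported for the poisson family only", call. = FALSE)
  }
  Xs <- if (intercept_only || is.null(X) || ncol(as.matrix(X)) == 0L) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    cbind("(Intercept)" = 1, X)
  }
  p <- ncol(Xs)
  if (sum(w > 0) < p) {
    stop("fewer effective observations than coefficients", call. = FALSE)
  }
  if (qr(Xs * sqrt(w))$rank < p) {
    stop("singular design: weighted design matrix is rank deficient",
         call. = FALSE)
  }

  if (family$name == "gaussian") {
    fit <- stats::lm.wfit(Xs, y, w)
    beta <- fit$coefficients
    mu <- drop(Xs %*% beta)
    conv <- TRUE
  } else {
    ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100L)
    if (family$name == "poisson") {
      fit <- quiet_glm_fit(Xs, y, weights = w, offset = offset,
                           family = stats::poisson(), control = ctrl)
      beta <- fit$coefficients
      mu <- fit$fitted.values
    } else {
      m <- family$m
      fit <- quiet_glm_fit(Xs, y / m, weights = w * m,
                           family = stats::binomial(), control = ctrl)
      beta <- fit$coefficients
      mu <- m * fit$fitted.values
    }
    conv <- isTRUE(fit$converged)
    if (!conv) {
      warning("IRLS did not converge within 100 iterations; returning last iterate",
              call. = FALSE)
    }
    if (isTRUE(fit$boundary)) {
      attr(beta, "divergence") <- TRUE
    }
  }
  list(coefficients = beta, fitted = mu, converged = conv)
}

# glm.fit, muffling the benign chatter that soft EM weights trigger:
# non-integer successes (binomial initializer) and fitted values touching
# the boundary on near-zero-weight observations; true divergence is still
# surfaced through the `boundary` flag
quiet_glm_fit <- function(x, y, ...) {
  withCallingHandlers(
    stats::glm.fit(x, y, ...),
    warning = function(wrn) {
      msg <- conditionMessage(wrn)
      if (grepl("non-integer|fitted rates numerically 0|fitted probabilities numerically 0 or 1",
                msg)) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Weighted maximum-likelihood dispersion estimate
#'
#' Gaussian: the weighted mean squared residual
#' \eqn{\sum_i w_i (y_i - \mu_i)^2 / \sum_i w_i}, floored at a small positive
#' constant to avoid degenerate components (a floored estimate carries
#' attribute `floored = TRUE`).  Poisson and binomial: the dispersion is
#' known and equal to 1 (the binomial's `a(phi) = 1/m` lives in the family
#' object).
#'
#' @param y,mu,w Response, mean and weight vectors.
#' @param family A [glm_family()] object.
#' @param floor Lower bound for the Gaussian variance.
#' @return The dispersion estimate `phi`.
#' @export
dispersion_mle <- function(y, mu, w, family, floor = 1e-10) {
  stopifnot(inherits(family, "mixglm_family"))
  if (family$name != "gaussian") return(1)
  sw <- sum(w)
  if (sw <= 0) stop("total weight must be positive", call. = FALSE)
  phi <- sum(w * (y - mu)^2) / sw
  if (phi < floor) {
    phi <- floor
    attr(phi, "floored") <- TRUE
  }
  phi
}

# validate a response/covariate/offset bundle; returns the pieces invisibly
validate_regression_inputs <- function(y, X, family, offset = NULL,
                                       true_labels = NULL) {
  n <- length(y)
  if (n < 1L) stop("empty response", call. = FALSE)
  if (anyNA(y) || (!is.null(X) && anyNA(X))) {
    stop("missing values are not supported", call. = FALSE)
  }
  if (!family$validate_y(y)) {
    stop(sprintf("response violates the %s support%s", family$name,
                 if (family$name == "binomial")
                   sprintf(" {0, ..., %d}", family$m) else ""),
         call. = FALSE)
  }
  if (!is.null(offset)) {
    if (family$name != "poisson") {
      stop("offsets are supported for the poisson family only", call. = FALSE)
    }
    if (length(offset) != n || anyNA(offset)) {
      stop("offset must be a complete n-vector", call. = FALSE)
    }
  }
  if (!is.null(true_labels) && length(true_labels) != n) {
    stop("true labels must have length n", call. = FALSE)
  }
  invisible(TRUE)
}
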