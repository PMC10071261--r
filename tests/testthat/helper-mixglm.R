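# Shared fixtures: small random problem instances built in code.

all_families <- function() {
  list(glm_family("gaussian"), glm_family("poisson"),
       glm_family("binomial", trials = 10))
}

# draw a small two-group regression data set for a family
random_instance <- function(family, n = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  lab <- sample(1:2, n, replace = TRUE)
  eta <- cbind(c(-1, 1)[lab] + c(-0.5, 0.5)[lab] * x)
  y <- switch(family$name,
    gaussian = rnorm(n, eta, c(0.7, 0.4)[lab]),
    poisson  = rpois(n, exp(eta)),
    binomial = rbinom(n, family$m, plogis(eta))
  )
  tibble::tibble(x = x, y = y, class = lab)
}

# fit a small k = 2 mixture from the true labels
small_fit <- function(family, n = 40, seed = 1,
                      control = mixglm_control()) {
  dat <- random_instance(family, n = n, seed = seed)
  mixglm(dat, y ~ x, family = family$name, k = 2,
         trials = if (family$name == "binomial") family$m,
         labels = "class", init = "true_labels", control = control)
}

# an arbitrary (non-ML) mixture state wrapped as a fit object, for checks
# that hold at any soft partition and mean matrix
fake_state <- function(family, n = 12, seed = 1) {
  set.seed(seed)
  dat <- random_instance(family, n = n)
  z <- matrix(runif(2 * n), n, 2)
  z <- z / rowSums(z)
  nhat <- colSums(z)
  eta <- cbind(-0.8 + 0.3 * dat$x, 0.9 - 0.4 * dat$x)
  mu <- matrix(family$linkinv(eta), n, 2)
  phi <- if (family$name == "gaussian") c(0.5, 0.9) else c(1, 1)
  structure(list(
    y = dat$y, X = matrix(dat$x, ncol = 1), k = 2L, d = 1L, n = n,
    posteriors = z, fitted_means = mu, soft_sizes = nhat,
    soft_means = colSums(z * dat$y) / nhat, grand_mean = mean(dat$y),
    params = list(phi = phi), family = family, offset = NULL
  ), class = "mixglm")
}

# brute-force pair-counting adjusted Rand index (independent oracle)
ari_bruteforce <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  npairs <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / npairs
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}
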