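test_that("closed-form deviances equal twice the log-likelihood differences", {
  for (fam in all_families()) {
    for (s in 1:10) {
      st <- fake_state(fam, n = 12, seed = 200 + s)
      closed <- local_deviances(st, method = "closed")
      exact <- local_deviances(st, method = "loglik")
      for (col in c("D", "RD", "ED", "BD")) {
        expect_equal(closed[[col]], exact[[col]], tolerance = 1e-8)
      }
    }
  }
})

test_that("gaussian deviances equal the standardized sums of squares", {
  gaus <- glm_family("gaussian")
  # the ED/BD sum-of-squares forms rely on the weighted-least-squares
  # orthogonality, so refresh the component fits at the final posteriors
  st <- small_fit(gaus, n = 50, seed = 31)
  dat_x <- st$X
  p <- m_step(st$y, dat_x, st$posteriors, gaus)
  st$fitted_means <- attr(p, "mu")
  st$params <- p
  loc <- local_deviances(st)
  z <- st$posteriors
  for (j in 1:2) {
    phi <- st$params$phi[j]
    expect_equal(loc$D[j], sum(z[, j] * (st$y - st$soft_means[j])^2) / phi)
    expect_equal(loc$RD[j],
                 sum(z[, j] * (st$y - st$fitted_means[, j])^2) / phi)
    expect_equal(loc$ED[j],
                 sum(z[, j] * (st$fitted_means[, j] - st$soft_means[j])^2) /
                   phi, tolerance = 1e-6)
    expect_equal(loc$BD[j],
                 st$soft_sizes[j] * (st$soft_means[j] - st$grand_mean)^2 /
                   phi)
  }
})

test_that("poisson toy case matches the count-scale closed forms", {
  pois <- glm_family("poisson")
  y <- c(0, 2)
  z <- cbind(c(1, 1))
  mu <- cbind(c(0.5, 1.5))
  st <- structure(list(
    y = y, k = 1L, d = 1L, n = 2L, posteriors = z, fitted_means = mu,
    soft_sizes = 2, soft_means = 1, grand_mean = 1,
    params = list(phi = 1), family = pois, offset = NULL
  ), class = "mixglm")
  loc <- local_deviances(st)
  # direct evaluation with 0*log(0) = 0
  expect_equal(loc$D[1], 2 * ((0 - 0 + 1) + (2 * log(2) - 2 + 1)))
  expect_equal(loc$RD[1],
               2 * ((0 - 0 + 0.5) + (2 * (log(2) - log(1.5)) - 2 + 1.5)))
  expect_equal(loc$ED[1], loc$D[1] - loc$RD[1], tolerance = 1e-12)
  exact <- local_deviances(st, method = "loglik")
  expect_equal(loc$D, exact$D, tolerance = 1e-10)
})

test_that("decomposition identities hold on fitted mixtures of all families", {
  for (fam in all_families()) {
    fit <- small_fit(fam, n = 60, seed = 37)
    dec <- deviance_decomposition(fit)
    loc <- dec$local
    expect_equal(loc$D, loc$ED + loc$RD, tolerance = 1e-8)
    expect_equal(dec$totals$WD, sum(loc$D), tolerance = 1e-10)
    expect_equal(dec$totals$BD, sum(loc$BD), tolerance = 1e-10)
    expect_equal(dec$totals$TD,
                 dec$totals$BD + dec$totals$EWD + dec$totals$RWD,
                 tolerance = 1e-8)
    nm <- dec$normalized
    expect_equal(nm$NBD + nm$NEWD + nm$NRWD, 1, tolerance = 1e-10)
    expect_equal(nm$NED, 1 - nm$NRWD, tolerance = 1e-12)
    expect_equal(dec$r2, sum(loc$weight * loc$R2), tolerance = 1e-10)
    # nonnegativity at the converged ML fit, R2 in [0, 1]
    expect_true(all(c(loc$D, loc$RD, loc$ED, loc$BD) >= -1e-8))
    expect_true(all(loc$R2 >= 0 & loc$R2 <= 1))
    expect_true(dec$r2 >= 0 && dec$r2 <= 1)
  }
})

test_that("equal soft means zero the between deviance", {
  gaus <- glm_family("gaussian")
  st <- fake_state(gaus, n = 20, seed = 41)
  # force both local nulls onto the grand mean
  st$soft_means <- rep(st$grand_mean, 2)
  loc <- local_deviances(st)
  expect_equal(loc$BD, c(0, 0), tolerance = 1e-10)
})

test_that("points on a common fitted line zero the residual deviance", {
  gaus <- glm_family("gaussian")
  n <- 20
  set.seed(43)
  x <- rnorm(n)
  y <- 1 + 2 * x  # exact line
  z <- matrix(runif(2 * n), n, 2); z <- z / rowSums(z)
  mu <- cbind(y, y)  # overlapped components on the common line
  nhat <- colSums(z)
  st <- structure(list(
    y = y, k = 2L, d = 1L, n = n, posteriors = z, fitted_means = mu,
    soft_sizes = nhat, soft_means = colSums(z * y) / nhat,
    grand_mean = mean(y), params = list(phi = c(0.5, 0.5)),
    family = gaus, offset = NULL
  ), class = "mixglm")
  dec <- deviance_decomposition(st)
  expect_equal(dec$totals$RWD, 0, tolerance = 1e-10)
  expect_equal(dec$normalized$NED, 1, tolerance = 1e-10)
})

test_that("total deviance is partition-free for one-parameter families", {
  for (nm in c("poisson", "binomial")) {
    fam <- glm_family(nm, trials = if (nm == "binomial") 10)
    dat <- random_instance(fam, n = 80, seed = 47)
    f1 <- mixglm(dat, y ~ x, family = nm, k = 2,
                 trials = if (nm == "binomial") 10,
                 labels = "class", init = "true_labels")
    f2 <- mixglm(dat, y ~ x, family = nm, k = 2,
                 trials = if (nm == "binomial") 10, init = "kmeans",
                 seed = 99)
    t1 <- deviance_decomposition(f1)$totals$TD
    t2 <- deviance_decomposition(f2)$totals$TD
    expect_equal(t1, t2, tolerance = 1e-8)
  }
})

test_that("undefined ratios are flagged rather than coerced", {
  gaus <- glm_family("gaussian")
  n <- 10
  y <- rep(2, n)  # constant response: every deviance vanishes
  st <- structure(list(
    y = y, k = 1L, d = 1L, n = n, posteriors = matrix(1, n, 1),
    fitted_means = matrix(2, n, 1), soft_sizes = n, soft_means = 2,
    grand_mean = 2, params = list(phi = c(1)), family = gaus, offset = NULL
  ), class = "mixglm")
  dec <- deviance_decomposition(st)
  expect_true(dec$flags$td_zero)
  expect_true(is.na(dec$normalized$NBD))
  expect_true(is.na(dec$r2))
  expect_true(is.na(dec$local$R2[1]))
})

test_that("adjusted R-squared uses soft degrees of freedom and warns", {
  # hand case: RD = 2, D = 10, nhat = 11, d = 1 -> 1 - (2/9)/(10/10) = 7/9
  expect_warning(
    adj <- adjusted_r2(RD = 2, D = 10, RWD = 2, WD = 10, soft_sizes = 11,
                       n = 11, d = 1, k = 1),
    "descriptive"
  )
  expect_equal(adj$R2bar_j, 7 / 9)
  expect_true(isTRUE(attr(adj, "descriptive_only")))
  # RD = 0 gives a perfect adjusted local R2
  expect_warning(
    adj0 <- adjusted_r2(0, 5, 0, 5, soft_sizes = 10, n = 10, d = 1, k = 1)
  )
  expect_equal(adj0$R2bar_j, 1)
  # k = 1 reduces the overall formula to the single-GLM adjustment
  expect_warning(
    adj1 <- adjusted_r2(3, 12, 3, 12, soft_sizes = 20, n = 20, d = 2, k = 1)
  )
  expect_equal(adj1$R2bar, 1 - (3 / (20 - 3)) / (12 / 19))
  # nonpositive dof flagged as NA
  expect_warning(
    adjna <- adjusted_r2(1, 2, 1, 2, soft_sizes = 2, n = 2, d = 2, k = 1)
  )
  expect_true(is.na(adjna$R2bar_j))
})

test_that("offset-aware local null is available but off by default", {
  set.seed(53)
  n <- 60
  x <- rnorm(n)
  pop <- runif(n, 50, 500)
  lab <- sample(1:2, n, replace = TRUE)
  eta <- c(-4, -2.5)[lab] + 0.3 * x + log(pop)
  dat <- tibble::tibble(x = x, y = rpois(n, exp(eta)), off = log(pop),
                        class = lab)
  fit <- mixglm(dat, y ~ x, family = "poisson", k = 2, offset = "off",
                labels = "class", init = "true_labels")
  d0 <- local_deviances(fit)                      # mean-based null
  d1 <- local_deviances(fit, offset_null = TRUE)  # offset-aware null
  expect_false(isTRUE(all.equal(d0$D, d1$D)))
  # both satisfy the additive identity
  expect_equal(d0$D, d0$ED + d0$RD, tolerance = 1e-8)
  expect_equal(d1$D, d1$ED + d1$RD, tolerance = 1e-8)
})

test_that("boundary soft means raise an addressed error", {
  pois <- glm_family("poisson")
  st <- fake_state(pois, n = 10, seed = 59)
  st$soft_means[2] <- 0
  expect_error(local_deviances(st), "cluster 2.*boundary")
})
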