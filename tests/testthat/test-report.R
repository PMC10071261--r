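write_fixture_csv <- function(path, dat) {
  readr::write_csv(dat, path)
  path
}

test_that("delimited tables are read, typed and validated", {
  tmp <- withr::local_tempdir()
  f <- write_fixture_csv(file.path(tmp, "toy.csv"),
                         tibble::tibble(count = c(1, 0, 3), x1 = c(0.1, -1, 2)))
  tab <- read_regression_table(f, response = "count", covariates = "x1",
                               family = "poisson")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "d"), 1L)
  expect_named(tab, c("y", "x1"))

  # missing column is addressed by name
  expect_error(read_regression_table(f, "count", "zz", family = "poisson"),
               "zz")
  # binomial support violation
  fb <- write_fixture_csv(file.path(tmp, "bad.csv"),
                          tibble::tibble(y = c(11, 2), x = c(1, 2)))
  expect_error(read_regression_table(fb, "y", "x", family = "binomial",
                                     trials = 10), "support")
  # raw population column becomes a log offset, explicitly
  fp <- write_fixture_csv(file.path(tmp, "pop.csv"),
                          tibble::tibble(y = c(2, 5), x = c(0, 1),
                                         pop = c(100, 1000)))
  tp <- read_regression_table(fp, "y", "x", family = "poisson",
                              offset_col = "pop", raw_population = TRUE)
  expect_equal(tp$.offset, log(c(100, 1000)))
  tq <- read_regression_table(fp, "y", "x", family = "poisson",
                              offset_col = "pop")
  expect_equal(tq$.offset, c(100, 1000))
  # offsets denied outside poisson
  expect_error(read_regression_table(fp, "y", "x", family = "gaussian",
                                     offset_col = "pop"), "poisson")
})

test_that("fit reports scan k, write all files, and zero NBD at k = 1", {
  tmp <- withr::local_tempdir()
  set.seed(107)
  n <- 120
  x <- rnorm(n)
  pop <- runif(n, 100, 1000)
  lab <- sample(1:3, n, replace = TRUE)
  y <- rpois(n, exp(c(-5.5, -4, -2.5)[lab] + 0.3 * x + log(pop)))
  dat <- tibble::tibble(y = y, x = x, .offset = log(pop))
  out <- file.path(tmp, "rep")
  criteria <- fit_report(dat, covariates = "x", family = "poisson",
                         k_range = 1:3, init = "kmeans", seed = 11,
                         out_dir = out)
  expect_equal(criteria$k, 1:3)
  expect_named(criteria, c("k", "logLik", "n_params", "BIC", "ICL",
                           "converged"))
  for (k in 1:3) {
    expect_true(file.exists(file.path(out, sprintf("params_k%d.json", k))))
    expect_true(file.exists(file.path(out, sprintf("posteriors_k%d.csv", k))))
    expect_true(file.exists(file.path(out,
                                      sprintf("deviance_report_k%d.json", k))))
  }
  expect_true(file.exists(file.path(out, "criteria.csv")))
  rep1 <- jsonlite::read_json(file.path(out, "deviance_report_k1.json"))
  expect_equal(rep1$normalized$NBD, 0, tolerance = 1e-12)
  expect_true(isTRUE(rep1$descriptive_only))
  pars2 <- jsonlite::read_json(file.path(out, "params_k2.json"))
  expect_equal(length(pars2$pi), 2L)
  expect_true(all(c("package_version", "seed", "config_hash") %in%
                    names(pars2)))
  # standard errors present and positive for every coefficient
  co <- pars2$coefficients[["1"]]
  expect_true(all(vapply(co$std.error, function(v) v > 0, logical(1))))
})

test_that("written posteriors round-trip the decomposition", {
  tmp <- withr::local_tempdir()
  fam <- glm_family("gaussian")
  fit <- small_fit(fam, n = 80, seed = 109)
  dec <- deviance_decomposition(fit)
  f <- file.path(tmp, "posteriors.csv")
  readr::write_csv(tibble::as_tibble(as.data.frame(fit$posteriors),
                                     .name_repair = ~ c("z1", "z2")), f)
  z2 <- as.matrix(readr::read_csv(f, show_col_types = FALSE))
  refit <- fit
  refit$posteriors <- z2
  refit$soft_sizes <- colSums(z2)
  refit$soft_means <- colSums(z2 * fit$y) / colSums(z2)
  dec2 <- deviance_decomposition(refit)
  expect_equal(dec2$totals$TD, dec$totals$TD, tolerance = 1e-12)
  expect_equal(dec2$r2, dec$r2, tolerance = 1e-12)
})

test_that("simulation reports write summary and replicate files", {
  tmp <- withr::local_tempdir()
  cond <- simulation_condition("gaussian", 4, reps = 5L)
  out <- file.path(tmp, "sim")
  s <- simulate_report(cond, reps = 5, base_seed = 113, out_dir = out)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "replicates.csv")))
  summ <- readr::read_csv(file.path(out, "summary.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(summ), 7L)  # one row per metric
  expect_true(all(c("metric", "mean", "sd", "base_seed",
                    "package_version") %in% names(summ)))
  repl <- readr::read_csv(file.path(out, "replicates.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(repl), 5L)
  # same seed twice: byte-identical summary
  out2 <- file.path(tmp, "sim2")
  simulate_report(cond, reps = 5, base_seed = 113, out_dir = out2)
  expect_identical(readLines(file.path(out, "summary.csv")),
                   readLines(file.path(out2, "summary.csv")))
})

test_that("tidiers and plots expose the fit in tabular form", {
  fit <- small_fit(glm_family("gaussian"), n = 60, seed = 127)
  td <- tidy(fit)
  expect_named(td, c("component", "term", "estimate", "std.error", "pi",
                     "phi"))
  expect_equal(nrow(td), 4L)  # 2 components x 2 terms
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_true(gl$BIC > 0)
  au <- augment(fit)
  expect_equal(nrow(au), 60L)
  expect_true(all(c(".class", ".fitted", ".posterior_1") %in% names(au)))
  dec <- deviance_decomposition(fit)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(dec), "ggplot")
  gd <- glance(dec)
  expect_equal(gd$NBD + gd$NEWD + gd$NRWD, 1, tolerance = 1e-10)
})
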