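# Two-component clusterwise-regression study designs.  Eight crossed
# conditions: class separation {small, large} x regression fit {poor, good}
# x sample size {100, 1000}; a single standard-normal covariate throughout.
dgp_tables <- list(
  gaussian = list(
    beta01 = rep(c(-0.80, -1.20), 4),
    beta11 = rep(c(0.02, 0.02, -0.40, -0.40), 2),
    beta02 = rep(c(0.80, 1.20), 4),
    beta12 = rep(c(0.02, 0.02, 0.40, 0.40), 2),
    sigma1 = rep(c(0.80, 0.80, 0.40, 0.40), 2),
    sigma2 = rep(c(0.60, 0.60, 0.20, 0.20), 2)
  ),
  poisson = list(
    beta01 = rep(c(-0.75, -1.00), 4),
    beta11 = rep(c(0.15, 0.15, 1.50, 1.50), 2),
    beta02 = rep(c(1.50, 2.00), 4),
    beta12 = rep(c(-0.07, -0.07, 0.50, 0.50), 2)
  ),
  binomial = list(
    beta01 = rep(c(-1.00, -2.00), 4),
    beta11 = rep(c(0.01, 0.01, 2.00, 2.00), 2),
    beta02 = rep(c(1.00, 2.00), 4),
    beta12 = rep(c(0.01, 0.01, 2.00, 2.00), 2)
  )
)

#' Simulation condition of the two-component benchmark design
#'
#' Returns the data-generating parameters for one of the eight benchmark
#' conditions: a balanced (`pi_1 = 0.5`) mixture of two simple regressions on
#' a standard-normal covariate, with `n = 100` for conditions 1–4 and
#' `n = 1000` for conditions 5–8.  Gaussian conditions carry component
#' standard deviations; binomial conditions use `m = 10` trials.
#'
#' @param family `"gaussian"`, `"poisson"` or `"binomial"`.
#' @param condition Integer 1–8.
#' @param reps Number of Monte Carlo replicates attached to the condition.
#' @return An object of class `"mixglm_condition"`: list with `family`,
#'   `condition`, `n`, `pi1`, `beta1`, `beta2`, `sigma1`, `sigma2` (Gaussian
#'   only), `m` (binomial only) and `reps`.
#' @examples
#' simulation_condition("gaussian", 8)
#' @export
simulation_condition <- function(family = c("gaussian", "poisson", "binomial"),
                                 condition, reps = 250L) {
  family <- match.arg(family)
  stopifnot(length(condition) == 1L, condition %in% 1:8)
  tb <- dgp_tables[[family]]
  cond <- list(
    family = family, condition = as.integer(condition),
    n = if (condition <= 4) 100L else 1000L,
    pi1 = 0.5,
    beta1 = c(tb$beta01[condition], tb$beta11[condition]),
    beta2 = c(tb$beta02[condition], tb$beta12[condition]),
    sigma1 = tb$sigma1[condition], sigma2 = tb$sigma2[condition],
    m = if (family == "binomial") 10L else NULL,
    reps = as.integer(reps)
  )
  structure(cond, class = "mixglm_condition")
}

#' @export
print.mixglm_condition <- function(x, ...) {
  cat(sprintf("<mixglm_condition> %s, condition %d: n = %d, pi1 = %.2f\n",
              x$family, x$condition, x$n, x$pi1))
  cat(sprintf("  beta1 = (%.2f, %.2f)  beta2 = (%.2f, %.2f)\n",
              x$beta1[1], x$beta1[2], x$beta2[1], x$beta2[2]))
  if (x$family == "gaussian") {
    cat(sprintf("  sigma = (%.2f, %.2f)\n", x$sigma1, x$sigma2))
  }
  if (x$family == "binomial") cat(sprintf("  m = %d trials\n", x$m))
  invisible(x)
}

# true parameters of a condition as a mixglm_params object
condition_params <- function(cond) {
  fam <- glm_family(cond$family, trials = cond$m)
  phi <- if (cond$family == "gaussian") {
    c(cond$sigma1^2, cond$sigma2^2)
  } else c(1, 1)
  mixglm_params(pi = c(cond$pi1, 1 - cond$pi1),
                beta = rbind(cond$beta1, cond$beta2),
                phi = phi, family = fam)
}

#' Generate one data set from a simulation condition
#'
#' Draws labels from a Bernoulli(`pi1`) assignment, a standard-normal
#' covariate, and the response from the condition's component regression:
#' Gaussian `N(b0 + b1 x, sigma^2)`, Poisson with log-mean `b0 + b1 x`, or
#' binomial(`m`, inverse-logit(`b0 + b1 x`)).
#'
#' @param cond A [simulation_condition()] object.
#' @param seed Integer seed; every draw flows through it.
#' @param n Optional sample-size override.
#' @return Tibble with columns `x`, `y`, `class`.
#' @export
generate_mixture_data <- function(cond, seed = NULL, n = cond$n) {
  stopifnot(inherits(cond, "mixglm_condition"))
  if (!is.null(seed)) set.seed(seed)
  lab <- 1L + (stats::runif(n) > cond$pi1)
  x <- stats::rnorm(n)
  b0 <- c(cond$beta1[1], cond$beta2[1])[lab]
  b1 <- c(cond$beta1[2], cond$beta2[2])[lab]
  eta <- b0 + b1 * x
  y <- switch(cond$family,
    gaussian = stats::rnorm(n, eta, c(cond$sigma1, cond$sigma2)[lab]),
    poisson  = stats::rpois(n, exp(eta)),
    binomial = stats::rbinom(n, cond$m, stats::plogis(eta))
  )
  tibble::tibble(x = x, y = y, class = lab)
}

#' Adjusted Rand index of two partitions
#'
#' Permutation-model (Hubert–Arabie) chance-corrected Rand index from the
#' contingency table of the two label vectors.  Equals 1 for identical
#' partitions (up to relabeling), is close to 0 for independent ones, and
#' can be negative.
#'
#' @param a,b Label vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(length(a))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Align estimated components with reference labels
#'
#' Finds the permutation of the estimated component labels that maximizes
#' agreement with a reference partition, so that per-cluster metrics are
#' comparable across Monte Carlo replicates despite label switching.
#' Exhaustive search over the `k!` permutations for `k <= 6`; a greedy
#' assignment on the agreement matrix otherwise.
#'
#' @param map_labels Estimated label vector.
#' @param true_labels Reference label vector.
#' @param k Number of components.
#' @return Integer permutation `p` of `1..k`: estimated component `j`
#'   corresponds to reference component `p[j]`.
#' @export
align_components <- function(map_labels, true_labels, k) {
  stopifnot(all(map_labels %in% seq_len(k)), all(true_labels %in% seq_len(k)))
  agree <- matrix(0, k, k)
  tab <- table(factor(map_labels, levels = seq_len(k)),
               factor(true_labels, levels = seq_len(k)))
  agree[] <- tab
  if (k <= 6) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p) {
      sum(agree[cbind(seq_len(k), p)])
    }, numeric(1))
    perms[[which.max(scores)]]
  } else {
    p <- integer(k)
    left <- seq_len(k)
    for (j in order(-apply(agree, 1, max))) {
      pick <- left[which.max(agree[j, left])]
      p[j] <- pick
      left <- setdiff(left, pick)
    }
    p
  }
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# metrics of one fitted replicate, components aligned to the true labels
replicate_metrics <- function(fit) {
  dec <- deviance_decomposition(fit)
  perm <- align_components(fit$map_labels, fit$true_labels, fit$k)
  ord <- order(perm)  # row of `local` whose aligned label is 1, 2, ...
  loc <- dec$local[ord, ]
  c(ARI = adjusted_rand_index(fit$map_labels, fit$true_labels),
    NBD = dec$normalized$NBD,
    R2_1 = loc$R2[1], R2_2 = loc$R2[2],
    D1_over_WD = loc$weight[1], D2_over_WD = loc$weight[2],
    R2 = dec$r2)
}

#' Monte Carlo run of one simulation condition
#'
#' For each replicate `r`, generates a data set with seed `base_seed + r`,
#' builds the initial partition with the requested strategy, fits the
#' two-component mixture EM, aligns the estimated components with the true
#' labels, and records ARI, NBD, the aligned local R-squared values and
#' deviance weights, and the overall R-squared.  Failed replicates
#' (degenerate components, underflow) are excluded and counted; a failure
#' rate above 5% flags the summary as unreliable.
#'
#' @param cond A [simulation_condition()] object.
#' @param init Initialization strategy name (default `"true_labels"`, the
#'   harness default for table reproduction).
#' @param reps Number of replicates.
#' @param base_seed Base seed; replicate `r` uses `base_seed + r`.
#' @param keep_replicates If `TRUE`, attach the per-replicate tibble as
#'   attribute `"replicates"`.
#' @param ... Passed to [mixglm()] (e.g. `control`).
#' @return Tibble with one row per metric (`metric`, `mean`, `sd`) and
#'   attributes `n_completed`, `n_failed`, `unreliable`,
#'   `single_replicate`.
#' @export
run_condition <- function(cond, init = "true_labels", reps = cond$reps,
                          base_seed = 2027L, keep_replicates = FALSE, ...) {
  stopifnot(inherits(cond, "mixglm_condition"))
  dgp <- condition_params(cond)
  rows <- vector("list", reps)
  failed <- 0L
  for (r in seq_len(reps)) {
    seed_r <- base_seed + r
    dat <- generate_mixture_data(cond, seed = seed_r)
    res <- tryCatch({
      fit <- mixglm(dat, y ~ x, family = cond$family, k = 2,
                    trials = cond$m, labels = "class", init = init,
                    dgp = dgp, seed = seed_r, ...)
      c(rep = r, replicate_metrics(fit))
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else rows[[r]] <- res
  }
  repl <- dplyr::bind_rows(lapply(rows[!vapply(rows, is.null, logical(1))],
                                  function(v) tibble::as_tibble(as.list(v))))
  metrics <- setdiff(names(repl), "rep")
  summ <- tidyr::pivot_longer(repl, -"rep", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metrics))
  attr(summ, "condition") <- cond$condition
  attr(summ, "family") <- cond$family
  attr(summ, "init") <- init
  attr(summ, "n_completed") <- nrow(repl)
  attr(summ, "n_failed") <- failed
  attr(summ, "unreliable") <- failed > 0.05 * reps
  attr(summ, "single_replicate") <- nrow(repl) == 1L
  if (keep_replicates) attr(summ, "replicates") <- repl
  summ
}

#' Compare initialization strategies on shared replicates
#'
#' Generates `reps` data sets from a condition and fits the mixture under
#' each initialization strategy on the *same* data, so that strategies can
#' be compared pairwise per replicate.
#'
#' @param cond A [simulation_condition()] object.
#' @param strategies Character vector of [initial_partition()] strategy
#'   names.
#' @param reps,base_seed As in [run_condition()].
#' @param ... Passed to [mixglm()].
#' @return Long tibble: `rep`, `strategy`, then one column per metric.
#' @export
run_init_comparison <- function(cond,
                                strategies = c("true_labels", "kmeans",
                                               "pam", "gmm_full"),
                                reps = 250L, base_seed = 2027L, ...) {
  stopifnot(inherits(cond, "mixglm_condition"))
  dgp <- condition_params(cond)
  out <- list()
  for (r in seq_len(reps)) {
    seed_r <- base_seed + r
    dat <- generate_mixture_data(cond, seed = seed_r)
    for (s in strategies) {
      res <- tryCatch({
        fit <- mixglm(dat, y ~ x, family = cond$family, k = 2,
                      trials = cond$m, labels = "class", init = s,
                      dgp = dgp, seed = seed_r, ...)
        m <- replicate_metrics(fit)
        tibble::as_tibble(as.list(c(rep = r, m)))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        res$strategy <- s
        out[[length(out) + 1L]] <- res
      }
    }
  }
  dplyr::relocate(dplyr::bind_rows(out), "rep", "strategy")
}
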