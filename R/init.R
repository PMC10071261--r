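#' Initial hard partitions for the mixture EM
#'
#' Produces the initial hard label vector the EM algorithm starts from.
#' Available strategies:
#'
#' * `"true_labels"` — the supplied true cluster memberships (the default
#'   strategy of the Monte Carlo harness).
#' * `"true_dgp_map"` — posterior probabilities under the *true* generating
#'   parameters (`dgp`), hardened by the MAP rule.
#' * `"short_em"` — `S` short EM runs of `H` iterations each from random
#'   uniform hard assignments; the start with the highest observed-data
#'   log-likelihood wins and its MAP partition is returned.
#' * `"kmeans"` — k-means on the joint `(X, y)` rows, best of `restarts`
#'   starts by within-cluster sum of squares.
#' * `"pam"` — partitioning around medoids on `(X, y)`, Euclidean
#'   dissimilarity.
#' * `"gmm_full"` — unconstrained ("VVV") Gaussian mixture on `(X, y)` via
#'   \pkg{mclust} (agglomerative hierarchical seeding), MAP labels.
#'
#' The joint clustering space is the raw, unstandardized `(X, y)` matrix.
#' Every strategy is deterministic given `(data, seed)`.  A partition with an
#' empty cluster is retried once with a shifted seed, then raises an error.
#'
#' @param y,X Response vector and covariate matrix.
#' @param k Number of clusters.
#' @param strategy Strategy name (see above).
#' @param family A [glm_family()] object (needed by the EM-based strategies).
#' @param dgp True [mixglm_params()] (for `"true_dgp_map"`).
#' @param true_labels True label vector (for `"true_labels"`).
#' @param offset Optional Poisson offset, passed to EM-based strategies.
#' @param S,H Short-EM restarts and iterations per restart.
#' @param restarts k-means restarts.
#' @param seed Integer seed controlling the strategy's randomness.
#' @return Integer label vector in `1..k`.
#' @export
initial_partition <- function(y, X, k,
                              strategy = c("true_labels", "true_dgp_map",
                                           "short_em", "kmeans", "pam",
                                           "gmm_full"),
                              family = NULL, dgp = NULL, true_labels = NULL,
                              offset = NULL, S = 10L, H = 5L, restarts = 10L,
                              seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(S >= 1, H >= 1)
  X <- as.matrix(X)
  joint <- cbind(X, y)

  one_try <- function(seed) {
    if (!is.null(seed)) set.seed(seed)
    switch(strategy,
      true_labels = {
        if (is.null(true_labels)) {
          stop("strategy 'true_labels' requires true labels", call. = FALSE)
        }
        as.integer(true_labels)
      },
      true_dgp_map = {
        if (is.null(dgp)) {
          stop("strategy 'true_dgp_map' requires the true parameters `dgp`",
               call. = FALSE)
        }
        map_classify(e_step(y, X, dgp, offset = offset))
      },
      short_em = {
        if (is.null(family)) {
          stop("strategy 'short_em' requires a family", call. = FALSE)
        }
        short_em_partition(y, X, k, family, offset, S = S, H = H)
      },
      kmeans = stats::kmeans(joint, centers = k, nstart = restarts)$cluster,
      pam = cluster::pam(joint, k = k, cluster.only = TRUE),
      gmm_full = {
        # Mclust() resolves mclustBIC in the caller's frame; bind it locally
        mclustBIC <- mclust::mclustBIC
        mc <- mclust::Mclust(joint, G = k, modelNames = "VVV",
                             verbose = FALSE)
        if (is.null(mc)) {
          stop("gmm_full initialization failed to fit", call. = FALSE)
        }
        as.integer(mc$classification)
      }
    )
  }

  lab <- one_try(seed)
  if (length(unique(lab)) < k) {
    lab <- one_try(if (is.null(seed)) NULL else seed + 10007L)
    if (length(unique(lab)) < k) {
      stop("initial partition has an empty cluster", call. = FALSE)
    }
  }
  as.integer(lab)
}

# S random-start short EM runs of H iterations; return MAP of the best run
short_em_partition <- function(y, X, k, family, offset, S, H) {
  n <- length(y)
  d <- ncol(as.matrix(X))
  best_ll <- -Inf
  best_z <- NULL
  tried <- 0L
  while (tried < S) {
    lab <- sample.int(k, n, replace = TRUE)
    if (min(tabulate(lab, k)) < d + 2) next  # resample a viable random start
    tried <- tried + 1L
    res <- tryCatch(
      em_core(y, X, family, k, lab, offset = offset,
              control = mixglm_control(tol = 0, max_iter = H)),
      error = function(e) NULL
    )
    if (!is.null(res) && res$loglik > best_ll) {
      best_ll <- res$loglik
      best_z <- res$posteriors
    }
  }
  if (is.null(best_z)) {
    stop("all short-EM starts failed", call. = FALSE)
  }
  map_classify(best_z)
}
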