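# Batch I/O layer: typed table reading, k-range fit reports and simulation
# reports.  A thin command-line wrapper over these functions lives in
# inst/cli/mixglm.R.

#' Read and validate a delimited regression table
#'
#' Reads a CSV/TSV file with a header, checks that the named columns exist
#' and are numeric, and validates the response against the family support
#' (counts for Poisson, counts in `{0, ..., m}` for binomial).  An offset
#' column is taken as already on the log scale unless `raw_population =
#' TRUE`, in which case its elementwise log is used — there is no silent
#' transformation.
#'
#' @param path File path (delimiter inferred from the extension:
#'   `.tsv`/`.tab` means tab, otherwise comma).
#' @param response,covariates Column names.
#' @param family `"gaussian"`, `"poisson"` or `"binomial"`.
#' @param trials Binomial trials `m`.
#' @param offset_col Optional offset column name (Poisson only).
#' @param raw_population If `TRUE`, `offset = log(offset_col)`.
#' @param labels_col Optional true-label column name.
#' @return Tibble with columns `y`, the covariates, and optionally
#'   `.offset` and `.label`; attributes `family` and `d`.
#' @export
read_regression_table <- function(path, response, covariates,
                                  family = c("gaussian", "poisson",
                                             "binomial"),
                                  trials = NULL, offset_col = NULL,
                                  raw_population = FALSE, labels_col = NULL) {
  family <- match.arg(family)
  fam <- glm_family(family, trials = trials)
  delim <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  needed <- c(response, covariates, offset_col, labels_col)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("column(s) not found in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c(response, covariates, offset_col)) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' (row %s)", col,
                   ifelse(is.na(bad), "?", bad)), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' (row %d)", col,
                   which(is.na(v))[1]), call. = FALSE)
    }
  }
  y <- tab[[response]]
  if (!fam$validate_y(y)) {
    stop(sprintf("response column '%s' violates the %s support", response,
                 family), call. = FALSE)
  }
  out <- tibble::tibble(y = y)
  for (col in covariates) out[[col]] <- tab[[col]]
  if (!is.null(offset_col)) {
    if (family != "poisson") {
      stop("offsets are supported for the poisson family only", call. = FALSE)
    }
    off <- tab[[offset_col]]
    if (raw_population) {
      if (any(off <= 0)) {
        stop(sprintf("raw population column '%s' must be positive (row %d)",
                     offset_col, which(off <= 0)[1]), call. = FALSE)
      }
      off <- log(off)
    }
    out$.offset <- off
  }
  if (!is.null(labels_col)) out$.label <- as.integer(tab[[labels_col]])
  attr(out, "family") <- family
  attr(out, "d") <- length(covariates)
  out
}

#' Fit report over a range of component counts
#'
#' Fits the mixture for each `k` in `k_range`, decomposes the deviance, and
#' writes per-`k` reports: `params_k<k>.json` (mixing weights, coefficients
#' with approximate standard errors, dispersions), `posteriors_k<k>.csv`,
#' `deviance_report_k<k>.json` (local and overall measures), and a single
#' `criteria.csv` with log-likelihood, BIC and ICL per `k`.  Every JSON
#' report carries the package version, the seed and a configuration hash.
#' On error, partial outputs for the failing `k` are removed before the
#' condition is rethrown.
#'
#' @param data A tibble from [read_regression_table()] (or any data frame
#'   with a `y` column and the covariates; optional `.offset`, `.label`).
#' @param covariates Covariate column names.
#' @param family,trials Family specification.
#' @param k_range Integer vector of component counts to scan.
#' @param init,seed,control Passed to [mixglm()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the criteria tibble.
#' @export
fit_report <- function(data, covariates, family, trials = NULL,
                       k_range = 1:4, init = "kmeans", seed = 1L,
                       control = mixglm_control(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fml <- stats::as.formula(paste("y ~", paste(covariates, collapse = " + ")))
  offset <- if (".offset" %in% names(data)) ".offset"
  labels <- if (".label" %in% names(data)) ".label"
  cfg_hash <- sum(utf8ToInt(paste(covariates, family, trials,
                                  paste(k_range, collapse = ","),
                                  init, collapse = "|")))
  provenance <- list(package_version = as.character(utils::packageVersion("mixglm")),
                     seed = seed, config_hash = cfg_hash)
  rows <- list()
  for (k in k_range) {
    files_k <- file.path(out_dir, sprintf(c("params_k%d.json",
                                            "posteriors_k%d.csv",
                                            "deviance_report_k%d.json"), k))
    res <- tryCatch({
      fit <- mixglm(data, fml, family = family, k = k, trials = trials,
                    offset = offset, labels = labels,
                    init = if (k == 1) rep(1L, nrow(data)) else init,
                    seed = seed, control = control)
      dec <- deviance_decomposition(fit)
      co <- tidy(fit)
      jsonlite::write_json(
        c(provenance,
          list(k = k, pi = fit$params$pi,
               coefficients = split(co[c("term", "estimate", "std.error")],
                                    co$component),
               phi = fit$params$phi,
               converged = fit$converged)),
        files_k[1], auto_unbox = TRUE, digits = NA, pretty = TRUE)
      readr::write_csv(tibble::as_tibble(
        as.data.frame(fit$posteriors),
        .name_repair = ~ paste0("z", seq_along(.x))), files_k[2])
      jsonlite::write_json(
        c(provenance,
          list(k = k, local = dec$local, totals = dec$totals,
               normalized = dec$normalized, R2 = dec$r2,
               R2bar = dec$adjusted$R2bar,
               descriptive_only = TRUE)),
        files_k[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
      tibble::tibble(k = k, logLik = fit$loglik, n_params = fit$n_params,
                     BIC = fit$BIC, ICL = fit$ICL,
                     converged = fit$converged)
    }, error = function(e) {
      unlink(files_k[file.exists(files_k)])
      stop(e)
    })
    rows[[length(rows) + 1L]] <- res
  }
  criteria <- dplyr::bind_rows(rows)
  readr::write_csv(criteria, file.path(out_dir, "criteria.csv"))
  invisible(criteria)
}

#' Simulation report for one condition
#'
#' Runs [run_condition()] and writes `summary.csv` (one row per metric with
#' its Monte Carlo mean and standard deviation) and `replicates.csv`
#' (per-replicate long format), logging seed and provenance columns.
#'
#' @param cond A [simulation_condition()] object.
#' @param init Initialization strategy.
#' @param reps,base_seed As in [run_condition()].
#' @param out_dir Output directory.
#' @return Invisibly, the summary tibble.
#' @export
simulate_report <- function(cond, init = "true_labels", reps = cond$reps,
                            base_seed = 2027L, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- run_condition(cond, init = init, reps = reps,
                        base_seed = base_seed, keep_replicates = TRUE)
  out <- dplyr::mutate(summ,
                       family = cond$family, condition = cond$condition,
                       init = init, reps = reps, base_seed = base_seed,
                       n_completed = attr(summ, "n_completed"),
                       n_failed = attr(summ, "n_failed"),
                       package_version =
                         as.character(utils::packageVersion("mixglm")))
  readr::write_csv(out, file.path(out_dir, "summary.csv"))
  readr::write_csv(attr(summ, "replicates"),
                   file.path(out_dir, "replicates.csv"))
  invisible(summ)
}
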