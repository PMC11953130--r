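#' Per-environment prediction accuracy
#'
#' Computes the Pearson correlation between predictions and observations
#' within each environment — the accuracy criterion of interest when the goal
#' is ranking genotypes per environment. Environments with fewer than `min_n`
#' observed cells, or with zero variance in predictions or observations, get
#' an undefined (`NA`) correlation and are excluded from the summary mean.
#'
#' @param preds A `gxe_predictions` tibble with a `y_obs` column, or any data
#'   frame with `genotype`, `env`, `y_hat`, `y_obs`.
#' @param observed Optional tibble (`genotype`, `env`, `y`) replacing the
#'   evaluation target, e.g. simulated true genetic values instead of noisy
#'   phenotypes.
#' @param min_n Minimum number of observed cells for a defined correlation
#'   (default 3).
#' @return A tibble of class `gxe_accuracy` with columns `env`, `n`, `r`, and
#'   attributes `apcor_env` (unweighted mean of the defined correlations) and
#'   `n_envs_used`.
#' @examples
#' p <- tibble::tibble(genotype = rep(c("a", "b", "c"), 2),
#'                     env = rep(c("e1", "e2"), each = 3),
#'                     y_hat = c(2, 4, 6, 3, 2, 1),
#'                     y_obs = c(1, 2, 3, 1, 2, 3))
#' acc <- accuracy_by_env(p)
#' apcor_env(acc)
#' @export
accuracy_by_env <- function(preds, observed = NULL, min_n = 3) {
  df <- as_tibble(preds)
  if (!is.null(observed)) {
    obs <- tibble(genotype = as.character(observed$genotype),
                  env = as.character(observed$env),
                  y_obs = as.numeric(observed$y))
    df$y_obs <- NULL
    df <- dplyr::left_join(df, obs, by = c("genotype", "env"))
  }
  if (!"y_obs" %in% names(df)) {
    abort("predictions carry no observations to evaluate against",
          class = "gxenet_validation_error")
  }
  out <- df |>
    dplyr::filter(!is.na(.data$y_obs)) |>
    dplyr::group_by(env = .data$env) |>
    dplyr::summarise(n = dplyr::n(),
                     r = pearson_or_na(.data$y_hat, .data$y_obs, min_n),
                     .groups = "drop")
  defined <- !is.na(out$r)
  structure(out,
            apcor_env = if (any(defined)) mean(out$r[defined]) else NA_real_,
            n_envs_used = sum(defined),
            class = c("gxe_accuracy", class(out)))
}

pearson_or_na <- function(x, y, min_n) {
  if (length(x) < min_n) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Average per-environment accuracy (APCOR_Env)
#'
#' The Pearson correlation between predictions and observations within each
#' environment, averaged over environments. The default is the unweighted
#' arithmetic mean over environments with a defined correlation; set
#' `weighted = TRUE` to weight environments by their number of observed cells.
#'
#' @param x A `gxe_accuracy` table from [accuracy_by_env()], or a (possibly
#'   named) numeric vector of per-environment correlations (`NA` = undefined).
#' @param weighted Weight environments by sample size (default `FALSE`).
#' @return A single number in `[-1, 1]`, with attribute `n_envs_used`.
#' @export
apcor_env <- function(x, weighted = FALSE) {
  if (inherits(x, "gxe_accuracy")) {
    r <- x$r
    n <- x$n
  } else {
    r <- as.numeric(x)
    n <- rep(1, length(r))
  }
  defined <- !is.na(r)
  if (!any(defined)) {
    abort("no environment has a defined correlation",
          class = "gxenet_validation_error")
  }
  val <- if (weighted) {
    sum(r[defined] * n[defined]) / sum(n[defined])
  } else {
    mean(r[defined])
  }
  structure(val, n_envs_used = sum(defined))
}

#' @export
print.gxe_accuracy <- function(x, ...) {
  cat("<gxe_accuracy> APCOR_Env = ",
      signif(attr(x, "apcor_env"), 4), " over ", attr(x, "n_envs_used"),
      " environments\n", sep = "")
  NextMethod()
}

#' Write an accuracy report (CSV + JSON summary)
#'
#' @param acc A `gxe_accuracy` table.
#' @param path_csv Per-environment CSV path (`env`, `n`, `r`).
#' @param path_json Optional JSON summary path (`apcor_env`, `n_envs_used`).
#' @return `acc`, invisibly.
#' @export
write_accuracy <- function(acc, path_csv, path_json = NULL) {
  readr::write_csv(as_tibble(acc), path_csv, progress = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(apcor_env = attr(acc, "apcor_env"),
                              n_envs_used = attr(acc, "n_envs_used")),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(acc)
}
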