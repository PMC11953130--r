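#' Serialize a fit to plain text (JSON + CSV)
#'
#' Writes `fit.json` (scalars, penalty settings, main-effect maps, EC
#' standardization statistics), `B.csv` (the sensitivity matrix on the
#' original EC scale) and `cv_trace.csv` into a directory, from which
#' [read_fit()] reconstructs a fit usable for prediction.
#'
#' @param fit A `gxe_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    mu = fit$mu, g = as.list(fit$g), e = as.list(fit$e),
    penalty = fit$penalty[c("kind", "alpha")],
    lambda_selected = fit$lambda_selected,
    sigma2_hat = fit$sigma2_hat,
    standardize = fit$standardize, ec_mode = fit$ec_mode,
    ec_names = fit$ec_names,
    ec_stats = list(ec = fit$ec_stats$ec, mean = fit$ec_stats$mean,
                    sd = fit$ec_stats$sd),
    genotypes = fit$genotypes, environments = fit$environments,
    n_obs = fit$n_obs, df = fit$df,
    cv = fit$cv
  )
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  readr::write_csv(dplyr::bind_cols(tibble(genotype = rownames(fit$B)),
                                    as_tibble(fit$B)),
                   file.path(dir, "B.csv"), progress = FALSE)
  if (!is.null(fit$cv_trace)) {
    readr::write_csv(fit$cv_trace, file.path(dir, "cv_trace.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Load a serialized fit
#'
#' @param dir Directory written by [write_fit()].
#' @return A `gxe_fit` (without training fitted values).
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit.json"),
                              simplifyVector = TRUE)
  Btab <- readr::read_csv(file.path(dir, "B.csv"), show_col_types = FALSE,
                          progress = FALSE)
  B <- as.matrix(Btab[-1])
  rownames(B) <- Btab$genotype
  ec_stats <- tibble(ec = meta$ec_stats$ec, mean = meta$ec_stats$mean,
                     sd = meta$ec_stats$sd)
  B_std <- if (isTRUE(meta$standardize)) sweep(B, 2, ec_stats$sd, "*") else B
  genotypes <- meta$genotypes
  environments <- meta$environments
  columns <- design_columns(genotypes, environments, meta$ec_names)
  g <- setNames(rep(0, length(genotypes)), genotypes)
  g[names(meta$g)] <- unlist(meta$g)
  e <- setNames(rep(0, length(environments)), environments)
  e[names(meta$e)] <- unlist(meta$e)
  theta <- numeric(nrow(columns))
  theta[columns$role == "intercept"] <- meta$mu
  theta[columns$role == "geno_main"] <-
    g[columns$genotype[columns$role == "geno_main"]]
  theta[columns$role == "env_main"] <-
    e[columns$env[columns$role == "env_main"]]
  theta[columns$role == "sensitivity"] <- as.vector(t(B_std))
  cv_trace_path <- file.path(dir, "cv_trace.csv")
  cv_trace <- if (file.exists(cv_trace_path)) {
    readr::read_csv(cv_trace_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(
    mu = meta$mu, g = g, e = e, B = B, B_std = B_std,
    coefficients = setNames(theta, columns$column), columns = columns,
    penalty = list(kind = meta$penalty$kind, alpha = meta$penalty$alpha,
                   lambda_grid = numeric(0)),
    lambda_selected = meta$lambda_selected, sigma2_hat = meta$sigma2_hat,
    cv_trace = cv_trace, cv = meta$cv,
    ec_stats = ec_stats, standardize = isTRUE(meta$standardize),
    ec_mode = meta$ec_mode, genotypes = genotypes,
    environments = environments, ec_names = meta$ec_names,
    n_obs = meta$n_obs, df = meta$df, fitted = NULL
  ), class = "gxe_fit")
}
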