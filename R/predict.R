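#' Predict environment-centred performance in new environments
#'
#' Combines the training estimates of the genotype main effects and
#' sensitivities with EC values of the target environments:
#' \deqn{\hat y_{ij} = \hat\mu + \hat g_i + \sum_t \tilde v^{(t)}_{ij}
#'   \hat\beta_{it}}
#' where \eqn{\tilde v} is the EC on the training-standardized scale. No
#' environmental main effect enters (for a new environment it is unknown), so
#' predictions are environment-centred; within-environment correlations and
#' rankings — the quantities of interest for variety evaluation — are
#' unaffected by that per-environment constant.
#'
#' @param fit A `gxe_fit` (or `gxe_additive`).
#' @param ecs A `met_ecs` table carrying the training standardization
#'   statistics (e.g. `data$ecs` of the aligned dataset the fit was trained
#'   on, which also covers the test environments).
#' @param genotypes Genotype ids to predict (must all have been in training);
#'   default all training genotypes.
#' @param envs Environment ids to predict.
#' @param observed Optional tibble (`genotype`, `env`, `y`) of observations to
#'   attach as `y_obs` for later accuracy evaluation.
#' @return A tibble of class `gxe_predictions` with columns `genotype`, `env`,
#'   `y_hat` (and `y_obs` where supplied).
#' @export
predict_goen <- function(fit, ecs, genotypes = NULL, envs,
                         observed = NULL) {
  stopifnot(inherits(fit, "gxe_fit"))
  genotypes <- genotypes %||% fit$genotypes
  dp <- design_for_prediction(fit$columns, ecs, genotypes, envs,
                              standardize = fit$standardize)
  out <- dp$row_keys
  out$y_hat <- as.numeric(dp$X %*% fit$coefficients)
  if (!is.null(observed)) {
    obs <- tibble(genotype = as.character(observed$genotype),
                  env = as.character(observed$env),
                  y_obs = as.numeric(observed$y))
    out <- dplyr::left_join(out, obs, by = c("genotype", "env"))
  }
  structure(out, centred = TRUE,
            class = c("gxe_predictions", class(out)))
}

#' Predict from a fitted penalized factorial regression
#'
#' Convenience method around [predict_goen()]: given the aligned dataset (or
#' an EC table), predicts the test environments by default and attaches any
#' observed phenotypes for those cells.
#'
#' @param object A `gxe_fit`.
#' @param newdata A `met_aligned` dataset or a `met_ecs` table.
#' @param envs Environments to predict; defaults to the dataset's test split.
#' @param genotypes Genotypes to predict; defaults to all training genotypes.
#' @param ... Unused.
#' @return A `gxe_predictions` tibble.
#' @export
predict.gxe_fit <- function(object, newdata, envs = NULL, genotypes = NULL,
                            ...) {
  if (inherits(newdata, "met_aligned")) {
    envs <- envs %||% test_envs_of(newdata)
    if (length(envs) == 0) {
      abort("no test environments in the dataset; pass `envs` explicitly",
            class = "gxenet_validation_error")
    }
    observed <- as_tibble(newdata$pheno)[newdata$pheno$env %in% envs,
                                         c("genotype", "env", "y")]
    predict_goen(object, newdata$ecs, genotypes = genotypes, envs = envs,
                 observed = observed)
  } else if (inherits(newdata, "met_ecs")) {
    if (is.null(envs)) {
      abort("pass `envs` when predicting from a raw EC table",
            class = "gxenet_validation_error")
    }
    predict_goen(object, newdata, genotypes = genotypes, envs = envs)
  } else {
    abort("`newdata` must be a met_aligned dataset or a met_ecs table",
          class = "gxenet_validation_error")
  }
}
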