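#' Tidy a penalized factorial regression fit
#'
#' One row per model term: the general mean, each genotype and environment
#' main effect, and each genotype-by-EC sensitivity (on the original EC
#' scale).
#'
#' @param x A `gxe_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `role`, `genotype`, `env`, `ec`,
#'   `estimate`.
#' @export
tidy.gxe_fit <- function(x, ...) {
  est <- x$coefficients
  out <- dplyr::mutate(x$columns, estimate = unname(est))
  # report sensitivities on the original EC scale
  sens <- out$role == "sensitivity"
  if (x$standardize) {
    sd_map <- setNames(x$ec_stats$sd, x$ec_stats$ec)
    out$estimate[sens] <- out$estimate[sens] / sd_map[out$ec[sens]]
  }
  dplyr::select(dplyr::rename(out, term = "column"),
                "term", "role", "genotype", "env", "ec", "estimate")
}

#' One-row summary of a penalized factorial regression fit
#'
#' @param x A `gxe_fit`.
#' @param ... Unused.
#' @return A tibble with the penalty kind and mixing, selected lambda,
#'   problem dimensions, number of nonzero coefficients, residual variance
#'   and training APCOR_Env.
#' @export
glance.gxe_fit <- function(x, ...) {
  train_acc <- tryCatch(
    attr(accuracy_by_env(dplyr::rename(x$fitted, y_hat = "y_fit")),
         "apcor_env"),
    error = function(e) NA_real_)
  tibble(penalty = x$penalty$kind, alpha = x$penalty$alpha,
         lambda = x$lambda_selected,
         n_obs = x$n_obs, n_genotypes = length(x$genotypes),
         n_environments = length(x$environments), n_ecs = length(x$ec_names),
         df = x$df, sigma2 = x$sigma2_hat, apcor_train = train_acc)
}

#' @export
tidy.gxe_accuracy <- function(x, ...) as_tibble(x)

#' @export
glance.gxe_accuracy <- function(x, ...) {
  tibble(apcor_env = attr(x, "apcor_env"),
         n_envs_used = attr(x, "n_envs_used"),
         n_envs = nrow(x))
}

#' Plot the cross-validation curve of a fit
#'
#' Mean held-out squared error (with one-standard-error ribbon) against the
#' penalty strength, with the selected lambda marked.
#'
#' @param object A `gxe_fit` with a CV trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxe_fit <- function(object, ...) {
  tr <- object$cv_trace
  if (is.null(tr) || all(is.na(tr$mse_mean))) {
    abort("fit has no cross-validation trace to plot",
          class = "gxenet_validation_error")
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$lambda, y = .data$mse_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mse_mean - .data$mse_se,
                                      ymax = .data$mse_mean + .data$mse_se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda_selected,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "CV mean squared error",
                  title = paste0("Cross-validation curve (",
                                 object$penalty$kind, ")"))
}

#' Plot per-environment accuracies
#'
#' @param object A `gxe_accuracy` table.
#' @param ... Unused.
#' @return A ggplot object; the dashed line marks APCOR_Env.
#' @export
autoplot.gxe_accuracy <- function(object, ...) {
  df <- as_tibble(object)
  df$env <- stats::reorder(df$env, df$r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$env, y = .data$r)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "apcor_env"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson r (within environment)",
                  title = "Per-environment prediction accuracy")
}

#' Accuracy as a function of the penalty strength
#'
#' Refits the coefficient path on the training rows and evaluates training
#' and test APCOR_Env at every lambda — the train/test accuracy sweep that
#' shows overfitting at small penalties, convergence to the additive model at
#' large ones, and (typically) a unimodal test curve in between.
#'
#' @inheritParams fit_gxenet
#' @return A tibble of class `gxe_sweep` (`lambda`, `apcor_train`,
#'   `apcor_test`).
#' @export
lambda_sweep <- function(data, penalty = c("ridge", "lasso", "elnet"),
                         alpha = NULL, lambda = "auto", nlambda = 100,
                         lambda_min_ratio = 1e-4, standardize = TRUE) {
  penalty <- match.arg(penalty)
  if (is.null(alpha)) alpha <- switch(penalty, ridge = 0, lasso = 1,
                                      elnet = 0.5)
  design <- build_design(data, standardize = standardize)
  grid <- if (identical(lambda, "auto")) {
    lambda_grid(design, alpha = alpha, nlambda = nlambda,
                lambda_min_ratio = lambda_min_ratio)
  } else sort(as.numeric(lambda), decreasing = TRUE)
  theta <- elnet_path(design, alpha = alpha, lambda = grid)

  test_envs <- test_envs_of(data)
  fit_train <- as.matrix(design$X %*% theta)
  train_keys <- design$row_keys
  if (length(test_envs) > 0) {
    dp <- design_for_prediction(design$columns, data$ecs, design$genotypes,
                                test_envs, standardize = standardize)
    pred_test <- as.matrix(dp$X %*% theta)
    obs_test <- dplyr::left_join(
      dp$row_keys,
      as_tibble(data$pheno)[c("genotype", "env", "y")],
      by = c("genotype", "env"))
  }
  apcor_of <- function(keys, yhat, yobs) {
    keep <- !is.na(yobs)
    tb <- tibble(genotype = keys$genotype[keep], env = keys$env[keep],
                 y_hat = yhat[keep], y_obs = yobs[keep])
    attr(accuracy_by_env(tb), "apcor_env")
  }
  out <- tibble(
    lambda = as.numeric(grid),
    apcor_train = vapply(seq_along(grid), function(l) {
      apcor_of(train_keys, fit_train[, l], design$y)
    }, numeric(1)),
    apcor_test = if (length(test_envs) > 0) {
      vapply(seq_along(grid), function(l) {
        apcor_of(dp$row_keys, pred_test[, l], obs_test$y)
      }, numeric(1))
    } else NA_real_
  )
  structure(out, class = c("gxe_sweep", class(out)))
}

#' Plot a train/test accuracy sweep over the penalty path
#'
#' @param object A `gxe_sweep` from [lambda_sweep()].
#' @param additive Optional `gxe_accuracy` pair to draw as dotted reference
#'   lines: a list with elements `train` and/or `test` (APCOR_Env values of
#'   the additive model).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxe_sweep <- function(object, additive = NULL, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"lambda",
                              names_to = "set", names_prefix = "apcor_",
                              values_to = "apcor")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$apcor,
                                          colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = expression(APCOR[Env]),
                  colour = NULL)
  if (!is.null(additive)) {
    for (v in unlist(additive)) {
      p <- p + ggplot2::geom_hline(yintercept = v, linetype = "dotted")
    }
  }
  p
}
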