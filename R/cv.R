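#' Assign cross-validation folds to the training rows
#'
#' Two schemes, following common practice in multi-environment prediction:
#' `"random"` partitions the G-by-E observations near-uniformly at random,
#' ignoring environments; `"stratified"` partitions the ENVIRONMENTS into `k`
#' groups, so every observation of an environment shares its environment's
#' fold — held-out folds then consist of whole environments, mimicking the
#' new-environment prediction task.
#'
#' @param data A `met_aligned` dataset (folds cover its training rows, in
#'   phenotype-row order).
#' @param k Number of folds (default 10).
#' @param mode `"random"` or `"stratified"`.
#' @param seed Integer seed; folds are a pure function of it (no global RNG
#'   state is consumed).
#' @return Integer vector of fold labels in `1:k`, one per training row.
#' @export
make_folds <- function(data, k = 10, mode = c("random", "stratified"),
                       seed = 1) {
  mode <- match.arg(mode)
  rows <- train_rows(data)
  n <- length(rows)
  train_envs <- data$split$env[data$split$role == "train"]
  if (mode == "random") {
    if (k < 2 || k > n) {
      abort(sprintf("random CV needs 2 <= k <= N (= %d); got k = %d", n, k),
            class = "gxenet_cv_error")
    }
    withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    n_e <- length(train_envs)
    if (k < 2 || k > n_e) {
      abort(sprintf("stratified CV needs 2 <= k <= n_e (= %d); got k = %d",
                    n_e, k),
            class = "gxenet_cv_error")
    }
    env_fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n_e)))
    names(env_fold) <- train_envs
    unname(env_fold[data$pheno$env[rows]])
  }
}

#' Select the penalty strength by cross-validation
#'
#' For each fold, the path is refit on the remaining training rows and
#' held-out rows are predicted at every lambda; the CV criterion is the mean
#' of the per-fold held-out mean squared errors. Under stratified folds a
#' held-out environment's main-effect column is all-zero in the fold's
#' training block, so its coefficient is 0 — exactly the environment-centred
#' prediction rule used for genuinely new environments.
#'
#' @inheritParams elnet_path
#' @param folds Integer fold vector from [make_folds()].
#' @return List with `lambda_min` (the error-minimizing lambda; ties go to the
#'   larger value), `lambda_1se` (largest lambda within one standard error of
#'   the minimum) and `cv_trace`, a tibble (`lambda`, `mse_mean`, `mse_se`).
#' @export
cv_select_lambda <- function(design, alpha = 0.5, lambda, folds,
                             tol = 1e-4, max_passes = 1e5) {
  if (length(lambda) < 1) abort("empty lambda grid", class = "gxenet_cv_error")
  k <- max(folds)
  stopifnot(length(folds) == nrow(design$X))
  if (length(lambda) == 1) {
    return(list(lambda_min = lambda, lambda_1se = lambda,
                cv_trace = tibble(lambda = lambda, mse_mean = NA_real_,
                                  mse_se = NA_real_)))
  }
  mse <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    tr <- folds != f
    sub <- list(X = design$X[tr, , drop = FALSE], y = design$y[tr],
                columns = design$columns)
    theta <- elnet_path(sub, alpha = alpha, lambda = lambda, tol = tol,
                        max_passes = max_passes)
    pred <- as.matrix(design$X[!tr, , drop = FALSE] %*% theta)
    mse[f, ] <- colMeans((design$y[!tr] - pred)^2)
  }
  mse_mean <- colMeans(mse)
  mse_se <- apply(mse, 2, stats::sd) / sqrt(k)
  trace <- tibble(lambda = as.numeric(lambda), mse_mean = mse_mean,
                  mse_se = mse_se)
  if (max(mse_mean) - min(mse_mean) < 1e-12) {
    warn("cross-validation error is flat across the lambda grid; returning the largest lambda")
    return(list(lambda_min = lambda[1], lambda_1se = lambda[1],
                cv_trace = trace))
  }
  i_min <- which.min(mse_mean)     # grid is decreasing: first = largest lambda
  cutoff <- mse_mean[i_min] + mse_se[i_min]
  i_1se <- which(mse_mean <= cutoff)[1]
  list(lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
       cv_trace = trace)
}
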