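#' Fit penalized factorial regression to a multi-environment trial
#'
#' The end-to-end workhorse: standardizes ECs with the training statistics,
#' builds the sparse factorial-regression design, chooses the penalty
#' strength by cross-validation over an automatic (or user) lambda grid, and
#' refits on all training rows at the selected value. Genotype and environment
#' main effects are never shrunk; only the genotype-by-EC sensitivity slopes
#' are penalized.
#'
#' @param data A `met_aligned` dataset from [align_met()] (or the `$data`
#'   element of [simulate_met()]).
#' @param penalty `"elnet"` (default, mixing `alpha = 0.5`), `"ridge"` or
#'   `"lasso"`.
#' @param alpha Optional explicit elastic-net mixing, overriding `penalty`.
#' @param lambda `"auto"` for the automatic grid ([lambda_grid()]), or a
#'   numeric vector (a single value skips cross-validation).
#' @param nlambda,lambda_min_ratio Automatic grid shape.
#' @param cv `"random"` (10-fold over G-by-E observations, the common default)
#'   or `"stratified"` (folds are whole environments).
#' @param nfolds Number of folds.
#' @param select `"min"` for the CV-error-minimizing lambda (the default
#'   reported as `lambda_cv.min`) or `"1se"` for the one-standard-error rule.
#' @param standardize Standardize ECs to training mean 0, sd 1 (default
#'   `TRUE`; makes one lambda comparable across ECs of different units).
#' @param genotype_weights Optional named positive per-genotype penalty
#'   multipliers (see [tune_genotype_weights()]).
#' @param seed Integer seed controlling fold assignment only.
#' @return An object of class `gxe_fit`: general mean `mu`; named main-effect
#'   vectors `g` and `e` (reference levels fixed at 0); sensitivity matrix `B`
#'   (`n_g x n_c`, on the ORIGINAL EC scale) and `B_std` (standardized scale);
#'   the full coefficient vector and column metadata; penalty settings,
#'   `lambda_selected`, `sigma2_hat`, the CV trace and the EC standardization
#'   statistics needed for prediction.
#' @examples
#' sim <- simulate_met(n_g = 15, n_e_train = 25, n_e_test = 5, n_c = 4,
#'                     n_active = 2, seed = 1)
#' fit <- fit_gxenet(sim$data, penalty = "ridge", nlambda = 30, seed = 1)
#' glance(fit)
#' @export
fit_gxenet <- function(data, penalty = c("elnet", "ridge", "lasso"),
                       alpha = NULL, lambda = "auto", nlambda = 100,
                       lambda_min_ratio = 1e-4,
                       cv = c("random", "stratified"), nfolds = 10,
                       select = c("min", "1se"), standardize = TRUE,
                       genotype_weights = NULL, seed = 1) {
  penalty <- match.arg(penalty)
  cv <- match.arg(cv)
  select <- match.arg(select)
  if (is.null(alpha)) {
    alpha <- switch(penalty, ridge = 0, lasso = 1, elnet = 0.5)
  } else {
    stopifnot(alpha >= 0, alpha <= 1)
    penalty <- if (alpha == 0) "ridge" else if (alpha == 1) "lasso" else "elnet"
  }
  design <- build_design(data, standardize = standardize,
                         genotype_weights = genotype_weights)
  if (identical(lambda, "auto")) {
    grid <- lambda_grid(design, alpha = alpha, nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio)
  } else {
    grid <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  if (length(grid) > 1) {
    folds <- make_folds(data, k = nfolds, mode = cv, seed = seed)
    sel <- cv_select_lambda(design, alpha = alpha, lambda = grid,
                            folds = folds)
    lambda_selected <- if (select == "min") sel$lambda_min else sel$lambda_1se
    cv_trace <- sel$cv_trace
  } else {
    lambda_selected <- grid[1]
    cv_trace <- tibble(lambda = grid, mse_mean = NA_real_, mse_se = NA_real_)
  }
  # refit on all training rows, warm-started from the top of the grid
  path_grid <- grid[grid >= lambda_selected]
  theta_path <- elnet_path(design, alpha = alpha, lambda = path_grid)
  theta <- theta_path[, ncol(theta_path)]
  fit <- assemble_fit(theta, design, alpha = alpha, penalty = penalty,
                      lambda_grid = as.numeric(grid),
                      lambda_selected = lambda_selected, cv_trace = cv_trace,
                      cv_mode = cv, nfolds = nfolds, seed = seed)
  fit
}

# Build a gxe_fit object from a full coefficient vector on a design.
assemble_fit <- function(theta, design, alpha, penalty, lambda_grid,
                         lambda_selected, cv_trace = NULL, cv_mode = NA,
                         nfolds = NA, seed = NA) {
  cols <- design$columns
  mu <- theta[cols$role == "intercept"]
  g <- setNames(numeric(design$n_g), design$genotypes)
  g[cols$genotype[cols$role == "geno_main"]] <- theta[cols$role == "geno_main"]
  e <- setNames(numeric(design$n_e), design$environments)
  e[cols$env[cols$role == "env_main"]] <- theta[cols$role == "env_main"]
  # sensitivity block is genotype-major, ec-minor
  B_std <- matrix(theta[cols$role == "sensitivity"], nrow = design$n_g,
                  ncol = design$n_c, byrow = TRUE,
                  dimnames = list(design$genotypes, design$ec_names))
  if (design$standardize) {
    B <- sweep(B_std, 2, design$ec_stats$sd, "/")
  } else {
    B <- B_std
  }
  fitted <- as.numeric(design$X %*% theta)
  rss <- sum((design$y - fitted)^2)
  df <- sum(theta != 0)
  n <- length(design$y)
  sigma2_hat <- rss / max(n - df, 1)
  structure(list(
    mu = unname(mu), g = g, e = e, B = B, B_std = B_std,
    coefficients = theta, columns = cols,
    penalty = list(kind = penalty, alpha = alpha, lambda_grid = lambda_grid),
    lambda_selected = unname(lambda_selected), sigma2_hat = sigma2_hat,
    cv_trace = cv_trace,
    cv = list(mode = cv_mode, nfolds = nfolds, seed = seed),
    ec_stats = design$ec_stats, standardize = design$standardize,
    ec_mode = design$ec_mode,
    genotypes = design$genotypes, environments = design$environments,
    ec_names = design$ec_names,
    n_obs = n, df = df,
    fitted = tibble(genotype = design$row_keys$genotype,
                    env = design$row_keys$env,
                    y_obs = design$y, y_fit = fitted)
  ), class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("<gxe_fit> penalized factorial regression (", x$penalty$kind,
      ", alpha = ", x$penalty$alpha, ")\n", sep = "")
  cat("  ", length(x$genotypes), " genotypes x ", length(x$environments),
      " training environments, ", length(x$ec_names), " ECs, N = ",
      x$n_obs, "\n", sep = "")
  cat("  lambda selected: ", signif(x$lambda_selected, 4),
      "  nonzero coefficients: ", x$df,
      "  sigma^2: ", signif(x$sigma2_hat, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.gxe_fit <- function(object, ...) object$coefficients

#' Second cross-validation loop for genotype-specific penalties
#'
#' Optionally, the penalty on the sensitivities can be genotype-specific
#' rather than uniform. Because the sensitivity columns of different genotypes
#' occupy disjoint rows of the design (coupling only through the shared main
#' effects), the cross-validated error of genotype i under a penalty
#' multiplier is read off from a fit in which all genotypes share that
#' multiplier; each genotype then gets the multiplier minimizing its own
#' held-out error, and the model is refit once with the selected weights. Most
#' useful when the number of training environments per genotype is large;
#' with few observations per genotype it can hurt accuracy.
#'
#' @inheritParams fit_gxenet
#' @param multipliers Candidate penalty multipliers (grid shared by all
#'   genotypes).
#' @return A `gxe_fit` fitted with the selected per-genotype weights (stored
#'   in its column metadata), with the chosen multipliers attached as
#'   attribute `genotype_weights`.
#' @export
tune_genotype_weights <- function(data, penalty = c("elnet", "ridge", "lasso"),
                                  alpha = NULL,
                                  multipliers = c(0.25, 0.5, 1, 2, 4),
                                  lambda = "auto", nlambda = 50,
                                  cv = c("random", "stratified"), nfolds = 10,
                                  standardize = TRUE, seed = 1) {
  penalty <- match.arg(penalty)
  cv <- match.arg(cv)
  if (is.null(alpha)) alpha <- switch(penalty, ridge = 0, lasso = 1, elnet = 0.5)
  design <- build_design(data, standardize = standardize)
  grid <- if (identical(lambda, "auto")) {
    lambda_grid(design, alpha = alpha, nlambda = nlambda)
  } else sort(as.numeric(lambda), decreasing = TRUE)
  folds <- make_folds(data, k = nfolds, mode = cv, seed = seed)
  rows_geno <- design$row_keys$genotype

  per_geno_err <- matrix(NA_real_, length(design$genotypes),
                         length(multipliers),
                         dimnames = list(design$genotypes, NULL))
  for (m in seq_along(multipliers)) {
    w <- setNames(rep(multipliers[m], design$n_g), design$genotypes)
    dm <- build_design(data, standardize = standardize, genotype_weights = w)
    sel <- cv_select_lambda(dm, alpha = alpha, lambda = grid, folds = folds)
    # per-genotype held-out error at that multiplier's lambda_cv.min
    sse <- setNames(numeric(design$n_g), design$genotypes)
    cnt <- setNames(numeric(design$n_g), design$genotypes)
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      sub <- list(X = dm$X[tr, , drop = FALSE], y = dm$y[tr],
                  columns = dm$columns)
      theta <- elnet_path(sub, alpha = alpha,
                          lambda = grid[grid >= sel$lambda_min])
      pred <- as.numeric(dm$X[!tr, , drop = FALSE] %*%
                           theta[, ncol(theta)])
      err <- (dm$y[!tr] - pred)^2
      gh <- rows_geno[!tr]
      agg <- tapply(err, gh, sum)
      sse[names(agg)] <- sse[names(agg)] + agg
      cnt[names(agg)] <- cnt[names(agg)] + tabulate(factor(gh, names(cnt)),
                                                    length(cnt))
    }
    per_geno_err[, m] <- sse / pmax(cnt, 1)
  }
  best <- multipliers[apply(per_geno_err, 1, which.min)]
  w_best <- setNames(best, design$genotypes)
  fit <- fit_gxenet(data, alpha = alpha, lambda = grid, cv = cv,
                    nfolds = nfolds, standardize = standardize,
                    genotype_weights = w_best, seed = seed)
  attr(fit, "genotype_weights") <- w_best
  fit
}
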