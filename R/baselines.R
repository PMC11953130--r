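#' Additive main-effects baseline
#'
#' Least-squares fit of `Y_ij = mu + g_i + e_j + eps_ij` — the factorial
#' regression model stripped of all EC terms. This is the large-penalty limit
#' of the penalized fit (all sensitivities shrunk to zero) and the reference
#' any G-by-E model has to beat. For balanced data the estimates reduce to
#' row/column mean contrasts against the reference levels.
#'
#' @param data A `met_aligned` dataset.
#' @return Object of class `c("gxe_additive", "gxe_fit")`: same shape as a
#'   [fit_gxenet()] result with `B` identically zero, so it predicts and
#'   evaluates through the same methods.
#' @export
fit_additive <- function(data) {
  design <- build_design(data, standardize = FALSE)
  main <- design$columns$role != "sensitivity"
  Xm <- design$X[, main, drop = FALSE]
  theta_m <- ls_solve(Xm, design$y)
  theta <- numeric(nrow(design$columns))
  theta[main] <- theta_m
  fit <- assemble_fit(theta, design, alpha = NA_real_, penalty = "additive",
                      lambda_grid = numeric(0), lambda_selected = Inf)
  fit$sigma2_hat <- {
    rss <- sum((design$y - as.numeric(Xm %*% theta_m))^2)
    rss / max(length(design$y) - sum(main), 1)
  }
  class(fit) <- c("gxe_additive", class(fit))
  fit
}

#' Unpenalized ("Full") factorial regression
#'
#' The factorial regression model fit by ordinary least squares (penalty
#' `lambda = 0`). Requires a full-rank design — in practice the number of
#' training environments must comfortably exceed the number of ECs, since
#' each genotype spends `n_c + 1` degrees of freedom. With many ECs this
#' model badly overfits: training accuracy rises but accuracy in new
#' environments collapses, which is precisely what penalization repairs.
#'
#' @param data A `met_aligned` dataset.
#' @param standardize Standardize ECs (irrelevant for the fitted values, kept
#'   for comparability of coefficients; default `TRUE`).
#' @return A `gxe_fit` with `lambda_selected = 0`.
#' @export
fit_full <- function(data, standardize = TRUE) {
  design <- build_design(data, standardize = standardize)
  theta <- tryCatch(ls_solve(design$X, design$y),
                    error = function(e) {
                      abort(paste0(conditionMessage(e),
                                   " (the unpenalized factorial regression ",
                                   "needs n_e well above n_c; consider a ",
                                   "penalized fit)"),
                            class = "gxenet_rank_error")
                    })
  assemble_fit(theta, design, alpha = NA_real_, penalty = "full",
               lambda_grid = 0, lambda_selected = 0)
}
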