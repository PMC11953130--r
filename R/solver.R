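#' Solve the selectively penalized least-squares path
#'
#' Minimizes, for each value of `lambda` on a decreasing grid,
#' \deqn{\frac{1}{2N}\sum_r (y_r - x_r'\theta)^2 +
#'       \lambda \sum_k w_k\,(\alpha|\theta_k| + \tfrac{1-\alpha}{2}\theta_k^2)}
#' where `w_k` is the design's penalty factor (0 for the intercept and the
#' main effects, positive for the sensitivity slopes). Three exact routes are
#' used: `lambda = 0` is an unpenalized sparse-QR least-squares solve; ridge
#' (`alpha = 0`) profiles out the unpenalized columns and solves the whole
#' path through one eigendecomposition of the projected penalized Gram matrix;
#' `alpha > 0` runs warm-started coordinate descent in compiled code.
#'
#' @param design A `gxe_design` (or any list with `X`, `y`,
#'   `columns$penalty_factor`).
#' @param alpha Elastic-net mixing in `[0, 1]`: 0 ridge, 1 lasso, 0.5 default
#'   elastic net.
#' @param lambda Decreasing vector of penalty strengths.
#+
#'   change per sweep.
#' @param max_passes Coordinate-descent pass budget per lambda.
#' @return A `p x length(lambda)` coefficient matrix (rows named by design
#'   columns, columns by lambda).
#' @export
elnet_path <- function(design, alpha = 0.5, lambda, tol = 1e-4,
                       max_passes = 1e5) {
  stopifnot(alpha >= 0, alpha <= 1, all(lambda >= 0))
  lambda <- as.numeric(lambda)
  if (is.unsorted(rev(lambda), strictly = FALSE)) {
    abort("lambda grid must be decreasing", class = "gxenet_solver_error")
  }
  X <- design$X
  y <- design$y
  pf <- design$columns$penalty_factor
  if (all(pf == 0)) abort("at least one penalized column required",
                          class = "gxenet_solver_error")
  out <- matrix(0, ncol(X), length(lambda),
                dimnames = list(colnames(X), signif(lambda, 6)))

  pos <- lambda > 0
  if (any(pos)) {
    if (alpha == 0) {
      out[, pos] <- ridge_path_exact(X, y, pf, lambda[pos])
    } else {
      # start from the main-effects-only least-squares fit: at and above
      # lambda_max this is already the exact solution (all slopes zero)
      cd <- cd_elnet_path(X, y, pf, alpha, lambda[pos], tol,
                          as.integer(max_passes),
                          main_effects_start(X, y, pf))
      if (!all(cd$converged)) {
        bad <- which(!cd$converged)[1]
        theta <- cd$coef[, bad]
        kkt <- kkt_violation(X, y, pf, alpha, lambda[pos][bad], theta)
        abort(sprintf(
          "coordinate descent did not converge at lambda = %.4g (KKT residual %.3g) after %d passes",
          lambda[pos][bad], kkt, max_passes),
          class = "gxenet_solver_error")
      }
      out[, pos] <- cd$coef
    }
  }
  if (any(!pos)) out[, !pos] <- ls_solve(X, y)
  out
}

# Unpenalized least squares via sparse QR; errors on rank deficiency.
ls_solve <- function(X, y) {
  qr_x <- Matrix::qr(X)
  if (methods::is(qr_x, "sparseQR")) {
    d_r <- abs(Matrix::diag(qr_x@R))
    if (!all(is.finite(d_r)) || min(d_r) < max(d_r) * 1e-10) {
      abort(paste0("design is rank deficient at lambda = 0; ",
                   "use a positive penalty (lambda > 0)"),
            class = "gxenet_rank_error")
    }
  }
  theta <- tryCatch(Matrix::qr.coef(qr_x, y),
                    error = function(e) rep(NA_real_, ncol(X)))
  theta <- as.numeric(theta)
  if (anyNA(theta) || any(!is.finite(theta))) {
    abort(paste0("design is rank deficient at lambda = 0; ",
                 "use a positive penalty (lambda > 0)"),
          class = "gxenet_rank_error")
  }
  theta
}

# Exact ridge path with penalty factors. Unpenalized columns U are profiled
# out through their QR; the penalized block (scaled to unit penalty factors)
# is projected onto the orthogonal complement of U and its Gram matrix
# eigendecomposed once, after which every lambda costs one backsolve.
ridge_path_exact <- function(X, y, pf, lambda) {
  N <- nrow(X)
  unpen <- which(pf == 0)
  pen <- which(pf > 0)
  U <- as.matrix(X[, unpen, drop = FALSE])
  keep <- colSums(abs(U)) > 0         # fold subsets can zero out dummies
  qr_u <- qr(U[, keep, drop = FALSE])
  if (qr_u$rank < sum(keep)) {
    abort("unpenalized main-effect block is rank deficient (disconnected data?)",
          class = "gxenet_rank_error")
  }
  Q <- qr.Q(qr_u)
  Ps <- X[, pen, drop = FALSE] %*% Matrix::Diagonal(x = 1 / sqrt(pf[pen]))
  QtP <- as.matrix(Matrix::crossprod(Q, Ps))
  A <- as.matrix(Matrix::crossprod(Ps)) - crossprod(QtP)
  rhs <- as.numeric(Matrix::crossprod(Ps, y)) -
    drop(crossprod(QtP, crossprod(Q, y)))
  eig <- eigen(A, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  w <- drop(crossprod(eig$vectors, rhs))

  out <- matrix(0, ncol(X), length(lambda))
  for (l in seq_along(lambda)) {
    b <- drop(eig$vectors %*% (w / (d + N * lambda[l])))
    beta <- b / sqrt(pf[pen])
    resid_u <- y - as.numeric(X[, pen, drop = FALSE] %*% beta)
    delta <- qr.coef(qr_u, resid_u)
    full_u <- numeric(length(unpen))
    full_u[keep] <- delta
    out[unpen, l] <- full_u
    out[pen, l] <- beta
  }
  out
}

#' Automatic lambda grid for a design
#'
#' `lambda_max` is the smallest penalty at which every sensitivity slope is
#' exactly zero: after profiling out the unpenalized main effects (residual
#' `r0` of their least-squares fit), `lambda_max = max_k |x_k' r0| / (N alpha
#' w_k)` over penalized columns. The grid is `nlambda` log-spaced values from
#' `lambda_max` down to `lambda_max * lambda_min_ratio`. Ridge has no finite
#' all-zero point, so its grid is anchored at the lasso-equivalent
#' `lambda_max * 1e3`.
#'
#' @inheritParams elnet_path
#' @param nlambda Grid length (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest grid value.
#' @return Decreasing numeric vector with attribute `lambda_max` (the
#'   all-zero point for `alpha > 0`).
#' @export
lambda_grid <- function(design, alpha = 0.5, nlambda = 100,
                        lambda_min_ratio = 1e-4) {
  lmax1 <- lambda_zero_point(design, 1)
  # a hair above the exact threshold so the all-zero endpoint survives
  # floating-point roundoff
  anchor <- (1 + 1e-8) * if (alpha > 0) lmax1 / alpha else lmax1 * 1e3
  grid <- exp(seq(log(anchor), log(anchor * lambda_min_ratio),
                  length.out = nlambda))
  attr(grid, "lambda_max") <- if (alpha > 0) anchor else Inf
  grid
}

# least-squares fit of the unpenalized (main-effect) columns, zeros elsewhere
main_effects_start <- function(X, y, pf) {
  unpen <- which(pf == 0)
  U <- as.matrix(X[, unpen, drop = FALSE])
  keep <- colSums(abs(U)) > 0
  qr_u <- qr(U[, keep, drop = FALSE])
  theta <- numeric(ncol(X))
  if (qr_u$rank == sum(keep)) {
    theta[unpen[keep]] <- qr.coef(qr_u, y)
  }
  theta
}

# max_k |x_k' r0| / (N * alpha * pf_k) over penalized columns
lambda_zero_point <- function(design, alpha) {
  X <- design$X
  y <- design$y
  pf <- design$columns$penalty_factor
  unpen <- which(pf == 0)
  U <- as.matrix(X[, unpen, drop = FALSE])
  keep <- colSums(abs(U)) > 0
  qr_u <- qr(U[, keep, drop = FALSE])
  r0 <- qr.resid(qr_u, y)
  pen <- which(pf > 0)
  scores <- abs(as.numeric(Matrix::crossprod(X[, pen, drop = FALSE], r0))) /
    (nrow(X) * alpha * pf[pen])
  max(scores)
}

#' Karush-Kuhn-Tucker residual of a candidate solution
#'
#' Returns the largest violation of the stationarity conditions of the
#' penalized objective: unpenalized coordinates must have zero gradient;
#' penalized nonzero coordinates must satisfy the subgradient equation; zero
#' coordinates must have gradient within the L1 threshold.
#'
#' @param X,y Design matrix and response.
#' @param pf Penalty factors.
#' @param alpha,lambda Penalty parameters.
#' @param theta Candidate coefficient vector.
#' @return Scalar maximal violation (0 at an exact solution).
#' @export
kkt_violation <- function(X, y, pf, alpha, lambda, theta) {
  N <- nrow(X)
  grad <- as.numeric(Matrix::crossprod(X, as.numeric(X %*% theta) - y)) / N
  v <- numeric(length(theta))
  for (k in seq_along(theta)) {
    if (pf[k] == 0) {
      v[k] <- abs(grad[k])
    } else if (theta[k] != 0) {
      v[k] <- abs(grad[k] + lambda * pf[k] *
                    (alpha * sign(theta[k]) + (1 - alpha) * theta[k]))
    } else {
      v[k] <- max(0, abs(grad[k]) - lambda * pf[k] * alpha)
    }
  }
  max(v)
}
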