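#' Second-stage marker ridge for new-genotype prediction (GnEn)
#'
#' Regresses the first-stage genotypic parameters — the estimated main effect
#' \eqn{\hat g_i} and each column of the sensitivity matrix — on centred
#' marker dosages with an independent univariate ridge per response. The
#' resulting marker model predicts reaction-norm parameters for genotypes
#' never phenotyped, turning the observed-genotype model into a genomic
#' prediction model for new genotypes in new environments.
#'
#' The ridge strength per response is selected by generalized cross-validation
#' (GCV) on a log grid by default, reusing a single SVD of the centred marker
#' matrix; pass a positive number to fix it.
#'
#' @param fit A `gxe_fit` (penalized or unpenalized).
#' @param markers Genotype-by-marker dosage matrix ([met_markers()]) covering
#'   all fitted genotypes.
#' @param shrinkage `"gcv"` (default) or a positive ridge penalty applied to
#'   every response.
#' @return Object of class `gxe_stage2`: marker coefficient matrix
#'   (`n_markers x (1 + n_c)`, responses `g` then one per EC on the
#'   standardized-EC scale), per-response intercepts and shrinkage, marker
#'   centring means, and the first-stage metadata needed for prediction.
#' @export
stage2_marker_ridge <- function(fit, markers, shrinkage = "gcv") {
  stopifnot(inherits(fit, "gxe_fit"))
  missing_g <- setdiff(fit$genotypes, rownames(markers))
  if (length(missing_g) > 0) {
    abort(paste0("genotype(s) without marker rows: ",
                 paste(missing_g, collapse = ", ")),
          class = "gxenet_validation_error")
  }
  M <- markers[fit$genotypes, , drop = FALSE]
  Y <- cbind(g = fit$g, fit$B_std)
  colnames(Y) <- c("g", fit$ec_names)
  n <- nrow(M)
  mm <- colMeans(M)
  Mc <- sweep(M, 2, mm, "-")
  sv <- svd(Mc)
  pos <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  UtY <- crossprod(U, Yc)

  if (identical(shrinkage, "gcv")) {
    k_grid <- exp(seq(log(max(d)^2 * 1e2), log(max(d)^2 * 1e-8),
                      length.out = 60))
    k_sel <- vapply(seq_len(ncol(Y)), function(j) {
      gcv <- vapply(k_grid, function(k) {
        shr <- d^2 / (d^2 + k)
        res <- Yc[, j] - U %*% (shr * UtY[, j])
        eff_df <- sum(shr) + 1
        if (n - eff_df < 1e-8) return(Inf)
        n * sum(res^2) / (n - eff_df)^2
      }, numeric(1))
      k_grid[which.min(gcv)]
    }, numeric(1))
  } else {
    stopifnot(is.numeric(shrinkage), shrinkage > 0)
    k_sel <- rep(shrinkage, ncol(Y))
  }
  coefs <- vapply(seq_len(ncol(Y)), function(j) {
    drop(V %*% ((d / (d^2 + k_sel[j])) * UtY[, j]))
  }, numeric(ncol(M)))
  dimnames(coefs) <- list(colnames(M), colnames(Y))
  structure(list(coefficients = coefs,
                 intercepts = setNames(colMeans(Y), colnames(Y)),
                 shrinkage = setNames(k_sel, colnames(Y)),
                 marker_means = mm,
                 mu = fit$mu, ec_stats = fit$ec_stats,
                 standardize = fit$standardize, ec_names = fit$ec_names,
                 columns = fit$columns, genotypes = fit$genotypes),
            class = "gxe_stage2")
}

#' @export
print.gxe_stage2 <- function(x, ...) {
  cat("<gxe_stage2> marker ridge: ", nrow(x$coefficients), " markers -> ",
      ncol(x$coefficients), " responses (g + ", length(x$ec_names),
      " sensitivities)\n", sep = "")
  invisible(x)
}

#' Predict genotypic parameters for new genotypes from markers
#'
#' @param stage2 A `gxe_stage2` model.
#' @param markers_new Marker matrix for the new genotypes (same columns).
#' @return List with named vector `g` and matrix `B_std` for the new
#'   genotypes.
#' @export
predict_parameters <- function(stage2, markers_new) {
  miss <- setdiff(rownames(stage2$coefficients), colnames(markers_new))
  if (length(miss) > 0) {
    abort(paste0("new marker matrix lacks ", length(miss), " marker(s), e.g. ",
                 miss[1]),
          class = "gxenet_validation_error")
  }
  M <- markers_new[, rownames(stage2$coefficients), drop = FALSE]
  Mc <- sweep(M, 2, stage2$marker_means, "-")
  P <- sweep(Mc %*% stage2$coefficients, 2, stage2$intercepts, "+")
  list(g = setNames(P[, "g"], rownames(M)),
       B_std = P[, -1, drop = FALSE])
}

#' Predict new genotypes in new environments (GnEn)
#'
#' Feeds marker-predicted genotypic intercepts and sensitivity slopes through
#' the environment-centred prediction arithmetic. Only environment-level ECs
#' are supported: genotype-specific ECs depend on each genotype's phenology,
#' which is unobservable for genotypes never grown.
#'
#' @param stage2 A `gxe_stage2` model.
#' @param markers_new Marker matrix for the new genotypes.
#' @param ecs An environment-level `met_ecs` table with training
#'   standardization statistics.
#' @param envs Environment ids to predict.
#' @return A `gxe_predictions` tibble.
#' @export
predict_gnen <- function(stage2, markers_new, ecs, envs) {
  if (attr(ecs, "mode") != "env_level") {
    abort(paste0("GnEn prediction needs environment-level ECs; ",
                 "genotype-specific ECs are undefined for untested genotypes"),
          class = "gxenet_unsupported_error")
  }
  par <- predict_parameters(stage2, markers_new)
  keys <- tidyr::expand_grid(env = as.character(envs),
                             genotype = rownames(markers_new))
  keys <- keys[c("genotype", "env")]
  V <- ec_matrix(ecs, keys, stage2$standardize)
  gi <- match(keys$genotype, rownames(markers_new))
  y_hat <- stage2$mu + par$g[gi] +
    rowSums(V * par$B_std[gi, , drop = FALSE])
  out <- dplyr::mutate(keys, y_hat = unname(y_hat))
  structure(out, centred = TRUE,
            class = c("gxe_predictions", class(out)))
}
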