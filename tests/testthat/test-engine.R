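test_that("the lambda = 0 path equals the normal-equations least-squares oracle", {
  sim <- simulate_met(n_g = 8, n_e_train = 20, n_e_test = 0, n_c = 3,
                      n_active = 2, seed = 5)
  des <- build_design(sim$data)
  theta <- elnet_path(des, alpha = 0.5, lambda = 0)[, 1]
  Xd <- as.matrix(des$X)
  oracle <- drop(solve(crossprod(Xd), crossprod(Xd, des$y)))
  expect_lt(max(abs(theta - oracle)), 1e-6)
})

test_that("at lambda >= lambda_max the fit is exactly the additive model", {
  sim <- simulate_met(n_g = 7, n_e_train = 18, n_e_test = 0, n_c = 4,
                      n_active = 2, seed = 6)
  des <- build_design(sim$data)
  add <- fit_additive(sim$data)
  sens <- des$columns$role == "sensitivity"
  for (alpha in c(1, 0.5)) {
    lmax <- attr(lambda_grid(des, alpha = alpha, nlambda = 3), "lambda_max")
    for (lam in c(lmax, 3 * lmax)) {
      theta <- elnet_path(des, alpha = alpha, lambda = lam)[, 1]
      expect_identical(unname(theta[sens]), rep(0, sum(sens)))
      expect_lt(max(abs(theta[!sens] - add$coefficients[!sens])), 1e-6)
    }
  }
})

test_that("rescaling an EC leaves the standardized fit unchanged", {
  sim <- simulate_met(n_g = 6, n_e_train = 14, n_e_test = 3, n_c = 3,
                      n_active = 2, seed = 9)
  f1 <- fit_gxenet(sim$data, penalty = "elnet", lambda = 0.02, seed = 1)
  scaled <- sim$data
  ec_df <- as.data.frame(scaled$ecs)
  ec2 <- attr(scaled$ecs, "ec_names")[2]
  ec_df[[ec2]] <- ec_df[[ec2]] * 10
  ecs2 <- met_ecs(ec_df, mode = attr(scaled$ecs, "mode"))
  d2 <- align_met(scaled$pheno, ecs2,
                  test_envs = scaled$split$env[scaled$split$role == "test"])
  f2 <- fit_gxenet(d2, penalty = "elnet", lambda = 0.02, seed = 1)
  expect_equal(f2$fitted$y_fit, f1$fitted$y_fit, tolerance = 1e-6)
  expect_equal(f2$B_std, f1$B_std, tolerance = 1e-6)
  # original-scale slopes for the rescaled EC shrink by the scale factor
  expect_equal(f2$B[, ec2] * 10, f1$B[, ec2], tolerance = 1e-6)
  p1 <- predict(f1, sim$data)
  p2 <- predict(f2, d2)
  expect_equal(p2$y_hat, p1$y_hat, tolerance = 1e-6)
})

test_that("the selective path agrees with glmnet on a unit-variance response", {
  skip_if_not_installed("glmnet")
  sim <- simulate_met(n_g = 8, n_e_train = 20, n_e_test = 0, n_c = 3,
                      n_active = 2, seed = 5)
  des <- build_design(sim$data)
  sy <- sqrt(mean((des$y - mean(des$y))^2))
  des$y <- des$y / sy  # glmnet internally rescales y to unit 1/n variance
  pf2 <- des$columns$penalty_factor[-1]
  X2 <- des$X[, -1]
  for (alpha in c(1, 0.5)) {
    grid <- lambda_grid(des, alpha = alpha, nlambda = 25)
    mine <- elnet_path(des, alpha = alpha, lambda = grid, tol = 1e-6)
    gl <- glmnet::glmnet(X2, des$y, alpha = alpha, penalty.factor = pf2,
                         standardize = FALSE,
                         lambda = grid * sum(pf2) / ncol(X2),
                         thresh = 1e-14, maxit = 1e6)
    expect_lt(max(abs(as.matrix(coef(gl)) - mine)), 2e-4)
  }
})

test_that("returned solutions satisfy the KKT conditions", {
  sim <- simulate_met(n_g = 6, n_e_train = 15, n_e_test = 0, n_c = 4,
                      n_active = 2, seed = 8)
  des <- build_design(sim$data)
  pf <- des$columns$penalty_factor
  for (alpha in c(0, 0.5, 1)) {
    grid <- lambda_grid(des, alpha = alpha, nlambda = 12)
    P <- elnet_path(des, alpha = alpha, lambda = grid, tol = 1e-7)
    for (l in seq_along(grid)) {
      expect_lt(kkt_violation(des$X, des$y, pf, alpha, grid[l], P[, l]), 1e-5)
    }
  }
})

test_that("ridge slope norms shrink and training error grows with lambda", {
  sim <- simulate_met(n_g = 8, n_e_train = 16, n_e_test = 0, n_c = 3,
                      n_active = 2, seed = 12)
  des <- build_design(sim$data)
  grid <- lambda_grid(des, alpha = 0, nlambda = 20)
  P <- elnet_path(des, alpha = 0, lambda = grid)
  sens <- des$columns$role == "sensitivity"
  norms <- sqrt(colSums(P[sens, ]^2))
  mse <- colMeans((des$y - as.matrix(des$X %*% P))^2)
  # grid is decreasing, so norms increase and training error decreases along it
  expect_true(all(diff(norms) > 0))
  expect_true(all(diff(mse) <= 1e-12))
})

test_that("fold assignment honours both schemes and the seed contract", {
  envs <- sprintf("e%02d", 1:25)
  p <- grid_pheno(sprintf("g%d", 1:4), envs, withr::with_seed(2, rnorm(100)))
  d <- align_met(p, grid_ecs(envs, 2))

  fs <- make_folds(d, k = 5, mode = "stratified", seed = 3)
  env_folds <- tapply(fs, d$pheno$env, function(x) length(unique(x)))
  expect_true(all(env_folds == 1))
  fold_env_counts <- table(tapply(fs, d$pheno$env, unique))
  expect_equal(unname(sort(as.integer(fold_env_counts))), rep(5L, 5))

  fr <- make_folds(d, k = nrow(p), mode = "random", seed = 3)
  expect_equal(sort(unique(table(fr))), 1L)  # leave-one-out

  expect_identical(make_folds(d, 10, "random", seed = 11),
                   make_folds(d, 10, "random", seed = 11))
  expect_false(identical(make_folds(d, 10, "random", seed = 11),
                         make_folds(d, 10, "random", seed = 12)))
  expect_error(make_folds(d, k = 26, mode = "stratified", seed = 1),
               class = "gxenet_cv_error")
  expect_error(make_folds(d, k = 1, mode = "random", seed = 1),
               class = "gxenet_cv_error")
})

test_that("cross-validation selection respects limits and degenerate grids", {
  sim <- simulate_met(n_g = 6, n_e_train = 12, n_e_test = 0, n_c = 2,
                      n_active = 1, seed = 4)
  des <- build_design(sim$data)
  folds <- make_folds(sim$data, k = 4, mode = "random", seed = 1)

  one <- cv_select_lambda(des, alpha = 0.5, lambda = 0.37, folds = folds)
  expect_equal(one$lambda_min, 0.37)

  # far beyond lambda_max every lambda gives the additive fit: CV error is the
  # additive model's CV error and the flat-trace warning fires
  lmax <- attr(lambda_grid(des, alpha = 1, nlambda = 3), "lambda_max")
  big <- c(100, 10, 2) * lmax
  expect_warning(
    sel <- cv_select_lambda(des, alpha = 1, lambda = big, folds = folds),
    regexp = "flat")
  add_mse <- vapply(1:4, function(f) {
    tr <- folds != f
    sub <- list(X = des$X[tr, , drop = FALSE], y = des$y[tr],
                columns = des$columns)
    main <- des$columns$role != "sensitivity"
    th <- numeric(ncol(des$X))
    th[main] <- qr.coef(qr(as.matrix(sub$X[, main])), sub$y)
    mean((des$y[!tr] - as.numeric(des$X[!tr, ] %*% th))^2)
  }, numeric(1))
  expect_equal(sel$cv_trace$mse_mean, rep(mean(add_mse), 3), tolerance = 1e-8)
})

test_that("the end-to-end fit is deterministic and uses alpha 0.5 for elnet", {
  sim <- simulate_met(n_g = 6, n_e_train = 12, n_e_test = 3, n_c = 2,
                      n_active = 1, seed = 10)
  f1 <- fit_gxenet(sim$data, penalty = "elnet", nlambda = 12, seed = 7)
  f2 <- fit_gxenet(sim$data, penalty = "elnet", nlambda = 12, seed = 7)
  expect_equal(f1$penalty$alpha, 0.5)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda_selected, f2$lambda_selected)
})

test_that("noise-free data with many environments recovers the true slopes", {
  sim <- simulate_met(n_g = 10, n_e_train = 60, n_e_test = 0, n_c = 4,
                      n_active = 3, h2 = 1, seed = 13)
  fit <- fit_gxenet(sim$data, penalty = "ridge", lambda = 1e-8, seed = 1)
  expect_lt(sqrt(mean((fit$B - sim$truth$B)^2)), 1e-3)
  # with centred ECs the genotype effect absorbs sum_t mean_t * B_it
  gg <- sim$truth$g + drop(sim$truth$B %*% fit$ec_stats$mean)
  expect_equal(fit$g, gg - gg[1], tolerance = 1e-4)
})

test_that("relabelling genotypes permutes the estimates equivariantly", {
  sim <- simulate_met(n_g = 5, n_e_train = 12, n_e_test = 0, n_c = 2,
                      n_active = 1, seed = 14)
  fit <- fit_gxenet(sim$data, penalty = "ridge", lambda = 0.05, seed = 1)
  relabel <- setNames(sprintf("z%02d", 1:5), attr(sim$data$pheno, "genotypes"))
  df <- as.data.frame(sim$data$pheno)
  df$genotype <- unname(relabel[df$genotype])
  pheno2 <- met_phenotypes(data.frame(genotype = df$genotype, env = df$env,
                                      value = df$y))
  ec_df <- as.data.frame(sim$data$ecs)
  ec_df$genotype <- unname(relabel[ec_df$genotype])
  ecs2 <- met_ecs(ec_df, mode = "genotype_specific")
  fit2 <- fit_gxenet(align_met(pheno2, ecs2), penalty = "ridge",
                     lambda = 0.05, seed = 1)
  expect_equal(unname(fit2$g[relabel]), unname(fit$g), tolerance = 1e-10)
  expect_equal(unname(fit2$B[relabel, ]), unname(fit$B), tolerance = 1e-10)
  expect_equal(fit2$mu, fit$mu, tolerance = 1e-10)
})

test_that("genotype-specific penalty weights enter the penalty factors", {
  sim <- simulate_met(n_g = 4, n_e_train = 10, n_e_test = 0, n_c = 2,
                      n_active = 1, seed = 15)
  w <- setNames(c(1, 2, 0.5, 1), attr(sim$data$pheno, "genotypes"))
  des <- build_design(sim$data, genotype_weights = w)
  sens <- des$columns$role == "sensitivity"
  expect_equal(as.numeric(tapply(des$columns$penalty_factor[sens],
                                 des$columns$genotype[sens],
                                 unique)[names(w)]),
               as.numeric(w))
  expect_error(build_design(sim$data, genotype_weights = c(bad = -1)),
               class = "gxenet_design_error")
  # heavier penalty multiplier shrinks that genotype's slopes more
  f1 <- fit_gxenet(sim$data, penalty = "ridge", lambda = 0.05, seed = 1)
  f2 <- fit_gxenet(sim$data, penalty = "ridge", lambda = 0.05,
                   genotype_weights = setNames(100, names(w)[2]), seed = 1)
  g2 <- names(w)[2]
  expect_lt(sum(f2$B_std[g2, ]^2), sum(f1$B_std[g2, ]^2))
})
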