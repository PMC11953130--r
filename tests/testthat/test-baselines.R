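test_that("the additive fit solves the balanced two-way layout in closed form", {
  d <- two_by_two()
  add <- fit_additive(d)
  expect_equal(add$mu, 1)
  expect_equal(unname(add$g), c(0, 2))
  expect_equal(unname(add$e), c(0, 1))
  expect_equal(add$fitted$y_obs, add$fitted$y_fit, tolerance = 1e-12)
  expect_true(all(add$B == 0))

  const <- align_met(grid_pheno(c("g1", "g2"), c("e1", "e2"), rep(5, 4)),
                     grid_ecs(c("e1", "e2"), 1))
  addc <- fit_additive(const)
  expect_equal(addc$mu, 5)
  expect_equal(unname(addc$g), c(0, 0))
  expect_equal(unname(addc$e), c(0, 0))
})

test_that("additive predictions equal the lasso fit at lambda_max", {
  sim <- simulate_met(n_g = 7, n_e_train = 14, n_e_test = 4, n_c = 3,
                      n_active = 2, seed = 16)
  des <- build_design(sim$data)
  lmax <- attr(lambda_grid(des, alpha = 1, nlambda = 3), "lambda_max")
  fit <- fit_gxenet(sim$data, penalty = "lasso", lambda = lmax, seed = 1)
  add <- fit_additive(sim$data)
  pr_fit <- predict(fit, sim$data)
  pr_add <- predict(add, sim$data)
  expect_equal(pr_fit$y_hat, pr_add$y_hat, tolerance = 1e-6)
})

test_that("the Full model equals the lambda = 0 path and recovers noise-free truth", {
  sim <- simulate_met(n_g = 6, n_e_train = 20, n_e_test = 0, n_c = 3,
                      n_active = 2, seed = 17)
  full <- fit_full(sim$data)
  des <- build_design(sim$data)
  theta0 <- elnet_path(des, alpha = 0.5, lambda = 0)[, 1]
  expect_equal(unname(full$coefficients), unname(theta0), tolerance = 1e-8)

  nf <- simulate_met(n_g = 6, n_e_train = 25, n_e_test = 0, n_c = 3,
                     n_active = 2, h2 = 1, seed = 18)
  fullnf <- fit_full(nf$data)
  expect_equal(fullnf$B, nf$truth$B, tolerance = 1e-6)
  expect_lt(max(abs(fullnf$fitted$y_obs - fullnf$fitted$y_fit)), 1e-8)
})

test_that("environment-level ECs make the Full design rank deficient", {
  # summing an EC's sensitivity columns over genotypes reproduces an
  # environment function already spanned by the main effects
  sim <- simulate_met(n_g = 6, n_e_train = 15, n_e_test = 0, n_c = 2,
                      n_active = 1, mode = "env_level", seed = 19)
  expect_error(fit_full(sim$data), class = "gxenet_rank_error")
  # the penalized fit handles the same data without complaint
  expect_s3_class(fit_gxenet(sim$data, penalty = "ridge", lambda = 0.01,
                             seed = 1), "gxe_fit")
})

test_that("stage-2 ridge has the correct shrinkage limits", {
  sim <- simulate_met(n_g = 12, n_e_train = 20, n_e_test = 0, n_c = 2,
                      n_active = 2, n_markers = 30, seed = 20)
  fit <- fit_gxenet(sim$data, penalty = "ridge", lambda = 0.02, seed = 1)
  # shrinkage -> infinity: marker effects vanish, predictions are the means
  s2 <- stage2_marker_ridge(fit, sim$markers, shrinkage = 1e12)
  par <- predict_parameters(s2, sim$markers)
  expect_equal(unname(par$g), rep(mean(fit$g), 12), tolerance = 1e-6)
  expect_equal(unname(par$B_std[, 1]), rep(mean(fit$B_std[, 1]), 12),
               tolerance = 1e-6)

  # identity marker basis with vanishing shrinkage reproduces the responses
  ident <- diag(12)
  dimnames(ident) <- list(fit$genotypes, paste0("I", 1:12))
  s2i <- stage2_marker_ridge(fit, ident, shrinkage = 1e-10)
  pari <- predict_parameters(s2i, ident)
  expect_equal(pari$g, fit$g, tolerance = 1e-6)
  expect_equal(unname(pari$B_std), unname(fit$B_std), tolerance = 1e-6)

  expect_error(stage2_marker_ridge(fit, sim$markers[-1, , drop = FALSE]),
               class = "gxenet_validation_error")
})

test_that("marker-determined slopes are recovered for held-out genotypes", {
  # held-out accuracy of a univariate marker ridge is capped near
  # sqrt(n/(n + n_markers)); sizes chosen so the signal is recoverable
  sim <- simulate_met(n_g = 300, n_e_train = 50, n_e_test = 10, n_c = 4,
                      n_active = 2, n_markers = 100, n_causal = 20,
                      marker_effects = TRUE, mode = "env_level", h2 = 0.8,
                      seed = 25)
  train_g <- attr(sim$data$pheno, "genotypes")[1:225]
  new_g <- setdiff(attr(sim$data$pheno, "genotypes"), train_g)
  df <- as.data.frame(sim$data$pheno)
  pheno_tr <- met_phenotypes(
    data.frame(genotype = df$genotype, env = df$env, value = df$y)[
      df$genotype %in% train_g, ])
  data_tr <- align_met(pheno_tr, sim$data$ecs,
                       test_envs = sim$data$split$env[
                         sim$data$split$role == "test"])
  fit <- fit_gxenet(data_tr, penalty = "ridge", lambda = 0.01, seed = 1)
  s2 <- stage2_marker_ridge(fit, sim$markers[train_g, ])
  par <- predict_parameters(s2, sim$markers[new_g, ])
  # correlation between predicted and true slopes for genotypes never seen
  sd_map <- setNames(fit$ec_stats$sd, fit$ec_stats$ec)
  for (t in sim$truth$active) {
    slope_hat <- par$B_std[, t] / sd_map[t]
    expect_gt(stats::cor(slope_hat, sim$truth$B[new_g, t]), 0.8)
  }

  # GnEn predictions correlate with the true genetic values in new envs
  test_envs <- sim$data$split$env[sim$data$split$role == "test"]
  pr <- predict_gnen(s2, sim$markers[new_g, ], data_tr$ecs, test_envs)
  gv <- sim$truth$genetic_values
  gv_new <- gv[gv$genotype %in% new_g & gv$env %in% test_envs, ]
  acc <- accuracy_by_env(pr, observed = tibble::tibble(
    genotype = gv_new$genotype, env = gv_new$env, y = gv_new$gv))
  expect_gt(attr(acc, "apcor_env"), 0.5)

  # a genotype sharing a training profile reproduces its predictions
  twin <- sim$markers[train_g[1], , drop = FALSE]
  rownames(twin) <- "twin"
  s2small <- stage2_marker_ridge(fit, sim$markers[train_g, ],
                                 shrinkage = 1e-8)
  pr_twin <- predict_gnen(s2small, twin, data_tr$ecs, test_envs[1])
  pr_orig <- predict_gnen(s2small, sim$markers[train_g[1], , drop = FALSE],
                          data_tr$ecs, test_envs[1])
  expect_equal(pr_twin$y_hat, pr_orig$y_hat, tolerance = 1e-8)

  # genotype-specific ECs are rejected for untested genotypes
  simgs <- simulate_met(n_g = 6, n_e_train = 8, n_e_test = 2, n_c = 2,
                        n_active = 1, n_markers = 10, seed = 26)
  fitgs <- fit_gxenet(simgs$data, penalty = "ridge", lambda = 0.05, seed = 1)
  s2gs <- stage2_marker_ridge(fitgs, simgs$markers)
  expect_error(predict_gnen(s2gs, simgs$markers, simgs$data$ecs, "E009"),
               class = "gxenet_unsupported_error")
})

test_that("a zero marker profile predicts the population-mean reaction norm", {
  sim <- simulate_met(n_g = 10, n_e_train = 15, n_e_test = 2, n_c = 2,
                      n_active = 1, n_markers = 20, mode = "env_level",
                      seed = 27)
  fit <- fit_gxenet(sim$data, penalty = "ridge", lambda = 0.05, seed = 1)
  s2 <- stage2_marker_ridge(fit, sim$markers)
  zero <- matrix(colMeans(sim$markers), 1,
                 dimnames = list("avg", colnames(sim$markers)))
  par <- predict_parameters(s2, zero)
  expect_equal(unname(par$g), unname(mean(fit$g)), tolerance = 1e-8)
  expect_equal(unname(drop(par$B_std)), unname(colMeans(fit$B_std)),
               tolerance = 1e-8)
})
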