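# Small in-code fixtures shared across test files.

tiny_pheno_df <- function() {
  data.frame(genotype = c("g1", "g1", "g2"),
             env = c("e1", "e2", "e1"),
             value = c(1, 2, 3))
}

# fully balanced grid phenotype table with deterministic values
grid_pheno <- function(genotypes, envs, values = NULL) {
  cells <- tidyr::expand_grid(genotype = genotypes, env = envs)
  if (is.null(values)) values <- seq_len(nrow(cells))
  met_phenotypes(data.frame(genotype = cells$genotype, env = cells$env,
                            value = values))
}

# env-level EC table with deterministic values
grid_ecs <- function(envs, n_c, seed = 1) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(rnorm(length(envs) * n_c), length(envs), n_c))
  })
  names(df) <- paste0("ec", seq_len(n_c))
  met_ecs(cbind(data.frame(env = envs), df), mode = "env_level")
}

# balanced 2x2 dataset, Y = [[1,2],[3,4]] (genotypes x environments)
two_by_two <- function(ec_value = c(e1 = 0.3, e2 = -0.2)) {
  pheno <- grid_pheno(c("g1", "g2"), c("e1", "e2"), c(1, 2, 3, 4))
  ecs <- met_ecs(data.frame(env = c("e1", "e2"), ec1 = unname(ec_value)),
                 mode = "env_level")
  align_met(pheno, ecs)
}

# brute-force accuracy oracle, kept deliberately naive
brute_apcor <- function(df, min_n = 3) {
  rs <- c()
  for (e in unique(df$env)) {
    sub <- df[df$env == e & !is.na(df$y_obs), ]
    r <- NA_real_
    if (nrow(sub) >= min_n && sd(sub$y_hat) > 0 && sd(sub$y_obs) > 0) {
      num <- sum((sub$y_hat - mean(sub$y_hat)) * (sub$y_obs - mean(sub$y_obs)))
      den <- sqrt(sum((sub$y_hat - mean(sub$y_hat))^2) *
                    sum((sub$y_obs - mean(sub$y_obs))^2))
      r <- num / den
    }
    rs[e] <- r
  }
  list(per_env = rs, apcor = mean(rs, na.rm = TRUE))
}

apcor_of_fit <- function(fit, data, test = TRUE, observed = NULL) {
  if (test) {
    preds <- predict(fit, data)
  } else {
    preds <- fit$fitted
    names(preds)[names(preds) == "y_fit"] <- "y_hat"
  }
  attr(accuracy_by_env(preds, observed = observed), "apcor_env")
}
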