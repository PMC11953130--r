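#' Default envirotype definitions
#'
#' Envirotypes are discrete environmental scenario classes (e.g. well-watered
#' vs water-deficit) around which a trial's EC values cluster. The default set
#' mirrors a typical drought-stress characterization: five scenarios with
#' equal frequency, scenario EC means drawn once from a standard normal
#' (scaled by `separation`), and within-scenario EC standard deviation
#' `within_sd` for every covariate.
#'
#' @param n_c Number of ECs.
#' @param n_types Number of envirotypes (default 5).
#' @param separation Standard deviation of scenario means across envirotypes.
#' @param within_sd Within-envirotype EC standard deviation.
#' @param seed Integer seed used to draw the scenario means.
#' @return A tibble (`label`, `frequency`, `mean` list-column, `sd`
#'   list-column).
#' @export
default_envirotypes <- function(n_c, n_types = 5, separation = 1,
                                within_sd = 0.5, seed = 1) {
  means <- withr::with_seed(seed,
                            replicate(n_types, rnorm(n_c, 0, separation),
                                      simplify = FALSE))
  tibble(label = paste0("ET", seq_len(n_types)),
         frequency = rep(1 / n_types, n_types),
         mean = means,
         sd = replicate(n_types, rep(within_sd, n_c), simplify = FALSE))
}

#' Per-environment error variance for a target heritability
#'
#' Within-environment heritability is the fraction of phenotypic variance
#' among genotypes in one environment that is genetic. Setting
#' \deqn{\sigma^2_j = \mathrm{Var}_i(\text{genetic value}_{ij})
#'   \cdot (1 - h^2)/h^2}
#' makes the expected within-environment heritability equal the target.
#'
#' @param genetic_values Tibble (`genotype`, `env`, `gv`) of noise-free
#'   values.
#' @param h2 Target within-environment heritability in `(0, 1]`.
#' @return Named numeric vector of error variances, one per environment.
#' @export
calibrate_noise <- function(genetic_values, h2) {
  stopifnot(h2 > 0, h2 <= 1)
  gv <- dplyr::summarise(dplyr::group_by(genetic_values, .data$env),
                         v = stats::var(.data$gv), n = dplyr::n(),
                         .groups = "drop")
  if (any(gv$n < 2)) {
    abort("every environment needs at least 2 genotypes",
          class = "gxenet_validation_error")
  }
  if (h2 < 1 && any(gv$v == 0)) {
    abort(paste0("zero genetic variance in environment(s) ",
                 paste(gv$env[gv$v == 0], collapse = ", "),
                 "; heritability below 1 is unattainable there"),
          class = "gxenet_validation_error")
  }
  setNames(gv$v * (1 - h2) / h2, gv$env)
}

#' Simulate a multi-environment trial with envirotype structure
#'
#' Generates the full test bed for the penalized reaction-norm pipeline:
#' environments are drawn from envirotype scenarios (ECs Gaussian around the
#' scenario means, so scenarios present in the test set also occur in
#' training); each genotype gets a main effect and a sparse vector of true
#' sensitivities (only `n_active` ECs carry signal); phenotypes follow
#' `Y = mu + g_i + e_j + sum_t v_ijt * beta_it + eps` with per-environment
#' error variance calibrated to the target within-environment heritability.
#'
#' Defaults describe a mid-sized trial network: 50 genotypes, 60 training and
#' 20 test environments, 20 candidate ECs of which 3 drive G-by-E,
#' environmental main effects (sd 2) dominating genotypic main effects (sd 1)
#' which in turn are comparable to the G-by-E signal, and heritability 0.5.
#'
#' @param n_g,n_e_train,n_e_test Numbers of genotypes and environments.
#' @param n_c Number of ECs; `n_active` of them have nonzero sensitivities.
#' @param n_active Number of signal ECs.
#' @param envirotypes Envirotype tibble ([default_envirotypes()] by default).
#' @param mu True general mean (default 6, a yield-like scale).
#' @param sd_g,sd_e Standard deviations of genotype and environment main
#'   effects.
#' @param sensitivity_scale Standard deviation of true sensitivities across
#'   genotypes for each active EC.
#' @param h2 Target within-environment heritability in `(0, 1]` (1 = no
#'   noise).
#' @param mode `"env_level"` ECs or `"genotype_specific"` (adds genotype-level
#'   Gaussian jitter of sd `geno_jitter_sd` to the environment value,
#'   emulating phenology-dependent covariate windows).
#' @param geno_jitter_sd Jitter scale for genotype-specific ECs.
#' @param n_markers,n_causal Optional marker simulation; when
#'   `marker_effects = TRUE`, genotype main effects and active sensitivities
#'   are driven by `n_causal` causal markers (`B = M Gamma`), otherwise
#'   markers are neutral covariates for stage-2 testing.
#' @param marker_effects Make genetic parameters marker-determined.
#' @param seed Integer seed; output is a pure function of the configuration
#'   and seed.
#' @return List of class `met_sim`: `data` (a `met_aligned` dataset whose
#'   phenotype table covers training and test environments), `markers`
#'   (matrix or `NULL`) and `truth`, a list with true `mu`, `g`, `e`, `B`,
#'   `active` EC names, per-environment `sigma2`, envirotype assignment and
#'   `genetic_values` (`genotype`, `env`, `gv` — noise-free phenotypes).
#' @export
simulate_met <- function(n_g = 50, n_e_train = 60, n_e_test = 20, n_c = 20,
                         n_active = 3, envirotypes = NULL, mu = 6,
                         sd_g = 1, sd_e = 2, sensitivity_scale = 0.5,
                         h2 = 0.5, mode = c("genotype_specific", "env_level"),
                         geno_jitter_sd = 0.25, n_markers = NULL,
                         n_causal = NULL, marker_effects = FALSE, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_active <= n_c, h2 > 0, h2 <= 1, n_g >= 2,
            n_e_train >= 2, n_e_test >= 0)
  if (is.null(envirotypes)) {
    envirotypes <- default_envirotypes(n_c, seed = seed)
  }
  stopifnot(abs(sum(envirotypes$frequency) - 1) < 1e-8,
            all(lengths(envirotypes$mean) == n_c))

  withr::with_seed(seed, {
    genotypes <- sprintf("G%03d", seq_len(n_g))
    envs <- sprintf("E%03d", seq_len(n_e_train + n_e_test))
    train_envs <- envs[seq_len(n_e_train)]
    test_envs <- setdiff(envs, train_envs)
    ec_names <- sprintf("ec%02d", seq_len(n_c))

    # envirotype per environment; both splits follow the same frequencies so
    # test scenarios are represented among training environments
    et <- sample(nrow(envirotypes), length(envs), replace = TRUE,
                 prob = envirotypes$frequency)
    env_ec <- do.call(rbind, lapply(et, function(k) {
      rnorm(n_c, envirotypes$mean[[k]], envirotypes$sd[[k]])
    }))
    dimnames(env_ec) <- list(envs, ec_names)

    g <- setNames(rnorm(n_g, 0, sd_g), genotypes)
    e <- setNames(rnorm(length(envs), 0, sd_e), envs)
    active <- ec_names[seq_len(n_active)]
    B <- matrix(0, n_g, n_c, dimnames = list(genotypes, ec_names))

    markers <- NULL
    if (!is.null(n_markers)) {
      freq <- runif(n_markers, 0.1, 0.9)
      markers <- vapply(freq, function(p) rbinom(n_g, 2, p), numeric(n_g))
      dimnames(markers) <- list(genotypes,
                                sprintf("M%04d", seq_len(n_markers)))
      if (marker_effects) {
        n_causal <- n_causal %||% min(20, n_markers)
        causal <- sample(n_markers, n_causal)
        Mc <- scale(markers[, causal, drop = FALSE], scale = FALSE)
        gam_g <- rnorm(n_causal)
        g_raw <- drop(Mc %*% gam_g)
        g <- setNames(g_raw * sd_g / max(stats::sd(g_raw), 1e-12), genotypes)
        if (n_active > 0) {
          Gam <- matrix(rnorm(n_causal * n_active), n_causal, n_active)
          Braw <- Mc %*% Gam
          Braw <- sweep(Braw, 2, apply(Braw, 2, stats::sd), "/") *
            sensitivity_scale
          B[, active] <- Braw
        }
      }
    }
    if (!marker_effects && n_active > 0) {
      B[, active] <- matrix(rnorm(n_g * n_active, 0, sensitivity_scale),
                            n_g, n_active)
    }

    cells <- tidyr::expand_grid(genotype = genotypes, env = envs)
    gi <- match(cells$genotype, genotypes)
    ej <- match(cells$env, envs)
    if (mode == "env_level") {
      V <- env_ec[ej, , drop = FALSE]
      ec_tbl <- met_ecs(dplyr::bind_cols(tibble(env = envs),
                                         as_tibble(env_ec)),
                        mode = "env_level")
    } else {
      V <- env_ec[ej, , drop = FALSE] +
        matrix(rnorm(nrow(cells) * n_c, 0, geno_jitter_sd), ncol = n_c)
      ec_tbl <- met_ecs(dplyr::bind_cols(cells, as_tibble(V)),
                        mode = "genotype_specific")
    }
    gxe <- rowSums(V * B[gi, , drop = FALSE])
    gv <- mu + g[gi] + e[ej] + gxe
    genetic_values <- tibble(genotype = cells$genotype, env = cells$env,
                             gv = unname(gv))
    sigma2 <- if (h2 < 1) calibrate_noise(genetic_values, h2) else
      setNames(rep(0, length(envs)), envs)
    y <- gv + rnorm(nrow(cells), 0, sqrt(sigma2[cells$env]))

    pheno <- met_phenotypes(tibble(genotype = cells$genotype,
                                   env = cells$env, value = unname(y)))
    data <- align_met(pheno, ec_tbl, test_envs = test_envs)

    truth <- list(mu = mu, g = g, e = e, B = B, active = active,
                  sigma2 = sigma2,
                  envirotype = setNames(envirotypes$label[et], envs),
                  genetic_values = genetic_values, h2 = h2)
    structure(list(data = data, markers = markers, truth = truth,
                   config = list(n_g = n_g, n_e_train = n_e_train,
                                 n_e_test = n_e_test, n_c = n_c,
                                 n_active = n_active, mu = mu, sd_g = sd_g,
                                 sd_e = sd_e,
                                 sensitivity_scale = sensitivity_scale,
                                 h2 = h2, mode = mode, seed = seed)),
              class = "met_sim")
  })
}

#' @export
print.met_sim <- function(x, ...) {
  cfg <- x$config
  cat("<met_sim> ", cfg$n_g, " genotypes, ", cfg$n_e_train, "+",
      cfg$n_e_test, " environments, ", cfg$n_c, " ECs (", cfg$n_active,
      " active), h2 = ", cfg$h2, ", seed = ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated trial to the standard CSV layout
#'
#' Emits `phenotypes.csv`, `ecs.csv`, `truth_effects.csv` (genotype
#' parameters), `truth_genetic_values.csv`, optionally `markers.csv`, plus
#' `test_envs.txt`.
#'
#' @param sim A `met_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dplyr::rename(as_tibble(sim$data$pheno), value = "y"),
                   file.path(dir, "phenotypes.csv"), progress = FALSE)
  readr::write_csv(as_tibble(sim$data$ecs), file.path(dir, "ecs.csv"),
                   progress = FALSE)
  truth_eff <- dplyr::bind_cols(tibble(genotype = names(sim$truth$g),
                                       g = unname(sim$truth$g)),
                                as_tibble(sim$truth$B))
  readr::write_csv(truth_eff, file.path(dir, "truth_effects.csv"),
                   progress = FALSE)
  readr::write_csv(sim$truth$genetic_values,
                   file.path(dir, "truth_genetic_values.csv"),
                   progress = FALSE)
  if (!is.null(sim$markers)) {
    mk <- dplyr::bind_cols(tibble(genotype = rownames(sim$markers)),
                           as_tibble(sim$markers))
    readr::write_csv(mk, file.path(dir, "markers.csv"), progress = FALSE)
  }
  writeLines(test_envs_of(sim$data), file.path(dir, "test_envs.txt"))
  invisible(dir)
}
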