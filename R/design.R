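#' Build the sparse factorial-regression design matrix
#'
#' Encodes the reaction-norm model
#' \deqn{Y_{ij} = \mu + g_i + e_j + \sum_t v^{(t)}_{ij} \beta_{it} + \epsilon_{ij}}
#' over the training rows of an aligned dataset as a sparse model matrix with
#' treatment (reference-level) coding: the first genotype and the first
#' environment carry no dummy column, so the column count is always
#' `p = n_g + n_e - 1 + n_g * n_c` (intercept + (n_g-1) genotype dummies +
#' (n_e-1) environment dummies + n_g * n_c sensitivity columns). The
#' sensitivity column (i, t) holds the (optionally training-standardized) EC
#' value of covariate t in the rows of genotype i and is zero elsewhere, which
#' keeps the matrix very sparse (at most `n_c + 3` nonzeros per row).
#'
#' Main-effect columns get penalty factor 0 (never shrunk: environmental main
#' effects are typically much larger than the G-by-E signal the ECs carry);
#' sensitivity columns get penalty factor 1, or a positive genotype-specific
#' weight.
#'
#' @param data A `met_aligned` dataset from [align_met()].
#' @param standardize Centre and scale each EC to training mean 0, sd 1 before
#'   it enters the design (default `TRUE`); test ECs are always transformed
#'   with the stored training statistics.
#' @param genotype_weights Optional named positive vector of per-genotype
#'   penalty multipliers for the sensitivity columns (default all 1).
#' @return A list of class `gxe_design`: sparse matrix `X` (`dgCMatrix`),
#'   response `y`, `columns` metadata tibble (`column`, `role`, `genotype`,
#'   `env`, `ec`, `penalty_factor`), `row_keys`, dimension counts and the EC
#'   standardization statistics used.
#' @export
build_design <- function(data, standardize = TRUE, genotype_weights = NULL) {
  stopifnot(inherits(data, "met_aligned"))
  pheno <- data$pheno
  rows <- train_rows(data)
  keys <- pheno[rows, c("genotype", "env")]
  y <- pheno$y[rows]
  genotypes <- attr(pheno, "genotypes")
  train_envs <- data$split$env[data$split$role == "train"]
  ec_names <- attr(data$ecs, "ec_names")
  n_g <- length(genotypes)
  n_e <- length(train_envs)
  n_c <- length(ec_names)
  if (n_g < 2 || n_e < 2) {
    abort("degenerate design: need at least 2 genotypes and 2 environments",
          class = "gxenet_design_error")
  }
  stats <- attr(data$ecs, "standardization")
  if (standardize && any(stats$sd == 0)) {
    abort(paste0("EC(s) constant on the training set (sd = 0): ",
                 paste(stats$ec[stats$sd == 0], collapse = ", ")),
          class = "gxenet_design_error")
  }

  columns <- design_columns(genotypes, train_envs, ec_names, genotype_weights)
  V <- ec_matrix(data$ecs, keys, standardize)

  gi <- match(keys$genotype, genotypes)
  ej <- match(keys$env, train_envs)
  N <- nrow(keys)
  p <- nrow(columns)

  # triplets: intercept, genotype dummy (i > 1), env dummy (j > 1), sensitivities
  ri <- seq_len(N)
  trip_i <- c(ri, ri[gi > 1], ri[ej > 1],
              rep(ri, n_c))
  trip_j <- c(rep(1L, N),
              1L + (gi[gi > 1] - 1L),
              n_g + (ej[ej > 1] - 1L),
              # sensitivity column of (genotype gi, ec t), genotype-major
              as.vector(vapply(seq_len(n_c),
                               function(t) n_g + n_e - 1L + (gi - 1L) * n_c + t,
                               integer(N))))
  trip_x <- c(rep(1, N), rep(1, sum(gi > 1)), rep(1, sum(ej > 1)),
              as.vector(V))
  keep <- trip_x != 0
  X <- Matrix::sparseMatrix(i = trip_i[keep], j = trip_j[keep],
                            x = trip_x[keep], dims = c(N, p),
                            dimnames = list(NULL, columns$column))

  structure(list(X = X, y = y, columns = columns, row_keys = keys,
                 genotypes = genotypes, environments = train_envs,
                 ec_names = ec_names, n_g = n_g, n_e = n_e, n_c = n_c,
                 ec_stats = stats, standardize = standardize,
                 ec_mode = attr(data$ecs, "mode")),
            class = "gxe_design")
}

design_columns <- function(genotypes, envs, ec_names, genotype_weights = NULL) {
  n_g <- length(genotypes)
  n_e <- length(envs)
  n_c <- length(ec_names)
  w <- rep(1, n_g)
  names(w) <- genotypes
  if (!is.null(genotype_weights)) {
    if (is.null(names(genotype_weights)) ||
        !all(names(genotype_weights) %in% genotypes) ||
        any(genotype_weights <= 0)) {
      abort("genotype_weights must be a named positive vector over known genotypes",
            class = "gxenet_design_error")
    }
    w[names(genotype_weights)] <- genotype_weights
  }
  sens <- tidyr::expand_grid(genotype = genotypes, ec = ec_names)
  dplyr::bind_rows(
    tibble(column = "(Intercept)", role = "intercept",
           genotype = NA_character_, env = NA_character_, ec = NA_character_,
           penalty_factor = 0),
    tibble(column = paste0("g:", genotypes[-1]), role = "geno_main",
           genotype = genotypes[-1], env = NA_character_, ec = NA_character_,
           penalty_factor = 0),
    tibble(column = paste0("e:", envs[-1]), role = "env_main",
           genotype = NA_character_, env = envs[-1], ec = NA_character_,
           penalty_factor = 0),
    tibble(column = paste0("s:", sens$genotype, ":", sens$ec),
           role = "sensitivity", genotype = sens$genotype,
           env = NA_character_, ec = sens$ec,
           penalty_factor = w[sens$genotype])
  )
}

# EC values for a set of (genotype, env) keys as an N x n_c matrix, on the
# standardized scale when requested (training statistics).
ec_matrix <- function(ecs, keys, standardize) {
  ec_names <- attr(ecs, "ec_names")
  stats <- attr(ecs, "standardization")
  if (attr(ecs, "mode") == "env_level") {
    idx <- match(keys$env, ecs$env)
  } else {
    idx <- match(paste(keys$genotype, keys$env, sep = "\r"),
                 paste(ecs$genotype, ecs$env, sep = "\r"))
  }
  if (anyNA(idx)) {
    k <- which(is.na(idx))[1]
    abort(paste0("no EC values for cell (", keys$genotype[k], ", ",
                 keys$env[k], ")"),
          class = "gxenet_validation_error")
  }
  V <- as.matrix(ecs[idx, ec_names, drop = FALSE])
  if (standardize) {
    if (is.null(stats)) {
      abort("ECs carry no standardization statistics; run align_met() first",
            class = "gxenet_validation_error")
    }
    V <- sweep(sweep(V, 2, stats$mean, "-"), 2, stats$sd, "/")
  }
  unname(V)
}

#' Build prediction rows matching a fitted design's columns
#'
#' For new environments the environmental main effect is not estimable, so all
#' `env_main` columns are left at zero: predictions are environment-centred,
#' which leaves within-environment (rank and correlation) comparisons
#' unaffected. Requested genotypes must have been present in training;
#' predicting an untested genotype is the GnEn scenario and needs the
#' second-stage marker model ([stage2_marker_ridge()]).
#'
#' @param fit_cols Column metadata tibble from a `gxe_design` or `gxe_fit`.
#' @param ecs A `met_ecs` table with standardization statistics (from an
#'   aligned dataset or a fit).
#' @param genotypes,envs Ids of the genotype/environment grid to predict.
#' @param standardize Whether the fit standardized ECs (default `TRUE`).
#' @return List with sparse matrix `X` (rows = `expand_grid(env, genotype)`)
#'   and `row_keys`.
#' @export
design_for_prediction <- function(fit_cols, ecs, genotypes, envs,
                                  standardize = TRUE) {
  train_genotypes <- unique(stats::na.omit(
    fit_cols$genotype[fit_cols$role == "sensitivity"]))
  unknown <- setdiff(genotypes, train_genotypes)
  if (length(unknown) > 0) {
    abort(paste0("genotype(s) not in training set (GoEn violated): ",
                 paste(unknown, collapse = ", "),
                 ". Predicting new genotypes needs the stage-2 marker model."),
          class = "gxenet_goen_error")
  }
  keys <- tidyr::expand_grid(env = as.character(envs),
                             genotype = as.character(genotypes))
  keys <- keys[c("genotype", "env")]
  V <- ec_matrix(ecs, keys, standardize)
  ec_names <- attr(ecs, "ec_names")
  n_c <- length(ec_names)
  N <- nrow(keys)
  p <- nrow(fit_cols)

  geno_col <- match(paste0("g:", keys$genotype), fit_cols$column)
  sens_base <- match(paste0("s:", keys$genotype, ":", ec_names[1]),
                     fit_cols$column)
  # sensitivity columns of one genotype are contiguous, ec-major within genotype
  ri <- seq_len(N)
  has_g <- !is.na(geno_col)
  trip_i <- c(ri, ri[has_g], rep(ri, n_c))
  trip_j <- c(rep(which(fit_cols$role == "intercept"), N),
              geno_col[has_g],
              as.vector(vapply(seq_len(n_c) - 1L,
                               function(t) sens_base + t, integer(N))))
  trip_x <- c(rep(1, N), rep(1, sum(has_g)), as.vector(V))
  keep <- trip_x != 0
  X <- Matrix::sparseMatrix(i = trip_i[keep], j = trip_j[keep],
                            x = trip_x[keep], dims = c(N, p),
                            dimnames = list(NULL, fit_cols$column))
  list(X = X, row_keys = keys)
}

#' Dump a design to MatrixMarket plus column-metadata CSV (debug aid)
#'
#' @param design A `gxe_design`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(design$X, file.path(dir, "design.mtx"))
  readr::write_csv(design$columns, file.path(dir, "columns.csv"),
                   progress = FALSE)
  readr::write_csv(dplyr::mutate(design$row_keys, y = design$y),
                   file.path(dir, "rows.csv"), progress = FALSE)
  invisible(dir)
}
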