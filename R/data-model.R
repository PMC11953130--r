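#' Build a validated multi-environment-trial phenotype table
#'
#' A phenotype table holds one trait value per observed genotype-by-environment
#' cell of a multi-environment trial (MET), in long format. Genotype and
#' environment identifiers are opaque strings; their first-appearance order is
#' fixed at construction and later determines the design-column order and the
#' identifiability reference levels (first genotype and first environment).
#'
#' @param df A data frame with at least the three mapped columns.
#' @param genotype,env,value Names of the columns holding the genotype id,
#'   environment id and trait value. Defaults `"genotype"`, `"env"`, `"value"`.
#' @return A tibble of class `met_pheno` with columns `genotype`, `env`, `y`
#'   and attributes `genotypes` and `environments` (ordered unique ids).
#' @examples
#' met_phenotypes(data.frame(genotype = c("g1", "g1", "g2"),
#'                           env = c("e1", "e2", "e1"),
#'                           value = c(1, 2, 3)))
#' @export
met_phenotypes <- function(df, genotype = "genotype", env = "env", value = "value") {
  missing_cols <- setdiff(c(genotype, env, value), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("phenotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gxenet_schema_error")
  }
  y <- df[[value]]
  if (!is.numeric(y)) {
    abort(paste0("phenotype column '", value, "' is not numeric"),
          class = "gxenet_parse_error")
  }
  if (any(!is.finite(y))) {
    abort("phenotype values must be finite (no NA/Inf)",
          class = "gxenet_validation_error")
  }
  out <- tibble(
    genotype = as.character(df[[genotype]]),
    env = as.character(df[[env]]),
    y = as.numeric(y)
  )
  dup <- duplicated(out[c("genotype", "env")])
  if (any(dup)) {
    keys <- paste0("(", out$genotype[dup], ", ", out$env[dup], ")")
    abort(paste0("duplicate genotype-environment cell(s): ",
                 paste(unique(keys), collapse = ", ")),
          class = "gxenet_validation_error")
  }
  structure(out,
            genotypes = unique(out$genotype),
            environments = unique(out$env),
            class = c("met_pheno", class(out)))
}

#' Read a phenotype table from a delimited text file
#'
#' Expects comma-separated text with a header row; see [met_phenotypes()] for
#' the validation rules.
#'
#' @param path Path to a CSV file.
#' @param column_map Named list/vector mapping the roles `genotype`, `env`,
#'   `value` to column names in the file.
#' @return A `met_pheno` tibble.
#' @export
read_phenotypes <- function(path,
                            column_map = c(genotype = "genotype", env = "env",
                                           value = "value")) {
  column_map <- as.list(column_map)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  met_phenotypes(df,
                 genotype = column_map$genotype %||% "genotype",
                 env = column_map$env %||% "env",
                 value = column_map$value %||% "value")
}

#' Build an environmental-covariate (EC) table
#'
#' ECs are measured or derived environmental variables (e.g. night temperature
#' around flowering). They may be environment-level (one value per environment,
#' shared by all genotypes) or genotype-specific (one value per genotype-by-
#' environment cell, as happens for covariates windowed on each genotype's
#' phenology).
#'
#' @param df Data frame keyed by `env` (and `genotype` in genotype-specific
#'   mode) with one numeric column per EC.
#' @param mode `"env_level"` or `"genotype_specific"`.
#' @param env,genotype Key column names.
#' @return A tibble of class `met_ecs` with attributes `ec_names`, `mode` and
#'   (once aligned) `standardization`, a per-EC tibble of training mean/sd.
#' @export
met_ecs <- function(df, mode = c("env_level", "genotype_specific"),
                    env = "env", genotype = "genotype") {
  mode <- match.arg(mode)
  key_cols <- if (mode == "env_level") env else c(genotype, env)
  missing_cols <- setdiff(key_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("EC table lacks key column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gxenet_schema_error")
  }
  ec_names <- setdiff(names(df), c(env, genotype))
  if (length(ec_names) < 1) {
    abort("EC table needs at least one covariate column",
          class = "gxenet_schema_error")
  }
  bad <- ec_names[!vapply(df[ec_names], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric EC column(s): ", paste(bad, collapse = ", ")),
          class = "gxenet_parse_error")
  }
  out <- tibble(env = as.character(df[[env]]))
  if (mode == "genotype_specific") out$genotype <- as.character(df[[genotype]])
  out <- dplyr::bind_cols(out, as_tibble(df[ec_names]))
  dup <- duplicated(out[intersect(c("genotype", "env"), names(out))])
  if (any(dup)) {
    abort("duplicate EC rows for the same key", class = "gxenet_validation_error")
  }
  structure(out,
            ec_names = ec_names,
            mode = mode,
            standardization = NULL,
            class = c("met_ecs", class(out)))
}

#' Read an EC table from a delimited text file
#'
#' @inheritParams met_ecs
#' @param path Path to a CSV file keyed by `env` (plus `genotype` in
#'   genotype-specific mode), remaining columns numeric ECs.
#' @return A `met_ecs` tibble.
#' @export
read_ecs <- function(path, mode = c("env_level", "genotype_specific")) {
  mode <- match.arg(mode)
  met_ecs(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
          mode = mode)
}

#' Build a genotype-by-marker dosage matrix
#'
#' Missing entries are imputed to the column mean (deterministic); used only by
#' the second-stage marker ridge for the new-genotype (GnEn) extension.
#'
#' @param df Data frame with a `genotype` column and numeric marker columns,
#'   or a numeric matrix with genotype ids as rownames.
#' @return A numeric matrix with genotype rownames, no missing entries.
#' @export
met_markers <- function(df) {
  if (is.matrix(df)) {
    m <- df
    if (is.null(rownames(m))) {
      abort("marker matrix needs genotype ids as rownames",
            class = "gxenet_schema_error")
    }
  } else {
    if (!"genotype" %in% names(df)) {
      abort("marker table lacks a 'genotype' column",
            class = "gxenet_schema_error")
    }
    m <- as.matrix(df[setdiff(names(df), "genotype")])
    rownames(m) <- as.character(df$genotype)
  }
  if (anyDuplicated(rownames(m))) {
    abort("duplicate genotype rows in marker matrix",
          class = "gxenet_validation_error")
  }
  if (ncol(m) < 1) abort("marker matrix needs at least one column",
                         class = "gxenet_schema_error")
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  m
}

#' Read a marker matrix from CSV
#'
#' @param path CSV with a `genotype` column and one numeric column per marker.
#' @return Numeric matrix, see [met_markers()].
#' @export
read_markers <- function(path) {
  met_markers(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Align phenotypes with ECs and declare the train/test environment split
#'
#' Validates that every phenotype record's environment has EC values, that
#' every test environment has ECs for every genotype to be predicted, and that
#' the training set is non-empty. EC standardization statistics (per-EC mean
#' and sd) are computed on TRAINING cells only and stored with the EC table, so
#' adding or removing test-environment EC rows never changes them; test ECs are
#' later transformed with the stored training statistics.
#'
#' @param pheno A `met_pheno` table (observed cells, training and optionally
#'   test environments).
#' @param ecs A `met_ecs` table covering all environments involved.
#' @param test_envs Character vector of environment ids held out as the test
#'   set ("new environments", known only through their ECs). May be empty.
#' @return A list of class `met_aligned` with elements `pheno`, `ecs` (with
#'   standardization statistics attached) and `split`, a tibble
#'   (`env`, `role`) with role `"train"` or `"test"`.
#' @export
align_met <- function(pheno, ecs, test_envs = character()) {
  stopifnot(inherits(pheno, "met_pheno"), inherits(ecs, "met_ecs"))
  test_envs <- as.character(test_envs)
  pheno_envs <- attr(pheno, "environments")
  train_envs <- setdiff(pheno_envs, test_envs)
  if (length(train_envs) == 0) {
    abort("no training environments left after removing test environments",
          class = "gxenet_validation_error")
  }
  all_envs <- union(pheno_envs, test_envs)
  missing_ec <- setdiff(all_envs, unique(ecs$env))
  if (length(missing_ec) > 0) {
    abort(paste0("environment(s) without EC values: ",
                 paste(missing_ec, collapse = ", ")),
          class = "gxenet_validation_error")
  }
  mode <- attr(ecs, "mode")
  genotypes <- attr(pheno, "genotypes")
  if (mode == "genotype_specific") {
    # every observed training cell and every (genotype, test env) cell needs ECs
    need <- dplyr::bind_rows(
      pheno[pheno$env %in% train_envs, c("genotype", "env")],
      tidyr::expand_grid(genotype = genotypes, env = test_envs)
    )
    have <- dplyr::distinct(ecs[c("genotype", "env")])
    missing_cells <- dplyr::anti_join(need, have, by = c("genotype", "env"))
    if (nrow(missing_cells) > 0) {
      abort(paste0("missing genotype-specific EC cells, e.g. (",
                   missing_cells$genotype[1], ", ", missing_cells$env[1],
                   ") and ", nrow(missing_cells) - 1, " more"),
            class = "gxenet_validation_error")
    }
  }
  ecs <- ec_compute_standardization(ecs, train_envs, genotypes)
  split <- dplyr::bind_rows(
    tibble(env = train_envs, role = "train"),
    tibble(env = test_envs, role = "test")
  )
  structure(list(pheno = pheno, ecs = ecs, split = split),
            class = "met_aligned")
}

# Training-cell restriction used for EC standardization: EC rows whose
# environment is a training environment (and, for genotype-specific ECs, whose
# genotype occurs in the phenotype table).
ec_compute_standardization <- function(ecs, train_envs, genotypes) {
  ec_names <- attr(ecs, "ec_names")
  rows <- ecs$env %in% train_envs
  if (attr(ecs, "mode") == "genotype_specific") {
    rows <- rows & ecs$genotype %in% genotypes
  }
  sub <- ecs[rows, ec_names, drop = FALSE]
  stats <- tibble(
    ec = ec_names,
    mean = unname(vapply(sub, mean, numeric(1))),
    sd = unname(vapply(sub, function(x) stats::sd(x), numeric(1)))
  )
  # single training row: sd is NA; treat as degenerate (flagged at design time)
  stats$sd[is.na(stats$sd)] <- 0
  attr(ecs, "standardization") <- stats
  ecs
}

#' @export
print.met_aligned <- function(x, ...) {
  n_train <- sum(x$split$role == "train")
  n_test <- sum(x$split$role == "test")
  cat("<met_aligned> ", length(attr(x$pheno, "genotypes")), " genotypes, ",
      n_train, " train + ", n_test, " test environments, ",
      nrow(x$pheno), " phenotype records, ",
      length(attr(x$ecs, "ec_names")), " ECs (", attr(x$ecs, "mode"), ")\n",
      sep = "")
  invisible(x)
}

train_rows <- function(data) {
  train_envs <- data$split$env[data$split$role == "train"]
  which(data$pheno$env %in% train_envs)
}

test_envs_of <- function(data) data$split$env[data$split$role == "test"]

#' Write a prediction table to CSV
#'
#' Columns: `genotype`, `env`, `y_hat` and, when observations exist, `y_obs`.
#' The round trip through [readr::read_csv()] is lossless (full double
#' precision is written).
#'
#' @param preds A prediction tibble as returned by [predict.gxe_fit()].
#' @param path Output file path.
#' @return `preds`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  cols <- intersect(c("genotype", "env", "y_hat", "y_obs"), names(preds))
  readr::write_csv(preds[cols], path, progress = FALSE)
  invisible(preds)
}
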