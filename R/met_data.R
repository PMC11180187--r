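#' Replicate-level trial table
#'
#' Validates and classes a long-format multi-environment-trial (MET) table:
#' one row per environment x genotype x replicate, one column per trait.
#' Trait columns must be numeric and finite; the (env, gen, rep) key must be
#' unique.
#'
#' @param data A data frame with environment, genotype and replicate columns
#'   plus at least one numeric trait column.
#' @param env,gen,rep Names of the design columns in `data`. Defaults follow
#'   the common `ENV`/`GEN`/`REP` convention.
#' @return A `trial_table`: a tibble with attributes `env`, `gen`, `rep`
#'   (column names) and `traits` (trait column names).
#' @examples
#' df <- expand.grid(ENV = c("E1", "E2"), GEN = c("G1", "G2"), REP = "R1")
#' df$GY <- c(5.1, 4.8, 5.3, 5.0)
#' trial_table(df)
#' @export
trial_table <- function(data, env = "ENV", gen = "GEN", rep = "REP") {
  data <- as.data.frame(data)
  for (col in c(env, gen, rep)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in trial data", call. = FALSE)
    }
  }
  traits <- setdiff(names(data), c(env, gen, rep))
  if (length(traits) == 0L) {
    stop("trial data has no trait columns", call. = FALSE)
  }
  for (tr in traits) {
    v <- data[[tr]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("trait column '", tr, "' is not numeric (first bad row: ",
           if (is.na(bad)) "coercible but non-numeric class" else bad, ")",
           call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop("trait column '", tr, "' contains non-finite values (row ",
           which(!is.finite(v))[1], ")", call. = FALSE)
    }
  }
  key <- paste(data[[env]], data[[gen]], data[[rep]], sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), , drop = FALSE][1, ]
    stop("duplicated (env, gen, rep) key: (", d[[env]], ", ", d[[gen]],
         ", ", d[[rep]], ")", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  structure(out,
            env = env, gen = gen, rep = rep, traits = traits,
            class = c("trial_table", class(out)))
}

#' Read a replicate-level trial from delimited text
#'
#' @param path Path to a delimited text file with one header row.
#' @param sep Field separator (`","` default, `"\t"` for TSV).
#' @param env,gen,rep Design column names, passed to [trial_table()].
#' @return A validated [trial_table()].
#' @export
read_trial <- function(path, sep = ",", env = "ENV", gen = "GEN",
                       rep = "REP") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  trial_table(df, env = env, gen = gen, rep = rep)
}

#' Genotype x environment means matrix
#'
#' The central container of the package: a complete genotype (rows) by
#' environment (columns) matrix of trait means, carrying the replicate count
#' the means were taken over.
#'
#' @param x Numeric matrix, genotypes in rows, environments in columns, with
#'   dimnames. No missing cells are allowed.
#' @param n_reps Positive integer: replicates behind each cell mean.
#' @param trait Trait label.
#' @return A `means_matrix` object.
#' @export
means_matrix <- function(x, n_reps = 1L, trait = "trait") {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("means matrix has missing or non-finite cells",
                               call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("G", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("E", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("genotype and environment labels must be unique", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  if (length(n_reps) != 1L || is.na(n_reps) || n_reps < 1L) {
    stop("n_reps must be a single positive integer", call. = FALSE)
  }
  structure(x, n_reps = n_reps, trait = trait,
            class = c("means_matrix", "matrix", "array"))
}

#' @export
print.means_matrix <- function(x, ...) {
  cat("Genotype x environment means (", attr(x, "trait"), "), ",
      nrow(x), " genotypes x ", ncol(x), " environments, r = ",
      attr(x, "n_reps"), "\n", sep = "")
  print(unclass_means(x), ...)
  invisible(x)
}

# strip class/attrs for plain-matrix arithmetic
unclass_means <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

#' Average replicates into a means matrix
#'
#' Collapses a [trial_table()] to a genotype x environment matrix of
#' arithmetic means for one trait. The design must be balanced (a common
#' replicate count across all cells): the AMMI ANOVA degrees of freedom
#' assume it, so unbalanced data are rejected rather than silently averaged.
#'
#' @param trial A [trial_table()].
#' @param trait Trait column to average.
#' @return A [means_matrix()] with `n_reps` set to the common count.
#' @export
to_means <- function(trial, trait) {
  stopifnot(inherits(trial, "trial_table"))
  if (!trait %in% attr(trial, "traits")) {
    stop("trait '", trait, "' not present in trial", call. = FALSE)
  }
  env <- trial[[attr(trial, "env")]]
  gen <- trial[[attr(trial, "gen")]]
  y <- trial[[trait]]
  envs <- unique(as.character(env))
  gens <- unique(as.character(gen))
  counts <- table(factor(gen, gens), factor(env, envs))
  if (any(counts == 0L)) {
    stop("missing (genotype, environment) cells for trait '", trait, "'",
         call. = FALSE)
  }
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced replicate counts (range ", min(counts), "-",
         max(counts), "); AMMI ANOVA requires balance", call. = FALSE)
  }
  cell <- tapply(y, list(factor(gen, gens), factor(env, envs)), mean)
  means_matrix(cell, n_reps = counts[1, 1], trait = trait)
}

#' Marginal means of a means matrix
#'
#' @param m A [means_matrix()].
#' @return List with `genotype` (named row means), `environment` (named
#'   column means) and `grand` (overall mean).
#' @export
margin_means <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  list(genotype = rowMeans(x), environment = colMeans(x), grand = mean(x))
}

#' Export a means matrix as a long trial-like table
#'
#' Inverse of [to_means()] for `n_reps = 1` data; used for round-trip I/O.
#'
#' @param m A [means_matrix()].
#' @return Tibble with ENV, GEN, REP and one trait column.
#' @export
means_to_long <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  df <- data.frame(
    ENV = rep(colnames(x), each = nrow(x)),
    GEN = rep(rownames(x), times = ncol(x)),
    REP = "R1",
    stringsAsFactors = FALSE
  )
  df[[attr(m, "trait")]] <- as.vector(x)
  tibble::as_tibble(df)
}
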