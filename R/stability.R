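#' Wricke's ecovalence
#'
#' Each genotype's contribution to the genotype-by-environment interaction
#' sum of squares on the means scale:
#' \deqn{W_i^2 = \sum_j (x_{ij} - \bar x_{i.} - \bar x_{.j} + \bar x_{..})^2.}
#' The ecovalences sum to the total GEI SS of the matrix.
#'
#' @param m A [means_matrix()].
#' @return Named numeric vector of W2 per genotype.
#' @export
ecovalence <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  mm <- margin_means(m)
  z <- x - outer(mm$genotype, mm$environment, `+`) + mm$grand
  rowSums(z^2)
}

#' Joint-regression stability (Eberhart-Russell style)
#'
#' Regresses each genotype's cell means on the environment index
#' \eqn{I_j = \bar x_{.j} - \bar x_{..}}. The slope b measures
#' responsiveness (b = 1 tracks the environment average); Sij is the mean
#' squared deviation from the genotype's own regression with e - 2 degrees
#' of freedom.
#'
#' @param m A [means_matrix()] with at least 3 environments.
#' @return Tibble with `genotype`, `b`, `Sij`.
#' @export
joint_regression <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  e <- ncol(x)
  if (e < 3) stop("joint regression needs at least 3 environments",
                  call. = FALSE)
  mm <- margin_means(m)
  idx <- mm$environment - mm$grand
  sxx <- sum(idx^2)
  if (sxx < 1e-12) stop("environment index has zero variance; slope undefined",
                        call. = FALSE)
  b <- as.vector((x - rowMeans(x)) %*% idx) / sxx
  fitted <- rowMeans(x) + outer(b, idx)
  sij <- rowSums((x - fitted)^2) / (e - 2)
  tibble::tibble(genotype = rownames(x), b = b, Sij = unname(sij))
}

# within-environment ranks, rank 1 = highest value, average ties
env_ranks <- function(x) {
  apply(x, 2, function(col) rank(-col, ties.method = "average"))
}

# mean absolute difference over all environment pairs, per genotype row
pairwise_mean_absdiff <- function(r) {
  e <- ncol(r)
  out <- numeric(nrow(r))
  for (j in seq_len(e - 1)) {
    for (jp in (j + 1):e) {
      out <- out + abs(r[, j] - r[, jp])
    }
  }
  2 * out / (e * (e - 1))
}

#' Huehn's nonparametric stability statistics
#'
#' Rank-based stability measures computed from within-environment genotype
#' ranks (rank 1 = highest yield, ties averaged): S1 is the mean absolute
#' rank difference over all environment pairs; S2 the variance of the ranks
#' across environments. S3 and S6 are computed on corrected values
#' \eqn{x^*_{ij} = x_{ij} - \bar x_{i.} + \bar x_{..}} (genotype main effect
#' removed) before ranking: S3 sums squared rank deviations relative to the
#' mean rank, S6 sums absolute rank deviations relative to the mean rank.
#'
#' @param m A [means_matrix()].
#' @return Tibble with `genotype`, `S1`, `S2`, `S3`, `S6`.
#' @export
huehn_stats <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  e <- ncol(x)
  r_raw <- env_ranks(x)
  s1 <- pairwise_mean_absdiff(r_raw)
  s2 <- apply(r_raw, 1, stats::var)
  x_corr <- x - rowMeans(x) + mean(x)
  r_corr <- env_ranks(x_corr)
  rbar <- rowMeans(r_corr)
  s3 <- rowSums((r_corr - rbar)^2) / rbar
  s6 <- rowSums(abs(r_corr - rbar)) / rbar
  tibble::tibble(genotype = rownames(x),
                 S1 = unname(s1), S2 = unname(s2),
                 S3 = unname(s3), S6 = unname(s6))
}

#' Thennarasu's nonparametric stability statistics
#'
#' Four statistics on the ranks of adjusted means
#' \eqn{x^*_{ij} = x_{ij} - (\bar x_{i.} - \bar x_{..})}, which remove
#' genotype main effects so that stability is judged independently of
#' performance level. With \eqn{r^*_{ij}} the within-environment ranks of
#' the adjusted values, \eqn{r_{ij}} the raw ranks, and Md*, Md, \eqn{\bar
#' r^*}, \eqn{\bar r} their medians and means:
#' NP1 = mean |r* - Md*|; NP2 = NP1 / Md; NP3 = rms deviation of r* about
#' its mean, divided by the raw mean rank; NP4 = mean pairwise |r*
#' difference| divided by the raw mean rank.
#'
#' @param m A [means_matrix()].
#' @return Tibble with `genotype`, `NP1`..`NP4`.
#' @export
thennarasu_stats <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  e <- ncol(x)
  r_raw <- env_ranks(x)
  x_adj <- x - (rowMeans(x) - mean(x))
  r_adj <- env_ranks(x_adj)
  md_adj <- apply(r_adj, 1, stats::median)
  md_raw <- apply(r_raw, 1, stats::median)
  mean_adj <- rowMeans(r_adj)
  mean_raw <- rowMeans(r_raw)
  np1 <- rowMeans(abs(r_adj - md_adj))
  np2 <- np1 / md_raw
  np3 <- sqrt(rowSums((r_adj - mean_adj)^2) / e) / mean_raw
  np4 <- pairwise_mean_absdiff(r_adj) / mean_raw
  tibble::tibble(genotype = rownames(x),
                 NP1 = unname(np1), NP2 = unname(np2),
                 NP3 = unname(np3), NP4 = unname(np4))
}

#' Lin-Binns superiority indexes
#'
#' Mean squared distance between a genotype and the best genotype in each
#' environment, \eqn{P_i = \sum_j (x_{ij} - M_j)^2 / (2 e')}, over all
#' environments (`Pi_a`), over favorable environments only (`Pi_f`;
#' environment mean >= grand mean, ties counted favorable) and over
#' unfavorable ones (`Pi_u`). An empty subset yields NA.
#'
#' @param m A [means_matrix()].
#' @return Tibble with `genotype`, `Pi_a`, `Pi_f`, `Pi_u`, plus attribute
#'   `favorable` (logical per environment).
#' @export
superiority <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  mm <- margin_means(m)
  mx <- apply(x, 2, max)
  sq <- sweep(x, 2, mx)^2
  fav <- mm$environment >= mm$grand
  pi_of <- function(cols) {
    if (!any(cols)) return(rep(NA_real_, nrow(x)))
    rowSums(sq[, cols, drop = FALSE]) / (2 * sum(cols))
  }
  out <- tibble::tibble(genotype = rownames(x),
                        Pi_a = unname(pi_of(rep(TRUE, ncol(x)))),
                        Pi_f = unname(pi_of(fav)),
                        Pi_u = unname(pi_of(!fav)))
  attr(out, "favorable") <- fav
  out
}

#' Geometric adaptability index
#'
#' Geometric mean of each genotype's values across environments,
#' \eqn{(\prod_j x_{ij})^{1/e}}; requires strictly positive data.
#'
#' @param m A [means_matrix()].
#' @return Named numeric vector per genotype.
#' @export
gai <- function(m) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  if (any(x <= 0)) stop("geometric adaptability needs strictly positive values",
                        call. = FALSE)
  exp(rowMeans(log(x)))
}

#' BLUP-based stability: RPGV and HMRPGV
#'
#' Estimates variance components from the balanced replicate-level ANOVA by
#' the method of moments (genotype and interaction random), shrinks genotype
#' and interaction effects accordingly, and forms genotypic values
#' \eqn{GV_{ij} = \mu_j + c_g (\bar x_{i.} - \bar x_{..}) + c_{ge} z_{ij}}
#' with \eqn{c_g = re\sigma^2_g / (re\sigma^2_g + r\sigma^2_{ge} +
#' \sigma^2_\varepsilon)} and \eqn{c_{ge} = r\sigma^2_{ge} / (r\sigma^2_{ge}
#' + \sigma^2_\varepsilon)}. The relative performance of genotypic values is
#' \eqn{RPGV_{ij} = GV_{ij} / \mu_j}; RPGV is its arithmetic mean over
#' environments and HMRPGV its harmonic mean \eqn{e / \sum_j (1 /
#' RPGV_{ij})}, which rewards both level and consistency. Negative
#' variance-component estimates are truncated to zero with a warning.
#'
#' @param trial A balanced [trial_table()].
#' @param trait Trait to analyse.
#' @return Tibble with `genotype`, `RPGV`, `HMRPGV`; attribute `varcomp`
#'   holds (sigma2_g, sigma2_ge, sigma2_e) and the shrinkage factors.
#' @export
blup_stability <- function(trial, trait) {
  stopifnot(inherits(trial, "trial_table"))
  m <- to_means(trial, trait)
  x <- unclass_means(m)
  g <- nrow(x); e <- ncol(x); r <- attr(m, "n_reps")
  if (r < 2) stop("RPGV/HMRPGV need replicate-level data (r >= 2)",
                  call. = FALSE)
  mm <- margin_means(m)
  z <- x - outer(mm$genotype, mm$environment, `+`) + mm$grand

  y <- trial[[trait]]
  envf <- factor(trial[[attr(trial, "env")]], colnames(x))
  repf <- factor(trial[[attr(trial, "rep")]])
  ss_tot <- sum((y - mean(y))^2)
  ss_env <- r * g * sum((mm$environment - mm$grand)^2)
  ss_gen <- r * e * sum((mm$genotype - mm$grand)^2)
  ss_gei <- r * sum(z^2)
  m_jr <- tapply(y, list(envf, repf), mean)
  ss_rep <- g * sum((m_jr - rowMeans(m_jr))^2)
  df_err <- e * (g - 1) * (r - 1)
  ms_err <- (ss_tot - ss_env - ss_rep - ss_gen - ss_gei) / df_err
  ms_gen <- ss_gen / (g - 1)
  ms_gei <- ss_gei / ((g - 1) * (e - 1))

  s2_e <- max(ms_err, 0)
  s2_ge <- (ms_gei - ms_err) / r
  s2_g <- (ms_gen - ms_gei) / (r * e)
  if (s2_ge < 0 || s2_g < 0) {
    warning("negative variance-component estimate truncated to 0")
  }
  s2_ge <- max(s2_ge, 0); s2_g <- max(s2_g, 0)

  den_g <- r * e * s2_g + r * s2_ge + s2_e
  c_g <- if (den_g > 0) r * e * s2_g / den_g else 0
  den_ge <- r * s2_ge + s2_e
  c_ge <- if (den_ge > 0) r * s2_ge / den_ge else 0

  gv <- outer(rep(1, g), mm$environment) +
    c_g * (mm$genotype - mm$grand) + c_ge * z
  rpgv_ij <- sweep(gv, 2, mm$environment, `/`)
  rpgv <- rowMeans(rpgv_ij)
  hmrpgv <- e / rowSums(1 / rpgv_ij)
  out <- tibble::tibble(genotype = rownames(x),
                        RPGV = unname(rpgv), HMRPGV = unname(hmrpgv))
  attr(out, "varcomp") <- list(sigma2_g = s2_g, sigma2_ge = s2_ge,
                               sigma2_e = s2_e, c_g = c_g, c_ge = c_ge)
  out
}

#' Assemble the full stability table
#'
#' One row per genotype with mean yield (Y), ecovalence (W2), joint
#' regression (b, Sij), Huehn (S1, S2, S3, S6), Thennarasu (NP1-NP4),
#' Lin-Binns (Pi_a, Pi_f, Pi_u), GAI and ASV; RPGV and HMRPGV are added when
#' replicate-level data are supplied. A companion rank table ranks every
#' statistic in its "better" direction (higher for Y, GAI, RPGV, HMRPGV;
#' closer to zero for the rest, with |b - 1| for the slope).
#'
#' @param m A [means_matrix()].
#' @param trial Optional [trial_table()] for the BLUP statistics.
#' @return Object of class `stability_table`: list with `values` and
#'   `ranks` tibbles.
#' @export
stability_table <- function(m, trial = NULL) {
  stopifnot(inherits(m, "means_matrix"))
  mm <- margin_means(m)
  jr <- joint_regression(m)
  fit <- ammi_fit(m)
  tbl <- tibble::tibble(
    genotype = rownames(m),
    Y = unname(mm$genotype),
    W2 = unname(ecovalence(m)),
    b = jr$b, Sij = jr$Sij)
  tbl <- cbind(tbl, huehn_stats(m)[-1], thennarasu_stats(m)[-1],
               superiority(m)[-1])
  tbl$GAI <- unname(gai(m))
  tbl$ASV <- asv(fit)$asv
  if (!is.null(trial)) {
    bl <- blup_stability(trial, attr(m, "trait"))
    tbl$RPGV <- bl$RPGV
    tbl$HMRPGV <- bl$HMRPGV
  }
  tbl <- tibble::as_tibble(tbl)
  higher_better <- c("Y", "GAI", "RPGV", "HMRPGV")
  ranks <- tbl["genotype"]
  for (col in setdiff(names(tbl), "genotype")) {
    v <- tbl[[col]]
    key <- if (col %in% higher_better) -v else if (col == "b") abs(v - 1) else v
    ranks[[col]] <- rank(key, ties.method = "average")
  }
  structure(list(values = tbl, ranks = tibble::as_tibble(ranks)),
            class = "stability_table")
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Stability statistics (one row per genotype):\n")
  print(x$values, ...)
  invisible(x)
}

#' Spearman correlations among stability measures
#'
#' Rank correlation (average-rank ties) between every pair of statistics in
#' a stability table. Constant columns yield NA.
#'
#' @param tbl A [stability_table()] or a data frame of per-genotype
#'   statistics (non-numeric columns dropped).
#' @return Symmetric correlation matrix.
#' @export
stability_correlations <- function(tbl) {
  if (inherits(tbl, "stability_table")) tbl <- tbl$values
  num <- as.data.frame(tbl)[vapply(tbl, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 genotypes", call. = FALSE)
  suppressWarnings(stats::cor(num, method = "spearman",
                              use = "pairwise.complete.obs"))
}
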