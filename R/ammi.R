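#' Fit the AMMI model to a genotype x environment means matrix
#'
#' The additive main effects and multiplicative interaction (AMMI) model
#' combines a two-way ANOVA for genotype and environment main effects with a
#' singular value decomposition of the doubly-centred interaction matrix
#' \deqn{z_{ij} = x_{ij} - \bar x_{i.} - \bar x_{.j} + \bar x_{..}.}
#' Each interaction principal component axis (IPCA) k carries a share
#' \eqn{\lambda_k^2 / \sum \lambda^2} of the GEI sum of squares. Sums of
#' squares are reported on the observation scale (means-scale SS times the
#' replicate count r).
#'
#' Scores use the symmetric singular-value partition (both sides scaled by
#' \eqn{\sqrt{\lambda_k}}), so the product of a genotype and an environment
#' score reconstructs that axis's contribution to \eqn{z_{ij}}. Axis signs
#' are fixed by orienting each axis so its largest-magnitude environment
#' score is positive.
#'
#' When replicate-level data are supplied, the ANOVA adds REP(ENV) and
#' pooled-error rows and F-tests: GEN, GEI and each IPCA are tested against
#' the pooled error with Gollob degrees of freedom \eqn{g + e - 1 - 2k} for
#' axis k; ENV is tested against REP(ENV). With means only, F and p are NA.
#'
#' @param m A [means_matrix()], complete, with at least 3 genotypes and 3
#'   environments.
#' @param trial Optional [trial_table()] holding the replicate-level
#'   observations behind `m` (same trait, balanced).
#' @return An object of class `ammi_fit`: list with `anova` (tibble),
#'   `singulars`, `gen_scores`, `env_scores` (g x m and e x m, symmetric
#'   partition), `pct_gei`, `cum_pct`, `means` (margins), `interaction`
#'   (the doubly-centred matrix) and `n_reps`.
#' @examples
#' fit <- ammi_fit(yield_fixture("AWD"))
#' fit$pct_gei
#' @export
ammi_fit <- function(m, trial = NULL) {
  stopifnot(inherits(m, "means_matrix"))
  x <- unclass_means(m)
  g <- nrow(x); e <- ncol(x)
  if (g < 3 || e < 3) stop("AMMI needs at least 3 genotypes and 3 environments",
                           call. = FALSE)
  r <- attr(m, "n_reps")
  mm <- margin_means(m)
  z <- x - outer(mm$genotype, mm$environment, `+`) + mm$grand
  n_ax <- min(g - 1, e - 1)
  sv <- svd(z, nu = n_ax, nv = n_ax)
  lambda <- sv$d[seq_len(n_ax)]
  u <- sv$u; v <- sv$v
  for (k in seq_len(n_ax)) {          # deterministic axis orientation
    if (v[which.max(abs(v[, k])), k] < 0) {
      u[, k] <- -u[, k]; v[, k] <- -v[, k]
    }
  }
  ss_gei_means <- sum(z^2)
  degenerate <- lambda[1] <= max(g, e) * .Machine$double.eps * sqrt(sum(x^2))
  pct <- if (!degenerate) 100 * lambda^2 / sum(lambda^2) else
    rep(NA_real_, n_ax)
  scl <- sqrt(lambda)
  gen_scores <- u * rep(scl, each = g)
  env_scores <- v * rep(scl, each = e)
  dimnames(gen_scores) <- list(rownames(x), paste0("PC", seq_len(n_ax)))
  dimnames(env_scores) <- list(colnames(x), paste0("PC", seq_len(n_ax)))

  # observation-scale sums of squares
  ss_env <- r * g * sum((mm$environment - mm$grand)^2)
  ss_gen <- r * e * sum((mm$genotype - mm$grand)^2)
  ss_gei <- r * ss_gei_means
  ss_pc <- r * lambda^2
  df_env <- e - 1; df_gen <- g - 1; df_gei <- (g - 1) * (e - 1)
  df_pc <- g + e - 1 - 2 * seq_len(n_ax)

  src <- c("ENV", "REP(ENV)", "GEN", "GEI", paste0("PC", seq_len(n_ax)),
           "Residuals")
  df <- c(df_env, NA, df_gen, df_gei, df_pc, NA)
  ss <- c(ss_env, NA, ss_gen, ss_gei, ss_pc, NA)

  if (!is.null(trial)) {
    stopifnot(inherits(trial, "trial_table"))
    trait <- attr(m, "trait")
    if (!trait %in% attr(trial, "traits")) {
      stop("trial lacks trait '", trait, "'", call. = FALSE)
    }
    y <- trial[[trait]]
    envf <- factor(trial[[attr(trial, "env")]], colnames(x))
    repf <- factor(trial[[attr(trial, "rep")]])
    if (anyNA(envf)) stop("trial environments do not match the means matrix",
                          call. = FALSE)
    ss_tot <- sum((y - mean(y))^2)
    m_jr <- tapply(y, list(envf, repf), mean)     # env x rep means
    m_j <- rowMeans(m_jr)
    ss_rep_env <- g * sum((m_jr - m_j)^2)
    df_rep_env <- e * (nlevels(repf) - 1)
    ss_err <- ss_tot - ss_env - ss_rep_env - ss_gen - ss_gei
    df_err <- e * (g - 1) * (nlevels(repf) - 1)
    df[c(2, length(df))] <- c(df_rep_env, df_err)
    ss[c(2, length(ss))] <- c(ss_rep_env, ss_err)
    ms <- ss / df
    ms_err <- ss_err / df_err
    f <- rep(NA_real_, length(src))
    f[1] <- ms[1] / ms[2]                               # ENV vs REP(ENV)
    f[2] <- ms[2] / ms_err
    f[3:(4 + n_ax)] <- ms[3:(4 + n_ax)] / ms_err        # GEN, GEI, PCs
    p <- stats::pf(f, df, c(df_rep_env, rep(df_err, length(df) - 1)),
                   lower.tail = FALSE)
    p[length(p)] <- NA
  } else {
    ms <- ss / df
    f <- p <- rep(NA_real_, length(src))
  }

  anova <- tibble::tibble(source = src, df = df, SS = ss, MS = ms,
                          F = f, p = p)
  structure(list(anova = anova, singulars = lambda,
                 gen_scores = gen_scores, env_scores = env_scores,
                 pct_gei = pct, cum_pct = cumsum(pct),
                 means = mm, interaction = z, n_reps = r,
                 trait = attr(m, "trait")),
            class = "ammi_fit")
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI fit (", x$trait, "): ", nrow(x$gen_scores), " genotypes x ",
      nrow(x$env_scores), " environments\n", sep = "")
  cat("GEI explained by axis (%):",
      paste(sprintf("%.1f", x$pct_gei), collapse = ", "), "\n")
  print(x$anova)
  invisible(x)
}

#' AMMI1 biplot coordinates (mean vs IPCA1)
#'
#' @param fit An [ammi_fit()].
#' @return Tibble with `type` ("gen"/"env"), `label`, `mean` (abscissa) and
#'   `ipca1` (ordinate).
#' @export
ammi1_coords <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  tibble::tibble(
    type = rep(c("gen", "env"),
               c(nrow(fit$gen_scores), nrow(fit$env_scores))),
    label = c(rownames(fit$gen_scores), rownames(fit$env_scores)),
    mean = unname(c(fit$means$genotype, fit$means$environment)),
    ipca1 = unname(c(fit$gen_scores[, 1], fit$env_scores[, 1]))
  )
}

#' AMMI2 biplot coordinates (IPCA1 vs IPCA2)
#'
#' Environment "spoke length" is the Euclidean norm of the first two scores:
#' long spokes mark environments that interact strongly and so discriminate
#' among genotypes.
#'
#' @param fit An [ammi_fit()] with at least two axes.
#' @return Tibble with `type`, `label`, `ipca1`, `ipca2`, `spoke`.
#' @export
ammi2_coords <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (length(fit$singulars) < 2) {
    stop("AMMI2 coordinates need at least two interaction axes",
         call. = FALSE)
  }
  sc <- rbind(fit$gen_scores[, 1:2], fit$env_scores[, 1:2])
  tibble::tibble(
    type = rep(c("gen", "env"),
               c(nrow(fit$gen_scores), nrow(fit$env_scores))),
    label = rownames(sc),
    ipca1 = unname(sc[, 1]), ipca2 = unname(sc[, 2]),
    spoke = unname(sqrt(sc[, 1]^2 + sc[, 2]^2))
  )
}

#' Nominal (adaptation) plot lines
#'
#' Each genotype's nominal yield is a line over the environment IPCA1 score
#' t: \eqn{\hat y_i(t) = \bar x_{i.} + s_{i1} t}. Crossings of these lines
#' mark where the predicted winner changes along the environment-interaction
#' gradient.
#'
#' @param fit An [ammi_fit()].
#' @param env_grid IPCA1 values at which to evaluate the lines; defaults to
#'   the fitted environment scores.
#' @return List with `lines` (tibble: genotype, intercept, slope) and
#'   `nominal` (genotypes x grid matrix of nominal yields).
#' @export
nominal_plot <- function(fit, env_grid = NULL) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (is.null(env_grid)) env_grid <- fit$env_scores[, 1]
  intercept <- fit$means$genotype
  slope <- fit$gen_scores[, 1]
  nominal <- outer(intercept, rep(1, length(env_grid))) + outer(slope, env_grid)
  dimnames(nominal) <- list(names(intercept), names(env_grid))
  list(
    lines = tibble::tibble(genotype = names(intercept),
                           intercept = unname(intercept),
                           slope = unname(slope)),
    nominal = nominal
  )
}

#' AMMI stability value (ASV)
#'
#' Distance of each genotype from the origin of the IPCA1 x IPCA2
#' scattergram, with axis 1 weighted by the ratio of the first to second
#' axis interaction sums of squares:
#' \deqn{ASV_i = \sqrt{\left(\frac{SS_{IPCA1}}{SS_{IPCA2}} s_{i1}\right)^2
#'   + s_{i2}^2}.}
#' Lower values indicate more stable genotypes; a dense ascending rank is
#' attached.
#'
#' @param fit An [ammi_fit()] with at least two axes and a nonzero second
#'   singular value.
#' @return Tibble with `genotype`, `asv`, `rank`.
#' @export
asv <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (length(fit$singulars) < 2) {
    stop("ASV needs at least two interaction axes", call. = FALSE)
  }
  if (fit$singulars[2] == 0) {
    stop("second-axis interaction SS is zero; ASV undefined", call. = FALSE)
  }
  w <- fit$singulars[1]^2 / fit$singulars[2]^2
  s <- fit$gen_scores
  val <- sqrt((w * s[, 1])^2 + s[, 2]^2)
  tibble::tibble(
    genotype = rownames(s),
    asv = unname(val),
    rank = match(val, sort(unique(val)))
  )
}
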