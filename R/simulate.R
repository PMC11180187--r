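#' Specification for a simulated split-plot MET
#'
#' Collects the parameters of the generative model used throughout the test
#' suite: a balanced multi-environment trial with additive genotype and
#' environment effects, a planted low-rank bilinear genotype-by-environment
#' interaction, and iid plot error,
#' \deqn{y_{ijr} = \mu + g_i + e_j + \sum_k \lambda_k \alpha_{ik} \gamma_{jk}
#'   + \varepsilon_{ijr}.}
#' The interaction score vectors \eqn{\alpha_k} (genotypes) and
#' \eqn{\gamma_k} (environments) are orthonormal and sum to zero, matching
#' the identifiability constraints the AMMI decomposition imposes, so the
#' planted singular values are exactly what a noise-free AMMI fit recovers.
#'
#' Defaults mirror the rice trial the package's fixtures come from: 5
#' genotypes, 9 environments, 3 replicates, a grand mean of 4.85 t/ha,
#' genotype/environment effect spreads like the fixture margins, interaction
#' singular values sized to the fixture's GEI sum of squares, and a plot
#' error giving a cell-mean coefficient of variation near 5%.
#'
#' @param g,e,r Numbers of genotypes, environments, replicates.
#' @param mu Grand mean (t/ha for yield-like traits).
#' @param sigma_gen,sigma_env,sigma_err Standard deviations of genotype
#'   effects, environment effects and plot error.
#' @param gei_rank Rank k of the planted interaction, `0 <= k <= min(g-1, e-1)`.
#' @param gei_singulars Nonincreasing vector of k interaction singular values
#'   (on the cell-means scale).
#' @param seed Integer seed; one RNG stream drives every draw.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(g = 5, e = 9, r = 3, mu = 4.85,
                           sigma_gen = 0.13, sigma_env = 0.30,
                           sigma_err = 0.42,
                           gei_rank = 2, gei_singulars = c(1.0, 0.6),
                           seed = 1L) {
  if (gei_rank > min(g - 1, e - 1)) {
    stop("gei_rank must be <= min(g-1, e-1) = ", min(g - 1, e - 1),
         call. = FALSE)
  }
  gei_singulars <- as.numeric(gei_singulars)[seq_len(gei_rank)]
  if (gei_rank > 0) {
    if (any(is.na(gei_singulars)) || any(gei_singulars < 0) ||
        is.unsorted(rev(gei_singulars))) {
      stop("gei_singulars must be k nonnegative values in nonincreasing order",
           call. = FALSE)
    }
  }
  stopifnot(g >= 2, e >= 2, r >= 1, sigma_gen >= 0, sigma_env >= 0,
            sigma_err >= 0)
  structure(list(g = g, e = e, r = r, mu = mu, sigma_gen = sigma_gen,
                 sigma_env = sigma_env, sigma_err = sigma_err,
                 gei_rank = gei_rank, gei_singulars = gei_singulars,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# centered orthonormal score matrix: n x k, columns sum to zero,
# crossprod = identity (QR of a column-centred Gaussian draw)
centered_orthonormal <- function(n, k) {
  if (k == 0) return(matrix(0, n, 0))
  z <- matrix(stats::rnorm(n * (k + 1L)), n, k + 1L)
  z <- sweep(z, 2, colMeans(z))
  q <- qr.Q(qr(z))[, seq_len(k), drop = FALSE]
  # qr can flip spans; re-centre defensively and re-orthonormalize
  q <- sweep(q, 2, colMeans(q))
  qr.Q(qr(q))[, seq_len(k), drop = FALSE]
}

#' Simulate a balanced split-plot MET with planted structure
#'
#' Draws one trial from the model in [synthetic_spec()] and returns both the
#' replicate-level data and the truth record of every planted parameter, so
#' downstream estimates can be checked against what was planted.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `trial` (a [trial_table()] with trait `GY`) and `truth`
#'   (mu, gen_eff, env_eff, lambda, alpha, gamma, sigma_err, and the
#'   noise-free cell means `cell_means`).
#' @examples
#' sim <- simulate_met(synthetic_spec(seed = 42))
#' m <- to_means(sim$trial, "GY")
#' @export
simulate_met <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  g <- spec$g; e <- spec$e; r <- spec$r; k <- spec$gei_rank
  gen_eff <- stats::rnorm(g, 0, spec$sigma_gen)
  env_eff <- stats::rnorm(e, 0, spec$sigma_env)
  alpha <- centered_orthonormal(g, k)
  gamma <- centered_orthonormal(e, k)
  gei <- if (k > 0) {
    alpha %*% (spec$gei_singulars * t(gamma))
  } else matrix(0, g, e)
  cell <- spec$mu + outer(gen_eff, env_eff, `+`) + gei
  dimnames(cell) <- list(paste0("G", seq_len(g)), paste0("E", seq_len(e)))

  df <- expand.grid(REP = paste0("R", seq_len(r)),
                    GEN = rownames(cell), ENV = colnames(cell),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu_cell <- cell[cbind(df$GEN, df$ENV)]
  df$GY <- mu_cell + stats::rnorm(nrow(df), 0, spec$sigma_err)
  trial <- trial_table(df[c("ENV", "GEN", "REP", "GY")])
  truth <- list(mu = spec$mu, gen_eff = gen_eff, env_eff = env_eff,
                lambda = spec$gei_singulars, alpha = alpha, gamma = gamma,
                sigma_err = spec$sigma_err, cell_means = cell)
  list(trial = trial, truth = truth)
}

#' Simulate a multi-trait MET with correlated genotype effects
#'
#' Generates one balanced trial with several traits whose genotype effects
#' are drawn jointly from a multivariate normal with a requested between-trait
#' correlation, and whose entry-mean heritabilities are planted by sizing the
#' plot error per trait: for trait t with genetic variance
#' \eqn{\sigma^2_{g,t}}, the error variance is set to
#' \eqn{r e \, \sigma^2_{g,t} (1 - h^2_t) / h^2_t}, which makes the expected
#' entry-mean heritability \eqn{h^2_t} (no trait-specific interaction is
#' planted). Trait scales default to values typical of rice agronomy (plant
#' height in cm, effective tillers, panicle length in cm, thousand-grain
#' weight in g, days to maturity, grain yield in t/ha).
#'
#' @param g,e,r Design sizes.
#' @param traits Data frame with columns `label`, `sense` (`"increase"` or
#'   `"decrease"`), `h2` (entry-mean heritability in `[0, 1]`), and optionally
#'   `mean` and `sigma_g` (genetic SD; defaults to 5% of the mean).
#' @param trait_cor Between-trait genotype-effect correlation matrix
#'   (positive definite), or `NULL` for independence.
#' @param seed Integer seed.
#' @return A [trial_table()] with one column per trait; the planted genotype
#'   effect matrix is attached as attribute `truth`.
#' @export
simulate_multitrait <- function(g = 5, e = 9, r = 3,
                                traits = default_traits(),
                                trait_cor = NULL, seed = 1L) {
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) >= 2, all(c("label", "sense", "h2") %in% names(traits)))
  if (any(traits$h2 < 0 | traits$h2 > 1)) {
    stop("h2 must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(traits$mean)) traits$mean <- 100
  if (is.null(traits$sigma_g)) traits$sigma_g <- 0.05 * abs(traits$mean)
  t_n <- nrow(traits)
  if (is.null(trait_cor)) trait_cor <- diag(t_n)
  eg <- eigen(trait_cor, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    stop("trait_cor is not positive definite", call. = FALSE)
  }
  # PSD square root: permits perfectly correlated (rank-deficient) traits
  ch <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  set.seed(as.integer(seed))
  # genotype effects: g x t, unit variance, requested correlation, then scaled
  geff <- matrix(stats::rnorm(g * t_n), g, t_n) %*% ch
  geff <- sweep(geff, 2, traits$sigma_g, `*`)
  env_eff <- matrix(stats::rnorm(e * t_n), e, t_n)
  env_eff <- sweep(env_eff, 2, 0.05 * abs(traits$mean), `*`)

  df <- expand.grid(REP = paste0("R", seq_len(r)),
                    GEN = paste0("G", seq_len(g)),
                    ENV = paste0("E", seq_len(e)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(df$GEN, paste0("G", seq_len(g)))
  ej <- match(df$ENV, paste0("E", seq_len(e)))
  for (t_i in seq_len(t_n)) {
    h2 <- traits$h2[t_i]
    sg2 <- traits$sigma_g[t_i]^2
    if (h2 == 0) {
      sig_err <- sqrt(sg2) * sqrt(r * e)  # all-noise trait
      gcol <- rep(0, g)
    } else {
      sig_err <- sqrt(r * e * sg2 * (1 - h2) / h2)
      gcol <- geff[, t_i]
    }
    df[[traits$label[t_i]]] <- traits$mean[t_i] + gcol[gi] +
      env_eff[ej, t_i] + stats::rnorm(nrow(df), 0, sig_err)
  }
  out <- trial_table(df[c("ENV", "GEN", "REP", traits$label)])
  attr(out, "truth") <- list(gen_eff = geff, env_eff = env_eff,
                             traits = traits)
  out
}

#' Default multi-trait panel for simulation
#'
#' Six traits with scales typical of a rice agronomy trial; heritabilities
#' in the moderate range reported for such traits.
#'
#' @return Data frame with columns label, sense, h2, mean.
#' @export
default_traits <- function() {
  data.frame(
    label = c("PH", "ET", "PL", "TGW", "DM", "GY"),
    sense = c("increase", "increase", "increase", "increase", "increase",
              "increase"),
    h2 = c(0.7, 0.35, 0.5, 0.75, 0.6, 0.4),
    mean = c(97, 12.8, 24.9, 24.9, 144, 4.85),
    stringsAsFactors = FALSE
  )
}
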