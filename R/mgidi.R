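#' Rescale traits to a 0-100 desirability scale
#'
#' Each trait is mapped linearly onto [0, 100] with 100 at the desirable
#' extreme: the maximum for traits declared `"increase"`, the minimum for
#' `"decrease"`. Rescaled traits are the input to the MGIDI factor analysis,
#' putting all traits on a common footing regardless of units or direction.
#'
#' @param x Genotypes x traits numeric matrix (or data frame) with dimnames.
#' @param sense Character vector (`"increase"`/`"decrease"`), one per trait,
#'   recycled if length 1.
#' @return Matrix of the same shape on the 0-100 scale.
#' @export
rescale_traits <- function(x, sense = "increase") {
  x <- as.matrix(x)
  t_n <- ncol(x)
  sense <- rep_len(match.arg(sense, c("increase", "decrease"),
                             several.ok = TRUE), t_n)
  out <- x
  for (j in seq_len(t_n)) {
    rng <- range(x[, j])
    if (diff(rng) == 0) {
      stop("trait ", colnames(x)[j] %||% j, " is constant; cannot rescale",
           call. = FALSE)
    }
    v <- 100 * (x[, j] - rng[1]) / diff(rng)
    out[, j] <- if (sense[j] == "increase") v else 100 - v
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moore-Penrose pseudoinverse; handles the rank-deficient correlation
# matrices that arise whenever genotypes <= traits
pinv <- function(a, tol = sqrt(.Machine$double.eps)) {
  s <- svd(a)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) stop("correlation matrix is numerically zero", call. = FALSE)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Exploratory factor analysis for the MGIDI index
#'
#' Eigen-decomposes the correlation matrix of the rescaled traits, retains
#' the factors with initial eigenvalue >= 1 (Kaiser criterion), varimax-
#' rotates the retained loadings (Kaiser normalization) and computes
#' genotype scores by the regression method on the standardized rescaled
#' traits. The rotation sign of each factor is fixed so its largest-
#' magnitude loading is positive. The ideotype -- 100 on every trait -- is
#' passed through the same standardization and scoring map. A Moore-Penrose
#' pseudoinverse of the correlation matrix is used in the regression scores,
#' so more traits than genotypes is allowed.
#'
#' @param rescaled Genotypes x traits matrix from [rescale_traits()].
#' @return Object of class `factor_model`: `loadings` (traits x factors,
#'   rotated), `eigenvalues` (all initial), `pct_var`, `cum_pct`,
#'   `communality`, `uniqueness`, `scores` (genotypes x factors),
#'   `ideotype_scores`.
#' @export
factor_analysis <- function(rescaled) {
  x <- as.matrix(rescaled)
  if (is.null(colnames(x))) colnames(x) <- paste0("T", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("G", seq_len(nrow(x)))
  r_mat <- stats::cor(x)
  if (anyNA(r_mat)) stop("correlation matrix not computable", call. = FALSE)
  eig <- eigen(r_mat, symmetric = TRUE)
  eval <- pmax(eig$values, 0)
  nf <- max(1L, sum(eval >= 1))
  load <- eig$vectors[, seq_len(nf), drop = FALSE] *
    rep(sqrt(eval[seq_len(nf)]), each = ncol(x))
  if (nf > 1) {
    load <- stats::varimax(load, normalize = TRUE)$loadings[]
  }
  for (f in seq_len(nf)) {         # rotation sign is arbitrary; fix it
    if (load[which.max(abs(load[, f])), f] < 0) load[, f] <- -load[, f]
  }
  dimnames(load) <- list(colnames(x), paste0("FA", seq_len(nf)))
  communality <- rowSums(load^2)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  z <- scale(x, center = ctr, scale = scl)
  beta <- pinv(r_mat) %*% load          # regression-method score weights
  scores <- z %*% beta
  ideo_z <- (rep(100, ncol(x)) - ctr) / scl
  ideo <- as.vector(t(ideo_z) %*% beta)
  dimnames(scores) <- list(rownames(x), colnames(load))
  structure(list(loadings = load,
                 eigenvalues = eval,
                 pct_var = 100 * eval / sum(eval),
                 cum_pct = cumsum(100 * eval / sum(eval)),
                 communality = communality,
                 uniqueness = 1 - communality,
                 scores = scores,
                 ideotype_scores = ideo,
                 rescaled = x),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Factor model:", ncol(x$loadings), "retained factor(s) of",
      length(x$eigenvalues), "traits\n")
  cat("Eigenvalues:", sprintf("%.2f", x$eigenvalues), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Multi-trait genotype-ideotype distance index
#'
#' Ranks genotypes by the Euclidean distance between their factor scores
#' and the ideotype's,
#' \deqn{MGIDI_i = \sqrt{\sum_f (s_{if} - s^{ideo}_f)^2},}
#' and selects the `max(1, round(pressure * g))` closest. Base means (Xo)
#' and selected means (Xs) per trait are reported on the original scale when
#' `original` is supplied, else on the rescaled scale.
#'
#' @param model A [factor_analysis()] fit.
#' @param pressure Selection pressure in (0, 1]; default 0.2.
#' @param original Optional genotypes x traits matrix on the original scale
#'   (same row order as the model's data).
#' @return Object of class `mgidi_result`: `index` tibble (genotype,
#'   distance, rank, selected), `Xo`, `Xs` per trait, `n_selected`.
#' @export
mgidi_index <- function(model, pressure = 0.2, original = NULL) {
  stopifnot(inherits(model, "factor_model"))
  if (!is.numeric(pressure) || length(pressure) != 1 ||
      pressure <= 0 || pressure > 1) {
    stop("pressure must lie in (0, 1]", call. = FALSE)
  }
  dev <- sweep(model$scores, 2, model$ideotype_scores)
  dist <- sqrt(rowSums(dev^2))
  g <- length(dist)
  n_sel <- max(1L, round(pressure * g))
  ord <- order(dist, rownames(model$scores))
  rk <- integer(g); rk[ord] <- seq_len(g)
  selected <- rk <= n_sel
  xmat <- if (is.null(original)) model$rescaled else as.matrix(original)
  xo <- colMeans(xmat)
  xs <- colMeans(xmat[selected, , drop = FALSE])
  structure(list(
    index = tibble::tibble(genotype = rownames(model$scores),
                           distance = unname(dist), rank = rk,
                           selected = selected),
    Xo = xo, Xs = xs, n_selected = n_sel),
    class = "mgidi_result")
}

#' @export
print.mgidi_result <- function(x, ...) {
  cat("MGIDI ranking (", x$n_selected, " selected):\n", sep = "")
  print(x$index[order(x$index$rank), ])
  invisible(x)
}

#' Selection differentials and gains
#'
#' For each trait: SD = Xs - Xo (selected minus base mean), SDperc =
#' 100 SD / Xo, SG = SD x h2 (expected response given the trait's
#' heritability), SGperc = 100 SG / Xo. Heritabilities supplied as percent
#' (> 1) are divided by 100. Totals split the percent gains into those
#' aligned with the declared sense ("T. Increase" when the goal is to
#' increase) and misaligned ones ("T. decrease").
#'
#' @param Xo,Xs Named per-trait base and selected means; `Xs` may be omitted
#'   when `SD` is given directly.
#' @param h2 Per-trait heritability in `[0, 1]` (or percent).
#' @param sense Per-trait `"increase"`/`"decrease"`, recycled.
#' @param SD Optional per-trait selection differential, overriding Xs - Xo.
#' @return Tibble with trait, Xo, Xs, SD, SDperc, h2, SG, SGperc, sense;
#'   attribute `totals` = c(aligned, misaligned).
#' @export
selection_gains <- function(Xo, Xs = NULL, h2, sense = "increase",
                            SD = NULL) {
  if (is.null(SD)) {
    if (is.null(Xs)) stop("supply either Xs or SD", call. = FALSE)
    SD <- Xs - Xo
  } else if (is.null(Xs)) {
    Xs <- Xo + SD
  }
  if (any(Xo == 0)) stop("Xo must be nonzero for percent gains",
                         call. = FALSE)
  h2 <- ifelse(h2 > 1, h2 / 100, h2)
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]", call. = FALSE)
  t_n <- length(Xo)
  sense <- rep_len(match.arg(sense, c("increase", "decrease"),
                             several.ok = TRUE), t_n)
  sg <- SD * h2
  sgp <- 100 * sg / Xo
  aligned <- (sense == "increase" & sgp >= 0) |
             (sense == "decrease" & sgp < 0)
  out <- tibble::tibble(
    trait = names(Xo) %||% paste0("T", seq_len(t_n)),
    Xo = unname(Xo), Xs = unname(Xs), SD = unname(SD),
    SDperc = unname(100 * SD / Xo), h2 = unname(h2),
    SG = unname(sg), SGperc = unname(sgp), sense = sense)
  attr(out, "totals") <- c(aligned = sum(sgp[aligned]),
                           misaligned = sum(sgp[!aligned]))
  out
}

#' Strengths and weaknesses: factor contributions to MGIDI
#'
#' The share of genotype i's squared distance carried by factor f,
#' \eqn{(s_{if} - s^{ideo}_f)^2 / MGIDI_i^2}. Shares sum to 1 per genotype;
#' a small share marks a factor on which the genotype is close to the
#' ideotype (a strength). A genotype at distance 0 gets uniform shares and
#' is flagged.
#'
#' @param model A [factor_analysis()] fit.
#' @param result The matching [mgidi_index()] result.
#' @return Tibble: genotype, factor, contribution, degenerate flag.
#' @export
strengths_weaknesses <- function(model, result) {
  stopifnot(inherits(model, "factor_model"), inherits(result, "mgidi_result"))
  dev2 <- sweep(model$scores, 2, model$ideotype_scores)^2
  d2 <- rowSums(dev2)
  nf <- ncol(dev2)
  prop <- dev2 / ifelse(d2 > 0, d2, 1)
  degen <- d2 == 0
  prop[degen, ] <- 1 / nf
  tibble::tibble(
    genotype = rep(rownames(dev2), times = nf),
    factor = rep(colnames(model$loadings), each = nrow(dev2)),
    contribution = as.vector(prop),
    degenerate = rep(degen, times = nf))
}

#' One-call MGIDI analysis
#'
#' Convenience wrapper: rescale, factor-analyse, compute the index at the
#' given pressure, and (when heritabilities are supplied) the selection
#' gains on the original scale.
#'
#' @param x Genotypes x traits matrix of means on the original scale.
#' @param sense Per-trait sense.
#' @param h2 Optional per-trait heritability for gains.
#' @param pressure Selection pressure.
#' @return List with `model`, `result`, `gains` (or NULL), `contributions`.
#' @export
mgidi <- function(x, sense = "increase", h2 = NULL, pressure = 0.2) {
  x <- as.matrix(x)
  resc <- rescale_traits(x, sense)
  model <- factor_analysis(resc)
  result <- mgidi_index(model, pressure = pressure, original = x)
  gains <- if (!is.null(h2)) {
    selection_gains(result$Xo, result$Xs, h2 = h2,
                    sense = rep_len(sense, ncol(x)))
  }
  list(model = model, result = result, gains = gains,
       contributions = strengths_weaknesses(model, result))
}
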