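#' Fit a GGE biplot model
#'
#' Singular value decomposition of the environment-centred means matrix
#' \eqn{x_{ij} - \bar x_{.j}}, which retains genotype main effects plus
#' genotype-by-environment interaction ("G+GE") while removing environment
#' main effects. Axis shares are computed against the total G+GE sum of
#' squares over all nonzero axes. No column scaling is applied.
#'
#' Singular-value partitioning (`svp`) controls where \eqn{\lambda} goes:
#' `"genotype"`-focused scales genotype scores by \eqn{\lambda} (preferred
#' for comparing genotypes), `"environment"`-focused scales environment
#' scores (preferred for comparing environments), `"symmetric"` gives each
#' side \eqn{\sqrt\lambda} (preferred for which-won-where views). Axis signs
#' are oriented so each axis's largest-magnitude environment score is
#' positive.
#'
#' @param m A [means_matrix()].
#' @param svp `"symmetric"`, `"genotype"` or `"environment"`.
#' @return Object of class `gge_fit`: `gen_scores`, `env_scores` (2-axis,
#'   scaled per `svp`), `pct` (axis shares, all axes), `svp`, `d` (singular
#'   values) and the unscaled `u`, `v`.
#' @examples
#' fit <- gge_fit(yield_fixture("AWD"))
#' fit$pct[1:2]
#' @export
gge_fit <- function(m, svp = c("symmetric", "genotype", "environment")) {
  stopifnot(inherits(m, "means_matrix"))
  svp <- match.arg(svp)
  x <- unclass_means(m)
  g <- nrow(x); e <- ncol(x)
  cx <- sweep(x, 2, colMeans(x))
  sv <- svd(cx)
  d <- sv$d
  tol <- max(dim(cx)) * max(d, 0) * .Machine$double.eps
  nz <- sum(d > tol)
  if (nz == 0) warning("degenerate GGE fit: matrix has no G+GE variation")
  pct <- if (sum(d^2) > 0) 100 * d^2 / sum(d^2) else rep(NA_real_, length(d))
  u <- sv$u; v <- sv$v
  for (k in seq_len(min(2, ncol(v)))) {
    if (v[which.max(abs(v[, k])), k] < 0) {
      u[, k] <- -u[, k]; v[, k] <- -v[, k]
    }
  }
  d2 <- d[1:2]
  gs <- switch(svp,
    genotype    = u[, 1:2] * rep(d2, each = g),
    environment = u[, 1:2],
    symmetric   = u[, 1:2] * rep(sqrt(d2), each = g))
  es <- switch(svp,
    genotype    = v[, 1:2],
    environment = v[, 1:2] * rep(d2, each = e),
    symmetric   = v[, 1:2] * rep(sqrt(d2), each = e))
  dimnames(gs) <- list(rownames(x), c("PC1", "PC2"))
  dimnames(es) <- list(colnames(x), c("PC1", "PC2"))
  structure(list(gen_scores = gs, env_scores = es, pct = pct, svp = svp,
                 d = d, u = u, v = v, centered = cx,
                 trait = attr(m, "trait")),
            class = "gge_fit")
}

#' @export
print.gge_fit <- function(x, ...) {
  cat("GGE fit (", x$trait, "), svp = ", x$svp, "\n", sep = "")
  cat("PC1/PC2 share of G+GE (%):",
      sprintf("%.2f / %.2f", x$pct[1], x$pct[2]), "\n")
  invisible(x)
}

#' Which-won-where polygon and sectors
#'
#' Builds the convex hull of the 2-axis genotype scores; the winning
#' genotype of each environment is the hull vertex with the largest inner
#' product with that environment's score vector (the 2-axis fitted G+GE
#' value, up to the common environment scaling), with ties broken by label
#' order.
#'
#' @param fit A [gge_fit()] with at least 3 genotypes.
#' @return List with `polygon` (ordered hull vertex labels) and `sectors`
#'   (tibble: environment, winner).
#' @export
which_won_where <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  gs <- fit$gen_scores
  if (nrow(gs) < 3) stop("which-won-where needs at least 3 genotypes",
                         call. = FALSE)
  if (qr(sweep(gs, 2, colMeans(gs)))$rank < 2) {
    stop("genotype scores are collinear; hull is degenerate", call. = FALSE)
  }
  hull_idx <- grDevices::chull(gs[, 1], gs[, 2])
  hull <- rownames(gs)[hull_idx]
  es <- fit$env_scores
  winner <- vapply(seq_len(nrow(es)), function(j) {
    ip <- gs[hull_idx, , drop = FALSE] %*% es[j, ]
    cand <- hull[ip == max(ip)]
    sort(cand)[1]
  }, character(1))
  list(polygon = hull,
       sectors = tibble::tibble(environment = rownames(es), winner = winner))
}

# unit vector toward the average environment score; errors if ~0
aec_axis <- function(fit) {
  a <- colMeans(fit$env_scores)
  n <- sqrt(sum(a^2))
  if (n < 1e-10) {
    stop("average environment score is ~0; AEC axis undefined", call. = FALSE)
  }
  a / n
}

#' Mean performance vs stability along the average environment coordinate
#'
#' The AEC axis is the direction of the average environment score. A
#' genotype's projection onto it orders genotypes by (2-axis fitted) mean
#' performance; its perpendicular distance measures instability.
#'
#' @param fit A [gge_fit()] (genotype-focused svp recommended).
#' @return Tibble with `genotype`, `mean_proj`, `stability` (perpendicular
#'   distance, >= 0).
#' @export
mean_vs_stability <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  a <- aec_axis(fit)
  gs <- fit$gen_scores
  proj <- as.vector(gs %*% a)
  perp <- gs - outer(proj, a)
  tibble::tibble(genotype = rownames(gs),
                 mean_proj = proj,
                 stability = unname(sqrt(rowSums(perp^2))))
}

#' Rank genotypes by distance to the ideal genotype
#'
#' The ideal genotype sits on the AEC axis at the largest observed genotype
#' projection (highest mean performance, zero instability); genotypes are
#' ranked by Euclidean distance to it.
#'
#' @param fit A [gge_fit()] (genotype-focused svp recommended).
#' @return Tibble ordered by rank: `genotype`, `distance`, `rank`.
#' @export
ideal_genotype_ranking <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  a <- aec_axis(fit)
  gs <- fit$gen_scores
  ideal <- a * max(as.vector(gs %*% a))
  dist <- sqrt(rowSums(sweep(gs, 2, ideal)^2))
  ord <- order(dist, rownames(gs))
  tibble::tibble(genotype = rownames(gs)[ord],
                 distance = unname(dist[ord]),
                 rank = seq_along(ord))
}

#' Rank environments by distance to the ideal environment
#'
#' The ideal environment lies along the AEC direction (most representative)
#' with the length of the longest environment vector (most discriminating).
#' Environments are ranked by distance to it; their vector length
#' (discriminativeness) and cosine with the AEC (representativeness) are
#' reported alongside.
#'
#' @param fit A [gge_fit()]; environment-focused svp recommended.
#' @return Tibble ordered by rank: `environment`, `distance`, `rank`,
#'   `discriminativeness`, `representativeness`.
#' @export
ideal_environment_ranking <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  a <- aec_axis(fit)
  es <- fit$env_scores
  len <- sqrt(rowSums(es^2))
  ideal <- a * max(len)
  dist <- sqrt(rowSums(sweep(es, 2, ideal)^2))
  repr <- as.vector(es %*% a) / ifelse(len > 0, len, NA_real_)
  ord <- order(dist, rownames(es))
  tibble::tibble(environment = rownames(es)[ord],
                 distance = unname(dist[ord]),
                 rank = seq_along(ord),
                 discriminativeness = unname(len[ord]),
                 representativeness = unname(repr[ord]))
}
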