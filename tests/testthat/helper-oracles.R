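# Independent brute-force oracles used across test files. These deliberately
# re-derive quantities with naive loops rather than calling package internals.

# random complete means matrix with controlled magnitudes
random_means <- function(g = 5, e = 9, mu = 5, spread = 0.5) {
  x <- mu + matrix(stats::runif(g * e, -spread, spread), g, e)
  means_matrix(x, n_reps = 1L, trait = "GY")
}

# O(g * e^2) enumeration of Huehn's statistics from first principles
oracle_huehn <- function(x) {
  g <- nrow(x); e <- ncol(x)
  rk <- matrix(0, g, e)
  for (j in seq_len(e)) rk[, j] <- rank(-x[, j], ties.method = "average")
  xc <- x - rowMeans(x) + mean(x)
  rkc <- matrix(0, g, e)
  for (j in seq_len(e)) rkc[, j] <- rank(-xc[, j], ties.method = "average")
  s1 <- s2 <- s3 <- s6 <- numeric(g)
  for (i in seq_len(g)) {
    acc <- 0
    for (j in 1:(e - 1)) for (jp in (j + 1):e) {
      acc <- acc + abs(rk[i, j] - rk[i, jp])
    }
    s1[i] <- 2 * acc / (e * (e - 1))
    s2[i] <- sum((rk[i, ] - mean(rk[i, ]))^2) / (e - 1)
    rb <- mean(rkc[i, ])
    s3[i] <- sum((rkc[i, ] - rb)^2) / rb
    s6[i] <- sum(abs(rkc[i, ] - rb)) / rb
  }
  list(S1 = s1, S2 = s2, S3 = s3, S6 = s6)
}

# brute-force Thennarasu NP1-NP4 from the formula definitions
oracle_thennarasu <- function(x) {
  g <- nrow(x); e <- ncol(x)
  rk <- matrix(0, g, e)
  for (j in seq_len(e)) rk[, j] <- rank(-x[, j], ties.method = "average")
  xa <- x - (rowMeans(x) - mean(x))
  rka <- matrix(0, g, e)
  for (j in seq_len(e)) rka[, j] <- rank(-xa[, j], ties.method = "average")
  np1 <- np2 <- np3 <- np4 <- numeric(g)
  for (i in seq_len(g)) {
    mds <- stats::median(rka[i, ]); md <- stats::median(rk[i, ])
    mn_a <- mean(rka[i, ]); mn <- mean(rk[i, ])
    np1[i] <- mean(abs(rka[i, ] - mds))
    np2[i] <- mean(abs(rka[i, ] - mds)) / md
    np3[i] <- sqrt(sum((rka[i, ] - mn_a)^2) / e) / mn
    acc <- 0
    for (j in 1:(e - 1)) for (jp in (j + 1):e) {
      acc <- acc + abs(rka[i, j] - rka[i, jp])
    }
    np4[i] <- (2 / (e * (e - 1))) * acc / mn
  }
  list(NP1 = np1, NP2 = np2, NP3 = np3, NP4 = np4)
}

# loop-based replicate averaging (oracle for to_means)
oracle_cell_means <- function(df, trait) {
  envs <- unique(df$ENV); gens <- unique(df$GEN)
  out <- matrix(NA_real_, length(gens), length(envs),
                dimnames = list(gens, envs))
  for (i in gens) for (j in envs) {
    out[i, j] <- mean(df[[trait]][df$GEN == i & df$ENV == j])
  }
  out
}
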