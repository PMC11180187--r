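test_that("ecovalence partitions the GEI sum of squares", {
  x <- outer(1:4, 1:6, `+`)
  expect_equal(unname(ecovalence(means_matrix(x))), rep(0, 4),
               tolerance = 1e-20)
  m22 <- means_matrix(matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_equal(unname(ecovalence(m22)), c(0.5, 0.5))
  awd <- yield_fixture("AWD")
  expect_equal(sum(ecovalence(awd)),
               sum(ammi_fit(awd)$interaction^2), tolerance = 1e-10)
})

test_that("joint regression matches least squares and its limit cases", {
  # genotypes tracking the environment index exactly: b = 1, Sij = 0
  env <- c(3, 5, 4, 6, 2)
  x <- rbind(G1 = env, G2 = env + 1, G3 = env - 0.5)
  jr <- joint_regression(means_matrix(x))
  expect_equal(jr$b, rep(1, 3), tolerance = 1e-10)
  expect_equal(jr$Sij, rep(0, 3), tolerance = 1e-20)
  # a genotype constant over environments has zero slope
  x0 <- rbind(G1 = env, G2 = env + 1, G3 = env - 1, G4 = rep(4, 5))
  expect_equal(joint_regression(means_matrix(x0))$b[4], 0,
               tolerance = 1e-10)

  # lm oracle on the fixture
  awd <- yield_fixture("AWD")
  mm <- margin_means(awd)
  idx <- mm$environment - mm$grand
  jr2 <- joint_regression(awd)
  for (i in 1:5) {
    fit <- lm(unclass(awd)[i, ] ~ idx)
    expect_equal(jr2$b[i], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(jr2$Sij[i], sum(resid(fit)^2) / 7, tolerance = 1e-10)
  }

  # balanced data: slopes average to one
  set.seed(3)
  for (k in 1:5) {
    expect_equal(mean(joint_regression(random_means())$b), 1,
                 tolerance = 1e-10)
  }
})

test_that("Huehn statistics agree with brute-force enumeration", {
  # constant rank: S1 = S2 = 0
  x <- rbind(c(9, 9, 9), c(5, 5, 5), c(1, 1, 1))
  hs <- huehn_stats(means_matrix(x))
  expect_equal(hs$S1, rep(0, 3))
  expect_equal(hs$S2, rep(0, 3))

  # ranks (1, 2, 3) across three environments: S1 = 4/3
  x2 <- rbind(c(9, 5, 1), c(5, 9, 5.5), c(1, 1, 9))
  r1 <- apply(-x2, 2, rank)[1, ]
  stopifnot(identical(unname(r1), c(1, 2, 3)))
  expect_equal(huehn_stats(means_matrix(x2))$S1[1], 4 / 3)

  set.seed(13)
  for (k in 1:10) {
    m <- random_means()
    hs <- huehn_stats(m)
    o <- oracle_huehn(unclass(m))
    expect_equal(hs$S1, o$S1)
    expect_equal(hs$S2, o$S2)
    expect_equal(hs$S3, o$S3)
    expect_equal(hs$S6, o$S6)
  }
})

test_that("Thennarasu statistics agree with their formula oracle", {
  # identical adjusted behaviour: NP1 = 0
  x <- outer(c(1, 2, 3), c(0, 1, 0, 2), `+`)
  expect_equal(thennarasu_stats(means_matrix(x))$NP1, rep(0, 3))

  set.seed(37)
  for (k in 1:10) {
    m <- random_means()
    np <- thennarasu_stats(m)
    o <- oracle_thennarasu(unclass(m))
    expect_equal(np$NP1, o$NP1)
    expect_equal(np$NP2, o$NP2)
    expect_equal(np$NP3, o$NP3)
    expect_equal(np$NP4, o$NP4)
  }
})

test_that("rank statistics ignore monotone within-environment transforms", {
  set.seed(43)
  m <- random_means()
  tx <- unclass(m)
  for (j in 1:ncol(tx)) tx[, j] <- exp(1.7 * tx[, j]) + j
  mt <- means_matrix(tx)
  expect_equal(huehn_stats(mt)$S1, huehn_stats(m)$S1)
  expect_equal(huehn_stats(mt)$S2, huehn_stats(m)$S2)
  # NP statistics adjust by genotype means first, so only the raw-rank
  # pieces are transform invariant in general; S1/S2 use raw ranks only
})

test_that("superiority indexes and favorable split behave per definition", {
  # best genotype everywhere: Pi_a = 0
  x <- rbind(c(6, 7), c(4, 5))
  ps <- superiority(means_matrix(x))
  expect_equal(ps$Pi_a[1], 0)
  # one environment, values (4, 6): Pi = (6-4)^2 / 2 = 2 for the loser
  one <- superiority(means_matrix(cbind(c(4, 6))))
  expect_equal(one$Pi_a[2], 0)
  expect_equal(one$Pi_a[1], 2)

  awd <- superiority(yield_fixture("AWD"))
  expect_equal(names(which(attr(awd, "favorable"))),
               c("E1", "E2", "E4", "E7", "E9"))
  # decomposition: favorable + unfavorable squared sums equal the total
  fav <- attr(awd, "favorable")
  expect_equal(awd$Pi_a * 2 * 9,
               awd$Pi_f * 2 * sum(fav) + awd$Pi_u * 2 * sum(!fav),
               tolerance = 1e-12)
})

test_that("geometric adaptability is the geometric mean", {
  expect_equal(unname(gai(means_matrix(matrix(3, 2, 4)))), c(3, 3))
  expect_equal(unname(gai(means_matrix(rbind(c(1, 4), c(2, 2)))))[1], 2)
  awd <- yield_fixture("AWD")
  expect_equal(gai(awd)[["G3"]], exp(mean(log(unclass(awd)["G3", ]))))
  expect_error(gai(means_matrix(rbind(c(1, -1), c(1, 1)))), "positive")
})

test_that("BLUP stability shrinks toward the environment mean", {
  # all genotypes identical: RPGV = HMRPGV = 1
  df <- expand.grid(ENV = paste0("E", 1:4), GEN = paste0("G", 1:3),
                    REP = paste0("R", 1:2), stringsAsFactors = FALSE)
  df$GY <- 5 + as.integer(factor(df$ENV)) * 0.3
  bl <- suppressWarnings(blup_stability(trial_table(df), "GY"))
  expect_equal(bl$RPGV, rep(1, 3), tolerance = 1e-12)
  expect_equal(bl$HMRPGV, rep(1, 3), tolerance = 1e-12)

  # zero error, zero GEI, flat environments: exact mean ratio, no shrinkage
  df2 <- df
  geff <- c(0.5, 0, -0.5)[as.integer(factor(df2$GEN))]
  df2$GY <- 5 + geff
  bl2 <- blup_stability(trial_table(df2), "GY")
  expect_equal(bl2$RPGV, (5 + c(0.5, 0, -0.5)) / 5, tolerance = 1e-10)

  # heavy noise shrinks the spread below the raw mean ratios
  sim <- simulate_met(synthetic_spec(sigma_err = 2, sigma_gen = 0.1,
                                     seed = 77))
  m <- to_means(sim$trial, "GY")
  mm <- margin_means(m)
  bl3 <- suppressWarnings(blup_stability(sim$trial, "GY"))
  raw_ratio <- mm$genotype / mm$grand
  expect_lt(diff(range(bl3$RPGV)) + 1e-12, diff(range(raw_ratio)))
  vc <- attr(bl3, "varcomp")
  expect_true(vc$c_g >= 0 && vc$c_g <= 1 && vc$c_ge >= 0 && vc$c_ge <= 1)
})

test_that("stability table assembles all measures with ranks", {
  sim <- simulate_met(synthetic_spec(seed = 55))
  m <- to_means(sim$trial, "GY")
  st <- stability_table(m, sim$trial)
  expect_true(all(c("Y", "W2", "b", "Sij", "S1", "S2", "S3", "S6",
                    "NP1", "NP2", "NP3", "NP4", "Pi_a", "Pi_f", "Pi_u",
                    "GAI", "ASV", "RPGV", "HMRPGV") %in% names(st$values)))
  expect_equal(dim(st$ranks), dim(st$values))
  expect_true(all(st$values$W2 >= 0))
  expect_true(all(st$values$Pi_a >= 0))
  # rank direction: best yield gets rank 1 on Y
  expect_equal(st$ranks$Y[which.max(st$values$Y)], 1)
})

test_that("Spearman correlations among measures behave as expected", {
  tbl <- data.frame(a = 1:5, b = c(2, 4, 6, 8, 10), c = 5:1)
  cm <- stability_correlations(tbl)
  expect_equal(cm["a", "a"], 1)
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)

  sim <- simulate_met(synthetic_spec(gei_singulars = c(1.5, 0.9), seed = 66))
  st <- stability_table(to_means(sim$trial, "GY"), sim$trial)
  cm2 <- stability_correlations(st)
  expect_gt(cm2["RPGV", "HMRPGV"], 0.9)
})
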