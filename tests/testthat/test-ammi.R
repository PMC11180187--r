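test_that("fixture decompositions match the published GEI shares", {
  awd <- ammi_fit(yield_fixture("AWD"))
  expect_lt(max(abs(awd$pct_gei - c(59.8, 25.7, 9.5, 4.9))), 1.5)
  expect_lt(abs(awd$cum_pct[2] - 85.5), 1.5)

  cf <- ammi_fit(yield_fixture("CF"))
  expect_lt(abs(cf$pct_gei[1] - 66.6), 1.5)
  expect_lt(abs(cf$cum_pct[2] - 91.6), 1.5)
})

test_that("additive data give a null interaction", {
  x <- outer(1:5, seq(2, 4, length.out = 7), `+`)
  fit <- ammi_fit(means_matrix(x))
  expect_equal(sum(fit$interaction^2), 0, tolerance = 1e-24)
  expect_equal(fit$singulars, rep(0, 4), tolerance = 1e-12)
  expect_true(all(is.na(fit$pct_gei)))
})

test_that("SVD reconstruction and centering identities hold", {
  set.seed(17)
  for (i in 1:5) {
    m <- random_means()
    fit <- ammi_fit(m)
    # symmetric partition: product of score matrices rebuilds Z exactly
    expect_equal(fit$gen_scores %*% t(fit$env_scores), fit$interaction,
                 tolerance = 1e-10)
    expect_lt(max(abs(rowSums(fit$interaction))), 1e-10)
    expect_lt(max(abs(colSums(fit$interaction))), 1e-10)
    expect_equal(sum(fit$pct_gei), 100, tolerance = 1e-9)
    # 2-axis truncation leaves the complementary share as residual SS
    resid <- fit$interaction -
      fit$gen_scores[, 1:2] %*% t(fit$env_scores[, 1:2])
    expect_equal(sum(resid^2),
                 (1 - fit$cum_pct[2] / 100) * sum(fit$interaction^2),
                 tolerance = 1e-10)
  }
})

test_that("GEI shares ignore constants and main effects", {
  set.seed(23)
  m <- random_means()
  base <- ammi_fit(m)$pct_gei
  shifted <- unclass(m) + 7 + outer(rnorm(5), rep(0, 9), `+`) +
    outer(rep(0, 5), rnorm(9), `+`)
  expect_equal(ammi_fit(means_matrix(shifted))$pct_gei, base,
               tolerance = 1e-9)
})

test_that("replicate data complete the ANOVA with Gollob tests", {
  sim <- simulate_met(synthetic_spec(seed = 12))
  m <- to_means(sim$trial, "GY")
  fit <- ammi_fit(m, sim$trial)
  an <- fit$anova
  expect_equal(an$df[an$source %in% c("ENV", "REP(ENV)", "GEN", "GEI")],
               c(8, 18, 4, 32))
  expect_equal(an$df[grepl("^PC", an$source)], c(11, 9, 7, 5))
  expect_equal(an$df[an$source == "Residuals"], 72)
  # SS add up: ENV + REP(ENV) + GEN + GEI + error = total
  y <- sim$trial$GY
  expect_equal(sum(an$SS[an$source != "GEI" | TRUE][c(1:4, nrow(an))]),
               sum((y - mean(y))^2), tolerance = 1e-8)
  expect_equal(sum(an$SS[grepl("^PC", an$source)]),
               an$SS[an$source == "GEI"], tolerance = 1e-8)
  expect_true(all(is.finite(an$p[an$source %in% c("GEN", "GEI", "PC1")])))
  # means-only fit leaves F and p unavailable
  expect_true(all(is.na(ammi_fit(m)$anova$F)))
})

test_that("Gollob PC1 test is liberal under the null but has power", {
  set.seed(41)
  pnull <- replicate(120, {
    sim <- simulate_met(synthetic_spec(gei_rank = 0, sigma_err = 0.3,
                                       seed = sample.int(2^30, 1)))
    fit <- ammi_fit(to_means(sim$trial, "GY"), sim$trial)
    fit$anova$p[fit$anova$source == "PC1"]
  })
  palt <- replicate(40, {
    sim <- simulate_met(synthetic_spec(gei_rank = 1, gei_singulars = 1.5,
                                       sigma_err = 0.3,
                                       seed = sample.int(2^30, 1)))
    fit <- ammi_fit(to_means(sim$trial, "GY"), sim$trial)
    fit$anova$p[fit$anova$source == "PC1"]
  })
  null_rate <- mean(pnull < 0.05)
  expect_gt(null_rate, 0.03)    # not conservative
  expect_lt(null_rate, 0.45)    # liberal but bounded at this design size
  expect_gt(mean(palt < 0.05), null_rate)
})

test_that("AMMI1 coordinates pair margins with first scores", {
  awd <- yield_fixture("AWD")
  fit <- ammi_fit(awd)
  co <- ammi1_coords(fit)
  expect_equal(co$mean[co$type == "gen"],
               unname(margin_means(awd)$genotype))
  # oracle: direct SVD of the doubly-centred table
  mm <- margin_means(awd)
  z <- unclass(awd) - outer(mm$genotype, mm$environment, `+`) + mm$grand
  sv <- svd(z)
  oracle_ipca1 <- abs(sv$u[, 1] * sqrt(sv$d[1]))
  expect_equal(abs(co$ipca1[co$type == "gen"]), unname(oracle_ipca1),
               tolerance = 1e-10)
  # smallest two |IPCA1| genotypes per the oracle
  small2 <- co$label[co$type == "gen"][order(abs(co$ipca1[co$type == "gen"]))][1:2]
  expect_setequal(small2, c("G1", "G3"))

  # a genotype outside the planted rank-1 interaction has zero ordinate
  u <- c(0, 1, -1, 0.5, -0.5); u <- u / sqrt(sum(u^2))   # G1 carries no GEI
  v <- c(1, -1, 0.5, -0.5, 0, 0, 0, 0, 0); v <- v / sqrt(sum(v^2))
  cell <- 5 + outer(rnorm(5, 0, 0.1), rnorm(9, 0, 0.2), `+`) + 2 * u %o% v
  fit2 <- ammi_fit(means_matrix(cell))
  expect_equal(ammi1_coords(fit2)$ipca1[1], 0, tolerance = 1e-8)
})

test_that("AMMI2 coordinates and spoke lengths follow the SVD", {
  sim <- simulate_met(synthetic_spec(gei_rank = 1, gei_singulars = 2,
                                     sigma_err = 0, seed = 14))
  fit <- ammi_fit(to_means(sim$trial, "GY"))
  co <- ammi2_coords(fit)
  expect_lt(max(abs(co$ipca2)), 1e-6)

  awd <- ammi_fit(yield_fixture("AWD"))
  co2 <- ammi2_coords(awd)
  env <- co2[co2$type == "env", ]
  # oracle SVD of the printed table ranks E6, E9, E3 as the longest spokes
  expect_setequal(env$label[order(-env$spoke)][1:3], c("E6", "E9", "E3"))
  # environment-scale scores recover each environment's share of GEI SS
  es_full <- awd$env_scores * rep(sqrt(awd$singulars),
                                  each = nrow(awd$env_scores))
  expect_equal(rowSums(es_full^2), colSums(awd$interaction^2),
               tolerance = 1e-10)
})

test_that("nominal plot lines are the AMMI1 prediction minus environment effects", {
  awd <- yield_fixture("AWD")
  fit <- ammi_fit(awd)
  np <- nominal_plot(fit)
  # flat line for a zero-slope genotype
  fake <- fit
  fake$gen_scores[1, 1] <- 0
  np0 <- nominal_plot(fake)
  expect_equal(unname(np0$nominal[1, ]),
               rep(fit$means$genotype[[1]], 9))
  # crossing point algebra
  l <- np$lines
  t_star <- (l$intercept[2] - l$intercept[1]) / (l$slope[1] - l$slope[2])
  expect_equal(l$intercept[1] + l$slope[1] * t_star,
               l$intercept[2] + l$slope[2] * t_star, tolerance = 1e-10)
  # winner per environment equals the AMMI1-truncated prediction winner
  mm <- fit$means
  pred1 <- outer(mm$genotype, mm$environment, `+`) - mm$grand +
    fit$gen_scores[, 1] %o% fit$env_scores[, 1]
  expect_equal(apply(np$nominal, 2, which.max),
               apply(pred1, 2, which.max), ignore_attr = TRUE)
})

test_that("ASV matches its formula and handles degeneracies", {
  awd <- ammi_fit(yield_fixture("AWD"))
  tab <- asv(awd)
  w <- awd$singulars[1]^2 / awd$singulars[2]^2
  oracle <- sqrt((w * awd$gen_scores[, 1])^2 + awd$gen_scores[, 2]^2)
  expect_equal(tab$asv, unname(oracle), tolerance = 1e-12)
  expect_equal(tab$rank, match(tab$asv, sort(unique(tab$asv))))

  fake <- structure(list(singulars = c(sqrt(2), 1),
                         gen_scores = rbind(G1 = c(1, 0), G2 = c(0, 0))),
                    class = "ammi_fit")
  res <- asv(fake)
  expect_equal(res$asv, c(2, 0))     # SS ratio 2 weights axis 1
  expect_equal(res$rank, c(2, 1))
  fake$singulars[2] <- 0
  expect_error(asv(fake), "second-axis")
})
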