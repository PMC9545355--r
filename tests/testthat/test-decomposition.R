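test_that("decomposition rate is proportional daily mass loss", {
  expect_equal(decomposition_rate(20, 20, 32), 0)
  expect_equal(decomposition_rate(20, 10.144, 32), 0.0154)
  expect_equal(decomposition_rate(20, 22, 25), -0.004)  # detrital growth
  # invariant to mass units
  expect_equal(decomposition_rate(2000, 1014.4, 32),
               decomposition_rate(20, 10.144, 32))
  expect_error(decomposition_rate(0, 1, 10), "M0")
})

test_that("pooled rates equal weighted pooling of per-experiment results", {
  lb <- data.frame(species = "digitata", experiment = rep(c("a", "b"), c(4, 6)),
                   bag_id = paste0("b", 1:10), M0_g = 20,
                   M1_g = 20 * (1 - 0.01 * 30) + c(-2:1, -3:2) * 0.3,
                   delta_t_d = 30)
  pr <- pool_rates(lb)
  D <- decomposition_rate(lb$M0_g, lb$M1_g, lb$delta_t_d)
  expect_equal(pr$overall$mean_D, mean(D))
  by <- pr$by_experiment
  expect_equal(pr$overall$mean_D,
               sum(by$mean_D * by$n) / sum(by$n))
  expect_equal(pr$overall$n, 10)
  # degenerate: constant records give SE 0
  lb0 <- data.frame(species = "digitata", experiment = "a",
                    bag_id = c("x", "y"), M0_g = 20, M1_g = 14, delta_t_d = 30)
  expect_equal(pool_rates(lb0)$overall$se_D, 0)
})

test_that("grazing proportions scale excavation and perforation correctly", {
  expect_equal(grazing_proportions(0, 0, 10), list(E = 0, P = 0))
  g <- grazing_proportions(2, 1, 10)
  expect_equal(g$E, 2 / 9)
  expect_equal(g$P, 0.1)
  g2 <- grazing_proportions(9, 1, 10)
  expect_equal(g2$E, 1)
  # unit invariance (areas in mm^2)
  g3 <- grazing_proportions(200, 100, 1000)
  expect_equal(g3, g)
  expect_error(grazing_proportions(1, 10, 10), "smaller than total")
})

test_that("standard curve is an OLS line agreeing with the normal equations", {
  sc <- fit_standard_curve(1:3, 1:3)
  expect_equal(sc$slope, 1)
  expect_equal(sc$intercept, 0)
  expect_equal(sc$r_squared, 1)

  conc <- c(0.05, 0.1, 0.25, 0.5, 0.75, 1.0)
  sc2 <- fit_standard_curve(conc, 2 * conc + 0.01)
  expect_equal(sc2$slope, 2)
  expect_equal(sc2$intercept, 0.01)

  set.seed(3)
  ab <- 2 * conc + 0.01 + rnorm(6, 0, 0.01)
  sc3 <- fit_standard_curve(conc, ab)
  or <- ols_oracle(conc, ab)
  expect_equal(sc3$intercept, or[1])
  expect_equal(sc3$slope, or[2])
  se_slope <- summary(sc3$fit)$coefficients["concentrations", "Std. Error"]
  expect_lt(abs(sc3$slope - 2), 3 * se_slope)
  expect_error(fit_standard_curve(c(1, 1, 1), 1:3), "distinct")
})

test_that("phloroglucinol equivalents follow the unit chain", {
  sc <- fit_standard_curve(1:3, 2 * (1:3) + 0.05)
  expect_equal(pg_equivalents(0.05, sc), 0)                  # abs = intercept
  sc2 <- fit_standard_curve(1:3, 2 * (1:3))
  # abs 0.2 -> 0.1 mg/ml; 10% w/v = 100 mg dry per ml -> 0.1%
  expect_equal(pg_equivalents(0.2, sc2), 0.1)
  # triplicates averaged before inversion
  expect_equal(pg_equivalents(c(0.18, 0.2, 0.22), sc2), 0.1)
  # dilution scales linearly
  expect_equal(pg_equivalents(0.2, sc2, dilution = 2), 0.2)
  expect_warning(out <- pg_equivalents(-0.1, sc2), "clamped")
  expect_equal(out, 0)
})

test_that("age trends recover linear and exponential truths", {
  age <- rep(c(13, 25, 32), each = 9)
  tr0 <- age_trend(age, rep(1, length(age)), "linear")
  expect_equal(tr0$slope, 0)

  set.seed(5)
  y <- 0.4 + 0.03 * age + rnorm(length(age), 0, 0.05)
  tr <- age_trend(age, y, "linear")
  expect_lt(abs(tr$slope - 0.03), 2 * tr$se)
  or <- ols_oracle(age, y)
  expect_equal(tr$slope, or[2])

  cn <- 18 * exp(-0.005 * age) * exp(rnorm(length(age), 0, 0.02))
  tr2 <- age_trend(age, cn, "log-linear")
  expect_lt(abs(tr2$slope - (-0.005)), 2 * tr2$se)
  expect_error(age_trend(age, c(-1, rep(1, length(age) - 1)), "log-linear"),
               "positive")
})

test_that("decomposition-biochemistry slope recovers configured effects", {
  set.seed(9)
  x <- runif(40, 0, 1.2)                       # phenolic %
  D <- 1.6 - 1.05 * x + rnorm(40, 0, 0.2)      # % per day
  fit <- decomposition_vs_biochem(D, x)
  expect_lt(abs(fit$slope - (-1.05)), 2 * fit$se)

  xc <- runif(40, 20, 30)                      # carbon %
  Dc <- 3 - 0.08 * xc + rnorm(40, 0, 0.15)
  fitc <- decomposition_vs_biochem(Dc, xc)
  expect_lt(abs(fitc$slope - (-0.08)), 2 * fitc$se)
  expect_equal(decomposition_vs_biochem(rep(1, 5), 1:5)$slope, 0)
})
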