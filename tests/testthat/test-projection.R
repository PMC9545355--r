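make_temps <- function(year, t_min, t_mean, t_max, scenario = "test") {
  data.frame(scenario = scenario, year = year, t_min = t_min,
             t_mean = t_mean, t_max = t_max)
}

test_that("LOESS smoothing reproduces lines and quadratics exactly", {
  yr <- 2000:2030
  lin <- make_temps(yr, 8 + 0.02 * (yr - 2000), 12 + 0.02 * (yr - 2000),
                    17 + 0.02 * (yr - 2000))
  sm <- smooth_temperature(lin)
  expect_equal(sm$t_max, lin$t_max, tolerance = 1e-8)

  quad <- make_temps(yr, 8, 12, 17 + 0.001 * (yr - 2015)^2)
  smq <- smooth_temperature(quad)
  expect_equal(smq$t_max, quad$t_max, tolerance = 1e-6)
})

test_that("smoothing strictly reduces lag-1 roughness of a noisy series", {
  set.seed(17)
  yr <- 1950:2020
  raw <- make_temps(yr,
                    8 + 0.01 * (yr - 1950) + 0.3 * sin(yr / 3) + rnorm(length(yr), 0, 0.3),
                    12 + 0.01 * (yr - 1950) + rnorm(length(yr), 0, 0.3),
                    17 + 0.01 * (yr - 1950) + rnorm(length(yr), 0, 0.3))
  sm <- smooth_temperature(raw)
  rough <- function(x) sum(diff(x)^2)
  expect_lt(rough(sm$t_min), rough(raw$t_min))
  expect_lt(rough(sm$t_max), rough(raw$t_max))
  expect_error(smooth_temperature(raw[1:5, ]), ">= 10 years")
})

test_that("cold-species density scales linearly between floor and cap", {
  expect_equal(density_cold(4, 23, 17.5, 17.5), 4)            # reference year
  expect_equal(density_cold(4, 23, 17.5, 23), 0)              # threshold
  expect_equal(density_cold(4, 23, 17.5, (23 + 17.5) / 2), 2) # midway
  expect_equal(density_cold(4, 23, 17.5, 25), 0)              # beyond: floored
  expect_equal(density_cold(4, 23, 17.5, 15), 4)              # capped at 2016
  expect_error(density_cold(4, 17, 17.5, 16), "exceed")
})

test_that("warm-species density hits zero at the fertility threshold", {
  expect_equal(density_warm(2, 9.53, 10.14, 10.14, cap = 6), 2)
  expect_equal(density_warm(2, 9.53, 10.14, 9.53, cap = 6), 0)   # arrival year
  expect_equal(density_warm(2, 9.53, 10.14, 9.0, cap = 6), 0)    # pre-arrival
  expect_equal(density_warm(2, 9.53, 10.14, 20, cap = 6), 6)     # saturates
  mid <- 9.53 + (10.14 - 9.53) / 2
  expect_equal(density_warm(2, 9.53, 10.14, mid, cap = 6), 1)    # linearity
})

test_that("constant temperatures give a flat projection equal to the budget", {
  budgets <- data.frame(
    species = c("digitata", "hyperborea", "ochroleuca"),
    role = c("cold", "cold", "warm"),
    N_2016 = c(2, 3, 1.6), se_N = c(0.2, 0.3, 0.2),
    CE = c(44, 75, 75), se_CE = c(5, 9, 13),
    D = c(0.0093, 0.006, 0.0154))
  temps <- make_temps(2010:2030, 10.1, 12.5, 17.6)
  pr <- project_forest(budgets, temps, T_U = 23, reference_year = 2016)
  expect_equal(length(unique(round(pr$forest_CSP, 9))), 1L)
  y0 <- pr[pr$year == 2016, ]
  expect_equal(y0$N_M, budgets$N_2016)
  expect_equal(y0$CE_T, budgets$N_2016 * budgets$CE)
  expect_equal(y0$CSP_T, budgets$N_2016 * budgets$CE * (1 - 50 * budgets$D))
  # forest CSP_T <= forest CE_T whenever horizon*D <= 1
  expect_true(all(pr$forest_CSP <= pr$forest_CE))
})

test_that("cold-species CSP hits zero in the year temperatures reach T_U", {
  budgets <- data.frame(
    species = c("digitata", "hyperborea", "ochroleuca"),
    role = c("cold", "cold", "warm"),
    N_2016 = c(2, 3, 1.6), se_N = 0, CE = c(44, 75, 75), se_CE = 0,
    D = c(0.0093, 0.006, 0.0154))
  yr <- 2016:2050
  # linear ramp from the 2016 maximum to T_U = 23 in 2040
  t_max <- 17.6 + (23 - 17.6) * pmin(1, (yr - 2016) / (2040 - 2016))
  temps <- make_temps(yr, 10.1, 12.5, t_max)
  pr <- project_forest(budgets, temps, T_U = 23, reference_year = 2016)
  cold <- pr[pr$species == "digitata", ]
  expect_equal(cold$CSP_T[cold$year == 2040], 0)
  expect_gt(cold$CSP_T[cold$year == 2039], 0)
  expect_true(all(cold$CSP_T[cold$year > 2040] == 0))
})

test_that("warm-for-cold replacement at equal export lowers forest CSP", {
  # the central mechanism: same areal export, faster decomposition
  base <- data.frame(
    species = c("digitata", "hyperborea", "ochroleuca"),
    role = c("cold", "cold", "warm"),
    N_2016 = c(2, 3, 1e-9), se_N = 0, CE = c(75, 75, 75), se_CE = 0,
    D = c(0.006, 0.006, 0.0154))
  swapped <- base
  swapped$N_2016 <- c(2, 1, 2)   # 1:1 replacement of hyperborea by ochroleuca
  temps <- make_temps(2010:2030, 10.1, 12.5, 17.6)
  pr1 <- project_forest(base, temps, T_U = 23, reference_year = 2016,
                        warm_cap = 10)
  pr2 <- project_forest(swapped, temps, T_U = 23, reference_year = 2016,
                        warm_cap = 10)
  expect_equal(pr1$forest_CE[1], pr2$forest_CE[1], tolerance = 1e-6)
  expect_gt(pr1$forest_CSP[1], pr2$forest_CSP[1])
})

test_that("decline rate is the geometric-mean annual percentage change", {
  flat <- data.frame(year = 2000:2010, species = "digitata",
                     forest_CSP = 100)
  expect_equal(decline_rate(flat), 0)
  halving <- data.frame(year = c(2000, 2100), species = "digitata",
                        forest_CSP = c(100, 50))
  expect_equal(decline_rate(halving), (1 - 0.5^(1 / 100)) * 100)
  expect_equal(decline_rate(halving), 0.691, tolerance = 1e-3)
  # ratio of rates between two synthetic scenarios is recovered exactly
  s1 <- data.frame(year = c(2000, 2050), forest_CSP = c(100, 100 * (1 - 0.002)^50))
  s2 <- data.frame(year = c(2000, 2050), forest_CSP = c(100, 100 * (1 - 0.006)^50))
  expect_equal(decline_rate(s2) / decline_rate(s1), 3, tolerance = 1e-9)
  expect_error(decline_rate(flat[1, , drop = FALSE]), ">= 2 years")
})
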