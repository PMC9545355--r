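# Independent oracles used across test files.

# brute-force OLS via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)  # (intercept, slope)
}

# Monte-Carlo standard deviation of a product of two independent normal means
product_sd_mc <- function(mean_a, se_a, mean_b, se_b, n = 1e6) {
  a <- rnorm(n, mean_a, se_a)
  b <- rnorm(n, mean_b, se_b)
  sd(a * b)
}

# daily loop oracle for cumulative detrital carbon assimilation
cumulative_ca_oracle <- function(N, BE, D, gpp_intercept, gpp_slope, env, traj,
                                 t, season = "annual") {
  h <- env$daylight_h[[season]]
  total <- numeric(t)
  acc <- 0
  for (k in seq_len(t)) {
    d_ca <- max(0, 1 - k * D)
    g <- max(0, gpp_intercept + gpp_slope * k)
    acc <- acc + N * BE * d_ca * h * g * p_gpp(k, env, traj, season)
    total[k] <- acc
  }
  total
}

# one noiseless light/dark incubation pair with a known O2 rate (per hour)
exact_incubation <- function(rate_h, mode = "light", V_S = 0.13, V_B = 0.27,
                             M = 2, c0 = 250, blank_drift = 0) {
  sgn <- if (mode == "dark") -1 else 1
  per_min <- sgn * rate_h / 60
  dS <- function(dt) (per_min * M * dt + blank_drift * dt * V_B) / V_S
  list(mode = mode,
       c_S0 = c0, c_S10 = c0 + dS(10), c_S30 = c0 + dS(10) + dS(20),
       c_B0 = c0, c_B10 = c0 + blank_drift * 10, c_B30 = c0 + blank_drift * 30,
       V_S_L = V_S, V_B_L = V_B, mass_g = M)
}
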