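# Synthetic-data generators emulating the field designs: monthly hole-punch
# erosion (10 plants/species/month), two litterbag experiments (n = 43
# bags/species), paired light/dark closed-bottle incubations (n = 42
# pairs/species), detrital biochemistry (n = 27/species) and smooth SST
# trajectories. Defaults are the study-system values in kelp_params().

#' Generate bimonthly tissue carbon fractions
#'
#' @param params parameter list from [kelp_params()].
#' @param year calendar year of the campaign.
#' @param months sampling months (default every second month).
#' @param seed optional RNG seed.
#' @return Data frame in the `carbon_fraction` schema.
#' @export
gen_carbon_fractions <- function(params = kelp_params(), year = 2016,
                                 months = c(1, 3, 5, 7, 9, 11), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(laminaria_species(), function(sp) {
    p <- params[[sp]]
    data.frame(species = sp, month = months, year = year,
               carbon_pct = p$carbon_pct_fresh + stats::rnorm(length(months), 0, 0.5),
               nitrogen_pct = p$carbon_pct_fresh / p$cn0 +
                 stats::rnorm(length(months), 0, 0.05))
  }))
  rownames(out) <- NULL
  out
}

#' Generate hole-punch erosion records
#'
#' Monthly tagged plants with lognormal plant-to-plant variation around each
#' species' configured monthly carbon export; digit geometry is built to be
#' internally consistent (`L_F = L_I + G - E_L`), so the erosion stage
#' inverts the generator exactly at zero noise.
#'
#' @param params parameter list from [kelp_params()].
#' @param n_plants_per_month tagged plants per species and month (default 10).
#' @param year campaign year (default 2016).
#' @param fractions carbon-fraction table used for the carbon conversion; one
#'   is generated when NULL.
#' @param plant_sigma lognormal sd of plant-level export variation (default 0.4).
#' @param seed optional RNG seed.
#' @return List with `erosion` and `fractions` data frames.
#' @export
gen_erosion <- function(params = kelp_params(), n_plants_per_month = 10,
                        year = 2016, fractions = NULL, plant_sigma = 0.4,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fractions)) fractions <- gen_carbon_fractions(params, year)
  rows <- list()
  for (sp in laminaria_species()) {
    p <- params[[sp]]
    for (m in 1:12) {
      days <- days_in_month(m, year)
      ce_daily_truth <- p$ce_annual * p$monthly_weights[m] / days
      frac <- match_fraction(rep(sp, 1), m, year, fractions)  # % -> proportion
      for (i in seq_len(n_plants_per_month)) {
        ce_d <- ce_daily_truth * rlnorm1(1, plant_sigma)
        M_R <- p$M_R * rlnorm1(1, 0.05)
        seg_wet <- stats::rnorm(3, 2.2, 0.2)
        seg_dry <- seg_wet[3] * M_R
        ML_R <- mean(seg_wet) * M_R / 5
        E_M <- ce_d / frac
        E_L <- E_M * days / ML_R
        split <- stats::runif(1, 0, 0.3)
        el_digit <- E_L * c(1 + split, 1 - split)   # central, outer; mean E_L
        G <- pmax(0, stats::rnorm(2, 10, 2))
        L_I <- pmax(60, el_digit + 40) + abs(stats::rnorm(2, 0, 5))
        H_I <- stats::runif(2, 2.5, 15)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, plant_id = sprintf("%s_%02d_%02d", sp, m, i),
          month = m, year = year, digit = c("central", "outer"),
          L_I_cm = L_I, H_I_cm = H_I,
          L_F_cm = L_I + G - el_digit, H_F_cm = H_I + G,
          seg1_wet_g = seg_wet[1], seg2_wet_g = seg_wet[2],
          seg3_wet_g = seg_wet[3], seg3_dry_g = seg_dry,
          delta_t_d = days)
      }
    }
  }
  erosion <- do.call(rbind, rows)
  rownames(erosion) <- NULL
  list(erosion = erosion, fractions = fractions)
}

#' Generate litterbag records
#'
#' Linear daily proportional mass loss with mean-one multiplicative lognormal
#' noise, `M1 = M0 * (1 - D * dt) * eps`, truncated at zero. The default
#' design pools a sediment-style experiment (16 bags, 40-41 d, ~105 g) with a
#' forest-floor experiment (27 samples, 13/25/32 d, ~20 g): 43 records per
#' species.
#'
#' @param params parameter list from [kelp_params()].
#' @param sigma lognormal noise sd; defaults to each species' `D_sigma`.
#' @param seed optional RNG seed.
#' @return Data frame in the `litterbags` schema.
#' @export
gen_litterbags <- function(params = kelp_params(), sigma = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(laminaria_species(), function(sp) {
    p <- params[[sp]]
    sg <- if (is.null(sigma)) p$D_sigma else sigma
    d2016 <- data.frame(species = sp, experiment = "2016",
                        bag_id = sprintf("%s_16_%02d", sp, 1:16),
                        M0_g = stats::rnorm(16, 105, 8),
                        delta_t_d = rep(c(40, 41), 8))
    d2019 <- data.frame(species = sp, experiment = "2019",
                        bag_id = sprintf("%s_19_%02d", sp, 1:27),
                        M0_g = stats::rnorm(27, 20, 1),
                        delta_t_d = rep(c(13, 25, 32), each = 9))
    d <- rbind(d2016, d2019)
    d$M1_g <- pmax(0, d$M0_g * (1 - p$D * d$delta_t_d) * rlnorm1(nrow(d), sg))
    d[, c("species", "experiment", "bag_id", "M0_g", "M1_g", "delta_t_d")]
  }))
  rownames(out) <- NULL
  out
}

# exact concentration series for one incubation given a true mass-specific
# O2 rate (umol O2 g^-1 wet h^-1) and a blank drift (umol L^-1 min^-1)
conc_series <- function(rate_h, blank_drift, V_S, V_B, M, c0 = 250,
                        sensor_sd = 0) {
  per_min <- rate_h / 60
  dS <- function(dt) (per_min * M * dt + blank_drift * dt * V_B) / V_S
  cS <- c0 + c(0, dS(10), dS(10) + dS(20))
  cB <- c0 + blank_drift * c(0, 10, 30)
  if (sensor_sd > 0) {
    cS <- cS + stats::rnorm(3, 0, sensor_sd)
    cB <- cB + stats::rnorm(3, 0, sensor_sd)
  }
  list(cS = pmax(0, cS), cB = pmax(0, cB))
}

#' Generate paired light/dark incubation records
#'
#' Each pair carries a sample-level true NPP and R drawn around the species'
#' detrital-age trend (Gaussian between-sample variation), converted to O2
#' concentration series over the 0-10 and 10-30 min read windows with a
#' shared small blank drift and Gaussian sensor noise. At zero noise the
#' respirometry stage inverts the generator exactly.
#'
#' @param params parameter list from [kelp_params()].
#' @param species species code(s) to generate (default all three).
#' @param n pairs per species (default 42).
#' @param ages detrital ages (days) cycled over the pairs (default 13/25/32).
#' @param sensor_sd sd of concentration readings (umol O2 L^-1, default 0.3).
#' @param sample_cv between-sample CV of NPP and R (default `params$npp_cv`).
#' @param ambient_par collection-day photon flux attached to every record
#'   (default 500, below the photoinhibition threshold).
#' @param seed optional RNG seed.
#' @return Data frame in the `incubations` schema (two rows per pair).
#' @export
gen_incubations <- function(params = kelp_params(),
                            species = laminaria_species(), n = 42,
                            ages = c(13, 25, 32), sensor_sd = 0.3,
                            sample_cv = NULL, ambient_par = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cv <- if (is.null(sample_cv)) params$npp_cv else sample_cv
  to_o2 <- function(mg, M_R) mg * M_R * 1000 / 12.0107  # mg C g^-1 dry h^-1 -> umol O2 g^-1 wet h^-1
  out <- do.call(rbind, lapply(as_species(species), function(sp) {
    p <- params[[sp]]
    age <- rep(ages, length.out = n)
    rows <- lapply(seq_len(n), function(i) {
      npp_true_mg <- p$npp_level + p$npp_slope * age[i] +
        stats::rnorm(1, 0, cv * abs(p$npp_level))
      r_true_mg <- max(0.02, p$r_level + p$r_slope * age[i] +
                         stats::rnorm(1, 0, cv * p$r_level))
      M <- stats::rnorm(1, 2, 0.2)
      V_S <- stats::rnorm(1, 0.130, 0.005)
      V_B <- stats::rnorm(1, 0.270, 0.005)
      drift <- stats::rnorm(2, 0, 0.02)
      li <- conc_series(to_o2(npp_true_mg, p$M_R), drift[1], V_S, V_B, M,
                        sensor_sd = sensor_sd)
      da <- conc_series(-to_o2(r_true_mg, p$M_R), drift[2], V_S, V_B, M,
                        sensor_sd = sensor_sd)
      data.frame(species = sp, detrital_age_d = age[i],
                 pair_id = sprintf("%s_%03d", sp, i),
                 mode = c("light", "dark"),
                 c_S0 = c(li$cS[1], da$cS[1]), c_S10 = c(li$cS[2], da$cS[2]),
                 c_S30 = c(li$cS[3], da$cS[3]),
                 c_B0 = c(li$cB[1], da$cB[1]), c_B10 = c(li$cB[2], da$cB[2]),
                 c_B30 = c(li$cB[3], da$cB[3]),
                 V_S_L = V_S, V_B_L = V_B, mass_g = M,
                 ambient_par = ambient_par)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  out
}

#' Generate detrital biochemistry records
#'
#' Per species: carbon content follows its linear detrital-age trend, the
#' carbon:nitrogen ratio declines exponentially at the common configured rate
#' (nitrogen is derived as carbon / C:N so recomputed ratios carry only the
#' intended log-scale noise), phenolic content follows the species' linear
#' trend (an increase only in the high-phenolic species), and water content
#' is stationary.
#'
#' @param params parameter list from [kelp_params()].
#' @param n_per_age records per species per retrieval age (default 9).
#' @param ages retrieval ages in days (default 13/25/32; n = 27 per species).
#' @param seed optional RNG seed.
#' @return Data frame in the `biochem` schema.
#' @export
gen_biochem <- function(params = kelp_params(), n_per_age = 9,
                        ages = c(13, 25, 32), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age_vec <- rep(ages, each = n_per_age)
  mean_age <- mean(age_vec)
  out <- do.call(rbind, lapply(laminaria_species(), function(sp) {
    p <- params[[sp]]
    n <- length(age_vec)
    cn <- p$cn0 * exp(-params$cn_decline_rate * age_vec) *
      exp(stats::rnorm(n, 0, params$log_cn_sigma))
    carbon <- (p$carbon_pct_detrital - p$carbon_age_slope * mean_age) +
      p$carbon_age_slope * age_vec + stats::rnorm(n, 0, 1)
    phen <- pmax(0.01, (p$phenolic_mean - p$phenolic_slope * mean_age) +
                   p$phenolic_slope * age_vec +
                   stats::rnorm(n, 0, params$phenolic_sigma))
    data.frame(species = sp, detrital_age_d = age_vec,
               carbon_pct = carbon, nitrogen_pct = carbon / cn,
               phenolic_pct = phen,
               water_pct = stats::rnorm(n, p$water_pct, 0.5))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a sea-surface-temperature trajectory
#'
#' Smooth warming trajectories for Plymouth-Sound-like conditions: a slow
#' historical trend from 1850 and a scenario-specific ramp after 2005, with
#' summer (August) amplification so the harshest scenario approaches the
#' cold-temperate upper thermal limit late in the century. February SST
#' crosses the warm-temperate fertility threshold (9.53 degC) around the
#' historical arrival year (1946) by construction.
#'
#' @param scenario one of "historical", "RCP2.6", "RCP6.0", "RCP8.5".
#' @param years calendar years (default 1850:2100; "historical" is truncated
#'   at 2020).
#' @param noise_sd interannual Gaussian noise (degC, default 0.15); set 0 for
#'   an exactly smooth trajectory.
#' @param seed optional RNG seed.
#' @return Data frame in the `temperature` schema.
#' @export
gen_temperature <- function(scenario = c("historical", "RCP2.6", "RCP6.0", "RCP8.5"),
                            years = 1850:2100, noise_sd = 0.15, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  if (scenario == "historical") years <- years[years <= 2020]
  rate <- switch(scenario, historical = 0, "RCP2.6" = 0.7 / 95,
                 "RCP6.0" = 1.6 / 95, "RCP8.5" = 3.2 / 95)
  hist_warm <- 0.004 * (pmin(years, 2005) - 1850)
  scen_warm <- rate * pmax(0, years - 2005)
  t_mean <- 11.75 + hist_warm + scen_warm
  t_max <- t_mean + 4.9 + scen_warm          # summer amplification
  t_min <- t_mean - 2.6
  if (noise_sd > 0) {
    t_mean <- t_mean + stats::rnorm(length(years), 0, noise_sd)
    t_max <- t_max + stats::rnorm(length(years), 0, noise_sd)
    t_min <- t_min + stats::rnorm(length(years), 0, noise_sd)
  }
  data.frame(scenario = scenario, year = years,
             t_min = pmin(t_min, t_mean), t_mean = t_mean,
             t_max = pmax(t_max, t_mean))
}

#' Write a complete synthetic data set to disk
#'
#' Runs every generator under one seed and writes schema-valid CSVs
#' (erosion, carbon_fraction, litterbags, incubations, biochem, temperature
#' for all four scenarios) into a directory.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed; the same seed reproduces the files byte for byte.
#' @param params parameter list from [kelp_params()].
#' @return Invisibly, the named list of file paths.
#' @export
simulate_kelp_data <- function(out_dir, seed = 1, params = kelp_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  er <- gen_erosion(params)
  lb <- gen_litterbags(params)
  inc <- gen_incubations(params)
  bio <- gen_biochem(params)
  temps <- do.call(rbind, lapply(c("historical", "RCP2.6", "RCP6.0", "RCP8.5"),
                                 function(s) gen_temperature(s)))
  files <- list(
    erosion = file.path(out_dir, "erosion.csv"),
    carbon_fraction = file.path(out_dir, "carbon_fraction.csv"),
    litterbags = file.path(out_dir, "litterbags.csv"),
    incubations = file.path(out_dir, "incubations.csv"),
    biochem = file.path(out_dir, "biochem.csv"),
    temperature = file.path(out_dir, "temperature.csv"))
  utils::write.csv(er$erosion, files$erosion, row.names = FALSE)
  utils::write.csv(er$fractions, files$carbon_fraction, row.names = FALSE)
  utils::write.csv(lb, files$litterbags, row.names = FALSE)
  utils::write.csv(inc, files$incubations, row.names = FALSE)
  utils::write.csv(bio, files$biochem, row.names = FALSE)
  utils::write.csv(temps, files$temperature, row.names = FALSE)
  invisible(files)
}
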