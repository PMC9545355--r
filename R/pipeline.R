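#' Run the full kelp carbon-flux pipeline
#'
#' Orchestrates every stage on a directory of schema-valid CSVs (as written
#' by [simulate_kelp_data()]): erosion to per-plant and aggregated carbon
#' export, litterbag decomposition, respirometry to production estimates and
#' detrital production trends, biochemistry age trends, per-species CSP decay
#' models with areal export, temperature smoothing and the forest projection
#' under each scenario, and cumulative detrital carbon assimilation along a
#' sinking trajectory.
#'
#' @param data_dir directory containing erosion.csv, carbon_fraction.csv,
#'   litterbags.csv, incubations.csv, biochem.csv, temperature.csv. When
#'   NULL, a synthetic data set is generated under `seed` in a temporary
#'   directory.
#' @param out_dir optional directory for stage outputs (budgets.csv,
#'   csp_curves.csv, projection.csv, ca.csv); nothing is written when NULL.
#' @param params parameter list from [kelp_params()] (densities, zone
#'   weights, dry:wet ratios used for configuration).
#' @param T_U upper thermal limit for cold-temperate sporophyte growth
#'   (degC); required for the projection.
#' @param T_L lower fertility threshold (degC), default 9.53.
#' @param horizon_t sequestration horizon (days), default 50.
#' @param traj a [detrital_trajectory()]; default a 30 m sink 4000 m away.
#' @param env a [light_environment()] (defaults per the study region).
#' @param seed RNG seed, used only when data are simulated.
#' @param scenarios scenarios to project (default all in the file).
#' @return List: export (monthly/seasonal/annual), decomposition, production,
#'   trends, budgets (per-species data frame), csp_models (list of
#'   [csp_model()] objects), projection (per scenario), decline_rates,
#'   assimilation (per species), summary data frame.
#' @export
run_kelp_pipeline <- function(data_dir = NULL, out_dir = NULL,
                              params = kelp_params(), T_U, T_L = 9.53,
                              horizon_t = 50,
                              traj = detrital_trajectory(30, 4000, 50),
                              env = light_environment(), seed = 1,
                              scenarios = NULL) {
  if (is.null(data_dir)) {
    data_dir <- tempfile("kelpdata")
    simulate_kelp_data(data_dir, seed = seed, params = params)
  }
  rd <- function(f) utils::read.csv(file.path(data_dir, f), stringsAsFactors = FALSE)
  erosion <- rd("erosion.csv"); fractions <- rd("carbon_fraction.csv")
  litterbags <- rd("litterbags.csv"); incubations <- rd("incubations.csv")
  biochem <- rd("biochem.csv"); temps <- rd("temperature.csv")
  for (nm in c("erosion", "litterbags", "incubations", "biochem", "temperature")) {
    v <- validate_table(get(switch(nm, temperature = "temps", nm)), nm)
    if (!v$ok) stop("schema violation in ", nm, ".csv: ",
                    paste(v$missing_columns, collapse = ", "),
                    if (nrow(v$bad_rows)) paste(" +", nrow(v$bad_rows), "bad rows"))
  }

  # 1. carbon export
  plants <- plant_export(erosion, fractions)
  export <- aggregate_export(plants)

  # 2. decomposition
  decomp <- pool_rates(litterbags)

  # 3. respirometry
  M_R <- vapply(laminaria_species(), function(sp) params[[sp]]$M_R, numeric(1))
  production <- process_incubations(incubations, M_R)
  prod_trend <- lapply(split(production, production$species), function(d) {
    net <- age_trend(d$detrital_age_d, d$CA_net, model = "linear")
    gross <- age_trend(d$detrital_age_d, d$CA_gross, model = "linear")
    list(net = net, gross = gross,
         mean_CA_net = mean(d$CA_net), se_CA_net = se_mean(d$CA_net),
         mean_CA_gross = mean(d$CA_gross), n = nrow(d))
  })

  # 4. biochemistry trends
  bio_trend <- lapply(split(biochem, biochem$species), function(d) {
    list(phenolic = age_trend(d$detrital_age_d, d$phenolic_pct, "linear"),
         carbon = age_trend(d$detrital_age_d, d$carbon_pct, "linear"))
  })
  cn_rate <- age_trend(biochem$detrital_age_d,
                       biochem$carbon_pct / biochem$nitrogen_pct, "log-linear")

  # 5. budgets + CSP models
  budgets <- do.call(rbind, lapply(laminaria_species(), function(sp) {
    p <- params[[sp]]
    ann <- export$annual[export$annual$species == sp, ]
    dd <- decomp$overall[decomp$overall$species == sp, ]
    data.frame(species = sp,
               role = if (sp == "ochroleuca") "warm" else "cold",
               N_2016 = p$density * p$zone_weight,
               se_N = p$density_se * p$zone_weight,
               CE = ann$mean_CE, se_CE = ann$se_CE,
               BE = ann$mean_BE, se_BE = ann$se_BE,
               D = dd$mean_D, se_D = dd$se_D)
  }))
  csp_models <- lapply(seq_len(nrow(budgets)), function(i) {
    b <- budgets[i, ]
    csp_model(b$N_2016, b$CE, b$D, b$se_N, b$se_CE, b$se_D,
              species = b$species)
  })
  names(csp_models) <- budgets$species
  budgets$t_zero <- vapply(csp_models, function(m) time_to_zero(m$D, m$se_D)$days,
                           numeric(1))
  areal <- lapply(csp_models, function(m) {
    pc <- product_ci(m$N, m$se_N, m$CE, m$se_CE)
    c(mean = pc$mean, lo = pc$mean - pc$half_width, hi = pc$mean + pc$half_width)
  })
  budgets$areal_CE <- vapply(areal, `[[`, numeric(1), "mean")
  budgets$areal_CE_lo <- vapply(areal, `[[`, numeric(1), "lo")
  budgets$areal_CE_hi <- vapply(areal, `[[`, numeric(1), "hi")

  ages <- 0:200
  curves <- do.call(rbind, lapply(csp_models, function(m) {
    pr <- predict(m, t = ages)
    cbind(species = m$species, pr)
  }))

  # 6. projection per scenario
  sm <- smooth_temperature(temps)
  if (is.null(scenarios)) scenarios <- unique(sm$scenario)
  projection <- list(); declines <- c()
  for (sc in scenarios) {
    pr <- project_forest(budgets, sm[sm$scenario == sc, ], T_U = T_U, T_L = T_L,
                         horizon_t = horizon_t)
    projection[[sc]] <- pr
    declines[sc] <- decline_rate(pr)
  }

  # 7. cumulative detrital carbon assimilation (annual regime)
  assimilation <- lapply(seq_len(nrow(budgets)), function(i) {
    b <- budgets[i, ]
    tr <- prod_trend[[b$species]]$gross
    cumulative_assimilation(b$N_2016, b$BE, b$D,
                            gpp_intercept = tr$intercept, gpp_slope = tr$slope,
                            env = env, traj = traj, t = traj$travel_time)
  })
  names(assimilation) <- budgets$species

  summary_df <- data.frame(
    species = budgets$species,
    areal_CE_gC_m2_yr = budgets$areal_CE,
    D_pct_day = budgets$D * 100,
    t_zero_days = budgets$t_zero,
    CA_net_mg_g_h = vapply(budgets$species, function(sp)
      prod_trend[[sp]]$mean_CA_net * 1000, numeric(1)),
    cumulative_CA_gC_m2 = vapply(budgets$species, function(sp)
      utils::tail(assimilation[[sp]]$cumulative_CA, 1), numeric(1)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(budgets, file.path(out_dir, "budgets.csv"), row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "csp_curves.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, projection), file.path(out_dir, "projection.csv"),
                     row.names = FALSE)
    ca <- do.call(rbind, lapply(names(assimilation), function(sp)
      data.frame(species = sp, age = assimilation[[sp]]$ages,
                 cumulative_CA = assimilation[[sp]]$cumulative_CA)))
    utils::write.csv(ca, file.path(out_dir, "ca.csv"), row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }

  list(export = export, decomposition = decomp, production = production,
       production_trends = prod_trend, biochem_trends = bio_trend,
       cn_rate = cn_rate, budgets = budgets, csp_models = csp_models,
       csp_curves = curves, projection = projection,
       decline_rates = declines, assimilation = assimilation,
       summary = summary_df)
}
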