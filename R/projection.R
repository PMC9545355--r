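#' Smooth a sea-surface-temperature series
#'
#' Locally estimated scatterplot smoothing (local quadratic regression with
#' tricube weights, smoothing parameter alpha = 1) applied independently to
#' the minimum (February), mean and maximum (August) SST columns and
#' evaluated at each year.
#'
#' @param temps data frame in the `temperature` schema: scenario, year,
#'   t_min, t_mean, t_max, with >= 10 years per scenario.
#' @param span LOESS span (default 1).
#' @return The data frame with t_min, t_mean, t_max replaced by smoothed
#'   values.
#' @export
smooth_temperature <- function(temps, span = 1) {
  v <- validate_table(temps, "temperature")
  if (!v$ok) stop("invalid temperature table")
  out <- lapply(split(temps, temps$scenario), function(d) {
    if (nrow(d) < 10L) stop("need >= 10 years per scenario to smooth")
    d <- d[order(d$year), ]
    for (cl in c("t_min", "t_mean", "t_max")) {
      fit <- stats::loess(d[[cl]] ~ d$year, span = span, degree = 2,
                          family = "gaussian", surface = "direct")
      d[[cl]] <- stats::predict(fit, d$year)
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Projected density of a cold-temperate species
#'
#' Density scales linearly with the remaining thermal headroom below the
#' upper sporophyte-growth limit, relative to the 2016 reference:
#' `N_C = N * (T_U - T_max) / (T_U - T_max2016)`, floored at 0 once August
#' SST reaches T_U and capped at the species' observed 2016 zone density (no
#' re-expansion above carrying capacity).
#'
#' @param N_2016 reference-year density (plants m^-2).
#' @param T_U upper temperature limit for sporophyte growth (degC).
#' @param T_max2016 reference-year August SST (degC), must be < T_U.
#' @param T_max projected August SST (degC), vectorised.
#' @param cap maximum density (default `N_2016`).
#' @return Projected density (plants m^-2).
#' @export
density_cold <- function(N_2016, T_U, T_max2016, T_max, cap = N_2016) {
  if (T_U <= T_max2016) stop("T_U must exceed T_max2016")
  pmin(cap, pmax(0, N_2016 * (T_U - T_max) / (T_U - T_max2016)))
}

#' Projected density of a warm-temperate species
#'
#' Density scales linearly with winter warmth above the gametophyte-fertility
#' threshold: `N_W = N * (T_min - T_L) / (T_min2016 - T_L)`, floored at 0
#' below T_L (before arrival) and capped at the total observed density of the
#' lower forest band (the species cannot occupy the emersion-stressed upper
#' band).
#'
#' @param N_2016 reference-year density (plants m^-2).
#' @param T_L lower temperature threshold for gametophyte fertility (degC),
#'   default 9.53 (the August SST at the species' historical arrival).
#' @param T_min2016 reference-year February SST (degC), must be > T_L.
#' @param T_min projected February SST (degC), vectorised.
#' @param cap total observed lower-band density (plants m^-2).
#' @return Projected density (plants m^-2).
#' @export
density_warm <- function(N_2016, T_L = 9.53, T_min2016, T_min, cap) {
  if (T_min2016 <= T_L) stop("T_min2016 must exceed T_L")
  pmin(cap, pmax(0, N_2016 * (T_min - T_L) / (T_min2016 - T_L)))
}

#' Project forest carbon export and CSP through time
#'
#' For each year of a (smoothed) temperature series, the modelled density of
#' each species (cold-temperate via August SST, warm-temperate via February
#' SST) is combined with its annual per-plant carbon export and decomposition
#' rate: `CE_T = N_M * CE` and `CSP_T = N_M * CE * (1 - t * D)` at the
#' sequestration horizon t, with product-of-means CIs per species and
#' variance-sum CIs on the forest totals.
#'
#' @param budgets data frame with one row per species: species, role
#'   ("cold"/"warm"), N_2016 (zone-weighted plants m^-2), se_N, CE (g C
#'   plant^-1 yr^-1), se_CE, D (day^-1).
#' @param temps smoothed temperature series (single scenario).
#' @param T_U upper thermal limit for cold-temperate sporophyte growth
#'   (degC); required, no default.
#' @param T_L lower fertility threshold (degC), default 9.53.
#' @param reference_year year of the density observations (default 2016);
#'   must be present in `temps`.
#' @param horizon_t sequestration horizon (days), default 50.
#' @param warm_cap density cap for the warm species (default: summed 2016
#'   density of the lower-band species).
#' @param z normal quantile for CIs.
#' @return Data frame with one row per year x species plus per-year forest
#'   totals in attributes; columns year, species, N_M, CE_T, CSP_T,
#'   CE_T_lo/hi, CSP_T_lo/hi, forest_CE, forest_CSP, forest_CE_lo/hi,
#'   forest_CSP_lo/hi (forest values repeated within year).
#' @export
project_forest <- function(budgets, temps, T_U, T_L = 9.53,
                           reference_year = 2016, horizon_t = 50,
                           warm_cap = NULL, z = 1.959964) {
  need <- laminaria_species()
  if (!all(need %in% budgets$species)) {
    stop("budgets must cover species: ", paste(setdiff(need, budgets$species), collapse = ", "))
  }
  if (missing(T_U)) stop("T_U is a required input")
  ref <- temps[temps$year == reference_year, , drop = FALSE]
  if (nrow(ref) != 1L) stop("reference year ", reference_year, " not in temperature series")
  if (is.null(warm_cap)) {
    lower <- budgets[budgets$species %in% c("hyperborea", "ochroleuca"), ]
    warm_cap <- sum(lower$N_2016)
  }
  decay <- function(D) max(0, 1 - horizon_t * D)

  rows <- lapply(seq_len(nrow(temps)), function(i) {
    yr <- temps$year[i]
    per_sp <- lapply(seq_len(nrow(budgets)), function(j) {
      b <- budgets[j, ]
      N_M <- if (b$role == "cold") {
        density_cold(b$N_2016, T_U, ref$t_max, temps$t_max[i])
      } else {
        density_warm(b$N_2016, T_L, ref$t_min, temps$t_min[i], cap = warm_cap)
      }
      se_N <- if (b$N_2016 > 0) b$se_N * N_M / b$N_2016 else 0
      ce <- product_ci(N_M, se_N, b$CE, b$se_CE, z = z)
      dc <- decay(b$D)
      data.frame(year = yr, species = b$species, N_M = N_M,
                 CE_T = ce$mean, CE_T_se = ce$half_width / z,
                 CE_T_lo = ce$mean - ce$half_width,
                 CE_T_hi = ce$mean + ce$half_width,
                 CSP_T = ce$mean * dc, CSP_T_se = ce$half_width / z * dc,
                 CSP_T_lo = (ce$mean - ce$half_width) * dc,
                 CSP_T_hi = (ce$mean + ce$half_width) * dc)
    })
    sp <- do.call(rbind, per_sp)
    sp$forest_CE <- sum(sp$CE_T)
    sp$forest_CSP <- sum(sp$CSP_T)
    ce_se <- variance_sum_se(sp$CE_T_se)
    csp_se <- variance_sum_se(sp$CSP_T_se)
    sp$forest_CE_lo <- sp$forest_CE - z * ce_se
    sp$forest_CE_hi <- sp$forest_CE + z * ce_se
    sp$forest_CSP_lo <- sp$forest_CSP - z * csp_se
    sp$forest_CSP_hi <- sp$forest_CSP + z * csp_se
    sp
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average annual percentage decline of forest CSP
#'
#' Geometric-mean annual rate of change of forest CSP between the first and
#' last year of a window, reported as a percentage decline per year (positive
#' = declining).
#'
#' @param projection output of [project_forest()].
#' @param years length-2 window `c(from, to)`; defaults to the projection's
#'   full span.
#' @return Decline rate (% year^-1), positive when CSP shrinks.
#' @export
decline_rate <- function(projection, years = range(projection$year)) {
  p <- projection[!duplicated(projection$year), c("year", "forest_CSP")]
  p <- p[p$year >= years[1] & p$year <= years[2], ]
  if (nrow(p) < 2L) stop("need >= 2 years in the window")
  v0 <- p$forest_CSP[which.min(p$year)]
  v1 <- p$forest_CSP[which.max(p$year)]
  if (v0 <= 0) stop("zero or negative baseline CSP")
  ny <- diff(range(p$year))
  (1 - (v1 / v0)^(1 / ny)) * 100
}
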