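#' Laminaria species codes
#'
#' The three Northeast Atlantic forest-forming \emph{Laminaria} species the
#' package models: cold-temperate \emph{L. digitata} (upper shore band) and
#' \emph{L. hyperborea}, and warm-temperate \emph{L. ochroleuca}. All
#' per-species parameters throughout the package are keyed by these codes.
#'
#' @return Character vector `c("digitata", "hyperborea", "ochroleuca")`.
#' @export
laminaria_species <- function() c("digitata", "hyperborea", "ochroleuca")

#' Validate and normalise a species code
#'
#' @param species character scalar or vector of species codes.
#' @return The validated code(s).
#' @export
as_species <- function(species) {
  ok <- species %in% laminaria_species()
  if (!all(ok)) {
    stop("unknown species code(s): ", paste(unique(species[!ok]), collapse = ", "),
         "; expected one of ", paste(laminaria_species(), collapse = ", "))
  }
  species
}

#' Default per-species parameters of the study system
#'
#' Central parameter set used by the synthetic-data generators and as the
#' worked-example configuration. Decomposition rates, detrital production
#' levels, biochemistry means and trends, tissue ratios and areal-export
#' anchors are the study-system values; plant densities and per-plant annual
#' export are chosen for internal consistency with the areal anchors and the
#' observed vertical zonation (see the methods vignette).
#'
#' Units: densities plants m^-2 (within the species' vertical band),
#' `zone_weight` the proportion of the ~20 m forest band occupied,
#' `ce_annual` g C plant^-1 yr^-1, `D` day^-1, `M_R` dry:wet mass ratio,
#' percentages in % of dry mass, NPP/R levels mg C g^-1 (dry) h^-1 and their
#' age slopes mg C g^-1 h^-1 day^-1, C:N dimensionless with an exponential
#' per-day decline rate.
#'
#' @return A nested list keyed by species plus shared elements
#'   (`cn_decline_rate`, `monthly_weights`, `photoinhibition_par`).
#' @export
kelp_params <- function() {
  # monthly shares of annual carbon export (sum to 1 per species):
  # hyperborea peaks in spring (May cast) with secondary autumn/winter peaks;
  # ochroleuca peaks in summer; digitata is flat-ish with an autumn maximum.
  w_hyp <- c(0.06, 0.05, 0.10, 0.18, 0.22, 0.05, 0.03, 0.03, 0.07, 0.09, 0.05, 0.07)
  w_och <- c(0.07, 0.05, 0.04, 0.05, 0.07, 0.12, 0.18, 0.15, 0.09, 0.08, 0.05, 0.05)
  w_dig <- c(0.04, 0.04, 0.05, 0.06, 0.07, 0.09, 0.10, 0.11, 0.13, 0.12, 0.11, 0.08)
  list(
    digitata = list(
      zone_weight = 0.2, density = 10.25, density_se = 1.0,
      ce_annual = 43.9, ce_se = 4.9,           # areal anchor 90 +/- 10
      D = 0.0093, D_sigma = 0.45,
      M_R = 0.1489, water_pct = 85.11,
      carbon_pct_fresh = 28.16, carbon_pct_detrital = 27.94,
      carbon_age_slope = 0.14,                 # % day^-1 increase in detritus
      cn0 = 18.6, phenolic_mean = 0.11, phenolic_slope = 0,
      npp_level = 0.98, npp_slope = 0, r_level = 0.40, r_slope = 0,
      monthly_weights = w_dig
    ),
    hyperborea = list(
      zone_weight = 0.8, density = 3.52, density_se = 0.35,
      ce_annual = 75, ce_se = 9.6,             # areal anchor 211 +/- 27
      D = 0.0060, D_sigma = 0.45,
      M_R = 0.1560, water_pct = 84.40,
      carbon_pct_fresh = 30.78, carbon_pct_detrital = 28.67,
      carbon_age_slope = 0,
      cn0 = 18.8, phenolic_mean = 1.07, phenolic_slope = 0.03,
      npp_level = 0.76, npp_slope = 0, r_level = 0.35, r_slope = 0,
      monthly_weights = w_hyp
    ),
    ochroleuca = list(
      zone_weight = 0.8, density = 2.12, density_se = 0.25,
      ce_annual = 75, ce_se = 13.0,            # areal anchor 127 +/- 22
      D = 0.0154, D_sigma = 0.45,
      M_R = 0.1268, water_pct = 87.32,
      carbon_pct_fresh = 27.38, carbon_pct_detrital = 22.03,
      carbon_age_slope = 0,
      cn0 = 19.2, phenolic_mean = 0.16, phenolic_slope = 0,
      # NPP declines to zero at 20 d; with constant R, GPP = 1.08 - 0.03 t
      # reaches zero at 36 d (detrital photosynthetic failure).
      npp_level = 0.60, npp_slope = -0.03, r_level = 0.48, r_slope = 0,
      monthly_weights = w_och
    ),
    cn_decline_rate = 0.005,       # day^-1, common exponential C:N decline
    phenolic_sigma = 0.10,         # % dry mass, assay-level residual
    log_cn_sigma = 0.02,           # residual sd of log(C:N)
    npp_cv = 0.33,                 # between-sample CV of NPP/R
    photoinhibition_par = 971,     # umol photons m^-2 s^-1
    z95 = 1.959964                 # 97.5 percentile of standard normal
  )
}
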