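#' Digit growth from hole displacement
#'
#' Under the hole-punch method a hole punched just above the stipe--lamina
#' transition is displaced distally by intercalary growth, so growth over the
#' deployment is the displacement of the hole.
#'
#' @param H_I initial hole position (cm from the stipe--lamina transition).
#' @param H_F final hole position (cm). Must satisfy `H_F >= H_I`.
#' @param plant_id optional identifier used in error messages.
#' @return Growth G (cm month^-1), `H_F - H_I`.
#' @export
growth <- function(H_I, H_F, plant_id = NULL) {
  bad <- which(H_F < H_I)
  if (length(bad)) {
    id <- if (is.null(plant_id)) paste("record", bad) else plant_id[bad]
    stop("negative growth (hole moved proximally) for plant(s): ",
         paste(unique(id), collapse = ", "))
  }
  H_F - H_I
}

#' Lamina length lost to distal erosion
#'
#' `E_L = L_I + G - L_F`: the length the digit would have reached without
#' erosion minus the observed final length.
#'
#' @param L_I initial digit length (cm).
#' @param G growth over the deployment (cm), from [growth()].
#' @param L_F final digit length (cm). Must satisfy `L_F <= L_I + G`.
#' @param plant_id optional identifier used in error messages.
#' @return E_L (cm plant^-1 month^-1), non-negative.
#' @export
lamina_loss <- function(L_I, G, L_F, plant_id = NULL) {
  bad <- which(L_F > L_I + G + 1e-9)
  if (length(bad)) {
    id <- if (is.null(plant_id)) paste("record", bad) else plant_id[bad]
    stop("final length exceeds initial length plus growth (measurement ",
         "inconsistency) for plant(s): ", paste(unique(id), collapse = ", "))
  }
  pmax(L_I + G - L_F, 0)
}

#' Distal lamina dry mass per unit length
#'
#' Three 5-cm distal segments are weighed wet; the outermost is also dried.
#' The plant's own dry:wet ratio (`M_R`) converts the wet masses of all three
#' segments to dry mass, and the mean dry mass per 5 cm gives the dry
#' mass-to-length ratio.
#'
#' @param segment_wet_masses numeric length-3: wet masses of the 5-cm
#'   segments (g), outermost last.
#' @param segment_dry_mass dry mass of the outermost segment (g).
#' @return List with `ML_R` (g cm^-1) and `M_R` (dry:wet ratio, reused by the
#'   respirometry stage).
#' @export
mass_per_length <- function(segment_wet_masses, segment_dry_mass) {
  if (length(segment_wet_masses) != 3L) stop("expected three 5-cm segment wet masses")
  if (any(segment_wet_masses <= 0) || segment_dry_mass <= 0) stop("segment masses must be > 0")
  if (segment_dry_mass > segment_wet_masses[3L]) {
    stop("segment dry mass exceeds its wet mass")
  }
  M_R <- segment_dry_mass / segment_wet_masses[3L]
  ML_R <- mean(segment_wet_masses * M_R) / 5
  list(ML_R = ML_R, M_R = M_R)
}

#' Daily biomass erosion rate
#'
#' `E_M = E_L * ML_R / delta_t` converts the monthly length loss to a daily
#' dry-mass loss.
#'
#' @param E_L lamina length loss (cm plant^-1 month^-1).
#' @param ML_R dry mass per length (g cm^-1).
#' @param delta_t elapsed days of the deployment.
#' @return E_M (g dry plant^-1 day^-1).
#' @export
daily_erosion <- function(E_L, ML_R, delta_t) {
  if (any(delta_t <= 0)) stop("delta_t must be > 0")
  E_L * ML_R / delta_t
}

#' Daily carbon export from biomass erosion
#'
#' @param E_M daily biomass erosion (g dry plant^-1 day^-1).
#' @param fraction tissue carbon content as a proportion of dry mass (0-1).
#' @return Carbon export (g C plant^-1 day^-1).
#' @export
carbon_export_daily <- function(E_M, fraction) {
  if (any(fraction <= 0 | fraction >= 1)) stop("carbon fraction must be in (0, 1)")
  E_M * fraction
}

# Match each erosion month to the nearest carbon-fraction sampling within a
# window (days); fractions are sampled roughly bimonthly so interpolation is
# avoided.
match_fraction <- function(species, month, year, fractions, window_days = 45) {
  vapply(seq_along(month), function(i) {
    f <- fractions[fractions$species == species[i], , drop = FALSE]
    if (nrow(f) == 0L) stop("no carbon fractions for species ", species[i])
    d <- abs((f$year - year[i]) * 365.25 + (f$month - month[i]) * 30.44)
    j <- which.min(d)
    if (d[j] > window_days) {
      stop("no carbon fraction within ", window_days, " days of ",
           species[i], " month ", month[i], "/", year[i])
    }
    f$carbon_pct[j] / 100
  }, numeric(1))
}

#' Per-plant daily carbon export from raw hole-punch records
#'
#' Reduces digit-level erosion records to one daily carbon-export value per
#' plant and month: growth and length loss per digit, the per-plant mean E_L
#' across central and outer digits (equal weights), the plant's own
#' mass-per-length ratio, and the nearest-in-time species carbon fraction.
#' Plants with fewer than two surviving punched digits are dropped with a
#' warning.
#'
#' @param erosion data frame in the `erosion` schema (see [validate_table()]):
#'   one row per digit with columns species, plant_id, month, year, digit,
#'   L_I_cm, H_I_cm, L_F_cm, H_F_cm, seg1_wet_g..seg3_wet_g, seg3_dry_g,
#'   delta_t_d.
#' @param fractions data frame in the `carbon_fraction` schema.
#' @param window_days matching window for carbon fractions (default 45).
#' @return Data frame: species, plant_id, month, year, delta_t_d, E_L_cm,
#'   ML_R, M_R, E_M_g_d, CE_g_d (g C plant^-1 day^-1).
#' @export
plant_export <- function(erosion, fractions, window_days = 45) {
  v <- validate_table(erosion, "erosion")
  if (!v$ok) stop("invalid erosion table: ",
                  paste(c(v$missing_columns,
                          utils::capture.output(print(utils::head(v$bad_rows)))),
                        collapse = "; "))
  key <- interaction(erosion$species, erosion$plant_id, erosion$month,
                     erosion$year, drop = TRUE)
  pieces <- lapply(split(erosion, key), function(d) {
    if (nrow(d) < 2L) return(NULL)  # fewer than 2 surviving digits
    G <- growth(d$H_I_cm, d$H_F_cm, d$plant_id)
    el <- lamina_loss(d$L_I_cm, G, d$L_F_cm, d$plant_id)
    E_L <- mean(el)
    ml <- mass_per_length(c(d$seg1_wet_g[1L], d$seg2_wet_g[1L], d$seg3_wet_g[1L]),
                          d$seg3_dry_g[1L])
    E_M <- daily_erosion(E_L, ml$ML_R, d$delta_t_d[1L])
    frac <- match_fraction(d$species[1L], d$month[1L], d$year[1L],
                           fractions, window_days)
    data.frame(species = d$species[1L], plant_id = d$plant_id[1L],
               month = d$month[1L], year = d$year[1L],
               delta_t_d = d$delta_t_d[1L], E_L_cm = E_L,
               ML_R = ml$ML_R, M_R = ml$M_R, E_M_g_d = E_M,
               CE_g_d = carbon_export_daily(E_M, frac))
  })
  dropped <- sum(vapply(pieces, is.null, logical(1)))
  if (dropped > 0) warning(dropped, " plant(s) dropped with fewer than 2 surviving digits")
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Aggregate per-plant export to monthly, seasonal and annual estimates
#'
#' Each plant's daily carbon export is scaled by the number of days in its
#' calendar month; the monthly estimate is the mean (and SE) across plants,
#' and seasonal/annual estimates are sums of monthly means with standard
#' errors combined by the variance sum law. Biomass export (BE, g dry
#' plant^-1) is aggregated identically from the erosion rates.
#'
#' @param plants output of [plant_export()].
#' @param require_complete if TRUE (default) error when any of the 12 months
#'   is missing for a species (no imputation).
#' @return List of data frames `monthly`, `seasonal`, `annual` with columns
#'   species, (month/season), mean_CE, se_CE, mean_BE, se_BE, n.
#' @export
aggregate_export <- function(plants, require_complete = TRUE) {
  agg_one <- function(d) {
    days <- days_in_month(d$month, d$year)
    ce <- d$CE_g_d * days
    be <- d$E_M_g_d * days
    data.frame(species = d$species[1L], month = d$month[1L],
               mean_CE = mean(ce), se_CE = se_mean(ce),
               mean_BE = mean(be), se_BE = se_mean(be), n = nrow(d))
  }
  monthly <- do.call(rbind, lapply(
    split(plants, interaction(plants$species, plants$month, drop = TRUE)), agg_one))
  monthly <- monthly[order(monthly$species, monthly$month), ]
  rownames(monthly) <- NULL

  if (require_complete) {
    for (sp in unique(monthly$species)) {
      gaps <- setdiff(1:12, monthly$month[monthly$species == sp])
      if (length(gaps)) stop("missing months for ", sp, ": ",
                             paste(gaps, collapse = ", "))
    }
  }

  monthly$season <- season_of_month(monthly$month)
  seasonal <- do.call(rbind, lapply(
    split(monthly, interaction(monthly$species, monthly$season, drop = TRUE)),
    function(d) data.frame(species = d$species[1L], season = d$season[1L],
                           mean_CE = sum(d$mean_CE),
                           se_CE = variance_sum_se(d$se_CE),
                           mean_BE = sum(d$mean_BE),
                           se_BE = variance_sum_se(d$se_BE),
                           n = sum(d$n))))
  rownames(seasonal) <- NULL
  annual <- do.call(rbind, lapply(
    split(monthly, monthly$species),
    function(d) data.frame(species = d$species[1L],
                           mean_CE = sum(d$mean_CE),
                           se_CE = variance_sum_se(d$se_CE),
                           mean_BE = sum(d$mean_BE),
                           se_BE = variance_sum_se(d$se_BE),
                           n = sum(d$n))))
  rownames(annual) <- NULL
  list(monthly = monthly[, c("species", "month", "season", "mean_CE", "se_CE",
                             "mean_BE", "se_BE", "n")],
       seasonal = seasonal, annual = annual)
}

#' Areal carbon export with a product-of-means confidence interval
#'
#' Multiplies per-plant export by the zone-weighted plant density of the
#' species' vertical band and attaches a 95% CI from Goodman's variance of a
#' product of independent means (only density and export carry error).
#'
#' @param density plant density within the species' band (plants m^-2).
#' @param density_se its standard error.
#' @param zone_weight proportion of the forest band the species occupies
#'   (0.2 for the upper-band species, 0.8 for the lower band).
#' @param mean_CE,se_CE per-plant carbon export and SE (g C plant^-1
#'   period^-1), e.g. from [aggregate_export()].
#' @param z normal quantile for the CI (default 1.959964).
#' @return List: `mean` (g C m^-2 period^-1), `ci_low`, `ci_high`,
#'   `half_width`.
#' @export
areal_export <- function(density, density_se, zone_weight, mean_CE, se_CE,
                         z = 1.959964) {
  if (density < 0) stop("density must be >= 0")
  if (zone_weight <= 0 || zone_weight > 1) stop("zone_weight must be in (0, 1]")
  n_eff <- density * zone_weight
  se_eff <- density_se * zone_weight
  pc <- product_ci(n_eff, se_eff, mean_CE, se_CE, z = z)
  list(mean = pc$mean, ci_low = pc$mean - pc$half_width,
       ci_high = pc$mean + pc$half_width, half_width = pc$half_width)
}
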