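#' Photosynthesis--irradiance response
#'
#' Saturating tanh curve `PE(x) = 1.8 * tanh(0.006 * x / 1.8)`: zero in
#' darkness, asymptote 1.8 at high photon flux.
#'
#' @param par photon flux density (umol photons m^-2 s^-1), >= 0.
#' @param p_max asymptote (default 1.8).
#' @param alpha initial slope (default 0.006).
#' @return Production response (relative units).
#' @export
pe <- function(par, p_max = 1.8, alpha = 0.006) {
  if (any(par < 0)) stop("PAR must be >= 0")
  p_max * tanh(alpha * par / p_max)
}

#' Light environment for the detrital trajectory
#'
#' Bundles the field and laboratory irradiances, per-season exponential
#' light-attenuation coefficients `PAR_D(x) = exp(-k * x + a)` and daylight
#' hours.
#'
#' @param par_field mean daytime field PAR during the decomposition
#'   experiment (default 0.54 umol photons m^-2 s^-1).
#' @param par_lab laboratory irradiance (default 50.4).
#' @param attenuation named list of `list(k =, a =)` pairs per season;
#'   default provides `annual` with k = 0.15 m^-1, a = 5.05.
#' @param daylight_h named vector of daylight hours per day; default
#'   `c(annual = 12.1)` (solar mean at 50.36 deg N).
#' @return List of class `light_environment`.
#' @export
light_environment <- function(par_field = 0.54, par_lab = 50.4,
                              attenuation = list(annual = list(k = 0.15, a = 5.05)),
                              daylight_h = c(annual = 12.1)) {
  stopifnot(par_field >= 0, par_lab > 0)
  for (s in names(attenuation)) {
    if (attenuation[[s]]$k <= 0) stop("attenuation k must be > 0")
  }
  structure(list(par_field = par_field, par_lab = par_lab,
                 attenuation = attenuation, daylight_h = daylight_h),
            class = "light_environment")
}

#' PAR at depth
#'
#' Exponential decay of photon flux with depth, `exp(-k * depth + a)`, with
#' seasonal or annual coefficients. The intercept applies at the surface.
#'
#' @param depth depth (m), >= 0.
#' @param env a [light_environment()].
#' @param season name of the attenuation pair (default "annual").
#' @return PAR (umol photons m^-2 s^-1).
#' @export
par_at_depth <- function(depth, env, season = "annual") {
  if (any(depth < 0)) stop("depth must be >= 0")
  att <- env$attenuation[[season]]
  if (is.null(att)) stop("no attenuation coefficients for season ", season)
  exp(-att$k * depth + att$a)
}

#' Detrital sinking trajectory
#'
#' Geometry of transport from the forest to the local carbon sink: seabed
#' slope `m = sink_depth / sink_distance`, path length the hypotenuse, and
#' minimal along-path speed `v = path_length / travel_time`.
#'
#' @param sink_depth depth of the carbon sink (m), > 0.
#' @param sink_distance horizontal distance from the nearest forest (m), > 0.
#' @param travel_time assumed detrital travel time (days), default 50.
#' @return List of class `detrital_trajectory` with fields sink_depth,
#'   sink_distance, travel_time, m, v.
#' @export
detrital_trajectory <- function(sink_depth, sink_distance, travel_time = 50) {
  stopifnot(sink_depth > 0, sink_distance > 0, travel_time > 0)
  m <- sink_depth / sink_distance
  path <- sqrt(sink_depth^2 + sink_distance^2)
  structure(list(sink_depth = sink_depth, sink_distance = sink_distance,
                 travel_time = travel_time, m = m, v = path / travel_time),
            class = "detrital_trajectory")
}

#' Depth along the trajectory at a detrital age
#'
#' `depth(t) = t * v / sqrt(m^2 + 1) * m`: the distance travelled resolves
#' trigonometrically into a horizontal run and a vertical drop along the
#' sloped seabed; capped at the sink depth.
#'
#' @param t detrital age (days), >= 0.
#' @param traj a [detrital_trajectory()].
#' @return Depth (m).
#' @export
depth_at_age <- function(t, traj) {
  if (any(t < 0)) stop("t must be >= 0")
  pmin(traj$sink_depth, t * traj$v / sqrt(traj$m^2 + 1) * traj$m)
}

#' Proportion by which laboratory GPP is rescaled along the trajectory
#'
#' Two factors: the proportion of laboratory GPP left after subtracting what
#' the detritus was already achieving in the dim field photoenvironment,
#' `1 - PE(PAR_F)/PE(PAR_L)`, and the proportion of laboratory GPP supported
#' by the light at the detritus' current depth, `PE(PAR_D(depth(t)))/PE(PAR_L)`
#' (capped at 1: excess production in a brighter milieu cannot
#' photosynthesise).
#'
#' @param t detrital age (days).
#' @param env a [light_environment()].
#' @param traj a [detrital_trajectory()].
#' @param season attenuation season (default "annual").
#' @return P_GPP in [0, 1 - PE(PAR_F)/PE(PAR_L)].
#' @export
p_gpp <- function(t, env, traj, season = "annual") {
  pl <- pe(env$par_lab)
  if (pl <= 0) stop("PE(PAR_L) must be > 0")
  excess <- 1 - pe(env$par_field) / pl
  depth <- depth_at_age(t, traj)
  avail <- pmin(1, pe(par_at_depth(depth, env, season)) / pl)
  excess * avail
}

#' Species GPP (gross carbon assimilation) at a detrital age
#'
#' Linear-in-age prediction from a fitted detrital production trend, floored
#' at 0 (a failed photosynthetic apparatus does not recover). Cold-temperate
#' species have zero slope (constant level); the warm-temperate species
#' declines to zero.
#'
#' @param t detrital age (days).
#' @param intercept GPP at age 0 (g C g^-1 dry h^-1).
#' @param slope change per day (g C g^-1 h^-1 day^-1), default 0.
#' @return GPP (g C g^-1 dry h^-1), >= 0.
#' @export
gpp_at_age <- function(t, intercept, slope = 0) {
  pmax(0, intercept + slope * t)
}

#' Cumulative detrital carbon assimilation along the trajectory
#'
#' Running sum over whole detrital days k = 1..t of
#' `N * BE * D_CA(k) * h * GPP(k) * P_GPP(k)`, where `D_CA(k) = max(0, 1 - k D)`
#' is the remaining biomass fraction (never negative), h the daylight hours
#' per day, GPP the species' gross assimilation at age k and P_GPP the light
#' rescaling along the sinking path. The result is the carbon a shrinking
#' detrital pool can assimilate on its way to the sink (g C m^-2 period^-1).
#'
#' @param N sporophyte density (plants m^-2, zone-weighted).
#' @param BE biomass export (g dry plant^-1 period^-1).
#' @param D decomposition rate (day^-1).
#' @param gpp_intercept,gpp_slope species GPP trend (g C g^-1 dry h^-1 and
#'   per-day change).
#' @param env a [light_environment()].
#' @param traj a [detrital_trajectory()].
#' @param t final detrital age (days).
#' @param season attenuation/daylight season (default "annual").
#' @return List of class `assimilation_curve`: ages 1..t and the cumulative
#'   CA at each age (non-decreasing).
#' @export
cumulative_assimilation <- function(N, BE, D, gpp_intercept, gpp_slope = 0,
                                    env, traj, t, season = "annual") {
  stopifnot(t >= 1, N >= 0, BE >= 0)
  h <- env$daylight_h[[season]]
  if (is.null(h) || is.na(h)) stop("no daylight hours for season ", season)
  k <- seq_len(t)
  d_ca <- pmax(0, 1 - k * D)
  daily <- N * BE * d_ca * h * gpp_at_age(k, gpp_intercept, gpp_slope) *
    p_gpp(k, env, traj, season)
  structure(list(ages = k, cumulative_CA = cumsum(daily), season = season),
            class = "assimilation_curve")
}
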