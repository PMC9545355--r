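#' Litterbag decomposition rate
#'
#' `D = (M0 - M1) / (M0 * delta_t)`: proportional mass loss per day. Negative
#' values (retrieved mass above initial) indicate detrital growth and are
#' retained.
#'
#' @param M0 initial wet mass (g), > 0.
#' @param M1 retrieved wet mass (g), >= 0.
#' @param delta_t days deployed, > 0.
#' @return D (day^-1).
#' @export
decomposition_rate <- function(M0, M1, delta_t) {
  if (any(M0 <= 0)) stop("M0 must be > 0")
  if (any(M1 < 0)) stop("M1 must be >= 0")
  if (any(delta_t <= 0)) stop("delta_t must be > 0")
  (M0 - M1) / (M0 * delta_t)
}

#' Pool litterbag decomposition rates per species
#'
#' All bags from both experiments are pooled into a single per-species mean,
#' SE and n (the species-level rates are overall means across experiments);
#' per-experiment means are also returned.
#'
#' @param litterbags data frame in the `litterbags` schema: species,
#'   experiment, bag_id, M0_g, M1_g, delta_t_d.
#' @return List with `overall` (species, mean_D, se_D, n) and
#'   `by_experiment` data frames; rates in day^-1.
#' @export
pool_rates <- function(litterbags) {
  v <- validate_table(litterbags, "litterbags")
  if (!v$ok) stop("invalid litterbag table")
  D <- decomposition_rate(litterbags$M0_g, litterbags$M1_g, litterbags$delta_t_d)
  litterbags$D <- D
  summ <- function(d) {
    if (nrow(d) < 2L) stop("need >= 2 records per species to estimate an SE")
    data.frame(species = d$species[1L], mean_D = mean(d$D),
               se_D = se_mean(d$D), n = nrow(d))
  }
  overall <- do.call(rbind, lapply(split(litterbags, litterbags$species), summ))
  by_exp <- do.call(rbind, lapply(
    split(litterbags, interaction(litterbags$species, litterbags$experiment, drop = TRUE)),
    function(d) cbind(summ(d), experiment = d$experiment[1L])))
  rownames(overall) <- rownames(by_exp) <- NULL
  list(overall = overall, by_experiment = by_exp)
}

#' Grazing-scar proportions
#'
#' Excavation is scaled to the non-perforated area, perforation to the total:
#' `E = A_E / (A_T - A_P)`, `P = A_P / A_T`.
#'
#' @param A_E excavated area (cm^2).
#' @param A_P perforated area (cm^2).
#' @param A_T total lamina area (cm^2).
#' @return List with proportions `E` and `P`.
#' @export
grazing_proportions <- function(A_E, A_P, A_T) {
  if (any(A_P >= A_T)) stop("perforated area must be smaller than total area")
  if (any(A_E < 0 | A_P < 0)) stop("areas must be >= 0")
  if (any(A_E > A_T - A_P + 1e-12)) stop("excavated area exceeds non-perforated area")
  list(E = A_E / (A_T - A_P), P = A_P / A_T)
}

#' Fit a phloroglucinol standard curve
#'
#' Ordinary least-squares line of absorbance (765 nm) on phloroglucinol
#' concentration.
#'
#' @param concentrations standard concentrations (mg ml^-1), >= 3 distinct.
#' @param absorbances measured absorbances (AU).
#' @return List of class `standard_curve`: slope (AU per mg ml^-1), intercept
#'   (AU), r_squared, and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  if (length(unique(concentrations)) < 3L) {
    stop("need >= 3 distinct standard concentrations")
  }
  fit <- stats::lm(absorbances ~ concentrations)
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r_squared = suppressWarnings(summary(fit)$r.squared),
              fit = fit)
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Phloroglucinol standard curve: A = %.4f * conc + %.4f (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Phloroglucinol equivalents from sample absorbance
#'
#' Inverts the standard curve (triplicate absorbances averaged first), scales
#' by the dilution factor, and expresses the extract concentration as % of
#' dry tissue mass via the extraction ratio (10% w/v means 100 mg dry tissue
#' per ml solvent, so 1 mg ml^-1 in the extract is 1% of dry mass).
#'
#' @param sample_abs absorbance(s) of a sample; a vector is treated as
#'   triplicate readings of one sample and averaged.
#' @param curve a `standard_curve` from [fit_standard_curve()].
#' @param extract_w_v extraction ratio as a proportion (default 0.1 = 10% w/v).
#' @param dilution extract dilution factor applied before the plate (default 1).
#' @return Phenolic content (% of dry mass, phloroglucinol equivalents);
#'   negative inversions are clamped to 0 with a warning.
#' @export
pg_equivalents <- function(sample_abs, curve, extract_w_v = 0.1, dilution = 1) {
  if (abs(curve$slope) < .Machine$double.eps) stop("standard curve slope is zero")
  conc <- (mean(sample_abs) - curve$intercept) / curve$slope * dilution
  if (conc < 0) {
    warning("negative concentration from curve inversion clamped to 0")
    conc <- 0
  }
  # extract holds extract_w_v * 1000 mg dry tissue per ml
  conc / (extract_w_v * 1000) * 100
}

#' Detrital-age trend of a biochemical response
#'
#' OLS slope of a response (or its log) on detrital age, per species or
#' pooled: linear for e.g. phenolic content (% day^-1), log-linear for
#' exponential trends such as the C:N decline (day^-1).
#'
#' @param age detrital age (days).
#' @param response response values (e.g. phenolic_pct, C:N).
#' @param model "linear" or "log-linear".
#' @return List: slope, se, intercept, n, model, and the `lm` fit. For
#'   "log-linear" the slope is the exponential rate (per day).
#' @export
age_trend <- function(age, response, model = c("linear", "log-linear")) {
  model <- match.arg(model)
  if (length(unique(age)) < 3L) stop("need >= 3 distinct detrital ages")
  y <- if (model == "log-linear") {
    if (any(response <= 0)) stop("log-linear trend requires positive responses")
    log(response)
  } else response
  fit <- stats::lm(y ~ age)
  # exact fits (zero-noise oracle data) are legitimate inputs here
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(sm["age", "Estimate"]), se = unname(sm["age", "Std. Error"]),
       intercept = unname(sm["(Intercept)", "Estimate"]), n = length(age),
       model = model, fit = fit)
}

#' Decomposition rate against a biochemical predictor
#'
#' OLS slope of per-sample decomposition (% day^-1) on a biochemistry value
#' (%), quantifying e.g. how much slower detritus decomposes per percent of
#' carbon or soluble phenolics.
#'
#' @param D per-sample decomposition rates (% day^-1).
#' @param x paired biochemical predictor (%).
#' @return List: slope, se, n and the `lm` fit.
#' @export
decomposition_vs_biochem <- function(D, x) {
  if (length(D) != length(x)) stop("D and x must be paired")
  if (length(D) < 3L) stop("need >= 3 paired observations")
  fit <- stats::lm(D ~ x)
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(sm["x", "Estimate"]), se = unname(sm["x", "Std. Error"]),
       n = length(D), fit = fit)
}
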