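#' Combine standard errors by the variance sum law
#'
#' For a sum of independent estimates the squared standard errors add:
#' `SE = sqrt(sum(SE_i^2))`.
#'
#' @param ses vector of standard errors (>= 1 value, all >= 0).
#' @return Combined standard error.
#' @export
variance_sum_se <- function(ses) {
  if (length(ses) < 1L) stop("need at least one SE")
  if (any(ses < 0)) stop("standard errors must be >= 0")
  sqrt(sum(ses^2))
}

#' Confidence half-width for a product of two means
#'
#' Goodman's exact variance of a product of two independent mean estimates:
#' `var(ab) = se_a^2 se_b^2 + se_a^2 b^2 + se_b^2 a^2`.
#'
#' @param mean_a,se_a first mean and its SE.
#' @param mean_b,se_b second mean and its SE.
#' @param z normal quantile (default 1.959964, the 97.5 percentile point).
#' @return List: `mean` = a*b and `half_width` = z * sqrt(var).
#' @export
product_ci <- function(mean_a, se_a, mean_b, se_b, z = 1.959964) {
  if (z <= 0) stop("z must be > 0")
  hw <- z * sqrt(se_a^2 * se_b^2 + se_a^2 * mean_b^2 + se_b^2 * mean_a^2)
  list(mean = mean_a * mean_b, half_width = hw)
}

#' Detrital age at which the linear CSP model reaches zero
#'
#' With linear proportional decay the exported pool is exhausted at
#' `t = 1/D`; the SE follows by the delta method, `SE(1/D) = SE_D / D^2`.
#'
#' @param D decomposition rate (day^-1).
#' @param se_D optional SE of D.
#' @return List: `days` (1/D rounded to whole days), `days_exact`, `se`
#'   (delta-method SE, NA if `se_D` missing). Non-positive D (growing
#'   detritus) returns `Inf` with a warning.
#' @export
time_to_zero <- function(D, se_D = NA_real_) {
  if (D <= 0) {
    warning("D <= 0: detritus is not decaying, time to zero is infinite")
    return(list(days = Inf, days_exact = Inf, se = NA_real_))
  }
  list(days = round(1 / D), days_exact = 1 / D, se = se_D / D^2)
}

#' Fit the carbon-sequestration-potential decay model
#'
#' Combines a species' plant density N (plants m^-2, zone-weighted), its
#' per-plant carbon export CE (g C plant^-1 period^-1) and its decomposition
#' rate D (day^-1) into the linear pool model
#' `CSP(t) = N * CE * max(0, 1 - t * D)` (g C m^-2 period^-1): the exported
#' carbon still unremineralized at detrital age t. Uncertainty comes from N
#' and CE only (Goodman product-of-means CI); D's uncertainty surfaces
#' through the delta-method SE of the zero-crossing age.
#'
#' @param N plant density (plants m^-2); already zone-weighted if areal
#'   figures are wanted.
#' @param CE carbon export per plant for the period (g C plant^-1 period^-1).
#' @param D decomposition rate (day^-1).
#' @param se_N,se_CE,se_D standard errors (default 0, 0, NA).
#' @param species optional label.
#' @param period "annual" or "seasonal" (labelling only).
#' @param z normal quantile for CIs.
#' @return Object of class `csp_model` with methods `print`, `summary`,
#'   `coef`, `predict` and `plot`.
#' @export
csp_model <- function(N, CE, D, se_N = 0, se_CE = 0, se_D = NA_real_,
                      species = NA_character_, period = "annual",
                      z = 1.959964) {
  if (N < 0 || CE < 0) stop("N and CE must be >= 0")
  if (se_N < 0 || se_CE < 0) stop("standard errors must be >= 0")
  obj <- list(N = N, CE = CE, D = D, se_N = se_N, se_CE = se_CE, se_D = se_D,
              species = species, period = period, z = z)
  class(obj) <- "csp_model"
  obj
}

#' Evaluate a CSP model at detrital ages
#'
#' @param object a `csp_model`.
#' @param t detrital ages (days), default 0:200.
#' @param interval "confidence" attaches the product-of-means 95% CI.
#' @param ... unused.
#' @return Data frame: t, csp, and (with interval) ci_low, ci_high. The CI
#'   scales with the same decay factor as the mean (the decay factor carries
#'   no error) and is floored at 0.
#' @export
predict.csp_model <- function(object, t = 0:200,
                              interval = c("confidence", "none"), ...) {
  interval <- match.arg(interval)
  if (any(t < 0)) stop("detrital age must be >= 0")
  decay <- pmax(0, 1 - t * object$D)
  base <- object$N * object$CE
  out <- data.frame(t = t, csp = base * decay)
  if (interval == "confidence") {
    pc <- product_ci(object$N, object$se_N, object$CE, object$se_CE, z = object$z)
    out$ci_low <- pmax(0, (pc$mean - pc$half_width) * decay)
    out$ci_high <- (pc$mean + pc$half_width) * decay
  }
  out
}

#' @export
coef.csp_model <- function(object, ...) {
  c(N = object$N, CE = object$CE, D = object$D)
}

#' @export
print.csp_model <- function(x, ...) {
  tz <- time_to_zero(x$D, x$se_D)
  cat("Linear CSP decay model", if (!is.na(x$species)) paste0(" [", x$species, "]"),
      "\n", sep = "")
  cat(sprintf("  CSP(t) = N * CE * (1 - t * D),  %s\n", x$period))
  cat(sprintf("  N  = %.3f plants m^-2 (SE %.3f)\n", x$N, x$se_N))
  cat(sprintf("  CE = %.2f g C plant^-1 (SE %.2f)\n", x$CE, x$se_CE))
  cat(sprintf("  D  = %.4f day^-1%s\n", x$D,
              if (is.na(x$se_D)) "" else sprintf(" (SE %.4f)", x$se_D)))
  cat(sprintf("  CSP(0) = %.1f g C m^-2; reaches zero at %s days%s\n",
              x$N * x$CE, format(tz$days),
              if (is.na(tz$se)) "" else sprintf(" (SE %.1f)", tz$se)))
  invisible(x)
}

#' @export
summary.csp_model <- function(object, horizon_t = 50, ...) {
  tz <- time_to_zero(object$D, object$se_D)
  at_h <- predict(object, t = horizon_t)
  out <- list(model = object, t_zero = tz, horizon_t = horizon_t,
              csp_at_horizon = at_h$csp,
              ci_at_horizon = c(at_h$ci_low, at_h$ci_high))
  class(out) <- "summary.csp_model"
  out
}

#' @export
print.summary.csp_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  CSP(%d d) = %.1f g C m^-2 [%.1f, %.1f]\n", x$horizon_t,
              x$csp_at_horizon, x$ci_at_horizon[1], x$ci_at_horizon[2]))
  invisible(x)
}

#' @export
plot.csp_model <- function(x, t = NULL, ...) {
  if (is.null(t)) {
    tmax <- if (x$D > 0) ceiling(1.1 / x$D) else 200
    t <- seq(0, tmax, length.out = 201)
  }
  pr <- predict(x, t = t)
  graphics::plot(pr$t, pr$csp, type = "l",
                 xlab = "detrital age (days)",
                 ylab = sprintf("CSP (g C m^-2 %s^-1)", x$period),
                 main = if (!is.na(x$species)) x$species else "CSP decay", ...)
  graphics::lines(pr$t, pr$ci_low, lty = 2)
  graphics::lines(pr$t, pr$ci_high, lty = 2)
  invisible(pr)
}

#' CSP decay curve over a set of detrital ages
#'
#' Convenience wrapper returning the curve, CI band and zero-crossing age for
#' a carbon budget.
#'
#' @inheritParams csp_model
#' @param ages sorted detrital ages (days).
#' @return List of class `csp_curve`: species, ages, csp, ci_low, ci_high,
#'   t_zero (whole days).
#' @export
csp_curve <- function(N, CE, D, ages, se_N = 0, se_CE = 0, se_D = NA_real_,
                      species = NA_character_, period = "annual",
                      z = 1.959964) {
  if (is.unsorted(ages)) stop("ages must be sorted ascending")
  m <- csp_model(N, CE, D, se_N, se_CE, se_D, species, period, z)
  pr <- predict(m, t = ages)
  structure(list(species = species, ages = ages, csp = pr$csp,
                 ci_low = pr$ci_low, ci_high = pr$ci_high,
                 t_zero = time_to_zero(D, se_D)$days),
            class = "csp_curve")
}
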