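# Internal helpers shared across stages.

# standard error of the mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))

# days in a calendar month of a given year (Feb = 28 unless leap)
days_in_month <- function(month, year) {
  stopifnot(all(month %in% 1:12))
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  out <- dm[month]
  out[month == 2 & leap] <- 29
  out
}

# meteorological season of a calendar month
season_of_month <- function(month) {
  stopifnot(all(month %in% 1:12))
  s <- c("winter", "winter", "spring", "spring", "spring",
         "summer", "summer", "summer", "autumn", "autumn", "autumn", "winter")
  factor(s[month], levels = c("winter", "spring", "summer", "autumn"))
}

# mean-one lognormal multiplicative noise
rlnorm1 <- function(n, sigma) stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)

#' Validate a data frame against a named column schema
#'
#' Checks presence of required columns and simple per-column constraints
#' (numeric positivity / non-negativity), returning a row-level report rather
#' than failing on first error.
#'
#' @param df data frame to check.
#' @param schema name of a built-in schema: one of "erosion",
#'   "carbon_fraction", "litterbags", "biochem", "scars", "incubations",
#'   "temperature".
#' @return A list with `ok` (logical), `missing_columns` (character) and
#'   `bad_rows` (data frame of row index, column, problem).
#' @export
validate_table <- function(df, schema) {
  schemas <- list(
    erosion = list(
      cols = c("species", "plant_id", "month", "year", "digit", "L_I_cm",
               "H_I_cm", "L_F_cm", "H_F_cm", "seg1_wet_g", "seg2_wet_g",
               "seg3_wet_g", "seg3_dry_g", "delta_t_d"),
      positive = c("L_I_cm", "L_F_cm", "seg1_wet_g", "seg2_wet_g",
                   "seg3_wet_g", "seg3_dry_g", "delta_t_d"),
      nonneg = c("H_I_cm", "H_F_cm")
    ),
    carbon_fraction = list(
      cols = c("species", "month", "year", "carbon_pct", "nitrogen_pct"),
      positive = c("carbon_pct", "nitrogen_pct"), nonneg = character()
    ),
    litterbags = list(
      cols = c("species", "experiment", "bag_id", "M0_g", "M1_g", "delta_t_d"),
      positive = c("M0_g", "delta_t_d"), nonneg = "M1_g"
    ),
    biochem = list(
      cols = c("species", "detrital_age_d", "carbon_pct", "nitrogen_pct",
               "phenolic_pct", "water_pct"),
      positive = c("carbon_pct", "nitrogen_pct"), nonneg = c("detrital_age_d", "phenolic_pct")
    ),
    scars = list(
      cols = c("species", "sample_id", "A_E_cm2", "A_P_cm2", "A_T_cm2"),
      positive = "A_T_cm2", nonneg = c("A_E_cm2", "A_P_cm2")
    ),
    incubations = list(
      cols = c("species", "detrital_age_d", "pair_id", "mode", "c_S0", "c_S10",
               "c_S30", "c_B0", "c_B10", "c_B30", "V_S_L", "V_B_L", "mass_g",
               "ambient_par"),
      positive = c("V_S_L", "V_B_L", "mass_g"),
      nonneg = c("c_S0", "c_S10", "c_S30", "c_B0", "c_B10", "c_B30", "ambient_par")
    ),
    temperature = list(
      cols = c("scenario", "year", "t_min", "t_mean", "t_max"),
      positive = character(), nonneg = character()
    )
  )
  if (!schema %in% names(schemas)) stop("unknown schema: ", schema)
  sc <- schemas[[schema]]
  missing <- setdiff(sc$cols, names(df))
  bad <- data.frame(row = integer(), column = character(), problem = character())
  if (length(missing) == 0L) {
    for (cl in sc$positive) {
      i <- which(!is.finite(df[[cl]]) | df[[cl]] <= 0)
      if (length(i)) bad <- rbind(bad, data.frame(row = i, column = cl, problem = "must be > 0"))
    }
    for (cl in sc$nonneg) {
      i <- which(!is.finite(df[[cl]]) | df[[cl]] < 0)
      if (length(i)) bad <- rbind(bad, data.frame(row = i, column = cl, problem = "must be >= 0"))
    }
    if ("species" %in% names(df)) {
      i <- which(!df$species %in% laminaria_species())
      if (length(i)) bad <- rbind(bad, data.frame(row = i, column = "species", problem = "unknown species code"))
    }
  }
  list(ok = length(missing) == 0L && nrow(bad) == 0L,
       missing_columns = missing, bad_rows = bad)
}
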