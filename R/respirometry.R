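# Closed-bottle respirometry: blank-corrected O2 flux per unit wet mass.
# rate = [(c_S1 - c_S0) * V_S - (c_B1 - c_B0) * V_B] / (M * delta_t)
o2_rate <- function(c_S0, c_S1, c_B0, c_B1, V_S, V_B, M, delta_t) {
  if (any(V_S <= 0 | V_B <= 0)) stop("incubation volumes must be > 0")
  if (any(M <= 0)) stop("sample mass must be > 0")
  if (any(delta_t <= 0)) stop("delta_t must be > 0")
  ((c_S1 - c_S0) * V_S - (c_B1 - c_B0) * V_B) / (M * delta_t)
}

#' Net primary production from a light incubation
#'
#' Blank-corrected O2 evolution per g wet mass. Readings are taken at 0, 10
#' and 30 min; the rate is computed per window (0-10 and 10-30 min) and the
#' two window rates averaged, then converted to per hour.
#'
#' @param rec one light-mode incubation record (list or one-row data frame
#'   with c_S0, c_S10, c_S30, c_B0, c_B10, c_B30, V_S_L, V_B_L, mass_g, mode).
#' @param per for the default `"hour"`, the per-minute rate is multiplied by
#'   60; `"minute"` returns the raw rate.
#' @return NPP (umol O2 g^-1 wet h^-1 by default). Negative when respiratory
#'   demand exceeds photosynthesis.
#' @export
npp <- function(rec, per = c("hour", "minute")) {
  per <- match.arg(per)
  if (!is.null(rec$mode) && rec$mode != "light") stop("npp() requires a light incubation")
  r1 <- o2_rate(rec$c_S0, rec$c_S10, rec$c_B0, rec$c_B10,
                rec$V_S_L, rec$V_B_L, rec$mass_g, 10)
  r2 <- o2_rate(rec$c_S10, rec$c_S30, rec$c_B10, rec$c_B30,
                rec$V_S_L, rec$V_B_L, rec$mass_g, 20)
  r <- (r1 + r2) / 2
  if (per == "hour") r * 60 else r
}

#' Respiration from a dark incubation
#'
#' Sign-flipped analogue of [npp()]: positive under net O2 consumption.
#'
#' @inheritParams npp
#' @return R (umol O2 g^-1 wet h^-1 by default).
#' @export
respiration <- function(rec, per = c("hour", "minute")) {
  per <- match.arg(per)
  if (!is.null(rec$mode) && rec$mode != "dark") stop("respiration() requires a dark incubation")
  rec2 <- rec
  rec2$mode <- "light"
  -npp(rec2, per = per)
}

#' Gross primary production
#'
#' `GPP = NPP + R` (respiration assumed equal in light and dark).
#'
#' @param npp_val NPP (umol O2 g^-1 h^-1).
#' @param r_val R (umol O2 g^-1 h^-1).
#' @return GPP in the same units.
#' @export
gpp <- function(npp_val, r_val) npp_val + r_val

#' Carbon assimilation from an O2 flux
#'
#' `CA = NPP * 1e-6 * 12.0107 / M_R` converts a mass-specific O2 flux
#' (umol O2 g^-1 wet h^-1) to a carbon flux per g dry mass, assuming
#' photosynthetic and respiratory quotients of 1.
#'
#' @param npp_o2 O2 flux (umol O2 g^-1 wet h^-1); GPP may be supplied for
#'   gross assimilation.
#' @param M_R dry:wet mass ratio in (0, 1].
#' @param pq photosynthetic (or respiratory) quotient, default 1.
#' @return CA (g C g^-1 dry h^-1).
#' @export
carbon_assimilation <- function(npp_o2, M_R, pq = 1) {
  if (any(M_R <= 0 | M_R > 1)) stop("M_R must be in (0, 1]")
  npp_o2 / pq * 1e-6 * 12.0107 / M_R
}

#' Drop incubation records from photoinhibited collection days
#'
#' Records whose collection-day ambient photon flux reached the
#' photoinhibition threshold are excluded (in situ O2 production is reduced
#' above it, so laboratory rates from those days are unrepresentative).
#'
#' @param records incubation data frame with an `ambient_par` column.
#' @param par_threshold threshold (umol photons m^-2 s^-1), default 971.
#' @return The filtered data frame; the number of dropped records is reported
#'   via a message.
#' @export
photoinhibition_filter <- function(records, par_threshold = 971) {
  if (is.null(records$ambient_par)) stop("records must carry ambient_par")
  keep <- records$ambient_par < par_threshold
  if (any(!keep)) message(sum(!keep), " record(s) dropped for photoinhibition ",
                          "(ambient PAR >= ", par_threshold, ")")
  records[keep, , drop = FALSE]
}

#' Reduce paired light/dark incubations to production estimates
#'
#' Applies the photoinhibition filter, computes NPP from each light record
#' and R from its paired dark record, GPP = NPP + R, and converts both to
#' carbon assimilation with the species' dry:wet ratio.
#'
#' @param incubations data frame in the `incubations` schema; light and dark
#'   rows are matched by `pair_id`.
#' @param M_R named vector of dry:wet ratios per species (May reference
#'   values), e.g. `c(digitata = 0.149, ...)`.
#' @param par_threshold photoinhibition threshold (default 971).
#' @return Data frame: species, detrital_age_d, pair_id, NPP, R, GPP
#'   (umol O2 g^-1 h^-1), CA_net, CA_gross (g C g^-1 dry h^-1).
#' @export
process_incubations <- function(incubations, M_R, par_threshold = 971) {
  v <- validate_table(incubations, "incubations")
  if (!v$ok) stop("invalid incubation table")
  inc <- photoinhibition_filter(incubations, par_threshold)
  out <- lapply(split(inc, interaction(inc$species, inc$pair_id, drop = TRUE)),
                function(d) {
    li <- d[d$mode == "light", , drop = FALSE]
    da <- d[d$mode == "dark", , drop = FALSE]
    if (nrow(li) != 1L || nrow(da) != 1L) return(NULL)  # unpaired after filtering
    np <- npp(li)
    r <- respiration(da)
    g <- gpp(np, r)
    mr <- M_R[[li$species]]
    if (is.null(mr)) stop("no M_R configured for species ", li$species)
    data.frame(species = li$species, detrital_age_d = li$detrital_age_d,
               pair_id = li$pair_id, NPP = np, R = r, GPP = g,
               CA_net = carbon_assimilation(np, mr),
               CA_gross = carbon_assimilation(g, mr))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$species, out$detrital_age_d, out$pair_id), ]
}
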