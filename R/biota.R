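#' Benthic functional-group biomass state
#'
#' Five functional groups: aerobic and anaerobic bacteria, meiofauna,
#' deposit feeders and suspension feeders, each tracked as a carbon biomass
#' (g C m^-2) with fixed Redfield internal stoichiometry.
#'
#' @param bact_aerobic,bact_anaerobic,meiofauna,deposit_feeders,suspension_feeders
#'   initial biomasses, g C m^-2
#' @return a named numeric vector of class \code{biota_state}
#' @export
biota_state <- function(bact_aerobic = 0.1, bact_anaerobic = 0.1,
                        meiofauna = 0.1, deposit_feeders = 0.5,
                        suspension_feeders = 0.2) {
  x <- c(bact_aerobic = bact_aerobic, bact_anaerobic = bact_anaerobic,
         meiofauna = meiofauna, deposit_feeders = deposit_feeders,
         suspension_feeders = suspension_feeders)
  if (any(x < 0)) stop_config("biomasses must be >= 0")
  structure(x, class = c("biota_state", "numeric"))
}

#' Default physiological parameters of the benthic food web
#'
#' Diet preference weights follow the food-web topology: suspension feeders
#' intercept settling pelagic detritus; deposit feeders eat semi-labile POM
#' with meiofauna as a less-preferred (half-weight) prey; meiofauna eat
#' aerobic bacteria and (half-weight) semi-labile POM; aerobic bacteria are
#' the exclusive consumers of labile DOM plus semi-labile POM inside the
#' oxic layer; anaerobic bacteria consume semi-labile and (half-weight)
#' refractory POM below the oxic layer. Rate magnitudes are calibration
#' values chosen so that spin-up equilibria land in observed orders of
#' magnitude (macrofauna ~0.1-2, meiofauna ~0.1-0.5, aerobic bacteria
#' ~0.1-0.3 g C m^-2); the background mortalities of deposit and suspension
#' feeders (0.001 day^-1 in the standard set) are the documented scenario
#' constants.
#'
#' @return a named list of per-group parameter lists with fields
#'   \code{max_uptake} (day^-1), \code{half_sat} (g C m^-2),
#'   \code{assim_eff}, \code{basal_resp} (day^-1), \code{mortality}
#'   (day^-1), \code{q10}, and \code{diet} (named preference weights,
#'   summing to 1)
#' @export
default_group_params <- function() {
  norm <- function(w) w / sum(w)
  list(
    bact_aerobic = list(
      max_uptake = 3.0, half_sat = 0.5, assim_eff = 0.3,
      basal_resp = 0.02, mortality = 0.04, closure_mort = 0, q10 = 2,
      diet = norm(c(dom = 1, semilabile_oxic = 0.5))),
    bact_anaerobic = list(
      max_uptake = 0.4, half_sat = 1.0, assim_eff = 0.3,
      basal_resp = 0.003, mortality = 0.018, closure_mort = 0, q10 = 3,
      diet = norm(c(semilabile_deep = 1, refractory_deep = 0.5))),
    meiofauna = list(
      max_uptake = 0.35, half_sat = 0.3, assim_eff = 0.35,
      basal_resp = 0.01, mortality = 0.01, closure_mort = 0.05, q10 = 2,
      diet = norm(c(bact_aerobic = 1, semilabile = 0.5))),
    deposit_feeders = list(
      max_uptake = 0.08, half_sat = 1.0, assim_eff = 0.5,
      basal_resp = 0.005, mortality = 0.001, closure_mort = 0.004, q10 = 2.5,
      diet = norm(c(semilabile = 1, meiofauna = 0.2))),
    suspension_feeders = list(
      max_uptake = 0.12, half_sat = 0.1, assim_eff = 0.6,
      basal_resp = 0.01, mortality = 0.001, closure_mort = 0.005, q10 = 2,
      diet = c(pelagic_detritus = 1))
  )
}

#' Q10 temperature scaling factor
#'
#' \eqn{q_{10}^{(T - T_{ref})/10}} with reference temperature 10 degrees C.
#'
#' @param q10 dimensionless Q10
#' @param temperature degrees C
#' @param t_ref reference temperature, degrees C
#' @return dimensionless factor (exactly 1 at the reference temperature)
#' @export
q10_factor <- function(q10, temperature, t_ref = 10) {
  q10^((temperature - t_ref) / 10)
}

#' Holling type-II uptake over a preference-weighted diet
#'
#' Total uptake saturates on the preference-weighted available resource;
#' consumption is apportioned across diet items by weighted availability and
#' limited so that no resource is consumed beyond a fixed fraction of its
#' stock per step.
#'
#' @param biomass consumer biomass, g C m^-2
#' @param resources named availabilities (g C m^-2, or g C m^-2 day^-1 * dt
#'   for flux-type resources) for each diet item
#' @param params one group's parameter list (see
#'   \code{\link{default_group_params}})
#' @param temperature degrees C
#' @param dt time step, day
#' @param max_frac maximum fraction of a resource consumable per step
#' @return named per-resource consumption (same units as resources,
#'   amounts over \code{dt})
#' @export
uptake_flux <- function(biomass, resources, params, temperature = 10,
                        dt = 1, max_frac = 0.8) {
  stopifnot(biomass >= 0, all(resources >= 0))
  w <- params$diet
  r <- resources[names(w)]
  r[is.na(r)] <- 0
  avail <- sum(w * r)
  if (avail <= 0 || biomass <= 0)
    return(stats::setNames(rep(0, length(w)), names(w)))
  ft <- q10_factor(params$q10, temperature)
  total <- params$max_uptake * biomass * ft * avail / (avail + params$half_sat) * dt
  u <- total * (w * r) / avail
  pmin(u, max_frac * r)
}

#' Bioturbation index from faunal biomass
#'
#' A weighted sum of faunal biomasses normalised by a reference biomass;
#' linear in biomass, zero without fauna.
#'
#' @param state a \code{\link{biota_state}}
#' @param weights named trait weights for the mixing groups
#' @param ref_biomass normalising biomass, g C m^-2
#' @return dimensionless index
#' @export
bioturbation_index <- function(state,
                               weights = c(deposit_feeders = 1,
                                           suspension_feeders = 0.5,
                                           meiofauna = 0.25),
                               ref_biomass = 1) {
  if (any(weights < 0)) stop_config("trait weights must be >= 0")
  sum(weights * state[names(weights)]) / ref_biomass
}

# element ratio (mmol per g C) descriptors -------------------------------

redfield_ratios <- function() {
  c(N = mmol_per_gC("N"), P = mmol_per_gC("P"), Si = 0)
}

pool_ratios <- function(om, pool) {
  cC <- om["C", pool]
  if (cC <= 0) return(c(N = 0, P = 0, Si = 0))
  c(N = om["N", pool], P = om["P", pool], Si = om["Si", pool]) / cC
}

#' Advance the benthic food web by one time step
#'
#' Forward-Euler step with per-flux limiting. All carbon is routed
#' explicitly: assimilated uptake grows biomass, the unassimilated fraction
#' and mortality return to the semi-labile POM pool, respiration is exported
#' as an oxygen-consuming carbon flux, and the nitrogen/phosphorus
#' associated with respired biomass is excreted to the ammonium/phosphate
#' pools (oxic layer for aerobic organisms and fauna, anoxic for anaerobic
#' bacteria). Silicate ingested with POM is either egested back to POM or,
#' for the assimilated share, released to pore water (fauna and bacteria do
#' not retain silica).
#'
#' @param biota a \code{\link{biota_state}}
#' @param om organic-matter pool matrix (rows C, N, P, Si; columns dom,
#'   semilabile, refractory, buried), as built by \code{\link{om_pools}}
#' @param env list with \code{temperature} (degC), \code{detritus_C_flux}
#'   (g C m^-2 day^-1), \code{detritus_N_flux}, \code{detritus_P_flux},
#'   \code{detritus_Si_flux} (mmol m^-2 day^-1), \code{D1} (m),
#'   \code{zp_sl}, \code{zp_rf} (m)
#' @param params group parameter list (see
#'   \code{\link{default_group_params}})
#' @param dt time step, day
#' @return a list with elements \code{biota} (updated state), \code{om}
#'   (updated pool matrix), \code{fluxes} (respiration, excretion, silica
#'   release, detritus consumption and per-group uptake diagnostics)
#' @export
step_biota <- function(biota, om, env, params = default_group_params(),
                       dt = 1) {
  if (dt <= 0) stop_config("dt must be > 0")
  groups <- names(biota)
  rr <- redfield_ratios()

  frac_ox_sl <- 1 - exp(-env$D1 / env$zp_sl)
  frac_deep_rf <- exp(-env$D1 / env$zp_rf)
  slC <- om["C", "semilabile"]

  det <- c(C = env$detritus_C_flux * dt, N = env$detritus_N_flux * dt,
           P = env$detritus_P_flux * dt, Si = env$detritus_Si_flux * dt)
  det_ratio <- if (det["C"] > 0) {
    c(N = det[["N"]], P = det[["P"]], Si = det[["Si"]]) / det[["C"]]
  } else c(N = 0, P = 0, Si = 0)

  # resource table: availability (g C) and element ratios, plus which stock
  # the removal is charged to
  res <- list(
    dom = list(avail = om["C", "dom"], pool = "om_dom",
               ratio = pool_ratios(om, "dom")),
    semilabile = list(avail = slC, pool = "om_sl",
                      ratio = pool_ratios(om, "semilabile")),
    semilabile_oxic = list(avail = slC * frac_ox_sl, pool = "om_sl",
                           ratio = pool_ratios(om, "semilabile")),
    semilabile_deep = list(avail = slC * (1 - frac_ox_sl), pool = "om_sl",
                           ratio = pool_ratios(om, "semilabile")),
    # only a small accessible share of refractory POM is edible as-is;
    # the rest must pass through bacterial breakdown to semi-labile first
    refractory_deep = list(avail = om["C", "refractory"] * frac_deep_rf *
                             (env$rf_access %||% 0.05),
                           pool = "om_rf",
                           ratio = pool_ratios(om, "refractory")),
    pelagic_detritus = list(avail = det[["C"]], pool = "detritus",
                            ratio = det_ratio),
    bact_aerobic = list(avail = biota[["bact_aerobic"]],
                        pool = "bact_aerobic", ratio = rr),
    meiofauna = list(avail = biota[["meiofauna"]],
                     pool = "meiofauna", ratio = rr)
  )
  avail <- vapply(res, function(r) r$avail, 0)

  # desired uptake per consumer, then joint scaling per resource so total
  # consumption never exceeds 80% of a stock in one step
  desired <- lapply(groups, function(g) {
    uptake_flux(biota[[g]], avail, params[[g]], env$temperature, dt)
  })
  names(desired) <- groups
  demand <- stats::setNames(rep(0, length(res)), names(res))
  for (g in groups) {
    d <- desired[[g]]
    demand[names(d)] <- demand[names(d)] + d
  }
  # suspension feeders filter only part of the water passing the bed, so
  # the settling flux can never be intercepted entirely
  cap <- stats::setNames(rep(0.8, length(res)), names(res))
  cap[["pelagic_detritus"]] <- 0.4
  scale <- stats::setNames(rep(1, length(res)), names(res))
  over <- demand > cap * avail & demand > 0
  scale[over] <- (cap * avail)[over] / demand[over]
  # shared-stock resources (all semilabile views draw the same pool)
  sl_names <- c("semilabile", "semilabile_oxic", "semilabile_deep")
  sl_demand <- sum((demand * scale)[sl_names])
  if (sl_demand > 0.8 * slC && sl_demand > 0)
    scale[sl_names] <- scale[sl_names] * 0.8 * slC / sl_demand

  # apply uptakes
  pool_removal <- c(om_dom = 0, om_sl = 0, om_rf = 0, detritus = 0,
                    bact_aerobic = 0, meiofauna = 0)
  elem_removal <- matrix(0, nrow = 3, ncol = length(pool_removal),
                         dimnames = list(c("N", "P", "Si"),
                                         names(pool_removal)))
  dB <- stats::setNames(rep(0, length(groups)), groups)
  uptake_diag <- stats::setNames(rep(0, length(groups)), groups)
  egest_sl <- c(C = 0, N = 0, P = 0, Si = 0)
  nh4 <- c(oxic = 0, anoxic = 0)
  po4 <- c(oxic = 0, anoxic = 0)
  si_rel <- c(oxic = 0, anoxic = 0)
  resp_aer_C <- 0
  resp_ana_C <- 0

  for (g in groups) {
    u <- desired[[g]] * scale[names(desired[[g]])]
    uC <- sum(u)
    uptake_diag[[g]] <- uC
    if (uC > 0) {
      aeff <- params[[g]]$assim_eff
      is_bacteria <- g %in% c("bact_aerobic", "bact_anaerobic")
      uN <- uP <- uSi <- 0
      for (rn in names(u)) {
        if (u[[rn]] <= 0) next
        rd <- res[[rn]]
        pool_removal[[rd$pool]] <- pool_removal[[rd$pool]] + u[[rn]]
        elem_removal[, rd$pool] <- elem_removal[, rd$pool] +
          u[[rn]] * rd$ratio
        uN <- uN + u[[rn]] * rd$ratio[["N"]]
        uP <- uP + u[[rn]] * rd$ratio[["P"]]
        uSi <- uSi + u[[rn]] * rd$ratio[["Si"]]
      }
      assimC <- aeff * uC
      dB[[g]] <- dB[[g]] + assimC
      layer <- if (g == "bact_anaerobic") "anoxic" else "oxic"
      if (is_bacteria) {
        # bacterial growth efficiency: the unassimilated share is respired
        # (not egested), its N/P remineralised, and ingested silica freed
        if (g == "bact_anaerobic") resp_ana_C <- resp_ana_C + (1 - aeff) * uC
        else resp_aer_C <- resp_aer_C + (1 - aeff) * uC
        nh4[[layer]] <- nh4[[layer]] + (uN - assimC * rr[["N"]])
        po4[[layer]] <- po4[[layer]] + (uP - assimC * rr[["P"]])
        si_rel[[layer]] <- si_rel[[layer]] + uSi
      } else {
        egest_sl <- egest_sl +
          c(C = (1 - aeff) * uC, N = (1 - aeff) * uN,
            P = (1 - aeff) * uP, Si = (1 - aeff) * uSi)
        # stoichiometric balancing: assimilated N/P beyond the Redfield
        # requirement of new biomass is excreted immediately
        nh4[[layer]] <- nh4[[layer]] + (aeff * uN - assimC * rr[["N"]])
        po4[[layer]] <- po4[[layer]] + (aeff * uP - assimC * rr[["P"]])
        si_rel[[layer]] <- si_rel[[layer]] + aeff * uSi
      }
    }
  }

  # temperature-scaled basal respiration; background mortality is a
  # temperature-independent constant
  for (g in groups) {
    ft <- q10_factor(params[[g]]$q10, env$temperature)
    respC <- min(params[[g]]$basal_resp * ft, 0.09) * biota[[g]] * dt
    # linear background mortality plus a quadratic closure standing in for
    # predation by unresolved higher trophic levels
    mrate <- params[[g]]$mortality +
      (params[[g]]$closure_mort %||% 0) * biota[[g]]
    mortC <- min(mrate, 0.09) * biota[[g]] * dt
    dB[[g]] <- dB[[g]] - respC - mortC
    layer <- if (g == "bact_anaerobic") "anoxic" else "oxic"
    if (g == "bact_anaerobic") resp_ana_C <- resp_ana_C + respC
    else resp_aer_C <- resp_aer_C + respC
    nh4[[layer]] <- nh4[[layer]] + respC * rr[["N"]]
    po4[[layer]] <- po4[[layer]] + respC * rr[["P"]]
    egest_sl <- egest_sl + c(C = mortC, N = mortC * rr[["N"]],
                             P = mortC * rr[["P"]], Si = 0)
  }
  # predation losses
  dB[["bact_aerobic"]] <- dB[["bact_aerobic"]] -
    pool_removal[["bact_aerobic"]]
  dB[["meiofauna"]] <- dB[["meiofauna"]] - pool_removal[["meiofauna"]]

  newb <- unclass(biota) + dB
  if (any(newb < -1e-12))
    stop("step_biota: time step too large, biomass would go negative",
         call. = FALSE)
  newb[newb < 0] <- 0

  om2 <- om
  om2["C", "dom"] <- om["C", "dom"] - pool_removal[["om_dom"]]
  om2[c("N", "P", "Si"), "dom"] <-
    om[c("N", "P", "Si"), "dom"] - elem_removal[, "om_dom"]
  om2["C", "semilabile"] <- om["C", "semilabile"] -
    pool_removal[["om_sl"]] + egest_sl[["C"]]
  om2[c("N", "P", "Si"), "semilabile"] <-
    om[c("N", "P", "Si"), "semilabile"] - elem_removal[, "om_sl"] +
    egest_sl[c("N", "P", "Si")]
  om2["C", "refractory"] <- om["C", "refractory"] - pool_removal[["om_rf"]]
  om2[c("N", "P", "Si"), "refractory"] <-
    om[c("N", "P", "Si"), "refractory"] - elem_removal[, "om_rf"]

  # bacterial seed stock: a trace inoculum persists (replenished from
  # semi-labile POM when that pool can fund it, so mass is conserved),
  # letting populations regrow after a grazing- or starvation-driven
  # collapse instead of going extinct
  seed <- 0.01
  for (g in c("bact_aerobic", "bact_anaerobic")) {
    if (newb[[g]] < seed && om2["C", "semilabile"] > 0) {
      fund <- min(seed - newb[[g]], 0.5 * om2["C", "semilabile"],
                  0.5 * om2["N", "semilabile"] / rr[["N"]],
                  0.5 * om2["P", "semilabile"] / rr[["P"]])
      fund <- max(fund, 0)
      newb[[g]] <- newb[[g]] + fund
      om2["C", "semilabile"] <- om2["C", "semilabile"] - fund
      om2["N", "semilabile"] <- om2["N", "semilabile"] - fund * rr[["N"]]
      om2["P", "semilabile"] <- om2["P", "semilabile"] - fund * rr[["P"]]
    }
  }
  om2[om2 < 0 & om2 > -1e-12] <- 0

  list(
    biota = structure(newb, class = class(biota)),
    om = om2,
    fluxes = list(
      detritus_consumed = c(C = pool_removal[["detritus"]],
                            elem_removal[, "detritus"]),
      resp_aerobic_C = resp_aer_C,
      resp_anaerobic_C = resp_ana_C,
      nh4_excretion = nh4,
      po4_excretion = po4,
      si_release = si_rel,
      uptake = uptake_diag
    )
  )
}
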