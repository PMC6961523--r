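#' Organic-matter pool matrix
#'
#' Depth-integrated stocks of the four benthic organic-matter pools for each
#' element. Carbon is in g C m^-2, nutrients in mmol m^-2. Unless overridden
#' the nutrient contents are Redfield-proportional to carbon (with a
#' diatom-like Si quota on the particulate pools only).
#'
#' @param dom_C,semilabile_C,refractory_C,buried_C initial carbon stocks,
#'   g C m^-2
#' @return a 4 x 4 numeric matrix, rows \code{C, N, P, Si}, columns
#'   \code{dom, semilabile, refractory, buried}
#' @export
om_pools <- function(dom_C = 0.05, semilabile_C = 1, refractory_C = 5,
                     buried_C = 0) {
  cc <- c(dom = dom_C, semilabile = semilabile_C,
          refractory = refractory_C, buried = buried_C)
  if (any(cc < 0)) stop_config("OM stocks must be >= 0")
  m <- rbind(C = cc,
             N = cc * mmol_per_gC("N"),
             P = cc * mmol_per_gC("P"),
             Si = cc * mmol_per_gC("Si"))
  m["Si", c("dom", "buried")] <- 0
  m
}

biota_N <- function(biota) sum(biota) * mmol_per_gC("N")
biota_P <- function(biota) sum(biota) * mmol_per_gC("P")

# move a carbon amount (with proportional elements) between om columns
om_transfer <- function(om, from, to, c_amount) {
  cC <- om["C", from]
  if (cC <= 0 || c_amount <= 0) return(om)
  f <- min(c_amount / cC, 1)
  moved <- om[, from] * f
  om[, from] <- om[, from] - moved
  om[, to] <- om[, to] + moved
  om
}

# re-apportion layer contents when D1/D2 move; the moving boundary carries
# the donor layer's mean concentration
relayer <- function(nut, d1_old, d2_old, d1_new, d2_new, z_bed) {
  shift <- function(nut, iu, il, b_old, b_new, top_u, bot_l) {
    th_u <- b_old - top_u
    th_l <- bot_l - b_old
    if (b_new > b_old && th_l > 0) {            # upper layer grows
      f <- min((b_new - b_old) / th_l, 1)
      moved <- nut[, il] * f
      nut[, il] <- nut[, il] - moved
      nut[, iu] <- nut[, iu] + moved
    } else if (b_new < b_old && th_u > 0) {      # upper layer shrinks
      f <- min((b_old - b_new) / th_u, 1)
      moved <- nut[, iu] * f
      nut[, iu] <- nut[, iu] - moved
      nut[, il] <- nut[, il] + moved
    }
    nut
  }
  nut <- shift(nut, 1, 2, d1_old, d1_new, 0, d2_old)
  nut <- shift(nut, 2, 3, d2_old, d2_new, d1_new, z_bed)
  nut
}

# layer fractions of an exponential profile with penetration depth zp
layer_fractions <- function(zp, d1, d2, z_bed) {
  f1 <- 1 - exp(-d1 / zp)
  f2 <- exp(-d1 / zp) - exp(-d2 / zp)
  f3 <- exp(-d2 / zp) # remainder (below d2, incl. below z_bed) to layer 3
  c(f1, f2, f3) / (f1 + f2 + f3)
}

#' Run a full coupled benthic simulation
#'
#' Daily forward loop: forcing sample, pore-water exchange coefficients,
#' food-web step, organic-matter processing (partitioning, refractory
#' breakdown, burial, silicate dissolution), oxygen and nitrate penetration
#' depths (quasi-steady square-root closures with one under-relaxed
#' fixed-point update per step), layered nutrient bookkeeping with
#' nitrification, denitrification and relaxation exchange with the
#' overlying water. Elemental conservation ledgers (C, N, P, Si) are checked
#' every step and a breach beyond tolerance aborts with a ledger dump.
#'
#' @param config a scenario configuration from \code{\link{load_scenario}}
#'   or \code{\link{scenario_config}}
#' @param forcing optional pre-built \code{forcing_series}; by default it is
#'   generated from \code{config$forcing}
#' @param ledger_tol relative per-step conservation tolerance
#' @return an object of class \code{bed_simulation}: a list with
#'   \code{tables} (daily outputs), \code{ledger} (max per-step residuals),
#'   \code{periodicity} (annual-mean relative differences of the final two
#'   years), \code{state} (final model state) and \code{config}
#' @export
run_simulation <- function(config, forcing = NULL, ledger_tol = 1e-8) {
  stopifnot(inherits(config, "scenario_config"))
  geom <- do.call(ripple_geometry, config$site$ripple)
  k_perm <- if (config$permeable_enabled) config$site$permeability else 0
  pparams <- permeable_params(
    k_perm = max(k_perm, 0), a1 = config$exchange$a1,
    a2 = config$exchange$a2, rho = config$exchange$rho,
    nu = config$exchange$nu, kappa = config$exchange$kappa,
    K0 = config$exchange$K0)
  if (is.null(forcing)) forcing <- generate_forcing(config$forcing, geom)
  n <- nrow(forcing)
  z_bed <- config$nutrients$z_bed
  poro <- config$site$porosity
  spd <- bgc_units$seconds_per_day
  rN <- mmol_per_gC("N"); rP <- mmol_per_gC("P")

  gp <- config$biota$groups
  om <- do.call(om_pools, config$om$init)
  biota <- do.call(biota_state, config$biota$init)
  nut <- matrix(c(1, 2, 0,    # NO3 by layer
                  1, 5, 10,   # NH4
                  0.5, 2, 4,  # PO4
                  2, 10, 20), # Si
                nrow = 4, byrow = TRUE,
                dimnames = list(c("NO3", "NH4", "PO4", "Si"),
                                c("oxic", "transition", "anoxic")))
  D1 <- 0.02; D2 <- 0.06
  zp_sl <- config$om$zp_sl$min; zp_rf <- config$om$zp_rf$min

  # dissolved fraction (partition coefficient) per nutrient and layer
  pc <- matrix(1, nrow = 4, ncol = 3, dimnames = dimnames(nut))
  pc["NH4", ] <- config$nutrients$nh4_partition
  pc["PO4", ] <- c(config$nutrients$po4_coef_oxic,
                   config$nutrients$po4_coef_anoxic,
                   config$nutrients$po4_coef_anoxic)

  # accumulators closing the whole-system ledgers
  respired_C <- 0
  denit_return_N <- 0
  exch_out <- c(NO3 = 0, NH4 = 0, PO4 = 0, Si = 0) # signed, + out of bed
  input_cum <- c(C = 0, N = 0, P = 0, Si = 0)

  tot_state <- function() c(
    C = sum(om["C", ]) + sum(biota) + respired_C,
    N = sum(om["N", ]) + biota_N(biota) + sum(nut["NO3", ]) +
      sum(nut["NH4", ]) + denit_return_N + exch_out[["NO3"]] +
      exch_out[["NH4"]],
    P = sum(om["P", ]) + biota_P(biota) + sum(nut["PO4", ]) +
      exch_out[["PO4"]],
    Si = sum(om["Si", ]) + sum(nut["Si", ]) + exch_out[["Si"]])
  tot0 <- tot_state()
  ledger_max <- c(C = 0, N = 0, P = 0, Si = 0)

  ratios <- partition_ratios(config$om$frac_dom, config$om$frac_semilabile,
                             config$om$frac_refractory)

  out_cols <- c("TOU", "D1", "D2", "pw_NO3", "pw_NH4", "pw_PO4", "pw_Si",
                "bact_aerobic", "bact_anaerobic", "meiofauna",
                "deposit_feeders", "suspension_feeders", "om_dom",
                "om_semilabile", "om_refractory", "om_buried", "bed_NO3",
                "nitrification", "denitrification", "K_eff",
                "resp_aerobic_C", "resp_anaerobic_C")
  acc <- sapply(out_cols, function(nm) numeric(n), simplify = FALSE)

  fcols <- as.list(forcing) # column access is much faster than row access

  for (i in seq_len(n)) {
    f <- list(bed_stress = fcols$bed_stress[i],
              bottom_temperature = fcols$bottom_temperature[i],
              detritus_C_flux = fcols$detritus_C_flux[i],
              detritus_N_flux = fcols$detritus_N_flux[i],
              detritus_P_flux = fcols$detritus_P_flux[i],
              detritus_Si_flux = fcols$detritus_Si_flux[i],
              bw_O2 = fcols$bw_O2[i], bw_NO3 = fcols$bw_NO3[i],
              bw_NH4 = fcols$bw_NH4[i], bw_PO4 = fcols$bw_PO4[i],
              bw_Si = fcols$bw_Si[i])

    # -- pore-water exchange coefficients (previous step's D1, fauna) -----
    ibio <- 1 + config$exchange$ibio_scale * bioturbation_index(biota)
    ec <- exchange_coefficients(f$bed_stress, D1, ibio, geom, pparams)
    K_eff_day <- ec$K_eff * spd          # oxic layer, m^2 day^-1
    K_deep_day <- pparams$K0 * ibio * spd # below oxic layer

    # -- food web ---------------------------------------------------------
    env <- list(temperature = f$bottom_temperature,
                detritus_C_flux = f$detritus_C_flux,
                detritus_N_flux = f$detritus_N_flux,
                detritus_P_flux = f$detritus_P_flux,
                detritus_Si_flux = f$detritus_Si_flux,
                D1 = D1, zp_sl = zp_sl, zp_rf = zp_rf,
                rf_access = config$om$refractory_accessibility)
    sb <- step_biota(biota, om, env, gp, dt = 1)
    biota <- sb$biota
    om <- sb$om
    fx <- sb$fluxes
    respired_C <- respired_C + fx$resp_aerobic_C + fx$resp_anaerobic_C

    # -- settle the unconsumed detritus and partition into pools ----------
    det <- c(C = f$detritus_C_flux, N = f$detritus_N_flux,
             P = f$detritus_P_flux, Si = f$detritus_Si_flux)
    input_cum <- input_cum + det
    rem <- det - fx$detritus_consumed
    rem[rem < 0] <- 0
    inc <- partition_input(rem, ratios)
    om[, "dom"] <- om[, "dom"] + inc$dom
    om[, "semilabile"] <- om[, "semilabile"] + inc$semilabile
    om[, "refractory"] <- om[, "refractory"] + inc$refractory

    # -- refractory breakdown and burial ----------------------------------
    bact_tot <- biota[["bact_aerobic"]] + biota[["bact_anaerobic"]]
    fb <- min(refractory_breakdown(om["C", "refractory"], bact_tot,
                                   config$om$refractory_breakdown_rate),
              0.5 * om["C", "refractory"])
    om <- om_transfer(om, "refractory", "semilabile", fb)
    bu <- min(burial_flux(om["C", "refractory"],
                          config$om$burial_rate_const),
              0.5 * om["C", "refractory"])
    om <- om_transfer(om, "refractory", "buried", bu)

    # -- silicate dissolution, distributed over layers by the POM profile -
    for (pool in c("semilabile", "refractory")) {
      zp <- if (pool == "semilabile") zp_sl else zp_rf
      fs <- min(silicate_dissolution(om["Si", pool],
                                     config$nutrients$silicate_rate),
                0.5 * om["Si", pool])
      if (fs > 0) {
        om["Si", pool] <- om["Si", pool] - fs
        nut["Si", ] <- nut["Si", ] + fs * layer_fractions(zp, D1, D2, z_bed)
      }
    }

    # -- faunal excretion into layers -------------------------------------
    nut["NH4", "oxic"] <- nut["NH4", "oxic"] + fx$nh4_excretion[["oxic"]]
    nut["NH4", "anoxic"] <- nut["NH4", "anoxic"] +
      fx$nh4_excretion[["anoxic"]]
    nut["PO4", "oxic"] <- nut["PO4", "oxic"] + fx$po4_excretion[["oxic"]]
    nut["PO4", "anoxic"] <- nut["PO4", "anoxic"] +
      fx$po4_excretion[["anoxic"]]
    nut["Si", "oxic"] <- nut["Si", "oxic"] + fx$si_release[["oxic"]]
    nut["Si", "anoxic"] <- nut["Si", "anoxic"] + fx$si_release[["anoxic"]]
    nut[nut < 0 & nut > -1e-12] <- 0

    # -- nitrification (oxic layer) ---------------------------------------
    nitr <- min(config$nutrients$nitrification_rate *
                  pc["NH4", "oxic"] * nut["NH4", "oxic"],
                0.5 * nut["NH4", "oxic"])
    nut["NH4", "oxic"] <- nut["NH4", "oxic"] - nitr
    nut["NO3", "oxic"] <- nut["NO3", "oxic"] + nitr

    # -- denitrification (transition + anoxic nitrate) --------------------
    no3_deep <- nut["NO3", "transition"] + nut["NO3", "anoxic"]
    dn <- min(denitrification(biota[["bact_anaerobic"]], no3_deep,
                              config$nutrients$denitrification_rate),
              0.5 * no3_deep)
    if (no3_deep > 0) {
      share <- nut["NO3", c("transition", "anoxic")] / no3_deep
      nut["NO3", c("transition", "anoxic")] <-
        nut["NO3", c("transition", "anoxic")] - dn * share
    }
    denit_return_N <- denit_return_N + dn

    # -- oxygen uptake and penetration depths -----------------------------
    tou <- total_oxygen_uptake(fx$resp_aerobic_C, nitr,
                               carbon_to_o2(fx$resp_anaerobic_C))
    demand_vol <- tou / max(D1, 1e-3) # mmol O2 m^-3 day^-1
    d1_raw <- oxygen_penetration_layered(K_eff_day, K_deep_day, geom$h,
                                         f$bw_O2, demand_vol, z_bed)
    D1_new <- max(min(0.5 * D1 + 0.5 * d1_raw, z_bed), 1e-3)

    th2 <- max(D2 - D1, 1e-4)
    no3_conc_d1 <- nut["NO3", "transition"] / (poro * th2)
    dn_vol <- dn / th2
    d2_raw <- nitrate_penetration(no3_conc_d1, dn_vol, K_deep_day, D1_new,
                                  z_bed)
    D2_new <- max(min(0.5 * max(D2, D1_new) + 0.5 * d2_raw, z_bed), D1_new)

    nut <- relayer(nut, D1, D2, D1_new, D2_new, z_bed)
    D1 <- D1_new; D2 <- D2_new

    # -- inter-layer diffusive relaxation ---------------------------------
    th <- c(D1, max(D2 - D1, 1e-4), max(z_bed - D2, 1e-4))
    mix_pair <- function(nut, i1, i2, K) {
      tau <- max((0.5 * (th[i1] + th[i2]))^2 / (2 * K), 0.5)
      for (nm in rownames(nut)) {
        c1 <- nut[nm, i1]; c2 <- nut[nm, i2]
        a1 <- poro * th[i1] / pc[nm, i1]
        a2 <- poro * th[i2] / pc[nm, i2]
        cstar <- (c1 + c2) / (a1 + a2)
        tr <- (c1 - cstar * a1) * (1 - exp(-1 / tau))
        nut[nm, i1] <- c1 - tr
        nut[nm, i2] <- c2 + tr
      }
      nut
    }
    nut <- mix_pair(nut, 1, 2, K_deep_day)
    nut <- mix_pair(nut, 2, 3, K_deep_day)

    # -- exchange with the overlying water (top layer) --------------------
    bw <- c(NO3 = f$bw_NO3, NH4 = f$bw_NH4, PO4 = f$bw_PO4, Si = f$bw_Si)
    for (nm in rownames(nut)) {
      ceq <- bw[[nm]] * poro * D1 / pc[nm, "oxic"]
      rx <- relax_exchange(nut[nm, "oxic"], ceq,
                           config$nutrients$tau_relax, dt = 1)
      exch_out[[nm]] <- exch_out[[nm]] + rx$flux
      nut[nm, "oxic"] <- rx$content
    }

    # -- penetration depths of POM from faunal mixing ---------------------
    bi <- bioturbation_index(biota)
    zp_sl <- penetration_depth(bi, config$om$zp_sl$min,
                               config$om$zp_sl$max, config$om$zp_sl$half_sat)
    zp_rf <- penetration_depth(bi, config$om$zp_rf$min,
                               config$om$zp_rf$max, config$om$zp_rf$half_sat)

    # -- conservation ledger ----------------------------------------------
    tot <- tot_state()
    res <- abs(tot - tot0 - input_cum) / pmax(abs(tot), 1)
    ledger_max <- pmax(ledger_max, res)
    if (any(res > ledger_tol)) {
      stop(sprintf(
        "conservation breach at day %d: residuals C=%.3e N=%.3e P=%.3e Si=%.3e",
        i, res[["C"]], res[["N"]], res[["P"]], res[["Si"]]), call. = FALSE)
    }

    diss <- rowSums(nut * pc)
    acc$TOU[i] <- tou
    acc$D1[i] <- D1; acc$D2[i] <- D2
    acc$pw_NO3[i] <- diss[["NO3"]] / (poro * z_bed)
    acc$pw_NH4[i] <- diss[["NH4"]] / (poro * z_bed)
    acc$pw_PO4[i] <- diss[["PO4"]] / (poro * z_bed)
    acc$pw_Si[i] <- diss[["Si"]] / (poro * z_bed)
    acc$bact_aerobic[i] <- biota[["bact_aerobic"]]
    acc$bact_anaerobic[i] <- biota[["bact_anaerobic"]]
    acc$meiofauna[i] <- biota[["meiofauna"]]
    acc$deposit_feeders[i] <- biota[["deposit_feeders"]]
    acc$suspension_feeders[i] <- biota[["suspension_feeders"]]
    acc$om_dom[i] <- om["C", "dom"]
    acc$om_semilabile[i] <- om["C", "semilabile"]
    acc$om_refractory[i] <- om["C", "refractory"]
    acc$om_buried[i] <- om["C", "buried"]
    acc$bed_NO3[i] <- sum(nut["NO3", ])
    acc$nitrification[i] <- nitr
    acc$denitrification[i] <- dn
    acc$K_eff[i] <- ec$K_eff
    acc$resp_aerobic_C[i] <- fx$resp_aerobic_C
    acc$resp_anaerobic_C[i] <- fx$resp_anaerobic_C
  }
  out <- data.frame(time = forcing$time, acc)

  # periodicity diagnostic over the final two years
  periodicity <- NULL
  if (n >= 2 * 365) {
    y20 <- out[(n - 2 * 365 + 1):(n - 365), ]
    y21 <- out[(n - 365 + 1):n, ]
    cols <- c("TOU", "D1", "bed_NO3", "om_semilabile", "deposit_feeders",
              "bact_aerobic")
    m20 <- colMeans(y20[cols]); m21 <- colMeans(y21[cols])
    periodicity <- abs(m21 - m20) / pmax(abs(m20), 1e-12)
  }

  attr(out, "units") <- c(
    time = "days", TOU = "mmol O2 m-2 day-1", D1 = "m", D2 = "m",
    pw_NO3 = "mmol m-3", pw_NH4 = "mmol m-3", pw_PO4 = "mmol m-3",
    pw_Si = "mmol m-3",
    bact_aerobic = "g C m-2", bact_anaerobic = "g C m-2",
    meiofauna = "g C m-2", deposit_feeders = "g C m-2",
    suspension_feeders = "g C m-2", om_dom = "g C m-2",
    om_semilabile = "g C m-2", om_refractory = "g C m-2",
    om_buried = "g C m-2", bed_NO3 = "mmol N m-2",
    nitrification = "mmol N m-2 day-1",
    denitrification = "mmol N m-2 day-1", K_eff = "m2 s-1",
    resp_aerobic_C = "g C m-2 day-1", resp_anaerobic_C = "g C m-2 day-1")

  structure(list(
    tables = out,
    ledger = ledger_max,
    periodicity = periodicity,
    state = list(om = om, biota = biota, nut = nut, D1 = D1, D2 = D2,
                 zp_sl = zp_sl, zp_rf = zp_rf,
                 respired_C = respired_C, denit_return_N = denit_return_N,
                 exchange_out = exch_out),
    config = config), class = "bed_simulation")
}

#' @export
print.bed_simulation <- function(x, ...) {
  cat("<bed_simulation>", x$config$name, "-",
      nrow(x$tables), "days\n")
  cat("  max ledger residuals:",
      paste(names(x$ledger), signif(x$ledger, 3), sep = "=",
            collapse = " "), "\n")
  if (!is.null(x$periodicity))
    cat("  final-two-year annual-mean rel. diff (max):",
        signif(max(x$periodicity), 3), "\n")
  invisible(x)
}
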