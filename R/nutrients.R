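#' Three-layer bed structure
#'
#' The bed is divided into an oxygenated layer (down to the oxygen
#' penetration depth D1), a nitrate transition layer (down to the nitrate
#' penetration depth D2, where pore-water nitrate reaches zero) and an
#' anoxic layer extending to the modelled bed depth. Depth is positive
#' downward from the sediment-water interface, in metres.
#'
#' @param D1 oxygen penetration depth, m
#' @param D2 nitrate penetration depth, m
#' @param z_bed modelled bed depth, m
#' @param porosity dimensionless site constant in (0, 1)
#' @return an object of class \code{layer_structure}
#' @export
layer_structure <- function(D1 = 0.01, D2 = 0.05, z_bed = 0.25,
                            porosity = 0.5) {
  if (!(D1 >= 0 && D1 <= D2 && D2 <= z_bed))
    stop_config("need 0 <= D1 <= D2 <= z_bed")
  if (porosity <= 0 || porosity >= 1)
    stop_config("porosity must be in (0, 1)")
  structure(list(D1 = D1, D2 = D2, z_bed = z_bed, porosity = porosity),
            class = "layer_structure")
}

layer_thicknesses <- function(ls) {
  c(oxic = ls$D1, transition = ls$D2 - ls$D1, anoxic = ls$z_bed - ls$D2)
}

#' Oxygen penetration depth from a quasi-steady oxygen balance
#'
#' With zero-order volumetric consumption R and diffusivity K, the steady
#' diffusion equation gives oxygen reaching zero (with zero gradient) at
#' \eqn{D_1 = \sqrt{2 K C_w / R}} where \eqn{C_w} is the bottom-water
#' oxygen concentration. Deeper exchange (larger K) or more oxygenated
#' bottom water deepens D1 by a square-root law; higher demand shallows it.
#'
#' @param K_eff effective oxic-layer diffusivity, m^2 s^-1
#' @param bw_O2 bottom-water oxygen, mmol m^-3
#' @param volumetric_demand zero-order O2 consumption, mmol O2 m^-3 s^-1
#'   (use consistent units with K_eff; any common time base cancels)
#' @param z_bed cap depth, m
#' @return D1, m (0 when bottom water is anoxic; capped at \code{z_bed},
#'   and at the cap when demand is zero)
#' @export
oxygen_penetration <- function(K_eff, bw_O2, volumetric_demand,
                               z_bed = 0.25) {
  if (any(K_eff <= 0)) stop_config("K_eff must be > 0")
  if (any(bw_O2 < 0)) stop_config("bw_O2 must be >= 0")
  if (any(volumetric_demand < 0)) stop_config("demand must be >= 0")
  d <- ifelse(volumetric_demand <= 0, z_bed,
              sqrt(2 * K_eff * bw_O2 / volumetric_demand))
  d[bw_O2 <= 0] <- 0
  pmin(d, z_bed)
}

#' Oxygen penetration depth with a flushed surface stratum
#'
#' Ripple-driven pore-water flushing only reaches a depth comparable to the
#' ripple height, so when the oxic layer is deeper than that the bed behaves
#' as two strata: diffusivity \code{K_top} down to \code{h_adv} and
#' \code{K_deep} below. Solving the quasi-steady zero-order oxygen balance
#' across both strata gives a quadratic for D1 that reduces exactly to
#' \code{\link{oxygen_penetration}} when the two diffusivities are equal
#' (in particular whenever the advective enhancement is zero).
#'
#' @param K_top diffusivity in the flushed stratum, m^2 s^-1 (or per day,
#'   consistently with \code{volumetric_demand})
#' @param K_deep diffusivity below the flushed stratum
#' @param h_adv thickness of the flushed stratum, m (ripple height)
#' @param bw_O2 bottom-water oxygen, mmol m^-3
#' @param volumetric_demand zero-order consumption, consistent units
#' @param z_bed cap depth, m
#' @return D1, m
#' @export
oxygen_penetration_layered <- function(K_top, K_deep, h_adv, bw_O2,
                                       volumetric_demand, z_bed = 0.25) {
  if (any(K_top < K_deep)) stop_config("K_top must be >= K_deep")
  d_top <- oxygen_penetration(K_top, bw_O2, volumetric_demand, z_bed)
  if (d_top <= h_adv || volumetric_demand <= 0 || bw_O2 <= 0)
    return(d_top)
  # oxygen crosses the flushed stratum with K_top, the rest with K_deep:
  # Cw = (R/K1)(D1 h - h^2/2) + (R/(2 K2))(D1 - h)^2, a quadratic in D1
  r <- K_deep / K_top
  disc <- h_adv^2 * (1 - r)^2 - h_adv^2 * (1 - r) +
    2 * K_deep * bw_O2 / volumetric_demand
  d <- h_adv * (1 - r) + sqrt(max(disc, 0))
  min(max(d, h_adv), z_bed)
}

#' Total benthic oxygen uptake
#'
#' Sums aerobic respiration (1 mol O2 per mol C), nitrification (2 mol O2
#' per mol N) and the reoxidation of reduced products of anaerobic
#' metabolism. Reported positive into the bed.
#'
#' @param aerobic_respiration_C aerobic respiration, g C m^-2 day^-1
#' @param nitrification_flux mmol N m^-2 day^-1
#' @param reoxidation_flux reoxidation O2 demand, mmol O2 m^-2 day^-1
#' @return TOU, mmol O2 m^-2 day^-1
#' @export
total_oxygen_uptake <- function(aerobic_respiration_C,
                                nitrification_flux = 0,
                                reoxidation_flux = 0) {
  if (any(c(aerobic_respiration_C, nitrification_flux, reoxidation_flux) < 0))
    stop_config("fluxes must be >= 0")
  carbon_to_o2(aerobic_respiration_C) + 2 * nitrification_flux +
    reoxidation_flux
}

#' First-order nitrification flux
#'
#' Proportional to the depth-averaged dissolved ammonium concentration in
#' the oxic layer times the oxic pore volume (so the flux equals rate times
#' dissolved oxic NH4 content).
#'
#' @param nh4_mean_conc dissolved NH4 concentration, mmol m^-3
#' @param rate_const day^-1
#' @param oxic_volume pore volume of the oxic layer per unit area,
#'   m^3 m^-2 (porosity * D1)
#' @return nitrification flux, mmol N m^-2 day^-1
#' @export
nitrification <- function(nh4_mean_conc, rate_const = 0.1, oxic_volume) {
  if (any(c(nh4_mean_conc, rate_const, oxic_volume) < 0))
    stop_config("nitrification inputs must be >= 0")
  rate_const * nh4_mean_conc * oxic_volume
}

#' Denitrification flux
#'
#' Bimolecular in anaerobic bacterial biomass and bed nitrate content. The
#' removed nitrogen is routed to a surface-nitrate return accumulator so the
#' whole-system nitrogen ledger closes (mirroring a model closure that
#' returns the denitrified flux to the sea surface).
#'
#' @param anaerobic_biomass g C m^-2
#' @param no3_content mmol N m^-2
#' @param rate_const m^2 (g C)^-1 day^-1
#' @return denitrification flux, mmol N m^-2 day^-1
#' @export
denitrification <- function(anaerobic_biomass, no3_content,
                            rate_const = 1e-3) {
  if (any(c(anaerobic_biomass, no3_content, rate_const) < 0))
    stop_config("denitrification inputs must be >= 0")
  rate_const * anaerobic_biomass * no3_content
}

#' First-order silicate dissolution from POM
#'
#' @param pom_si_content biogenic silica in POM, mmol Si m^-2
#' @param rate_const day^-1
#' @return dissolution flux, mmol Si m^-2 day^-1
#' @export
silicate_dissolution <- function(pom_si_content, rate_const = 0.005) {
  if (any(c(pom_si_content, rate_const) < 0))
    stop_config("silicate inputs must be >= 0")
  rate_const * pom_si_content
}

#' Dissolved/adsorbed phosphate partition
#'
#' Pore-water and adsorbed phases are in instantaneous equilibrium with a
#' fixed, layer-dependent partition coefficient (the dissolved fraction).
#' Adsorption is stronger under oxygenated conditions, so the oxic
#' coefficient is smaller than the anoxic one.
#'
#' @param po4_total total phosphate content, mmol m^-2
#' @param layer \code{"oxic"} or \code{"anoxic"}
#' @param coef_oxic,coef_anoxic dissolved fractions in (0, 1]
#' @return list with \code{dissolved} and \code{adsorbed}, summing to total
#' @export
phosphate_partition <- function(po4_total, layer = c("oxic", "anoxic"),
                                coef_oxic = 0.2, coef_anoxic = 0.6) {
  layer <- match.arg(layer)
  if (any(po4_total < 0)) stop_config("po4_total must be >= 0")
  if (coef_oxic >= coef_anoxic)
    stop_config("oxic partition coefficient must be < anoxic")
  pc <- if (layer == "oxic") coef_oxic else coef_anoxic
  dissolved <- pc * po4_total
  list(dissolved = dissolved, adsorbed = po4_total - dissolved)
}

#' Relaxation of a bed nutrient content toward its equilibrium
#'
#' \eqn{C' = C_{eq} + (C - C_{eq})\,e^{-dt/\tau}}; the benthic-pelagic flux
#' is the content lost per unit time (positive out of the bed).
#'
#' @param content current content, mmol m^-2
#' @param equilibrium_content equilibrium content, mmol m^-2
#' @param tau_relax relaxation timescale, day
#' @param dt time step, day
#' @return list with \code{content} (updated) and \code{flux}
#'   (mmol m^-2 day^-1, positive out of the bed)
#' @export
relax_exchange <- function(content, equilibrium_content, tau_relax = 1,
                           dt = 1) {
  if (tau_relax <= 0) stop_config("tau_relax must be > 0")
  new <- equilibrium_content + (content - equilibrium_content) *
    exp(-dt / tau_relax)
  list(content = new, flux = (content - new) / dt)
}

#' Nitrate penetration depth
#'
#' Same quasi-steady zero-order construction as the oxygen penetration
#' depth, seeded at D1 with the dissolved nitrate concentration there:
#' \eqn{D_2 = D_1 + \sqrt{2 K c_{NO3}(D_1) / R_{dn}}}, capped at the bed
#' depth. Zero nitrate at D1 gives D2 = D1; zero consumption caps D2 at the
#' bed depth.
#'
#' @param no3_conc_at_D1 dissolved nitrate concentration at D1, mmol m^-3
#' @param transition_consumption zero-order volumetric nitrate consumption,
#'   mmol m^-3 s^-1 (or any unit consistent with K)
#' @param K diffusivity below the oxic layer (K0 * I_bio), m^2 s^-1
#' @param D1 oxygen penetration depth, m
#' @param z_bed cap depth, m
#' @return D2, m, with D1 <= D2 <= z_bed
#' @export
nitrate_penetration <- function(no3_conc_at_D1, transition_consumption, K,
                                D1, z_bed = 0.25) {
  if (any(c(no3_conc_at_D1, transition_consumption, K, D1) < 0))
    stop_config("nitrate_penetration inputs must be >= 0")
  d <- ifelse(no3_conc_at_D1 <= 0, D1,
              ifelse(transition_consumption <= 0, z_bed,
                     D1 + sqrt(2 * K * no3_conc_at_D1 /
                                 transition_consumption)))
  pmax(pmin(d, z_bed), D1)
}

#' Piecewise-constant pore-water concentration profile
#'
#' Reconstructs per-depth dissolved concentrations from per-layer dissolved
#' contents: within each layer the concentration is content divided by pore
#' volume (porosity times thickness). Zero-thickness layers report the
#' adjacent (next deeper, else shallower) layer's value.
#'
#' @param dissolved_contents named vector (oxic, transition, anoxic),
#'   mmol m^-2
#' @param ls a \code{\link{layer_structure}}
#' @param grid depths within [0, z_bed], m
#' @return dissolved concentration at each grid depth, mmol m^-3
#' @export
porewater_profile <- function(dissolved_contents, ls, grid) {
  if (any(grid < 0) || any(grid > ls$z_bed))
    stop_config("grid depths must lie within [0, z_bed]")
  th <- layer_thicknesses(ls)
  conc <- ifelse(th > 0, dissolved_contents / (ls$porosity * th), NA_real_)
  # zero-thickness layers inherit the adjacent layer's concentration
  for (i in seq_along(conc)) {
    if (is.na(conc[i])) {
      nxt <- which(!is.na(conc[seq(i, length(conc))]))[1]
      prv <- rev(which(!is.na(conc[seq_len(i)])))[1]
      conc[i] <- if (!is.na(nxt)) conc[i + nxt - 1]
                 else if (!is.na(prv)) conc[prv] else 0
    }
  }
  layer_of <- findInterval(grid, c(ls$D1, ls$D2), left.open = FALSE) + 1
  unname(conc[layer_of])
}

#' Depth-mean dissolved pore-water concentration
#'
#' Content-weighted mean over the whole modelled bed depth.
#'
#' @inheritParams porewater_profile
#' @return mmol m^-3
#' @export
depth_mean_concentration <- function(dissolved_contents, ls) {
  sum(dissolved_contents) / (ls$porosity * ls$z_bed)
}
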