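#' Partition ratios for incoming detritus
#'
#' Incoming pelagic detritus is split into labile dissolved organic matter
#' (DOM), semi-labile particulate organic matter (POM) and refractory POM
#' using fixed ratios. The standard muddy-site configuration splits the
#' particulate share 9:1 semi-labile:refractory; the re-parameterised run
#' uses 1:1.
#'
#' @param frac_dom,frac_semilabile,frac_refractory dimensionless fractions,
#'   each in [0, 1], summing to 1
#' @return an object of class \code{partition_ratios}
#' @export
partition_ratios <- function(frac_dom = 0.1,
                             frac_semilabile = 0.9 * (1 - frac_dom),
                             frac_refractory = 0.1 * (1 - frac_dom)) {
  f <- c(dom = frac_dom, semilabile = frac_semilabile,
         refractory = frac_refractory)
  if (any(f < 0) || any(f > 1))
    stop_config("partition fractions must be in [0, 1]")
  if (abs(sum(f) - 1) > 1e-10)
    stop_config("partition fractions must sum to 1 (got %.6f)", sum(f))
  structure(as.list(f), class = "partition_ratios")
}

#' Partition an incoming detrital flux into benthic OM pool increments
#'
#' Element-wise exact conservation: the three increments sum to the input.
#'
#' @param flux incoming flux (scalar or named per-element vector), any unit
#' @param ratios a \code{\link{partition_ratios}}
#' @return a list with components \code{dom}, \code{semilabile},
#'   \code{refractory}, each the same shape as \code{flux}
#' @export
partition_input <- function(flux, ratios = partition_ratios()) {
  stopifnot(inherits(ratios, "partition_ratios"))
  if (any(flux < 0)) stop_config("detrital flux must be >= 0")
  sl <- flux * ratios$semilabile
  rf <- flux * ratios$refractory
  list(dom = flux - sl - rf, semilabile = sl, refractory = rf)
}

#' Exponential POM depth profile
#'
#' The depth-integrated stock and a characteristic penetration depth define
#' the volumetric concentration \eqn{c(z) = (S/z_p)\,e^{-z/z_p}}, which
#' integrates back to the stock over the half-line.
#'
#' @param stock depth-integrated amount (e.g. g C m^-2)
#' @param zp penetration depth, m (> 0)
#' @param z depth(s) below the sediment surface, m
#' @return volumetric concentration at \code{z} (stock unit per m^3)
#' @export
pom_profile <- function(stock, zp, z) {
  if (any(zp <= 0)) stop_config("penetration depth must be > 0")
  if (any(stock < 0) || any(z < 0)) stop_config("stock and z must be >= 0")
  (stock / zp) * exp(-z / zp)
}

#' Integrate an exponential POM profile down to a depth
#'
#' Closed form \eqn{S\,(1 - e^{-z_{max}/z_p})}.
#'
#' @inheritParams pom_profile
#' @param z_max integration depth, m
#' @return partial stock contained above \code{z_max}
#' @export
integrate_to_depth <- function(stock, zp, z_max) {
  if (any(zp <= 0)) stop_config("penetration depth must be > 0")
  if (any(z_max < 0)) stop_config("z_max must be >= 0")
  stock * (1 - exp(-z_max / zp))
}

#' Bacterial breakdown of refractory POM to semi-labile POM
#'
#' A bimolecular rate law: flux = rate * bacterial biomass * refractory
#' stock. The standard rate constant is 2e-6 m^2 (g C)^-1 day^-1; the
#' re-parameterised run increases it fivefold to 1e-5.
#'
#' @param refractory_stock g C m^-2
#' @param bacteria_biomass g C m^-2
#' @param rate m^2 (g C)^-1 day^-1
#' @return conversion flux, g C m^-2 day^-1
#' @export
refractory_breakdown <- function(refractory_stock, bacteria_biomass,
                                 rate = 2e-6) {
  if (any(c(refractory_stock, bacteria_biomass, rate) < 0))
    stop_config("refractory_breakdown inputs must be >= 0")
  rate * bacteria_biomass * refractory_stock
}

#' First-order burial of refractory POM
#'
#' A slow one-way leak from the refractory pool into a biologically inert
#' buried pool (which has no further dynamics). The default rate constant is
#' set so that a multi-decade run accumulates a few g C m^-2.
#'
#' @param refractory_stock g C m^-2
#' @param burial_rate_const day^-1
#' @return burial flux, g C m^-2 day^-1
#' @export
burial_flux <- function(refractory_stock, burial_rate_const = 2e-5) {
  if (any(c(refractory_stock, burial_rate_const) < 0))
    stop_config("burial inputs must be >= 0")
  burial_rate_const * refractory_stock
}

#' POM penetration depth from the bioturbation index
#'
#' A saturating (Michaelis-Menten) map from faunal mixing intensity to the
#' characteristic penetration depth:
#' \eqn{z_p = z_{min} + (z_{max} - z_{min})\,I/(I + I_{1/2})}.
#'
#' @param bioturbation_index dimensionless index (>= 0)
#' @param zp_min,zp_max bounds on the penetration depth, m
#' @param half_sat index at which zp reaches the midpoint of its range
#' @return penetration depth, m
#' @export
penetration_depth <- function(bioturbation_index, zp_min = 0.005,
                              zp_max = 0.04, half_sat = 1) {
  if (any(bioturbation_index < 0)) stop_config("index must be >= 0")
  if (zp_min <= 0 || zp_max < zp_min || half_sat <= 0)
    stop_config("need 0 < zp_min <= zp_max and half_sat > 0")
  zp_min + (zp_max - zp_min) *
    bioturbation_index / (bioturbation_index + half_sat)
}
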