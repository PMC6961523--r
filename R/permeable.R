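#' Ripple geometry for the permeable-sediment exchange parameterisation
#'
#' Ripple height and wavelength default to 3 and 20 cm (typical of rippled
#' shelf sands); the bed roughness length is tied to the ripple height as
#' \code{z0 = h / 7} and the log-law reference height is 10 cm.
#'
#' @param h ripple height, m
#' @param L_ripple ripple wavelength, m
#' @param z_r reference height for the near-bed velocity, m
#' @return an object of class \code{ripple_geometry}
#' @export
ripple_geometry <- function(h = 0.03, L_ripple = 0.2, z_r = 0.1) {
  if (h <= 0 || L_ripple <= 0) stop_config("ripple dimensions must be > 0")
  if (h >= L_ripple) stop_config("ripple height must be < wavelength")
  z0 <- h / 7.0
  if (z0 >= z_r) stop_config("bed roughness z0 must be < reference height")
  structure(list(h = h, L_ripple = L_ripple, z0 = z0, z_r = z_r),
            class = "ripple_geometry")
}

#' Physical parameters of the pore-water exchange chain
#'
#' @param k_perm sediment permeability, m^2 (default 5.0e-11, a literature
#'   value for medium sand; 0 recovers the impermeable-mud limit)
#' @param a1 empirical constant in the ripple pressure law (default 1.0)
#' @param a2 scaling constant of the advective diffusivity (default 4.0,
#'   treated as a given calibration constant)
#' @param rho water density, kg m^-3
#' @param nu kinematic viscosity, m^2 s^-1
#' @param kappa von Karman constant
#' @param K0 background (molecular) diffusivity, m^2 s^-1
#' @param log_law_form \code{"division"} (standard log law, the default) or
#'   \code{"literal"} which multiplies by kappa instead of dividing; the
#'   latter is kept as a switch for sensitivity testing only
#' @return an object of class \code{permeable_params}
#' @export
permeable_params <- function(k_perm = 5.0e-11, a1 = 1.0, a2 = 4.0,
                             rho = 1010, nu = 1.0e-6, kappa = 0.41,
                             K0 = 1.0e-9,
                             log_law_form = c("division", "literal")) {
  if (k_perm < 0) stop_config("permeability must be >= 0")
  if (any(c(a1, a2, rho, nu, kappa, K0) <= 0))
    stop_config("a1, a2, rho, nu, kappa and K0 must be > 0")
  structure(list(k_perm = k_perm, a1 = a1, a2 = a2, rho = rho, nu = nu,
                 kappa = kappa, K0 = K0,
                 log_law_form = match.arg(log_law_form)),
            class = "permeable_params")
}

#' Near-bed reference velocity from the bed stress (log law)
#'
#' \eqn{U = (u_*/\kappa)\,\ln(z_r/z_0)} with \eqn{u_* = \sqrt{\tau_b/\rho}}.
#'
#' @param tau_b bed stress, Pa (vectorised)
#' @param geom a \code{\link{ripple_geometry}}
#' @param params a \code{\link{permeable_params}}
#' @return near-bed reference velocity U, m s^-1
#' @export
log_law_velocity <- function(tau_b, geom = ripple_geometry(),
                             params = permeable_params()) {
  if (any(tau_b < 0)) stop_config("bed stress must be >= 0")
  ustar <- sqrt(tau_b / params$rho)
  lnfac <- log(geom$z_r / geom$z0)
  if (params$log_law_form == "division") ustar / params$kappa * lnfac
  else ustar * params$kappa * lnfac
}

#' Pressure difference across a ripple induced by near-bed flow
#'
#' \eqn{\Delta P = a_1 \rho U^2 (h/L)}.
#'
#' @inheritParams log_law_velocity
#' @param U near-bed reference velocity, m s^-1
#' @return pressure difference, Pa
#' @export
ripple_pressure <- function(U, geom = ripple_geometry(),
                            params = permeable_params()) {
  if (any(U < 0)) stop_config("velocity must be >= 0")
  params$a1 * params$rho * U^2 * (geom$h / geom$L_ripple)
}

#' Darcy pore-water flow velocity under a ripple
#'
#' \eqn{w_0 = k\,\Delta P / (\rho \nu L)}.
#'
#' @inheritParams log_law_velocity
#' @param deltaP ripple pressure difference, Pa
#' @return Darcy velocity, m s^-1
#' @export
darcy_velocity <- function(deltaP, geom = ripple_geometry(),
                           params = permeable_params()) {
  if (any(deltaP < 0)) stop_config("pressure difference must be >= 0")
  params$k_perm * deltaP / (params$rho * params$nu * geom$L_ripple)
}

#' Advective contribution to the within-bed diffusivity
#'
#' \eqn{K_{adv} = a_2 w_0 \min(h, D_1)}: the diffusivity is the product of
#' the pore-water velocity scale and a length scale, the smaller of the
#' ripple height and the oxic-layer depth.
#'
#' @inheritParams log_law_velocity
#' @param w0 Darcy velocity, m s^-1
#' @param D1 oxic layer depth, m
#' @return advective diffusivity, m^2 s^-1
#' @export
advective_diffusivity <- function(w0, D1, geom = ripple_geometry(),
                                  params = permeable_params()) {
  if (any(w0 < 0) || any(D1 < 0)) stop_config("w0 and D1 must be >= 0")
  params$a2 * w0 * pmin(geom$h, D1)
}

#' Effective oxic-layer diffusivity
#'
#' \eqn{K = (K_0 + K_{adv}) I_{bio}}: the advective enhancement adds to the
#' background molecular diffusivity before the bio-irrigation factor is
#' applied. The enhancement acts only in the oxic (top) layer; deeper layers
#' use \code{K0 * I_bio}.
#'
#' @param K0 background diffusivity, m^2 s^-1
#' @param K_adv advective diffusivity, m^2 s^-1
#' @param I_bio dimensionless bio-irrigation factor (>= 1 typical)
#' @return effective diffusivity, m^2 s^-1
#' @export
effective_diffusivity <- function(K0, K_adv, I_bio) {
  if (any(K0 < 0) || any(K_adv < 0) || any(I_bio < 0))
    stop_config("diffusivities and I_bio must be >= 0")
  (K0 + K_adv) * I_bio
}

#' Full bed-stress to effective-diffusivity chain
#'
#' Chains the log-law velocity, ripple pressure, Darcy velocity, advective
#' diffusivity and bio-irrigated effective diffusivity for a (vector of)
#' bed stress values.
#'
#' @inheritParams log_law_velocity
#' @param D1 oxic layer depth, m
#' @param I_bio bio-irrigation factor
#' @return a data frame with columns \code{tau_b, U, deltaP, w0, K_adv, K0,
#'   I_bio, K_eff} (diffusivities in m^2 s^-1)
#' @export
exchange_coefficients <- function(tau_b, D1, I_bio = 1,
                                  geom = ripple_geometry(),
                                  params = permeable_params()) {
  U <- log_law_velocity(tau_b, geom, params)
  dP <- ripple_pressure(U, geom, params)
  w0 <- darcy_velocity(dP, geom, params)
  K_adv <- advective_diffusivity(w0, D1, geom, params)
  data.frame(tau_b = tau_b, U = U, deltaP = dP, w0 = w0, K_adv = K_adv,
             K0 = params$K0, I_bio = I_bio,
             K_eff = effective_diffusivity(params$K0, K_adv, I_bio))
}
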