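#' Unit constants used throughout the package
#'
#' The model carries carbon in g C m^-2 and nutrients in mmol m^-2;
#' diffusivities are m^2 s^-1 internally and converted to m^2 day^-1 once,
#' at the time-stepping boundary. Detrital stoichiometry defaults to the
#' Redfield molar ratio C:N:P = 106:16:1 with a diatom-like Si:C of 15:106.
#'
#' @format A named list with components:
#' \describe{
#'   \item{seconds_per_day}{86400}
#'   \item{g_per_mol_C}{molar mass of carbon, 12.011 g mol^-1}
#'   \item{redfield_N_to_C}{molar N:C, 16/106}
#'   \item{redfield_P_to_C}{molar P:C, 1/106}
#'   \item{si_to_C}{molar Si:C, 15/106}
#' }
#' @export
bgc_units <- list(
  seconds_per_day = 86400,
  g_per_mol_C     = 12.011,
  redfield_N_to_C = 16 / 106,
  redfield_P_to_C = 1 / 106,
  si_to_C         = 15 / 106
)

# mmol of element per g C in Redfield organic matter
mmol_per_gC <- function(element = c("N", "P", "Si")) {
  element <- match.arg(element)
  ratio <- switch(element,
    N  = bgc_units$redfield_N_to_C,
    P  = bgc_units$redfield_P_to_C,
    Si = bgc_units$si_to_C
  )
  1000 * ratio / bgc_units$g_per_mol_C
}

#' Convert a carbon respiration flux to an oxygen uptake flux
#'
#' Aerobic respiration (and the eventual reoxidation of reduced products of
#' anaerobic metabolism) consumes 1 mol O2 per mol C respired.
#'
#' @param c_flux carbon flux, g C m^-2 day^-1
#' @return oxygen flux, mmol O2 m^-2 day^-1
#' @export
carbon_to_o2 <- function(c_flux) {
  stopifnot(all(c_flux >= 0))
  c_flux / bgc_units$g_per_mol_C * 1000
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
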