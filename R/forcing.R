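#' Configuration for synthetic pelagic forcing
#'
#' Builds the parameter set for the seeded daily forcing generator. The
#' generator emulates the pelagic boundary conditions a shelf-sea benthic
#' model needs: a seasonal bottom-temperature cycle with summer
#' stratification, a spring-bloom pulse of detrital carbon delivering a
#' configurable annual benthic input, a small autumn bloom, seasonal
#' bottom-water O2/NO3/NH4/PO4/Si, and M2+S2 tidal bed shear stress with a
#' spring-neap beat. The calendar has 365-day years and no leap days.
#'
#' Winter bottom-water nutrient concentrations are plausible temperate
#' shelf-sea defaults, not site measurements; treat them as calibration values.
#'
#' @param years number of simulated years
#' @param t_start label for day 0 (ISO-8601 date string; bookkeeping only)
#' @param bloom_day day-of-year of the spring-bloom detritus peak
#' @param bloom_width_days Gaussian s.d. of the bloom pulse (days)
#' @param annual_benthic_C_input annual detrital carbon delivered to the bed,
#'   g C m^-2 yr^-1 (default 20)
#' @param autumn_bloom_fraction relative size of the autumn pulse, in [0, 1)
#' @param autumn_bloom_day day-of-year of the autumn pulse
#' @param background_fraction weight of the uniform year-round settling floor
#'   relative to the normalised bloom shape
#' @param bloom_amplitude overall scale on the detrital delivery shape; 0
#'   switches detrital input off entirely
#' @param temp_mean,temp_amplitude bottom temperature mean and seasonal
#'   amplitude, degrees C
#' @param temp_peak_doy day-of-year of the bottom-temperature maximum
#'   (bottom waters warm late, near the end of stratification)
#' @param strat_onset_doy,remix_doy day-of-year of stratification onset and
#'   autumn water-column remixing
#' @param bw_O2_winter winter bottom-water oxygen, mmol m^-3
#' @param bw_O2_summer_drawdown_frac fractional O2 drawdown over the
#'   stratified season
#' @param bw_NO3_winter,bw_NH4_winter,bw_PO4_winter,bw_Si_winter winter
#'   bottom-water nutrient concentrations, mmol m^-3
#' @param nutrient_drawdown_frac fractional post-bloom nutrient drawdown
#' @param m2_current_amp,s2_current_amp M2 and S2 tidal current amplitudes at
#'   the reference height, m s^-1
#' @param seed integer seed for any stochastic components (observation
#'   fixtures); the forcing series itself is deterministic
#' @return an object of class \code{forcing_config}
#' @export
forcing_config <- function(years = 21,
                           t_start = "1995-01-01",
                           bloom_day = 120,
                           bloom_width_days = 10,
                           annual_benthic_C_input = 20,
                           autumn_bloom_fraction = 0.2,
                           autumn_bloom_day = 270,
                           background_fraction = 0.02,
                           bloom_amplitude = 1,
                           temp_mean = 11,
                           temp_amplitude = 2.5,
                           temp_peak_doy = 300,
                           strat_onset_doy = 110,
                           remix_doy = 330,
                           bw_O2_winter = 280,
                           bw_O2_summer_drawdown_frac = 0.10,
                           bw_NO3_winter = 8,
                           bw_NH4_winter = 0.5,
                           bw_PO4_winter = 0.6,
                           bw_Si_winter = 5,
                           nutrient_drawdown_frac = 0.6,
                           m2_current_amp = 0.10,
                           s2_current_amp = 0.035,
                           seed = 1L) {
  if (years < 1) stop_config("years must be >= 1")
  if (annual_benthic_C_input <= 0)
    stop_config("annual_benthic_C_input must be > 0")
  if (autumn_bloom_fraction < 0 || autumn_bloom_fraction >= 1)
    stop_config("autumn_bloom_fraction must be in [0, 1)")
  if (m2_current_amp < 0 || s2_current_amp < 0)
    stop_config("tidal current amplitudes must be >= 0")
  if (temp_amplitude < 0) stop_config("temp_amplitude must be >= 0")
  if (remix_doy <= strat_onset_doy)
    stop_config("remix_doy must fall later in the year than strat_onset_doy")
  if (bloom_width_days <= 0) stop_config("bloom_width_days must be > 0")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "forcing_config")
}

# truncated Gaussian bump in day-of-year, cut at +/- 4 s.d.
doy_gaussian <- function(doy, centre, width) {
  d <- (doy - centre + 182.5) %% 365 - 182.5  # circular distance
  out <- exp(-0.5 * (d / width)^2)
  out[abs(d) > 4 * width] <- 0
  out
}

# smooth 0->1 ramp over [d0, d1] in day-of-year
doy_ramp <- function(doy, d0, d1) {
  x <- pmin(pmax((doy - d0) / (d1 - d0), 0), 1)
  0.5 - 0.5 * cos(pi * x)
}

#' Tidal bed shear stress from M2 and S2 currents
#'
#' Instantaneous near-bed speed is the superposition of the two constituents,
#' \eqn{u(t) = |A_{M2} \cos(\omega_{M2} t) + A_{S2} \cos(\omega_{S2} t)|},
#' and the bed stress follows a quadratic drag law
#' \eqn{\tau_b = \rho C_d u^2} with the drag coefficient derived from the
#' logarithmic velocity profile at the reference height,
#' \eqn{C_d = [\kappa / \ln(z_r/z_0)]^2}. The interference of the two
#' constituents gives the stress envelope its fortnightly spring-neap beat
#' (period 14.77 days).
#'
#' @param m2_amp,s2_amp current amplitudes, m s^-1
#' @param z0 bed roughness length, m
#' @param time time points, days (may be fractional for sub-daily sampling)
#' @param z_r reference height, m (default 0.1)
#' @param rho water density, kg m^-3
#' @param kappa von Karman constant
#' @return bed stress at \code{time}, Pa
#' @export
tidal_stress <- function(m2_amp, s2_amp, z0, time,
                         z_r = 0.1, rho = 1010, kappa = 0.41) {
  if (m2_amp < 0 || s2_amp < 0) stop_config("tidal amplitudes must be >= 0")
  if (z0 <= 0 || z_r <= z0) stop_config("need 0 < z0 < z_r")
  # constituent periods in days: M2 12.4206 h, S2 12.0000 h
  w_m2 <- 2 * pi / (12.4206 / 24)
  w_s2 <- 2 * pi / (12.0000 / 24)
  u <- abs(m2_amp * cos(w_m2 * time) + s2_amp * cos(w_s2 * time))
  cd <- (kappa / log(z_r / z0))^2
  rho * cd * u^2
}

# daily-mean bed stress on integer day grid, averaging nsub sub-samples
daily_mean_stress <- function(m2_amp, s2_amp, z0, days, nsub = 48,
                              z_r = 0.1, rho = 1010, kappa = 0.41) {
  sub <- (seq_len(nsub) - 0.5) / nsub
  tt <- rep(days, each = nsub) + sub
  tau <- tidal_stress(m2_amp, s2_amp, z0, tt, z_r = z_r, rho = rho,
                      kappa = kappa)
  colMeans(matrix(tau, nrow = nsub))
}

#' Generate a synthetic daily pelagic forcing series
#'
#' Produces the daily boundary conditions at the sediment-water interface
#' that drive the benthic model: bottom temperature, detrital C/N/P/Si
#' fluxes, bottom-water dissolved concentrations, tidal bed stress and a
#' surface chlorophyll proxy. The detrital carbon flux is normalised so that
#' its integral over every simulated year equals
#' \code{config$annual_benthic_C_input} exactly; N, P and Si fluxes follow
#' fixed Redfield(-Brzezinski) stoichiometry. The series is deterministic
#' given the configuration.
#'
#' @param config a \code{\link{forcing_config}}
#' @param geom ripple geometry (for the bed roughness used by the stress
#'   law), see \code{\link{ripple_geometry}}
#' @return a data frame of class \code{forcing_series} with one row per day
#'   and a \code{units} attribute naming the unit of every column
#' @export
generate_forcing <- function(config, geom = ripple_geometry()) {
  stopifnot(inherits(config, "forcing_config"))
  n <- config$years * 365L
  time <- seq_len(n) - 1L
  doy <- time %% 365L + 1L

  # --- detrital delivery shape (one year, tiled) -------------------------
  d1 <- seq_len(365L)
  lag <- 7 # settling lag between surface bloom and benthic arrival, days
  shape <- config$bloom_amplitude *
    (doy_gaussian(d1, config$bloom_day + lag, config$bloom_width_days) +
       config$autumn_bloom_fraction *
         doy_gaussian(d1, config$autumn_bloom_day + lag,
                      config$bloom_width_days) +
       config$background_fraction)
  tot <- sum(shape)
  flux_year <- if (tot > 0) config$annual_benthic_C_input * shape / tot
               else rep(0, 365L)
  detritus_C <- rep(flux_year, config$years)
  c_mmol <- detritus_C / bgc_units$g_per_mol_C * 1000
  detritus_N <- c_mmol * bgc_units$redfield_N_to_C
  detritus_P <- c_mmol * bgc_units$redfield_P_to_C
  detritus_Si <- c_mmol * bgc_units$si_to_C

  # --- bottom temperature ------------------------------------------------
  temp <- config$temp_mean + config$temp_amplitude *
    cos(2 * pi * (doy - config$temp_peak_doy) / 365)

  # --- bottom-water oxygen: stratified-season drawdown -------------------
  draw <- doy_ramp(doy, config$strat_onset_doy, config$remix_doy - 20) *
    (1 - doy_ramp(doy, config$remix_doy - 5, config$remix_doy + 10))
  bw_O2 <- config$bw_O2_winter *
    (1 - config$bw_O2_summer_drawdown_frac * draw)

  # --- bottom-water nutrients: winter plateau, post-bloom drawdown, ------
  #     gradual recovery through the stratified season
  ndraw <- doy_ramp(doy, config$bloom_day - 2 * config$bloom_width_days,
                    config$bloom_day + config$bloom_width_days) *
    (1 - doy_ramp(doy, config$bloom_day + 30, config$remix_doy))
  nut_scale <- 1 - config$nutrient_drawdown_frac * ndraw
  bw_NO3 <- config$bw_NO3_winter * nut_scale
  bw_NH4 <- config$bw_NH4_winter * nut_scale
  bw_PO4 <- config$bw_PO4_winter * nut_scale
  bw_Si <- config$bw_Si_winter * nut_scale

  # --- tidal bed stress (daily mean over 48 sub-samples) -----------------
  tau1 <- daily_mean_stress(config$m2_current_amp, config$s2_current_amp,
                            geom$z0, 0:364)
  # the M2+S2 beat is not annually periodic; tile one year so the forcing
  # is, which is what the spin-up periodicity diagnostic assumes
  bed_stress <- rep(tau1, config$years)

  chl <- 0.5 + 5 * doy_gaussian(doy, config$bloom_day, config$bloom_width_days) +
    5 * config$autumn_bloom_fraction *
      doy_gaussian(doy, config$autumn_bloom_day, config$bloom_width_days)

  out <- data.frame(
    time = time,
    bottom_temperature = temp,
    detritus_C_flux = detritus_C,
    detritus_N_flux = detritus_N,
    detritus_P_flux = detritus_P,
    detritus_Si_flux = detritus_Si,
    bw_O2 = bw_O2, bw_NO3 = bw_NO3, bw_NH4 = bw_NH4,
    bw_PO4 = bw_PO4, bw_Si = bw_Si,
    bed_stress = bed_stress,
    surface_chl_proxy = chl
  )
  attr(out, "units") <- c(
    time = "days since t_start", bottom_temperature = "degC",
    detritus_C_flux = "g C m-2 day-1", detritus_N_flux = "mmol N m-2 day-1",
    detritus_P_flux = "mmol P m-2 day-1",
    detritus_Si_flux = "mmol Si m-2 day-1",
    bw_O2 = "mmol m-3", bw_NO3 = "mmol m-3", bw_NH4 = "mmol m-3",
    bw_PO4 = "mmol m-3", bw_Si = "mmol m-3",
    bed_stress = "Pa", surface_chl_proxy = "mg Chl m-3"
  )
  attr(out, "config") <- config
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' Write / read a forcing series as CSV
#'
#' The header carries the unit of every column as a comment line
#' (\code{# units: ...}) and dates are day offsets from the configured
#' ISO-8601 start date.
#'
#' @param x a \code{forcing_series}
#' @param path file path
#' @return \code{read_forcing_csv} returns a \code{forcing_series}
#'   (without the generating config attached)
#' @export
write_forcing_csv <- function(x, path) {
  stopifnot(inherits(x, "forcing_series"))
  units <- attr(x, "units")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ",
                    paste(names(units), units, sep = "=", collapse = "; ")),
             con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(path) {
  out <- utils::read.csv(path, comment.char = "#")
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' Generate synthetic observation fixtures around model truth
#'
#' Adds bias-corrected lognormal multiplicative noise to a table of "true"
#' model values, replicated, so that the replicate mean converges to the
#' truth as the number of replicates grows. This emulates the large
#' between-replicate scatter typical of benthic grab samples.
#'
#' @param truth data frame with columns \code{site}, \code{date},
#'   \code{quantity}, \code{value}
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param replicates number of replicates per (site, date, quantity)
#' @param seed integer seed
#' @return data frame with columns site, date, quantity, replicate, value,
#'   source
#' @export
generate_observation_fixtures <- function(truth, noise_cv = 0.5,
                                          replicates = 3L, seed = 1L) {
  stopifnot(all(c("site", "date", "quantity", "value") %in% names(truth)))
  if (noise_cv < 0) stop_config("noise_cv must be >= 0")
  if (replicates < 1) stop_config("replicates must be >= 1")
  set.seed(as.integer(seed))
  idx <- rep(seq_len(nrow(truth)), each = replicates)
  out <- truth[idx, c("site", "date", "quantity")]
  out$replicate <- rep(seq_len(replicates), nrow(truth))
  v <- truth$value[idx]
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    # meanlog offset -sdlog^2/2 so E[multiplier] = 1 (unbiased mean)
    mult <- stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    v <- v * mult
  }
  out$value <- v
  out$source <- "synthetic"
  rownames(out) <- NULL
  out
}
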