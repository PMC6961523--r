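mk_env <- function(temperature = 10, det = 0.05, D1 = 0.02,
                   zp_sl = 0.015, zp_rf = 0.05) {
  cmmol <- det / bgc_units$g_per_mol_C * 1000
  list(temperature = temperature, detritus_C_flux = det,
       detritus_N_flux = cmmol * 16 / 106,
       detritus_P_flux = cmmol / 106,
       detritus_Si_flux = cmmol * 15 / 106,
       D1 = D1, zp_sl = zp_sl, zp_rf = zp_rf, rf_access = 0.015)
}

test_that("the Q10 factor is exactly 1 at the reference temperature", {
  expect_identical(q10_factor(2, 10), 1)
  expect_identical(q10_factor(3, 10), 1)
  expect_equal(q10_factor(2, 20), 2)
})

test_that("uptake vanishes without resources and saturates when rich", {
  gp <- default_group_params()
  u0 <- uptake_flux(1, c(dom = 0, semilabile_oxic = 0), gp$bact_aerobic)
  expect_true(all(u0 == 0))
  rich <- c(dom = 1e6, semilabile_oxic = 1e6)
  u <- uptake_flux(0.2, rich, gp$bact_aerobic, temperature = 10)
  expect_equal(sum(u), gp$bact_aerobic$max_uptake * 0.2, tolerance = 1e-4)
})

test_that("a step with all rates zero leaves the state unchanged", {
  gp <- default_group_params()
  for (g in names(gp)) {
    gp[[g]]$max_uptake <- 0
    gp[[g]]$basal_resp <- 0
    gp[[g]]$mortality <- 0
    gp[[g]]$closure_mort <- 0
  }
  biota <- biota_state(0.2, 0.2, 0.2, 1, 0.5)
  om <- om_pools()
  out <- step_biota(biota, om, mk_env(det = 0), gp)
  expect_equal(unclass(out$biota), unclass(biota))
  expect_equal(out$om, om)
  expect_equal(out$fluxes$resp_aerobic_C, 0)
})

test_that("every food-web step closes the C, N, P and Si budgets", {
  gp <- default_group_params()
  set.seed(7)
  rN <- shelfbenthos:::mmol_per_gC("N")
  rP <- shelfbenthos:::mmol_per_gC("P")
  for (k in 1:20) {
    biota <- biota_state(runif(1, 0.01, 0.5), runif(1, 0.01, 0.5),
                         runif(1, 0.01, 0.5), runif(1, 0.1, 3),
                         runif(1, 0.1, 2))
    om <- om_pools(runif(1, 0, 0.5), runif(1, 0.2, 4), runif(1, 1, 50))
    env <- mk_env(temperature = runif(1, 5, 18), det = runif(1, 0, 0.5),
                  D1 = runif(1, 0.005, 0.2))
    out <- step_biota(biota, om, env, gp)
    fx <- out$fluxes
    det_in <- c(C = env$detritus_C_flux, N = env$detritus_N_flux,
                P = env$detritus_P_flux, Si = env$detritus_Si_flux)
    dC <- (sum(out$biota) + sum(out$om["C", ]) + fx$resp_aerobic_C +
             fx$resp_anaerobic_C) -
      (sum(biota) + sum(om["C", ])) - fx$detritus_consumed[["C"]]
    expect_lt(abs(dC), 1e-10)
    dN <- (sum(out$biota) * rN + sum(out$om["N", ]) +
             sum(fx$nh4_excretion)) -
      (sum(biota) * rN + sum(om["N", ])) - fx$detritus_consumed[["N"]]
    expect_lt(abs(dN), 1e-10)
    dP <- (sum(out$biota) * rP + sum(out$om["P", ]) +
             sum(fx$po4_excretion)) -
      (sum(biota) * rP + sum(om["P", ])) - fx$detritus_consumed[["P"]]
    expect_lt(abs(dP), 1e-10)
    dSi <- (sum(out$om["Si", ]) + sum(fx$si_release)) -
      sum(om["Si", ]) - fx$detritus_consumed[["Si"]]
    expect_lt(abs(dSi), 1e-10)
  }
})

test_that("higher background mortality lowers equilibrium biomass", {
  # paired relaxations to equilibrium under constant forcing; only the
  # deposit-feeder mortality differs (x4, the documented scenario change)
  run_to_eq <- function(mort) {
    gp <- default_group_params()
    gp$deposit_feeders$mortality <- mort
    biota <- biota_state()
    om <- om_pools()
    env <- mk_env()
    for (i in 1:2500) {
      out <- step_biota(biota, om, env, gp)
      biota <- out$biota
      om <- out$om
      # replenish consumed POM to hold the resource environment fixed
      om["C", "semilabile"] <- max(om["C", "semilabile"], 1)
      om["N", "semilabile"] <- om["C", "semilabile"] *
        shelfbenthos:::mmol_per_gC("N")
      om["P", "semilabile"] <- om["C", "semilabile"] *
        shelfbenthos:::mmol_per_gC("P")
      om["Si", "semilabile"] <- om["C", "semilabile"] *
        shelfbenthos:::mmol_per_gC("Si")
    }
    biota[["deposit_feeders"]]
  }
  b_low <- run_to_eq(0.001)
  b_high <- run_to_eq(0.004)
  expect_gt(b_low, 0)
  expect_lt(b_high, b_low)
})

test_that("too large a time step raises a step-size error", {
  gp <- default_group_params()
  gp$meiofauna$basal_resp <- 0.09
  gp$meiofauna$mortality <- 0.09
  biota <- biota_state()
  expect_error(step_biota(biota, om_pools(), mk_env(), gp, dt = 10),
               "time step too large")
})

test_that("the bioturbation index is linear in faunal biomass", {
  b0 <- biota_state(0.1, 0.1, 0, 0, 0)
  expect_equal(bioturbation_index(b0), 0)
  b1 <- biota_state(0.1, 0.1, 0.2, 1, 0.5)
  b2 <- biota_state(0.1, 0.1, 0.4, 2, 1)
  expect_equal(bioturbation_index(b2), 2 * bioturbation_index(b1))
  only_dep <- bioturbation_index(b1, weights = c(deposit_feeders = 1,
                                                 suspension_feeders = 0,
                                                 meiofauna = 0))
  expect_equal(only_dep, 1)
})
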