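test_that("oxygen penetration follows the square-root closure", {
  expect_equal(oxygen_penetration(1e-9, 250, 1.25e-3), 0.02)
  expect_equal(oxygen_penetration(1e-9, 0, 1e-3), 0)
  # quadrupling K doubles D1; quadrupling demand halves it
  d <- oxygen_penetration(1e-9, 250, 1e-4)
  expect_equal(oxygen_penetration(4e-9, 250, 1e-4), 2 * d)
  expect_equal(oxygen_penetration(1e-9, 250, 4e-4), d / 2)
  # zero demand caps at the bed depth
  expect_equal(oxygen_penetration(1e-9, 250, 0, z_bed = 0.25), 0.25)
  expect_error(oxygen_penetration(0, 250, 1e-3), "> 0")
})

test_that("the layered closure reduces to the single-layer law", {
  # equal diffusivities: identical to the plain square-root form
  expect_identical(oxygen_penetration_layered(1e-9, 1e-9, 0.03, 250, 1.25e-3),
                   oxygen_penetration(1e-9, 250, 1.25e-3))
  # shallow oxic layer (D1 < h): flushed-stratum value applies
  expect_equal(oxygen_penetration_layered(4e-8, 1e-9, 0.1, 250, 1),
               oxygen_penetration(4e-8, 250, 1))
  # enhancement deepens D1 relative to background alone, but far less than
  # applying the enhanced K over the whole column
  d_bg <- oxygen_penetration(1e-9, 250, 1e-4)
  d_two <- oxygen_penetration_layered(3e-8, 1e-9, 0.03, 250, 1e-4)
  d_full <- oxygen_penetration(3e-8, 250, 1e-4)
  expect_gt(d_two, d_bg)
  expect_lt(d_two, d_full)
  expect_error(oxygen_penetration_layered(1e-9, 2e-9, 0.03, 250, 1e-4),
               "K_top must be >= K_deep")
})

test_that("total oxygen uptake sums its stoichiometric components", {
  expect_equal(total_oxygen_uptake(0), 0)
  expect_equal(total_oxygen_uptake(0.06), 5.0, tolerance = 1e-3)
  expect_equal(total_oxygen_uptake(0, nitrification_flux = 1), 2)
  expect_equal(total_oxygen_uptake(0.06, 1, 3),
               0.06 / bgc_units$g_per_mol_C * 1000 + 2 + 3)
})

test_that("nitrification and denitrification are first order", {
  expect_equal(nitrification(0, 0.1, 0.01), 0)
  expect_equal(nitrification(50, 0.1, 0.01), 0.05)
  expect_equal(denitrification(0, 40), 0)
  expect_equal(denitrification(0.5, 40, 1e-3), 0.02)
})

test_that("silicate dissolution and phosphate partition behave as stated", {
  expect_equal(silicate_dissolution(0), 0)
  expect_equal(silicate_dissolution(100, 0.005), 0.5)
  pp <- phosphate_partition(100, "oxic", coef_oxic = 0.2, coef_anoxic = 0.6)
  expect_equal(pp$dissolved, 20)
  expect_equal(pp$adsorbed, 80)
  pa <- phosphate_partition(100, "anoxic", coef_oxic = 0.2,
                            coef_anoxic = 0.6)
  expect_equal(pa$dissolved + pa$adsorbed, 100)
  expect_gt(pa$dissolved, pp$dissolved) # stronger adsorption when oxic
  expect_error(phosphate_partition(1, coef_oxic = 0.7, coef_anoxic = 0.6),
               "must be <")
})

test_that("relaxation exchange follows the exponential closed form", {
  rx <- relax_exchange(100, 50, tau_relax = 10, dt = 1)
  expect_equal(rx$content, 50 + 50 * exp(-0.1))
  expect_equal(rx$content, 95.24, tolerance = 1e-4)
  expect_equal(rx$flux, 100 - rx$content)
  eq <- relax_exchange(50, 50, 10, 1)
  expect_equal(eq$content, 50)
  expect_equal(eq$flux, 0)
  lim <- relax_exchange(100, 50, tau_relax = 0.01, dt = 1)
  expect_equal(lim$content, 50, tolerance = 1e-10)
  expect_error(relax_exchange(1, 1, 0), "> 0")
})

test_that("nitrate penetration mirrors the D1 construction below D1", {
  expect_equal(nitrate_penetration(0, 1, 1e-9, 0.02), 0.02)
  expect_equal(nitrate_penetration(10, 0, 1e-9, 0.02, z_bed = 0.25), 0.25)
  d <- nitrate_penetration(10, 1e-4, 1e-9, 0.02) - 0.02
  d4 <- nitrate_penetration(10, 4e-4, 1e-9, 0.02) - 0.02
  expect_equal(d4, d / 2)
})

test_that("pore-water profiles conserve layer contents", {
  ls <- layer_structure(D1 = 0.02, D2 = 0.1, z_bed = 0.25, porosity = 0.5)
  conc <- porewater_profile(c(oxic = 10, transition = 10, anoxic = 10),
                            ls, grid = c(0.01, 0.05, 0.2))
  expect_equal(conc[1], 10 / (0.5 * 0.02))
  expect_equal(conc[2], 10 / (0.5 * 0.08))
  # single-layer (uniform) case: flat profile at content / (poro * thickness)
  ls1 <- layer_structure(0.1, 0.1, 0.1, 0.5)
  flat <- porewater_profile(c(oxic = 10, transition = 0, anoxic = 0), ls1,
                            grid = c(0, 0.05, 0.099))
  expect_equal(flat[1], 200) # 10 mmol in 0.1 m at porosity 0.5
  expect_equal(flat, rep(flat[1], 3))
  # depth-integrated reconstruction returns the total dissolved content
  th <- c(0.02, 0.08, 0.15)
  grid_mid <- c(0.01, 0.06, 0.17)
  back <- sum(porewater_profile(c(oxic = 3, transition = 7, anoxic = 2),
                                ls, grid_mid) * 0.5 * th)
  expect_equal(back, 12, tolerance = 1e-9)
  expect_error(porewater_profile(c(1, 1, 1), ls, grid = 0.3), "within")
})

test_that("depth-mean concentration is the content-weighted mean", {
  ls <- layer_structure(0.02, 0.1, 0.25, 0.5)
  expect_equal(depth_mean_concentration(c(10, 10, 5), ls),
               25 / (0.5 * 0.25))
})
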