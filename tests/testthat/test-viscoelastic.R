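dens_tbl <- function(n_PC = 0, n_sJZ = 0, n_JZ = 0)
  tibble::tibble(R = NA_real_, n_PC = n_PC, n_sJZ = n_sJZ, n_JZ = n_JZ)

test_that("swelling factor is the clamped super-threshold sum", {
  C0 <- 5.22e-3
  net <- network_params()
  nc <- percolation_densities(C0, net)
  expect_equal(unname(nc), c(1, 19, 62) * C0 / 15000)

  ## everything below threshold
  expect_equal(swelling_factor(dens_tbl(), C0, net), 0)
  expect_equal(swelling_factor(dens_tbl(n_JZ = nc[["JZ"]] / 2), C0, net), 0)

  ## unit check: one species exceeding its threshold by C0/S
  d <- dens_tbl(n_sJZ = nc[["sJZ"]] + C0 / 300)
  expect_equal(swelling_factor(d, C0, net), 1)

  d2 <- dens_tbl(n_JZ = nc[["JZ"]] + 1e-5)
  expect_equal(swelling_factor(d2, C0, net), 300 * 1e-5 / C0)
  expect_equal(swelling_factor(d2, C0, net), 0.5747, tolerance = 1e-4)
})

test_that("network amplitudes apply percolation and absorption factors", {
  C0 <- 5.22e-3
  net <- network_params()
  nc <- percolation_densities(C0, net)

  ## sub-percolation JZ: no permanent-network elasticity
  a0 <- base_amplitudes(dens_tbl(n_JZ = nc[["JZ"]] * 0.9), C0, net)
  expect_equal(a0$G_JZ, 0)

  ## JZ above threshold wipes out the PC amplitude
  a1 <- base_amplitudes(dens_tbl(n_PC = 1e-4, n_JZ = nc[["JZ"]] * 1.5),
                        C0, net)
  expect_equal(a1$G_PC, 0)

  ## direct arithmetic: G_JZ = A * sw * kB T * excess
  a2 <- base_amplitudes(dens_tbl(n_JZ = nc[["JZ"]] + 1e-5), C0, net)
  sw <- 300 * 1e-5 / C0
  expect_equal(a2$G_JZ,
               1e3 * 6.02214076e23 * sw * 1.380649e-23 * 296.15 * 1e-5)
  expect_equal(a2$G_JZ, 14.2, tolerance = 5e-3)
})

test_that("polymer-liquid loss is Newtonian in frequency", {
  expect_equal(polymer_liquid_loss(5, solvent_params(Cp = 0)), 5e-3)
  expect_equal(polymer_liquid_loss(10), 10e-3 * (1 + 3.28 * 0.80))
  expect_equal(polymer_liquid_loss(10), 0.0362, tolerance = 2e-3)
  expect_equal(polymer_liquid_loss(20), 2 * polymer_liquid_loss(10))
})

test_that("fractional elements reproduce their analytic frequency response", {
  C0 <- 5.22e-3
  net <- network_params()
  nc <- percolation_densities(C0, net)

  ## fractional Kelvin-Voigt at omega = omega_ref
  d <- dens_tbl(n_JZ = nc[["JZ"]] + 1e-5)
  cm <- component_moduli(d, omega = 10, C0, net)
  GJZ <- base_amplitudes(d, C0, net)$G_JZ
  expect_equal(cm$Gp_JZ / GJZ, cos(0.009 * pi))
  expect_equal(cm$Gpp_JZ / GJZ, sin(0.009 * pi))
  expect_equal(cm$Gp_JZ / GJZ, 0.99960, tolerance = 1e-5)
  expect_equal(cm$Gpp_JZ / GJZ, 0.02827, tolerance = 1e-4)

  ## fractional Maxwell with alpha = 1/2: G'/G'' = (x + cos(pi/4))/sin(pi/4)
  d2 <- dens_tbl(n_sJZ = nc[["sJZ"]] + 1e-5)
  cm2 <- component_moduli(d2, omega = 10, C0, net)  # omega*K_sJZ = 0.014
  x <- sqrt(0.014)
  expect_equal(cm2$Gp_sJZ / cm2$Gpp_sJZ, (x + cos(pi / 4)) / sin(pi / 4))
  expect_equal(cm2$Gp_sJZ / cm2$Gpp_sJZ, 1.167, tolerance = 1e-3)

  ## vanished amplitude: no sJZ response at all
  cm3 <- component_moduli(dens_tbl(), omega = 10, C0, net)
  expect_equal(cm3$Gp_sJZ, 0)
  expect_equal(cm3$Gpp_sJZ, 0)
})

test_that("forward profile starts as a polymer liquid and sums exactly", {
  pr <- fig1_profiles()[["omega_1"]]
  expect_equal(pr$Gp_Pa[1], 0)
  expect_equal(pr$Gpp_Pa[1], polymer_liquid_loss(1))

  ## bookkeeping identity at every time point
  expect_equal(pr$Gp_Pa, pr$Gp_PC + pr$Gp_sJZ + pr$Gp_JZ)
  expect_equal(pr$Gpp_Pa, pr$Gpp_PL + pr$Gpp_PC + pr$Gpp_sJZ + pr$Gpp_JZ)
})

test_that("pre-gel loss rises with frequency; late storage barely does", {
  profs <- fig1_profiles()
  tg <- detect_crossover(profs[["omega_1"]])
  pre <- profs[["omega_1"]]$time_s < 0.8 * tg &
    profs[["omega_1"]]$time_s > 100
  expect_true(all(profs[["omega_3"]]$Gpp_Pa[pre] >
                  profs[["omega_1"]]$Gpp_Pa[pre]))
  expect_true(all(profs[["omega_10"]]$Gpp_Pa[pre] >
                  profs[["omega_3"]]$Gpp_Pa[pre]))
  ## JZ-dominated tail: exponent 0.018 means a weak omega-dependence
  late <- which.max(profs[["omega_1"]]$time_s)
  g1 <- profs[["omega_1"]]$Gp_Pa[late]
  g10 <- profs[["omega_10"]]$Gp_Pa[late]
  expect_lt(g10 / g1, (10 / 1)^0.03)
})

test_that("total storage modulus increases with the binding ratio", {
  C0 <- 5.22e-3
  net <- network_params()
  R <- seq(0, 0.155, by = 0.002)
  d <- species_concentrations(R, C0, net$phi)
  cm <- component_moduli(d, omega = 1, C0, net)
  Gp <- cm$Gp_PC + cm$Gp_sJZ + cm$Gp_JZ
  expect_true(all(diff(Gp) >= -1e-12))
})

test_that("the ratio frequency convention yields the loss-modulus bump", {
  ## With K_sJZ read as a characteristic frequency the high-frequency
  ## profiles develop the local max/min pair in G'' after the gel point.
  net <- network_params(sjz_frequency_convention = "ratio")
  tr <- attr(fig1_profiles(), "trajectory")
  pr10 <- forward_profile(tr, 10, net)
  tg <- detect_crossover(pr10)
  ex <- detect_gpp_extrema(pr10, t_gel = tg)
  expect_false(is.null(ex))
  expect_gt(ex$t_max, tg)
  expect_gt(ex$t_min, ex$t_max)
  expect_lt(ex$t_min, 2 * tg)
})
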