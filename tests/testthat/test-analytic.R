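test_that("effective demethylation ratio interpolates between D and 1", {
  p <- fig1_params()
  expect_equal(rho_effective(p, 1e-12), p$D, tolerance = 1e-9)
  expect_equal(rho_effective(p, 1e6), 1, tolerance = 1e-9)
  rho <- rho_effective(p, 4.507)
  expect_true(rho > p$D && rho < 1)
})

test_that("analytic gel time matches its quadrature oracle and limits", {
  p <- fig1_params()
  rho <- rho_effective(p, 4.507)
  oracle <- integrate(function(r) 1 / ((p$Rmax - r) * (rho - r)^2), 0, 0.144,
                      rel.tol = 1e-12)$value * p$tau_Ca
  expect_equal(tgel_analytic(p, R_gel = 0.144, branch = "ELCC_rho"), oracle,
               tolerance = 1e-8)

  ## matches numerical inversion of the rho-modified kinetics within 5%
  rhs <- function(t, y, parms)
    list((p$Rmax - y) * (rho - y)^2 / p$tau_Ca)
  sol <- deSolve::lsoda(c(R = 0), seq(0, 2e4, by = 5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-13)
  t_num <- approx(sol[, "R"], sol[, "time"], 0.144)$y
  expect_equal(tgel_analytic(p, R_gel = 0.144, branch = "ELCC_rho"), t_num,
               tolerance = 0.05)

  ## tau_c -> 0 reduces to the plain ELCC closed form with D
  expect_equal(tgel_analytic(p, R_gel = 0.12, approx = approx_params(1e-12)),
               closed_form_time(0.12, p, "ELCC"), tolerance = 1e-6)

  ## EC branch vanishes as R_gel -> D
  expect_equal(tgel_analytic(p, R_gel = p$D, branch = "EC"), 0)
  expect_error(tgel_analytic(p, R_gel = 0.2, branch = "ELCC_rho",
                             approx = approx_params(1e-12)), "domain")
})

test_that("gel time scales exactly with tau_Ca at fixed dimensionless inputs", {
  ## tgel proportional to tau_Ca (hence C0^-2 at fixed gamma): rho is held
  ## fixed by scaling tau_E with tau_Ca
  p1 <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
  c_ <- 4.2
  p2 <- kinetic_params(kE = 1e-4 / c_, tau_Ca = 980 * c_, C0 = 5.22e-3,
                       Rmax = 0.158)
  t1 <- tgel_analytic(p1, R_gel = 0.144, branch = "ELCC_rho")
  t2 <- tgel_analytic(p2, R_gel = 0.144, branch = "ELCC_rho")
  expect_equal(t2 / t1, c_, tolerance = 1e-12)
})

test_that("implicit inflection relation behaves and degenerates correctly", {
  p <- fig1_params()
  tg <- 1e4   # low-concentration regime where t_gel ~ tau_E
  ts <- tstar_analytic(p, t_gel = tg, R_gel = 0.144, R_star = 0.154,
                       approx = approx_params(eps = 7.71e-6))
  expect_gt(ts, tg)
  ## the measured-parameter identity: kE (t* - tgel) ~ 0.3
  expect_equal(p$kE * (ts - tg), 0.3, tolerance = 0.1)
  expect_equal(exp(-0.3), 0.7408, tolerance = 1e-4)

  ## infinite consumption rate closes the interval
  ts_inf <- tstar_analytic(p, t_gel = tg, R_gel = 0.144, R_star = 0.154,
                           approx = approx_params(eps = 1))
  expect_lt(ts_inf - tg, 0.1)
  ## R* = Rgel means no interval at all
  expect_equal(tstar_analytic(p, t_gel = tg, R_gel = 0.144, R_star = 0.144),
               tg, tolerance = 1e-9)
})

test_that("the explicit inflection interval is independent of tau_Ca", {
  p1 <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
  p2 <- kinetic_params(kE = 1e-4, tau_Ca = 190, C0 = 13.05e-3, Rmax = 0.158)
  d1 <- tstar_analytic(p1, t_gel = 5000, R_gel = 0.144, R_star = 0.154,
                       branch = "explicit") - 5000
  d2 <- tstar_analytic(p2, t_gel = 1200, R_gel = 0.144, R_star = 0.154,
                       branch = "explicit") - 1200
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("consumption-rate extrapolation anchors at the reference", {
  expect_equal(eps_extrapolate(0.158), 7.71e-6)
  grid <- seq(0.2, 1.0, by = 0.05)
  expect_true(all(diff(eps_extrapolate(grid)) > 0))
  expect_error(eps_extrapolate(0.05), "positive")
})

test_that("empirical critical ratios follow the printed coefficients", {
  r <- empirical_critical_ratios(1)
  expect_equal(r$R_gel, 1 / 2.53)
  expect_equal(r$R_gel, 0.3953, tolerance = 5e-4)
  expect_equal(r$R_star, 1 / 2.18)

  expect_lt(empirical_critical_ratios(1e-6)$R_gel, 2e-6)

  grid <- seq(0.08, 2, by = 0.02)
  rr <- empirical_critical_ratios(grid)
  expect_true(all(rr$R_star >= rr$R_gel))
  expect_true(all(diff(rr$R_gel) > 0))
  expect_lt(max(rr$R_gel), 1 / 1.72)

  rb <- empirical_critical_ratios(0.5, band = "2.5SE")
  expect_true(rb$R_gel_lo <= rb$R_gel && rb$R_gel <= rb$R_gel_hi)
  expect_true(rb$R_star_lo <= rb$R_star && rb$R_star <= rb$R_star_hi)
})

test_that("critical ratios from detected times are trajectory-consistent", {
  p <- kinetic_params(kE = 1e-12, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
  tr <- solve_binding_ode(p, seq(0, 30000, by = 5))
  expect_equal(critical_ratios_from_times(tr, 0, 0)$R_gel, 0)

  ## invert the ELCC closed form at R(t_gel) and recover t_gel
  t_gel <- 9000; t_star <- 13000
  rr <- critical_ratios_from_times(tr, t_gel, t_star)
  expect_lt(rr$R_gel, rr$R_star)
  expect_equal(closed_form_time(rr$R_gel, p, "ELCC"), t_gel,
               tolerance = 1e-6)
  expect_error(critical_ratios_from_times(tr, -5, 100), "outside")
})

test_that("gelation markers assemble the stoichiometry quantities", {
  profs <- fig1_profiles()
  tr <- attr(profs, "trajectory")
  m <- gelation_markers(profs[["omega_1"]], tr)
  expect_gt(m$t_star, m$t_gel)
  expect_true(m$R_gel < m$R_star)
  expect_equal(m$MR, (0.158 - m$R_gel) / m$R_gel)
  expect_equal(m$y, 1 - 0.158 / m$R_gel)
  expect_equal(m$normalized_G,
               m$G_gel_prime / (1e3 * 6.02214076e23 * 5.22e-3 *
                                1.380649e-23 * 296.15))
})

test_that("predicted characteristic times fall with excess calcium", {
  p <- fig1_params()
  grid <- seq(0.2, 0.95, by = 0.05)
  tab <- predict_characteristic_times(grid, p, branch = "ELCC")
  expect_true(all(diff(tab$t_gel) < 0))
  expect_true(all(tab$t_star >= tab$t_gel))
  ## EC branch rises with Rmax instead
  tab_ec <- predict_characteristic_times(seq(1, 1.76, by = 0.2), p,
                                         branch = "EC")
  expect_true(all(diff(tab_ec$t_gel) > 0))
})
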