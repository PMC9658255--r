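test_that("parameter derivation fills consistent characteristic scales", {
  p <- kinetic_params(kE = 1e-4, k1 = 50, tau_Ca = 980, C0 = 5.22e-3,
                      Rmax = 0.158)
  expect_equal(p$gamma, 1 / (50 * (5.22e-3)^2 * 980))
  expect_equal(p$gamma, 0.749, tolerance = 1e-3)
  expect_equal(p$t_bar, 1e4 / 980)
  expect_equal(p$tau_Ca * p$k1 * p$C0^2 * p$gamma, 1)
  expect_equal(p$D, 0.4)
  expect_equal(p$R_bar, 0.158 / 0.4)

  ## gamma route gives the same tau_Ca back
  q <- kinetic_params(kE = 1e-4, k1 = 50, gamma = p$gamma, C0 = 5.22e-3,
                      Rmax = 0.158)
  expect_equal(q$tau_Ca, 980)

  ## seed-weight mapping
  s <- kinetic_params(kE = 1e-4, tau_Ca = 980, seed_conc = 2, Rmax = 0.158)
  expect_equal(s$C0, 5.22e-3)

  expect_error(kinetic_params(kE = 1e-4, C0 = 5e-3, Rmax = 0.1),
               "gamma.*tau_Ca")
  expect_error(kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = -1, Rmax = 0.1),
               "positive")
  expect_error(derive_params(list(kE = 1e-4, tau_Ca = 980, C0 = 5e-3,
                                  Rmax = 0.1, bogus = 1)),
               "unknown")
})

test_that("binding ODE solution honours its invariants", {
  ## zero calcium: no binding at all
  p0 <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0)
  tr0 <- solve_binding_ode(p0, seq(0, 5000, by = 100))
  expect_true(all(tr0$R == 0))

  p <- fig1_params()
  tr <- solve_binding_ode(p, seq(0, 15000, by = 10))
  expect_equal(tr$R[1], 0)
  ## analytic initial slope: Rmax * D^2 / tau_Ca
  expect_equal(tr$dRdt[1], 0.158 * 0.4^2 / 980, tolerance = 1e-12)
  expect_true(all(diff(tr$R) >= -1e-12))
  expect_true(all(tr$R <= p$Rmax + 1e-12))
  expect_true(all(tr$R <= 1 - p$cm0_frac * exp(-p$kE * tr$time_s) + 1e-6))

  expect_error(solve_binding_ode(p, seq(10, 100, by = 10)), "start at 0")
})

test_that("ODE matches the three closed-form limits", {
  ## slow enzyme, limiting calcium (ELCC)
  p <- kinetic_params(kE = 1e-12, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
  tt <- seq(0, 980 * 50, length.out = 1000)
  tr <- solve_binding_ode(p, tt)
  Rcf <- invert_closed_form(tt, p, "ELCC")
  expect_lt(max(abs(tr$R - Rcf)[-1] / pmax(Rcf[-1], 1e-12)), 1e-3)

  ## fast enzyme (CC); compare beyond the short demethylation transient
  p2 <- kinetic_params(kE = 100, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.5)
  tt2 <- seq(0, 980 * 40, length.out = 1000)
  tr2 <- solve_binding_ode(p2, tt2)
  Rcf2 <- invert_closed_form(tt2, p2, "CC")
  sel <- tt2 > 1
  expect_lt(max(abs(tr2$R - Rcf2)[sel] / Rcf2[sel]), 1e-3)

  ## slow enzyme, excess calcium (EC); binding equilibrates on tau_Ca
  p3 <- kinetic_params(kE = 1e-4, tau_Ca = 1e-3, C0 = 5.22e-3, Rmax = 1.76)
  tt3 <- seq(0, 3e4, length.out = 1000)
  tr3 <- solve_binding_ode(p3, tt3)
  Rcf3 <- invert_closed_form(tt3, p3, "EC")
  sel3 <- tt3 > 50
  expect_lt(max(abs(tr3$R - Rcf3)[sel3] / Rcf3[sel3]), 1e-3)
})

test_that("closed-form times agree with direct quadrature of dtau/dR", {
  p <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
  q_elcc <- integrate(function(r) 1 / ((0.158 - r) * (0.4 - r)^2), 0, 0.1,
                      rel.tol = 1e-12)$value * 980
  expect_equal(closed_form_time(0.1, p, "ELCC"), q_elcc, tolerance = 1e-9)

  p2 <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.5)
  q_cc <- integrate(function(r) 1 / ((0.5 - r) * (1 - r)^2), 0, 0.25,
                    rel.tol = 1e-12)$value * 980
  expect_equal(closed_form_time(0.25, p2, "CC"), q_cc, tolerance = 1e-9)

  ## EC branch anchored at R = D
  p3 <- kinetic_params(kE = 1e-4, tau_Ca = 10, C0 = 5.22e-3, Rmax = 1.76)
  expect_equal(closed_form_time(0.4, p3, "EC"), 0)
  expect_error(closed_form_time(0.2, p3, "EC"), "domain")
  expect_error(closed_form_time(0.2, p, "ELCC"), "domain")
})

test_that("closed-form inversion round-trips and matches algebra", {
  p <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
  set.seed(7)
  for (lab in c("ELCC", "CC")) {
    sup <- if (lab == "ELCC") 0.158 else 0.158
    R <- runif(20, 0, sup * 0.999)
    t <- closed_form_time(R, p, lab)
    expect_equal(invert_closed_form(t, p, lab), R, tolerance = 1e-8)
  }
  expect_equal(invert_closed_form(0, p, "ELCC"), 0)
  ## EC inversion is the explicit exponential relaxation to full binding
  p3 <- kinetic_params(kE = 1e-4, tau_Ca = 10, C0 = 5.22e-3, Rmax = 1.76)
  t <- c(0, 500, 5000)
  expect_equal(invert_closed_form(t, p3, "EC"),
               1 - 0.6 * exp(-t / 1e4), tolerance = 1e-12)
  expect_error(invert_closed_form(-1, p3, "EC"), "non-negative")
})

test_that("solutions are invariant under joint time rescaling", {
  ## scaling tau_Ca and tau_E by c and reading at c*t leaves R unchanged
  p1 <- kinetic_params(kE = 1e-4, tau_Ca = 980, C0 = 5.22e-3, Rmax = 0.158)
  c_ <- 3.7
  p2 <- kinetic_params(kE = 1e-4 / c_, tau_Ca = 980 * c_, C0 = 5.22e-3,
                       Rmax = 0.158)
  t1 <- seq(0, 12000, length.out = 400)
  tr1 <- solve_binding_ode(p1, t1)
  tr2 <- solve_binding_ode(p2, t1 * c_)
  expect_equal(tr2$R, tr1$R, tolerance = 1e-7)
})

test_that("regime classification follows the dimensionless groups", {
  p <- fig1_params()
  r <- classify_regime(p)
  expect_equal(r$label, "ELCC")
  expect_equal(r$R_bar, 0.395, tolerance = 1e-10)

  p_cc <- kinetic_params(kE = 1, tau_Ca = 100, C0 = 5e-3, Rmax = 2)
  expect_equal(classify_regime(p_cc)$label, "CC")

  p_ec <- kinetic_params(kE = 1e-4, tau_Ca = 1000, C0 = 5e-3, Rmax = 0.8)
  expect_equal(classify_regime(p_ec)$label, "EC")  # R_bar = 2

  ## threshold is exposed
  expect_equal(classify_regime(p, t_bar_threshold = 100)$label, "CC")
})
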