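# Vesicle geometry, charge balance and loading model.

test_that("geometry derives volume, area and capacitance for a 20 nm vesicle", {
  g <- vesicle_geometry()
  r_cm <- 20e-7
  expect_equal(g$volume_L, 4 / 3 * pi * r_cm^3 * 1e-3, tolerance = 1e-12)
  expect_equal(g$surface_area_cm2, 4 * pi * r_cm^2, tolerance = 1e-12)
  expect_equal(g$capacitance_F, 1e-6 * 4 * pi * r_cm^2, tolerance = 1e-12)
  # one mM of net monovalent charge shifts psi by ~64 mV in this volume
  expect_equal(g$mV_per_mM, 96485.33212 * g$volume_L / g$capacitance_F,
               tolerance = 1e-12)
  expect_equal(g$mV_per_mM, 64.33, tolerance = 1e-3)
  expect_error(vesicle_geometry(radius_nm = -1))
})

test_that("impermeant charge reproduces the construction identities", {
  init <- luminal_init(); geom <- vesicle_geometry()
  # equal leaflet potentials: B is the plain ionic charge sum
  p_eq <- vesicle_params(psi_in_mV = -20, psi_out_mV = -20)
  plain <- 10^(-init$pH_L0) * 1e3 + init$c_k_L0_mM + init$c_na_L0_mM -
    init$c_cl_L0_mM - init$c_glut_L0_mM
  expect_equal(impermeant_charge(init, geom, p_eq), plain, tolerance = 1e-12)
  # default potentials: surface term ~0.78 mM (direct arithmetic oracle)
  p <- vesicle_params()
  corr <- plain - impermeant_charge(init, geom, p)
  expect_equal(corr, 50 / geom$mV_per_mM, tolerance = 1e-12)
  expect_equal(corr, 0.777, tolerance = 2e-3)
})

test_that("membrane potential at t=0 equals psi_in - psi_out by construction", {
  geom <- vesicle_geometry()
  for (psi_out in c(-50, -20, 0)) {
    for (pH0 in c(6.9, 7.2)) {
      init <- luminal_init(pH_L0 = pH0)
      p <- vesicle_params(psi_in_mV = 0, psi_out_mV = psi_out)
      B <- impermeant_charge(init, geom, p)
      psi0 <- membrane_potential(10^(-pH0) * 1e3, init$c_k_L0_mM,
                                 init$c_na_L0_mM, init$c_cl_L0_mM,
                                 init$c_glut_L0_mM, B, geom)
      expect_equal(psi0, -psi_out, tolerance = 1e-9)
    }
  }
  # charge sum equal to B gives 0 mV
  expect_equal(membrane_potential(0, 5, 145, 110, 0, 40, geom), 0)
  # 1 mM net positive excess in a 20 nm vesicle: ~ +64 mV
  expect_equal(membrane_potential(1, 0, 0, 0, 0, 0, geom),
               96485.33212 * geom$volume_L / geom$capacitance_F,
               tolerance = 1e-12)
})

test_that("surface correction follows the Boltzmann factor", {
  expect_equal(surface_corrected_concentration(3, 1, 0), 3)
  f <- surface_corrected_concentration(1, 1, -50, 307)
  expect_equal(f, exp(50e-3 * 96485.33212 / (8.31446262 * 307)),
               tolerance = 1e-12)
  expect_equal(f, 6.62, tolerance = 1e-3)
  expect_equal(surface_corrected_concentration(1, -1, -50, 307), 1 / f,
               tolerance = 1e-12)
})

test_that("molecule count conversion is exact and round-trips", {
  g <- vesicle_geometry()
  expect_equal(molecules_from_concentration(0, g), 0)
  # 3500 molecules in a 20 nm vesicle ~ 173 mM (direct arithmetic oracle)
  c3500 <- 3500 / (6.02214076e23 * g$volume_L * 1e-3)
  expect_equal(concentration_from_molecules(3500, g), c3500,
               tolerance = 1e-12)
  expect_equal(c3500, 173.4, tolerance = 5e-3)
  cs <- c(0.001, 1, 50, 173.4)
  expect_equal(concentration_from_molecules(
    molecules_from_concentration(cs, g), g), cs, tolerance = 1e-14)
  expect_error(molecules_from_concentration(-1, g))
})

test_that("rhs is zero for zero fluxes and has the VGLUT sign convention", {
  parms <- list(geom = vesicle_geometry(), params = vesicle_params(),
                conditions = cytosol_conditions(), fluxes = zero_flux_model(),
                B = impermeant_charge(), pH_L0 = 7.2, h0_mM = 10^(-7.2) * 1e3)
  y <- c(pH_L = 7.2, c_glut_L = 0.001, c_cl_L = 110)
  d <- vesicle_rhs(0, y, parms)
  expect_equal(unname(d[[1]]), c(0, 0, 0))
  # VGLUT-only model: glutamate influx and proton export (pH rises)
  parms$fluxes <- default_flux_model(g_hleak = 0, k_vatpase = 0,
                                     g_vglut_cl = 0, g_glut_leak = 0)
  d2 <- vesicle_rhs(0, y, parms)
  expect_gt(d2[[1]][["c_glut_L"]], 0)
  expect_gt(d2[[1]][["pH_L"]], 0)
  expect_equal(d2[[1]][["c_cl_L"]], 0)
})

test_that("a pure V-ATPase flux acidifies at the hand-computed rate", {
  fm <- default_flux_model(k_vglut = 0, g_glut_leak = 0, g_vglut_cl = 0,
                           g_hleak = 0)
  params <- vesicle_params()
  J <- vesicle_fluxes(7.2, 0.001, 110, 50, fm, cytosol_conditions(), params)
  # independent arithmetic: dmu_H at psi=+50 with surface-shifted cytosolic pH
  Z <- log(10) * 8.31446262 * 307 / 96485.33212 * 1000
  shift <- log10(exp(50e-3 * 96485.33212 / (8.31446262 * 307)))
  dmu <- 50 + Z * ((7.2 - shift) - 7.2)
  J_hand <- fm$k_vatpase * tanh((fm$dmu_atpase - dmu) / fm$kappa_vatpase)
  expect_equal(J$J_vatpase, J_hand, tolerance = 1e-12)
  parms <- list(geom = vesicle_geometry(), params = params,
                conditions = cytosol_conditions(), fluxes = fm,
                B = impermeant_charge(), pH_L0 = 7.2, h0_mM = 10^(-7.2) * 1e3)
  d <- vesicle_rhs(0, c(pH_L = 7.2, c_glut_L = 0.001, c_cl_L = 110), parms)
  expect_equal(d[[1]][["pH_L"]], -J_hand / params$beta_pH_mM_per_pH,
               tolerance = 1e-9)
})

test_that("flux model validates rates and scales with atpase_scale", {
  expect_error(default_flux_model(k_vglut = -1))
  fm <- default_flux_model()
  J1 <- vesicle_fluxes(6.5, 10, 50, 30, fm,
                       cytosol_conditions(atpase_scale = 1))
  Jh <- vesicle_fluxes(6.5, 10, 50, 30, fm,
                       cytosol_conditions(atpase_scale = 0.5))
  expect_equal(Jh$J_vatpase, J1$J_vatpase / 2, tolerance = 1e-12)
  J0 <- vesicle_fluxes(6.5, 10, 50, 30, zero_flux_model(),
                       cytosol_conditions())
  expect_equal(J0$J_vglut, 0)
  expect_equal(J0$J_hleak, 0)
  expect_equal(J0$J_vatpase, 0)
  expect_equal(J0$J_vglut_cl, 0)
})

test_that("zero-flux simulation conserves every state variable", {
  s <- simulate_vesicle(fluxes = zero_flux_model(), t_end = 500)
  tr <- s$trajectory
  expect_true(s$steady_state_reached)
  expect_lt(max(abs(tr$pH_L - 7.2)), 1e-9)
  expect_lt(max(abs(tr$c_cl_L_mM - 110)), 1e-9)
  expect_lt(max(abs(tr$c_glut_L_mM - 0.001)), 1e-12)
  expect_lt(max(abs(tr$psi_mV - 50)), 1e-6)
  expect_lt(abs(steady_state_glutamate(s) -
                  molecules_from_concentration(0.001)), 1e-6)
})

test_that("control run loads monotonically to a plateau near 3500 molecules", {
  s <- simulate_vesicle()
  expect_true(s$steady_state_reached)
  n <- steady_state_glutamate(s)
  expect_gt(n, 3000)
  expect_lt(n, 4000)
  # monotone approach (small solver wiggle allowed)
  expect_true(all(diff(s$trajectory$n_glut) > -1e-4 * n))
  # lumen acidifies below cytosolic pH
  expect_lt(tail(s$trajectory$pH_L, 1), 7.2)
})

test_that("steady state is insensitive to tighter tolerances and longer runs", {
  n1 <- steady_state_glutamate(simulate_vesicle())
  n2 <- steady_state_glutamate(simulate_vesicle(rtol = 5e-9, atol = 5e-11))
  expect_lt(abs(n2 / n1 - 1), 1e-3)
  n3 <- steady_state_glutamate(simulate_vesicle(t_end = 6000))
  expect_lt(abs(n3 / n1 - 1), 1e-3)
})

test_that("identical configuration gives bit-identical trajectories", {
  s1 <- simulate_vesicle(t_end = 300)
  s2 <- simulate_vesicle(t_end = 300)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("membrane potential stays consistent with the charge balance", {
  s <- simulate_vesicle(t_end = 500)
  tr <- s$trajectory
  geom <- s$geom
  psi_re <- geom$mV_per_mM * (tr$h_charge_mM + 5 + 145 - tr$c_cl_L_mM -
                                tr$c_glut_L_mM - s$B_mM)
  expect_equal(tr$psi_mV, psi_re, tolerance = 1e-8)
})

test_that("a VGLUT-free vesicle stays empty", {
  s <- simulate_vesicle(fluxes = default_flux_model(k_vglut = 0,
                                                    g_glut_leak = 0))
  expect_lt(steady_state_glutamate(s), 1)
})

test_that("disabling the V-ATPase lowers steady-state loading", {
  n_ctrl <- steady_state_glutamate(simulate_vesicle())
  s0 <- simulate_vesicle(conditions = cytosol_conditions(atpase_scale = 0))
  expect_lt(steady_state_glutamate(s0), n_ctrl)
})

test_that("ischemia-like scenarios lower loading; alkalinization raises it", {
  res <- run_scenarios()
  expect_true(all(res$steady_state_reached))
  ctrl <- res[res$name == "control", ]
  expect_equal(ctrl$relative_change, 0)
  lower <- c("acidic_cytosol", "high_Na", "high_Cl", "low_K",
             "acidic_lumen", "low_ATPase")
  for (nm in lower)
    expect_lt(res$relative_change[res$name == nm], 0)
  expect_gt(res$relative_change[res$name == "alkaline_cytosol"], 0)
})

test_that("scenario overrides validate their paths", {
  expect_error(run_scenarios(list(scenario_spec("bad", list(foo = 1))),
                             t_end = 10), "override path")
  expect_error(run_scenarios(list(scenario_spec("bad", list(cytosol.nope = 1))),
                             t_end = 10), "unknown override field")
})
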