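test_that("uniform lungs apportion alveoli exactly with equal-thickness layers", {
  p <- alveolar_params(20, 4, 0.2)
  lung <- build_uniform_lung(35, 150e6, p, n_layers = 35)
  expect_equal(nrow(lung$layers), 35)
  expect_equal(sum(lung$layers$n_alveoli), 150e6)
  expect_true(all(abs(diff(lung$layers$z_top) - 1) < 1e-12))
  expect_true(all(abs(lung$layers$n_alveoli - 150e6 / 35) <= 1))

  one <- build_uniform_lung(35, 7, p, n_layers = 1)
  expect_equal(one$layers$z_bottom, 35)
  expect_equal(one$layers$n_alveoli, 7)

  # a count that does not divide evenly still sums exactly
  lung2 <- build_uniform_lung(10, 1e6 + 3, p, n_layers = 7)
  expect_equal(sum(lung2$layers$n_alveoli), 1e6 + 3)

  empty <- build_uniform_lung(35, 0, p, n_layers = 10)
  pr <- regional_profile(empty, lung_pressures(30, 8.75), closure_rule(0))
  expect_error(lung_summary(empty, pr), class = "lvrsim_error_empty_lung")
  expect_error(build_uniform_lung(0, 10, p), class = "lvrsim_error_invalid_input")
})

test_that("closed-form integrals match independent quadrature", {
  # verify the analytic oracle itself against stats::integrate before using
  # it to judge the discretization
  set.seed(21)
  for (i in 1:5) {
    sc <- random_uniform_scenario()
    cf <- closed_form_totals(sc$height, sc$params, sc$pressures, sc$rule)
    infl <- pressure_profile(sc$pressures$p_tlc_apex, sc$height, sc$rho)
    defl <- pressure_profile(sc$pressures$p_rv_apex, sc$height, sc$rho)
    num_tlc <- stats::integrate(
      function(z) alveolar_volume(sc$params, ptp_at_depth(infl, z)),
      0, sc$height, rel.tol = 1e-10
    )$value / sc$height
    num_rv <- stats::integrate(
      function(z) deflation_volume(sc$params, defl, sc$rule, z),
      0, sc$height, rel.tol = 1e-10, subdivisions = 500L
    )$value / sc$height
    expect_equal(cf$tlc_per_alveolus, num_tlc, tolerance = 1e-8)
    expect_equal(cf$rv_per_alveolus, num_rv, tolerance = 1e-6)
  }
})

test_that("discrete layered totals converge to the closed form (oracle equivalence)", {
  set.seed(22)
  for (i in 1:20) {
    sc <- random_uniform_scenario()
    cf <- closed_form_totals(sc$height, sc$params, sc$pressures, sc$rule)
    for (spec in list(c(200, 1e-3), c(1000, 1e-4))) {
      lung <- build_uniform_lung(sc$height, 1e8, sc$params, n_layers = spec[1])
      prof <- regional_profile(lung, sc$pressures, sc$rule)
      tlc_bar <- sum(prof$n_alveoli * prof$v_tlc_ul) / sum(prof$n_alveoli)
      rv_bar <- sum(prof$n_alveoli * prof$v_rv_ul) / sum(prof$n_alveoli)
      expect_lt(abs(tlc_bar - cf$tlc_per_alveolus) / cf$tlc_per_alveolus, spec[2])
      expect_lt(abs(rv_bar - cf$rv_per_alveolus) / cf$rv_per_alveolus, spec[2])
    }
  }
})

test_that("refinement moves the summary toward the oracle", {
  sc <- list(height = 35, params = alveolar_params(40, 20, 0.3),
             pressures = lung_pressures(12.5, 2.4), rule = closure_rule(1))
  cf <- closed_form_totals(sc$height, sc$params, sc$pressures, sc$rule)
  errs <- sapply(c(50, 100, 200, 400, 800), function(nl) {
    lung <- build_uniform_lung(sc$height, 1e8, sc$params, n_layers = nl)
    prof <- regional_profile(lung, sc$pressures, sc$rule)
    rv_bar <- sum(prof$n_alveoli * prof$v_rv_ul) / sum(prof$n_alveoli)
    abs(rv_bar - cf$rv_per_alveolus)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("gravity-off closed form reduces to the constant integrand", {
  params <- alveolar_params(20, 4, 0.2)
  pres <- lung_pressures(30, 5, rho_frac = 0)
  cf <- closed_form_totals(35, params, pres, closure_rule(0))
  expect_equal(cf$tlc_per_alveolus, alveolar_volume(params, 30))
  expect_equal(cf$rv_per_alveolus, alveolar_volume(params, 5))
})

test_that("regional RV/TLC decreases with depth above closure, rises below", {
  sc <- emphysema_preset()
  run <- simulate_scenario(sc)
  cp <- attr(run$profile, "closure")
  expect_equal(cp$status, "interior")
  above <- run$profile$z_from_apex_cm < cp$z
  expect_true(all(diff(run$profile$rv_tlc[above]) < 0))
  expect_true(all(diff(run$profile$rv_tlc[!above]) >= 0))
  # and the trapped volume is identical below closure
  expect_equal(length(unique(run$profile$v_rv_ul[!above])), 1L)
})

test_that("whole-lung RV/TLC is a weighted mean of layer ratios", {
  set.seed(23)
  for (i in 1:10) {
    sc <- random_uniform_scenario()
    lung <- build_uniform_lung(sc$height, 1e7, sc$params, n_layers = 50)
    prof <- regional_profile(lung, sc$pressures, sc$rule)
    s <- lung_summary(lung, prof)
    expect_gte(s$rv_tlc, min(prof$rv_tlc) - 1e-12)
    expect_lte(s$rv_tlc, max(prof$rv_tlc) + 1e-12)
    expect_equal(s$rv_tlc, s$rv_l / s$tlc_l)
    expect_lt(s$rv_l, s$tlc_l)
  }
})

test_that("RV/TLC is invariant to scaling alveolar count and common volume scale", {
  base <- scenario_spec("inv", 35, 150e6, alveolar_params(40, 20, 0.3),
                        p_tlc_apex = 12.5, p_rv_apex = 2.4, p_tm = 1)
  r0 <- simulate_scenario(base)$summary$rv_tlc
  n_scaled <- base
  n_scaled$n_total <- base$n_total * 3
  # counts are rounded to whole alveoli per layer, so n-scaling is exact only
  # up to the largest-remainder rounding (~1e-6 relative on layer weights)
  expect_equal(simulate_scenario(n_scaled)$summary$rv_tlc, r0, tolerance = 1e-6)
  v_scaled <- base
  v_scaled$params <- alveolar_params(40 * 0.37, 20 * 0.37, 0.3)
  expect_equal(simulate_scenario(v_scaled)$summary$rv_tlc, r0, tolerance = 1e-12)
})

test_that("a scenario whose inflation limb closes airways is refused", {
  lung <- build_uniform_lung(35, 1e6, alveolar_params(20, 4, 0.2))
  expect_error(
    regional_profile(lung, lung_pressures(9, 2), closure_rule(1)),
    class = "lvrsim_error_inflation_closure"
  )
})

test_that("single-layer totals equal count times per-alveolus volume", {
  params <- alveolar_params(20, 4, 0.2)
  lung <- build_uniform_lung(35, 1000, params, n_layers = 1)
  pres <- lung_pressures(30, 10)
  prof <- regional_profile(lung, pres, closure_rule(0))
  s <- lung_summary(lung, prof)
  z_mid <- 17.5
  v_tlc <- alveolar_volume(params, 30 - 0.25 * z_mid)
  v_rv <- alveolar_volume(params, 10 - 0.25 * z_mid)
  expect_equal(s$tlc_l, 1000 * v_tlc / 1e6)
  expect_equal(s$rv_l, 1000 * v_rv / 1e6)
})

test_that("profiles serialize to the fixed CSV contract", {
  run <- simulate_scenario(healthy_preset(n_layers = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(run$profile, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 20)
  expect_true(all(c("z_from_apex_cm", "z_from_base_cm", "n_alveoli",
                    "v_tlc_ul", "v_rv_ul", "rv_tlc") %in% names(df)))
  expect_equal(df$rv_tlc, run$profile$rv_tlc, tolerance = 1e-12)
})
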