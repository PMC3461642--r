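test_that("presets carry the stated constants", {
  h <- healthy_preset()
  expect_equal(h$n_total, 300e6)
  expect_equal(c(h$params$v_max, h$params$v_min, h$params$k), c(20, 4, 0.2))
  expect_equal(h$params$v_min / h$params$v_max, 0.2)
  expect_equal(h$p_tm, 0)
  expect_equal(h$height, 35)
  # default deflation pressure puts the healthy closure point exactly at the base
  cp <- closure_depth(pressure_profile(h$p_rv_apex, h$height, h$rho_frac),
                      closure_rule(h$p_tm))
  expect_equal(cp$status, "interior")
  expect_equal(cp$z, h$height)

  e <- emphysema_preset(calibrate = FALSE)
  expect_equal(e$n_total, 150e6)
  expect_equal(e$params$v_min / e$params$v_max, 0.5)
  expect_equal(e$params$k, 0.3)
  expect_equal(e$p_tm, 1)
  expect_equal(e$p_tlc_apex, 12.5)
  expect_true(is.na(e$p_rv_apex))
  expect_error(simulate_scenario(e), class = "lvrsim_error_invalid_input")
})

test_that("treatment removes exactly the requested count from the target region", {
  sc <- emphysema_preset()
  lung <- as_lung_state(sc)
  tr <- paper_treatments(sc)
  post <- apply_treatment(lung, lung_pressures(sc$p_tlc_apex, sc$p_rv_apex),
                          closure_rule(sc$p_tm), tr$ult)
  expect_equal(sum(post$lung$layers$n_alveoli), 150e6 - 22e6)
  expect_equal(post$lung$height, 33)
  # removal confined to the upper half (rescaled boundary at 16.5 cm)
  lower_half <- post$lung$layers$z_top >= 16.5 - 1e-9
  expect_equal(post$lung$layers$n_alveoli[lower_half],
               lung$layers$n_alveoli[lower_half])
  # pressures shift: inflation to its post value, deflation by the same increment
  expect_equal(post$pressures$p_tlc_apex, 14)
  expect_equal(post$pressures$p_rv_apex, sc$p_rv_apex + 1.5)
  expect_equal(post$rule$p_tm, 0.5)
})

test_that("a null treatment is the identity", {
  sc <- emphysema_preset()
  lung <- as_lung_state(sc)
  pres <- lung_pressures(sc$p_tlc_apex, sc$p_rv_apex)
  rule <- closure_rule(sc$p_tm)
  null_tr <- treatment_spec(c(0, 17.5), n_removed = 0,
                            p_tlc_apex_post = sc$p_tlc_apex,
                            p_tm_post = sc$p_tm, height_post = sc$height)
  post <- apply_treatment(lung, pres, rule, null_tr)
  expect_identical(post$lung$layers$n_alveoli, lung$layers$n_alveoli)
  s_pre <- lung_summary(lung, regional_profile(lung, pres, rule))
  s_post <- lung_summary(post$lung, regional_profile(post$lung, post$pressures, post$rule))
  expect_identical(s_pre$rv_tlc, s_post$rv_tlc)
  expect_identical(s_pre$tlc_l, s_post$tlc_l)
})

test_that("invalid treatments are refused", {
  sc <- emphysema_preset()
  lung <- as_lung_state(sc)
  pres <- lung_pressures(sc$p_tlc_apex, sc$p_rv_apex)
  rule <- closure_rule(sc$p_tm)
  too_many <- treatment_spec(c(0, 17.5), 100e6, 14, 0.5, 33)
  expect_error(apply_treatment(lung, pres, rule, too_many),
               class = "lvrsim_error_invalid_treatment")
  taller <- treatment_spec(c(0, 17.5), 1e6, 14, 0.5, 36)
  expect_error(apply_treatment(lung, pres, rule, taller),
               class = "lvrsim_error_invalid_treatment")
  lower_recoil <- treatment_spec(c(0, 17.5), 1e6, 10, 0.5, 33)
  expect_error(apply_treatment(lung, pres, rule, lower_recoil),
               class = "lvrsim_error_invalid_treatment")
  higher_ptm <- treatment_spec(c(0, 17.5), 1e6, 14, 2, 33)
  expect_error(apply_treatment(lung, pres, rule, higher_ptm),
               class = "lvrsim_error_invalid_treatment")
})

test_that("arm comparison validates pairing", {
  sc <- emphysema_preset()
  tr <- paper_treatments(sc)
  uneven <- treatment_spec(lobe_region(sc, "lower"), 10e6, 14, 0.5, 33)
  expect_error(compare_ult_llt(sc, tr$ult, uneven),
               class = "lvrsim_error_invalid_comparison")
  shifted <- treatment_spec(lobe_region(sc, "lower"), 22e6, 15, 0.5, 33)
  expect_error(compare_ult_llt(sc, tr$ult, shifted),
               class = "lvrsim_error_invalid_comparison")
  # identical specs on the same region give identical arms
  same <- compare_ult_llt(sc, tr$ult, treatment_spec(lobe_region(sc, "upper"),
                                                     22e6, 14, 0.5, 33))
  expect_equal(same$ult$summary$rv_tlc, same$llt$summary$rv_tlc)
})

test_that("upper-lobe removal beats equal lower-lobe removal on the preset", {
  sc <- emphysema_preset()
  tr <- paper_treatments(sc)
  cmp <- compare_ult_llt(sc, tr$ult, tr$llt)
  d <- cmp$deltas
  expect_lt(d$delta_rv_tlc_percent[d$arm == "ult"],
            d$delta_rv_tlc_percent[d$arm == "llt"])
  expect_lt(d$delta_rv_tlc_percent[d$arm == "ult"], 0)
  td <- tidy(cmp)
  expect_equal(nrow(td), 3)
  expect_true(is.na(td$delta_rv_tlc_percent[td$arm == "baseline"]))
})

test_that("pressure and height shifts alone produce the regional mechanism effects", {
  sc <- emphysema_preset()
  tr <- paper_treatments(sc)$ult
  eff <- treatment_shift_effects(sc, tr, n_grid = 400)
  cp_pre <- attr(eff, "closure_pre")
  cp_post <- attr(eff, "closure_post")
  # (C) closure moves caudally: distance from base strictly decreases
  expect_equal(cp_pre$status, "interior")
  expect_equal(cp_post$status, "interior")
  expect_lt(cp_post$z_from_base, cp_pre$z_from_base)
  # (A) the ratio rises toward the apex: strictly positive delta in the
  # apical quarter of the post-treatment lung
  apical <- eff$z_from_base_cm > 0.75 * max(eff$z_from_base_cm)
  expect_true(all(eff$delta[apical] > 0))
  # (B) the ratio falls toward the base: strictly negative delta at and below
  # the post-treatment closure point (trapped plus adjacent reopened layers)
  basal <- eff$z_from_base_cm <= cp_post$z_from_base + 1
  expect_true(all(eff$delta[basal] < 0))
  # the two regimes meet in a single sign change along the lung
  signs <- sign(eff$delta[eff$delta != 0])
  expect_equal(sum(diff(signs) != 0), 1L)
})

test_that("removing above-mean-ratio alveoli lowers overall RV/TLC (brute force)", {
  params <- alveolar_params(30, 10, 0.25)
  pres <- lung_pressures(12, 3)
  rule <- closure_rule(1)
  counts <- c(2e6, 3e6, 4e6, 3e6, 2e6)
  lung <- toy_lung(counts, params, height = 5)
  prof <- regional_profile(lung, pres, rule)
  r0 <- lung_summary(lung, prof)$rv_tlc
  for (j in seq_along(counts)) {
    lung2 <- lung
    lung2$layers$n_alveoli[j] <- lung2$layers$n_alveoli[j] - 1e6
    r1 <- lung_summary(lung2, regional_profile(lung2, pres, rule))$rv_tlc
    if (prof$rv_tlc[j] > r0) expect_lt(r1, r0) else expect_gt(r1, r0)
  }
})

test_that("heterogeneity index flags the homogeneous band inclusively", {
  expect_equal(heterogeneity_index(0.5, 0.5)$hi, 1)
  expect_true(heterogeneity_index(0.5, 0.5)$homogeneous)
  expect_equal(heterogeneity_index(0.575, 0.5)$hi, 1.15)
  expect_true(heterogeneity_index(0.575, 0.5)$homogeneous)
  expect_false(heterogeneity_index(0.6, 0.5)$homogeneous)
  expect_true(heterogeneity_index(0.85, 1)$homogeneous)
  expect_error(heterogeneity_index(0.5, 0), class = "lvrsim_error_division")
  expect_error(heterogeneity_index(1.2, 0.5), class = "lvrsim_error_invalid_input")
  expect_error(heterogeneity_index(0.5, -0.1), class = "lvrsim_error_invalid_input")
})

test_that("lobe regions partition the lung height at the chosen boundary", {
  sc <- emphysema_preset(calibrate = FALSE)
  expect_equal(lobe_region(sc, "upper"), c(0, 17.5))
  expect_equal(lobe_region(sc, "lower"), c(17.5, 35))
  expect_equal(lobe_region(35, "upper", fraction = 0.4), c(0, 14))
  expect_error(lobe_region(35, "upper", fraction = 1), class = "lvrsim_error_invalid_input")
})
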