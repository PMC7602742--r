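test_that("tumor parameter invariants are enforced", {
  expect_error(tumor_disposition_params(f_vascular = 0.2,
                                        f_extracellular = 0.2,
                                        f_intracellular = 0.2),
               "sum to 1")
  expect_error(tumor_disposition_params(tumor_volume = -1), "positive")
  expect_error(tumor_disposition_params(ps = -1), "non-negative")
  m <- study_model_tumor()
  expect_error(attach_tumor(m, tumor_disposition_params()),
               "already attached")
})

test_that("with no tumor clearances both water spaces reach unbound plasma", {
  phys <- build_mouse_physiology(20)
  cmp <- compound_params()
  kps <- assemble_final_kpset(predict_kp_method2(cmp),
                              mbq167_kp_overrides(), 0.29)
  m <- build_pbpk_model(phys, cmp, kps,
                        clearances = list(hepatic_clint_u = 1e-15,
                                          renal_cl = 1e-15))
  m <- attach_tumor(m, tumor_disposition_params(cl_efflux = 0,
                                                cl_tumor = 0))
  sim <- simulate_pbpk(m, dose_regimen(0.2, 0), t_grid = c(0, 5000))
  last <- nrow(sim$amounts)
  tum <- m$tumor
  c_ec <- sim$amounts[last, "tumor_ec"] /
    (tum$f_extracellular * tum$tumor_volume)
  c_ic <- sim$amounts[last, "tumor_ic"] /
    (tum$f_intracellular * tum$tumor_volume)
  unbound_plasma <- cmp$fu_plasma * sim$concentrations$plasma[last]
  expect_equal(unname(c_ec / unbound_plasma), 1, tolerance = 1e-3)
  expect_equal(unname(c_ic / unbound_plasma), 1, tolerance = 1e-3)
})

test_that("efflux depresses the intracellular space to ps/(ps + efflux)", {
  phys <- build_mouse_physiology(20)
  cmp <- compound_params()
  kps <- assemble_final_kpset(predict_kp_method2(cmp),
                              mbq167_kp_overrides(), 0.29)
  m <- build_pbpk_model(phys, cmp, kps,
                        clearances = list(hepatic_clint_u = 1e-15,
                                          renal_cl = 1e-15))
  tum <- tumor_disposition_params(ps = 1.2, cl_efflux = 7, cl_tumor = 0)
  m <- attach_tumor(m, tum)
  sim <- simulate_pbpk(m, dose_regimen(0.2, 0), t_grid = c(0, 5000))
  last <- nrow(sim$amounts)
  c_ec <- sim$amounts[last, "tumor_ec"] /
    (tum$f_extracellular * tum$tumor_volume)
  c_ic <- sim$amounts[last, "tumor_ic"] /
    (tum$f_intracellular * tum$tumor_volume)
  expect_equal(unname(c_ic / c_ec), 1.2 / 8.2, tolerance = 1e-3)
})

test_that("total tumor concentration is the repartition-invariant sum", {
  tum <- tumor_disposition_params(tumor_volume = 1)
  a <- c(tumor_vascular = 10, tumor_ec = 20, tumor_ic = 30)
  expect_equal(tumor_total_concentration(a, tum), 60)
  b <- c(tumor_vascular = 30, tumor_ec = 10, tumor_ic = 20)
  expect_equal(tumor_total_concentration(b, tum),
               tumor_total_concentration(a, tum))
  expect_equal(tumor_total_concentration(0 * a, tum), 0)
  expect_error(tumor_total_concentration(c(x = 1), tum), "tumor states")
})

test_that("tumor subsystem conserves mass through its elimination route", {
  reg <- dose_regimen(0.2, 0)
  sim <- simulate_pbpk(study_model_tumor(), reg,
                       t_grid = seq(0, 48, by = 0.1))
  expect_lt(max(abs(sim$mass_balance_residual)) / 2e5, 1e-6)
  expect_gt(sim$amounts[nrow(sim$amounts), "elim_tumor"], 0)
})

test_that("tumor exposure is lower and later than plasma", {
  sim <- simulate_pbpk(study_model_tumor(), dose_regimen(0.2, 0),
                       t_grid = seq(0, 24, by = 0.005))
  pl <- cmax_tmax(sim$time, sim$concentrations$plasma)
  tu <- cmax_tmax(sim$time, sim$concentrations$tumor_total)
  expect_lt(tu[["cmax"]], pl[["cmax"]])
  expect_gt(tu[["tmax"]], pl[["tmax"]])
})

test_that("without perfusion the tumor never sees drug", {
  m <- build_study_model()
  m <- attach_tumor(m, tumor_disposition_params(q_tumor = 1e-12))
  sim <- simulate_pbpk(m, dose_regimen(0.2, 0),
                       t_grid = seq(0, 24, by = 0.1))
  expect_lt(max(sim$concentrations$tumor_total),
            1e-9 * max(sim$concentrations$plasma))
})
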