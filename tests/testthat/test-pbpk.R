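test_that("well-stirred clearance respects its limits", {
  q <- 1.8; fu_b <- 0.0111; bp <- 1.8
  # flow-limited ceiling
  expect_equal(hepatic_clearance_well_stirred(q, fu_b, 1e9, bp) / bp, q,
               tolerance = 1e-6)
  # restrictive limit: CL_blood ~ fu_b * CLint
  expect_equal(hepatic_clearance_well_stirred(q, fu_b, 1, bp) / bp,
               fu_b * 1, tolerance = 0.01)
  expect_equal(hepatic_clearance_well_stirred(1.8, 0.0111, 152.36, 1.8),
               1.57, tolerance = 0.005)
})

test_that("hepatic calibration is a fixed point and rejects infeasible targets", {
  phys <- build_mouse_physiology(20)
  cmp <- compound_params()
  clint_u <- whole_liver_unbound_clint(79, 0.07, phys$hepatocellularity,
                                       phys$liver_weight)
  q_liver <- phys$tissue_flows[["liver_arterial"]] +
    phys$tissue_flows[["liver_portal"]]
  hep <- hepatic_clearance_well_stirred(q_liver,
                                        cmp$fu_plasma / cmp$bp_ratio,
                                        clint_u, cmp$bp_ratio)
  fu <- calibrate_hepatic_pathway(phys, cmp, hep + phys$gfr)
  expect_equal(as.numeric(fu), 0.07, tolerance = 1e-6)
  # a target above the flow-limited ceiling names the ceiling
  ceiling_cl <- q_liver * cmp$bp_ratio + phys$gfr
  expect_error(calibrate_hepatic_pathway(phys, cmp, ceiling_cl + 1),
               "ceiling")
  expect_error(calibrate_hepatic_pathway(phys, cmp, phys$gfr / 2),
               "renal")
})

test_that("simulated mass balance closes to 1e-6 of the dose at all times", {
  reg <- dose_regimen(0.2, c(0, 12, 24))
  sim <- simulate_pbpk(study_model(), reg, t_grid = seq(0, 48, by = 0.1))
  total_dose <- reg$fa * reg$dose_amount * 1e6 * length(reg$dose_times)
  expect_lt(max(abs(sim$mass_balance_residual)) / total_dose, 1e-6)
  expect_true(all(as.matrix(sim$concentrations[-1]) > -1e-9))
})

test_that("no drug appears before the absorption lag and Tmax follows it", {
  sim <- single_dose_sim()
  pre <- sim$time < 0.17
  expect_true(all(sim$concentrations$plasma[pre] == 0))
  expect_gte(cmax_tmax(sim$time, sim$concentrations$plasma)[["tmax"]],
             0.17)
})

test_that("the linear model doubles concentrations with the dose and superposes", {
  tg <- seq(0, 48, by = 0.1)
  s1 <- simulate_pbpk(study_model(), dose_regimen(0.2, 0), tg)
  s2 <- simulate_pbpk(study_model(), dose_regimen(0.4, 0), tg)
  expect_equal(s2$concentrations$plasma, 2 * s1$concentrations$plasma,
               tolerance = 1e-6)
  multi <- simulate_pbpk(study_model(), dose_regimen(0.2, c(0, 12)), tg)
  shifted <- stats::approx(s1$time + 12, s1$concentrations$plasma,
                           xout = multi$time, yleft = 0, rule = 2)$y
  sup <- stats::approx(s1$time, s1$concentrations$plasma,
                       xout = multi$time, rule = 2)$y + shifted
  expect_lt(max(abs(multi$concentrations$plasma - sup)) / max(sup), 1e-5)
})

test_that("a homogeneous high-flow body follows the one-compartment solution", {
  phys <- build_mouse_physiology(20,
                                 overrides = list(cardiac_output = 8000))
  cmp <- compound_params(bp_ratio = 1, fu_plasma = 1)
  tissues <- setdiff(names(phys$tissue_volumes),
                     c("arterial_blood", "venous_blood", "plasma"))
  kp1 <- assemble_final_kpset(
    stats::setNames(rep(1, length(tissues)), tissues), scalar = 1)
  cl <- 0.5
  m <- build_pbpk_model(phys, cmp, kp1,
                        clearances = list(hepatic_clint_u = 1e-12,
                                          renal_cl = cl))
  reg <- dose_regimen(0.2, 0, ka = 3, lag_time = 0.17)
  sim <- simulate_pbpk(m, reg, t_grid = seq(0, 6, by = 0.05))
  V <- sum(phys$tissue_volumes[c(tissues, "arterial_blood",
                                 "venous_blood")])
  ke <- cl * 60 / V
  tt <- pmax(sim$time - reg$lag_time, 0)
  closed <- 2e5 * reg$ka / (V * (reg$ka - ke)) *
    (exp(-ke * tt) - exp(-reg$ka * tt))
  i <- sim$time >= 0.3
  expect_lt(max(abs(sim$concentrations$plasma[i] - closed[i]) /
                  closed[i]), 1e-3)
})

test_that("with zero clearance every tissue equilibrates at its Kp", {
  phys <- build_mouse_physiology(20)
  cmp <- compound_params()
  kps <- assemble_final_kpset(predict_kp_method2(cmp),
                              mbq167_kp_overrides(), 0.29)
  m <- build_pbpk_model(phys, cmp, kps,
                        clearances = list(hepatic_clint_u = 1e-15,
                                          renal_cl = 1e-15))
  sim <- simulate_pbpk(m, dose_regimen(0.2, 0), t_grid = c(0, 5000))
  last <- nrow(sim$concentrations)
  cp <- sim$concentrations$plasma[last]
  for (tt in c("muscle", "kidney", "adipose", "heart")) {
    expect_equal(sim$concentrations[[tt]][last] / cp, kps$kp[[tt]],
                 tolerance = 1e-3)
  }
})

test_that("simulated systemic clearance matches the closed-form sum", {
  m <- study_model()
  sim <- simulate_pbpk(m, dose_regimen(0.2, 0),
                       t_grid = seq(0, 300, by = 0.05))
  auc_inf <- auc_trapezoid(sim$time, sim$concentrations$plasma)
  cl_sim <- 0.2e6 / auc_inf / 60       # mL/min
  expect_equal(cl_sim, total_plasma_cl(m), tolerance = 0.02)
})

test_that("tissue exposure ranks kidneys > liver > spleen > lung > heart", {
  sim <- single_dose_sim()
  i12 <- sim$time <= 12
  auc <- vapply(c("kidney", "liver", "spleen", "lung", "heart"),
                function(tt) auc_trapezoid(sim$time[i12],
                                           sim$concentrations[[tt]][i12]),
                numeric(1))
  cmax <- vapply(c("kidney", "liver", "spleen", "lung", "heart"),
                 function(tt) max(sim$concentrations[[tt]]), numeric(1))
  expect_true(all(diff(auc) < 0))
  expect_true(all(diff(cmax) < 0))
})

test_that("structural errors are caught", {
  phys <- build_mouse_physiology(20)
  cmp <- compound_params()
  kps <- assemble_final_kpset(predict_kp_method2(cmp),
                              mbq167_kp_overrides(), 0.29)
  kps$kp <- kps$kp[names(kps$kp) != "muscle"]
  expect_error(build_pbpk_model(phys, cmp, kps,
                                clearances = list(hepatic_clint_u = 1,
                                                  renal_cl = 0.3)),
               "muscle")
  expect_error(simulate_pbpk(study_model(), dose_regimen(0.2, c(0, 48)),
                             t_grid = seq(0, 24, by = 1)),
               "cover")
})
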