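test_that("a pKa 0.27 base is effectively neutral at plasma pH", {
  fi <- fraction_ionized(0.27, 7.4, "monoprotic_base")
  expect_equal(fi, 10^(0.27 - 7.4) / (1 + 10^(0.27 - 7.4)))
  expect_lt(fi, 1e-7)
})

test_that("partitioning reduces to tissue water when lipids cannot hold drug", {
  # vanishing logP and fu = 1 leave only the water terms (including the
  # water-equivalent 0.7 share of the neutral phospholipids)
  cmp <- compound_params(logP = -30, compound_type = "neutral",
                         fu_plasma = 1, pKa = 0)
  kp <- predict_kp_method2(cmp)
  comp <- tissue_composition()
  for (tt in c("muscle", "kidney", "adipose")) {
    r <- comp[comp$tissue == tt, ]
    expect_equal(kp[[tt]], r$f_ew + r$f_iw + 0.7 * r$f_npl,
                 tolerance = 1e-6)
  }
})

test_that("lipid-rich tissues receive larger Kp than lean tissues", {
  kp <- predict_kp_method2(compound_params())
  expect_gt(kp[["adipose"]], kp[["muscle"]])
  expect_true(all(kp > 0))
})

test_that("prediction matches an independent transcription of the equations", {
  comp <- tissue_composition()
  set.seed(11)
  for (i in 1:5) {
    cmp <- compound_params(
      molecular_weight = runif(1, 100, 600),
      logP = runif(1, -1, 5),
      compound_type = sample(c("neutral", "monoprotic_acid",
                               "monoprotic_base"), 1),
      pKa = runif(1, 0, 6),
      fu_plasma = runif(1, 0.01, 1),
      bp_ratio = runif(1, 0.6, 2))
    got <- predict_kp_method2(cmp, comp)
    want <- oracle_kp(cmp, comp)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("missing tissue composition is rejected by name", {
  expect_error(predict_kp_method2(compound_params(), tissues = "pancreas"),
               "pancreas")
})

test_that("final Kp assembly keeps overrides verbatim and scales the rest", {
  pred <- c(heart = 2, muscle = 10, adipose = 50)
  ov <- c(heart = 1)
  kps <- assemble_final_kpset(pred, ov, scalar = 0.29)
  expect_identical(kps$kp[["heart"]], 1)
  expect_equal(kps$kp[["muscle"]], 2.9)
  expect_equal(kps$provenance[["heart"]], "optimized")
  expect_equal(kps$provenance[["muscle"]], "predicted_scaled")
  # identity when scalar is 1 and nothing is overridden
  expect_equal(assemble_final_kpset(pred, scalar = 1)$kp, pred)
  expect_error(assemble_final_kpset(pred, c(heart = -1)), "positive")
  expect_error(assemble_final_kpset(pred, c(tumor = 2)), "tumor")
  # the study overrides land exactly in the final set
  final <- assemble_final_kpset(predict_kp_method2(compound_params()),
                                mbq167_kp_overrides(), 0.29)
  expect_identical(final$kp[names(mbq167_kp_overrides())],
                   mbq167_kp_overrides())
})

test_that("Vss reduces to the hand-computed sum in a minimal configuration", {
  # one tissue of 10 mL with Kp 2, 1 mL plasma, no erythrocyte
  # partitioning (B/P = 1 - Hct), 20 g body weight -> (1 + 20)/20
  phys <- structure(list(
    body_weight = 20, hematocrit = 0.5,
    tissue_volumes = c(single = 10, arterial_blood = 1, venous_blood = 1,
                       plasma = 1)), class = "mouse_physiology")
  cmp <- compound_params(bp_ratio = 0.5)
  kps <- assemble_final_kpset(c(single = 2), scalar = 1)
  expect_equal(compute_vss(kps, phys, cmp), 1.05)
})

test_that("Vss is increasing in every single Kp", {
  phys <- build_mouse_physiology(20)
  cmp <- compound_params()
  pred <- predict_kp_method2(cmp)
  kps <- assemble_final_kpset(pred, mbq167_kp_overrides(), 0.29)
  v0 <- compute_vss(kps, phys, cmp)
  for (tt in c("muscle", "liver", "adipose")) {
    kps2 <- kps
    kps2$kp[[tt]] <- kps2$kp[[tt]] * 1.5
    expect_gt(compute_vss(kps2, phys, cmp), v0)
  }
})

test_that("molar-mass concentration conversion is exact", {
  expect_equal(molar_to_mass_concentration(0.0187, 338.414), 6.3283,
               tolerance = 1e-4)
  expect_equal(molar_to_mass_concentration(0, 338.414), 0)
  expect_equal(molar_to_mass_concentration(1, 338.414), 338.414)
  expect_error(molar_to_mass_concentration(-1, 338.414), "non-negative")
})
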