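#' Build the final calibrated MBQ-167 whole-body model
#'
#' Convenience assembly of the study parameterization: default mouse
#' physiology at the requested body weight; MBQ-167 physicochemistry;
#' the final Kp set (five optimized tissue values verbatim, mechanistic
#' predictions scaled by 0.29 elsewhere); hepatic intrinsic clearance
#' calibrated so that well-stirred hepatic plasma clearance plus the
#' fixed renal clearance (0.3 mL/min at 20 g) reproduces the observed
#' systemic plasma clearance of 2.15 mL/min; and, optionally, the
#' permeability-limited tumor.
#'
#' @param body_weight g (default 20).
#' @param target_plasma_cl observed systemic plasma clearance used for
#'   the hepatic calibration, mL/min.
#' @param kp_scalar global scalar on predicted partition coefficients.
#' @param with_tumor attach the default tumor disposition block?
#' @param tumor tumor parameters when `with_tumor` is TRUE.
#' @return a `pbpk_model`.
#' @examples
#' \donttest{
#' model <- build_study_model()
#' sim <- simulate_pbpk(model, dose_regimen(0.2, 0),
#'                      t_grid = seq(0, 24, by = 0.01))
#' }
#' @export
build_study_model <- function(body_weight = 20, target_plasma_cl = 2.15,
                              kp_scalar = 0.29, with_tumor = FALSE,
                              tumor = tumor_disposition_params()) {
  phys <- build_mouse_physiology(body_weight)
  cmp <- compound_params()
  predicted <- predict_kp_method2(cmp, hematocrit = phys$hematocrit)
  kpset <- assemble_final_kpset(predicted, mbq167_kp_overrides(),
                                scalar = kp_scalar)
  fu_inc <- calibrate_hepatic_pathway(phys, cmp, target_plasma_cl)
  cmp$fu_inc <- as.numeric(fu_inc)
  model <- build_pbpk_model(
    phys, cmp, kpset,
    clearances = list(hepatic_clint_u = attr(fu_inc, "clint_u"),
                      renal_cl = phys$gfr))
  if (with_tumor) model <- attach_tumor(model, tumor)
  model
}
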