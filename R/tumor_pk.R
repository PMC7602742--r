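#' Permeability-limited tumor disposition parameters
#'
#' The tumor is modelled as three sub-spaces: a vascular space (16% of
#' tumor volume by default) perfused by tumor blood flow and exchanging
#' with extracellular water across the capillary wall on an
#' unbound-plasma basis, an extracellular (EC) and an intracellular (IC)
#' water space linked by bidirectional passive permeability `ps`, an
#' IC-to-EC efflux transporter clearance, and an intracellular intrinsic
#' clearance.  Clearance densities are per mL of tumor.  Defaults are the
#' optimized MBQ-167 values: PS 1.2, efflux 7 and CL_tumor 2.2
#' mL/min/mL tumor.
#'
#' @param tumor_volume tumor volume, mL (default 0.5, the PK-study
#'   setting).
#' @param f_vascular,f_extracellular,f_intracellular volume fractions
#'   (must sum to 1; defaults 0.16 / 0.40 / 0.44).
#' @param ps EC-IC passive permeability clearance, mL/min/mL tumor.
#' @param cl_efflux IC-to-EC efflux transporter clearance, mL/min/mL tumor.
#' @param cl_tumor intracellular intrinsic clearance, mL/min/mL tumor.
#' @param q_tumor tumor blood flow, mL/min (default 0.1 mL/min per mL
#'   tumor).
#' @param ps_capillary vascular-EC permeability clearance, mL/min/mL
#'   tumor; defaults to ten times `ps` so the capillary wall is not rate
#'   limiting.
#' @return An object of class `tumor_disposition_params`.
#' @export
tumor_disposition_params <- function(tumor_volume = 0.5,
                                     f_vascular = 0.16,
                                     f_extracellular = 0.40,
                                     f_intracellular = 0.44,
                                     ps = 1.2,
                                     cl_efflux = 7,
                                     cl_tumor = 2.2,
                                     q_tumor = 0.1 * tumor_volume,
                                     ps_capillary = 10 * ps) {
  if (tumor_volume <= 0) stop("tumor_volume must be positive")
  fr <- c(f_vascular, f_extracellular, f_intracellular)
  if (any(fr <= 0)) stop("tumor volume fractions must be positive")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("tumor volume fractions must sum to 1")
  }
  if (ps < 0 || cl_efflux < 0 || cl_tumor < 0 || ps_capillary < 0) {
    stop("tumor clearance densities must be non-negative")
  }
  if (q_tumor <= 0) stop("q_tumor must be positive")
  structure(list(tumor_volume = tumor_volume, f_vascular = f_vascular,
                 f_extracellular = f_extracellular,
                 f_intracellular = f_intracellular,
                 ps = ps, cl_efflux = cl_efflux, cl_tumor = cl_tumor,
                 q_tumor = q_tumor, ps_capillary = ps_capillary),
            class = "tumor_disposition_params")
}

#' Attach a permeability-limited tumor to a PBPK model
#'
#' Adds vascular, extracellular and intracellular tumor states (plus a
#' tumor-eliminated accumulator) to the whole-body system.  The vascular
#' space draws `q_tumor` from arterial blood and returns to venous blood;
#' capillary exchange with EC water is driven by the unbound plasma
#' concentration; EC and IC exchange passively at `ps`; the efflux
#' transporter moves drug IC to EC; `cl_tumor` eliminates from IC.
#'
#' @param model a `pbpk_model` without a tumor.
#' @param params a [tumor_disposition_params()] object.
#' @return the model with tumor states attached.
#' @export
attach_tumor <- function(model, params) {
  stopifnot(inherits(model, "pbpk_model"),
            inherits(params, "tumor_disposition_params"))
  if (!is.null(model$tumor)) {
    stop("a tumor is already attached to this model")
  }
  model$tumor <- params
  model$matrix <- pbpk_matrix(model)
  model
}

#' Total tumor concentration from state amounts
#'
#' Observed tumor data are homogenate totals; the matching model output
#' is the summed vascular, extracellular and intracellular amount divided
#' by tumor volume.
#'
#' @param amounts named numeric vector (or matrix row) of state amounts
#'   containing `tumor_vascular`, `tumor_ec`, `tumor_ic` (ng).
#' @param params the `tumor_disposition_params` of the model.
#' @return total tumor concentration, ng/mL.
#' @export
tumor_total_concentration <- function(amounts, params) {
  stopifnot(inherits(params, "tumor_disposition_params"))
  need <- c("tumor_vascular", "tumor_ec", "tumor_ic")
  if (is.matrix(amounts)) {
    if (!all(need %in% colnames(amounts))) {
      stop("tumor states are not present in `amounts`")
    }
    rowSums(amounts[, need, drop = FALSE]) / params$tumor_volume
  } else {
    if (!all(need %in% names(amounts))) {
      stop("tumor states are not present in `amounts`")
    }
    sum(amounts[need]) / params$tumor_volume
  }
}
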