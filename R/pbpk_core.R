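#' Dosing regimen for the PBPK model
#'
#' Intraperitoneal administration is represented as a lagged first-order
#' depot emptying directly into venous blood (bioavailability `fa`,
#' absorption rate `ka`, lag `lag_time`), bypassing gut and liver
#' first-pass.  Defaults are the optimized MBQ-167 absorption parameters
#' (ka 3 1/h, lag 0.17 h, fa 1).
#'
#' @param dose_amount dose per administration, mg.
#' @param dose_times administration times, h (non-decreasing).
#' @param ka first-order absorption rate constant, 1/h.
#' @param lag_time absorption lag, h.
#' @param fa fraction of the dose absorbed, in (0, 1].
#' @param route_label free-text label (metadata only).
#' @return An object of class `dose_regimen`.
#' @examples
#' dose_regimen(0.2, 0)   # single 10 mg/kg dose in a 20 g mouse
#' @export
dose_regimen <- function(dose_amount, dose_times = 0, ka = 3,
                         lag_time = 0.17, fa = 1, route_label = "IP") {
  if (dose_amount <= 0) stop("dose_amount must be positive")
  if (is.unsorted(dose_times)) stop("dose_times must be non-decreasing")
  if (ka <= 0) stop("ka must be positive")
  if (lag_time < 0) stop("lag_time must be non-negative")
  if (fa <= 0 || fa > 1) stop("fa must lie in (0, 1]")
  structure(list(dose_amount = dose_amount, dose_times = dose_times,
                 ka = ka, lag_time = lag_time, fa = fa,
                 route_label = route_label),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf(
    "<dose_regimen> %s: %d dose(s) of %.3g mg, ka %.3g 1/h, lag %.3g h, fa %.3g\n",
    x$route_label, length(x$dose_times), x$dose_amount, x$ka, x$lag_time,
    x$fa))
  invisible(x)
}

#' Well-stirred hepatic clearance
#'
#' `CL_blood = Q * fu_b * CLint_u / (Q + fu_b * CLint_u)`, returned on the
#' plasma-concentration basis by multiplying with the blood-to-plasma
#' ratio.
#'
#' @param q_liver_blood total liver blood flow, mL/min.
#' @param fu_blood unbound fraction in blood (`fu_plasma / bp_ratio`).
#' @param clint_u unbound whole-liver intrinsic clearance, mL/min.
#' @param bp_ratio blood-to-plasma concentration ratio.
#' @return hepatic plasma clearance, mL/min.
#' @export
hepatic_clearance_well_stirred <- function(q_liver_blood, fu_blood,
                                           clint_u, bp_ratio) {
  if (q_liver_blood <= 0 || fu_blood <= 0 || clint_u <= 0 || bp_ratio <= 0) {
    stop("all well-stirred arguments must be positive")
  }
  cl_blood <- q_liver_blood * fu_blood * clint_u /
    (q_liver_blood + fu_blood * clint_u)
  cl_blood * bp_ratio
}

#' Calibrate the hepatic pathway against an observed systemic clearance
#'
#' Finds the incubation unbound fraction `fu_inc` such that the
#' hepatocyte-scaled well-stirred hepatic plasma clearance plus the fixed
#' renal clearance reproduces a target systemic plasma clearance.  Hepatic
#' clearance is monotone in 1/fu_inc, so the calibration inverts the
#' well-stirred expression in closed form (residual < 1e-4 relative by
#' construction).
#'
#' @param phys a `mouse_physiology`.
#' @param compound a `compound_params` (supplies fu,plasma and B/P).
#' @param target_plasma_cl observed systemic plasma clearance, mL/min.
#' @param renal_cl renal plasma clearance, mL/min (default `phys$gfr`).
#' @param clint_per_million_cells in vitro hepatocyte intrinsic clearance,
#'   uL/min/10^6 cells (default 79, the MBQ-167 assay value).
#' @return the calibrated `fu_inc` with attributes `hepatic_plasma_cl` and
#'   `clint_u` (the implied whole-liver unbound intrinsic clearance,
#'   mL/min).
#' @export
calibrate_hepatic_pathway <- function(phys, compound, target_plasma_cl,
                                      renal_cl = phys$gfr,
                                      clint_per_million_cells = 79) {
  stopifnot(inherits(phys, "mouse_physiology"),
            inherits(compound, "compound_params"))
  q_liver <- phys$tissue_flows[["liver_arterial"]] +
    phys$tissue_flows[["liver_portal"]]
  fu_b <- compound$fu_plasma / compound$bp_ratio
  ceiling_cl <- q_liver * compound$bp_ratio + renal_cl
  if (target_plasma_cl < renal_cl) {
    stop("target clearance is below the renal clearance alone")
  }
  if (target_plasma_cl >= ceiling_cl) {
    stop(sprintf(
      "target plasma clearance %.4g mL/min is not reachable: flow-limited ceiling is %.4g mL/min",
      target_plasma_cl, ceiling_cl))
  }
  cl_blood <- (target_plasma_cl - renal_cl) / compound$bp_ratio
  clint_u <- q_liver * cl_blood / (q_liver - cl_blood) / fu_b
  fu_inc <- clint_per_million_cells * phys$hepatocellularity *
    phys$liver_weight / 1000 / clint_u
  if (fu_inc <= 0 || fu_inc > 1) {
    stop(sprintf("calibrated fu_inc = %.4g falls outside (0, 1]", fu_inc))
  }
  structure(fu_inc,
            hepatic_plasma_cl = target_plasma_cl - renal_cl,
            clint_u = clint_u)
}

# Internal time-unit note: the ODE system runs in ng, mL and hours;
# flows/clearances are supplied in mL/min and converted once here.

#' Build the whole-body PBPK model
#'
#' Assembles the linear ODE system: lagged first-order depot into venous
#' blood; lung in series between venous and arterial blood; systemic
#' tissues perfused in parallel from arterial blood with perfusion-limited
#' exchange (tissue venous outflow at concentration `C_t * B/P / Kp_t`);
#' the liver receives hepatic-arterial plus portal (spleen + gut outflow)
#' inflow and eliminates with an intrinsic-clearance term consistent with
#' the well-stirred model; the kidney eliminates from arterial plasma at
#' the renal clearance.  Cumulative eliminated amounts are tracked per
#' route for mass balance.
#'
#' @param phys a `mouse_physiology`.
#' @param compound a `compound_params`.
#' @param kpset a `kp_set` covering every perfused tissue.
#' @param clearances list with `hepatic_clint_u` (unbound whole-liver
#'   intrinsic clearance, mL/min) and `renal_cl` (plasma renal clearance,
#'   mL/min).
#' @return An object of class `pbpk_model`.
#' @export
build_pbpk_model <- function(phys, compound, kpset, clearances) {
  stopifnot(inherits(phys, "mouse_physiology"),
            inherits(compound, "compound_params"),
            inherits(kpset, "kp_set"))
  if (is.null(clearances$hepatic_clint_u) || is.null(clearances$renal_cl)) {
    stop("`clearances` must provide hepatic_clint_u and renal_cl (mL/min)")
  }
  tissues <- setdiff(names(phys$tissue_volumes),
                     c("arterial_blood", "venous_blood", "plasma"))
  missing <- setdiff(tissues, names(kpset$kp))
  if (length(missing)) {
    stop("Kp missing for tissue(s): ", paste(missing, collapse = ", "))
  }
  model <- structure(
    list(physiology = phys, compound = compound, kpset = kpset,
         clearances = clearances, tumor = NULL, tissues = tissues),
    class = "pbpk_model")
  model$matrix <- pbpk_matrix(model)
  model
}

# Assemble the constant coefficient matrix of the linear system (per hour).
pbpk_matrix <- function(model) {
  phys <- model$physiology
  cmp <- model$compound
  kp <- model$kpset$kp
  V <- phys$tissue_volumes
  Qh <- phys$tissue_flows * 60              # mL/h
  co_h <- phys$cardiac_output * 60
  bp <- cmp$bp_ratio
  fu_b <- cmp$fu_plasma / bp
  clint_h <- model$clearances$hepatic_clint_u * 60
  clr_h <- model$clearances$renal_cl * 60

  tissues <- model$tissues
  states <- c("depot", "venous_blood", "arterial_blood", tissues,
              "elim_hepatic", "elim_renal")
  tumor <- model$tumor
  if (!is.null(tumor)) {
    states <- c(states, "tumor_vascular", "tumor_ec", "tumor_ic",
                "elim_tumor")
  }
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))

  # With a tumor attached, its perfusion rides on top of the systemic
  # distribution, so the pulmonary (and venous return) flow carries
  # cardiac output plus the tumor flow; otherwise the circulation would
  # hold a permanent arterio-venous gradient at equilibrium.
  q_tumor_h <- if (!is.null(tumor)) tumor$q_tumor * 60 else 0
  co_eff <- co_h + q_tumor_h

  # tissue washout rate constants (amount basis): Q_t * B/P / (Kp_t * V_t)
  qflow <- function(t) {
    if (t == "lung") co_eff
    else if (t == "liver") Qh[["liver_arterial"]] + Qh[["liver_portal"]]
    else Qh[[t]]
  }
  kout <- vapply(tissues, function(t) {
    qflow(t) * bp / (kp[[t]] * V[[t]])
  }, numeric(1))

  # depot -> venous blood
  M["depot", "depot"] <- 0   # ka applied below; events load the depot
  # venous blood
  venous_return <- setdiff(tissues, c("lung", "spleen", "gut"))
  for (t in venous_return) M["venous_blood", t] <- kout[[t]]
  M["venous_blood", "venous_blood"] <- -co_eff / V[["venous_blood"]]
  # lung in series
  M["lung", "venous_blood"] <- co_eff / V[["venous_blood"]]
  M["lung", "lung"] <- -kout[["lung"]]
  M["arterial_blood", "lung"] <- kout[["lung"]]
  # arterial blood feeds all systemic tissues (and the tumor, if attached)
  q_sys <- sum(systemic_flows(phys)) * 60
  M["arterial_blood", "arterial_blood"] <-
    -(q_sys + q_tumor_h) / V[["arterial_blood"]]
  for (t in setdiff(tissues, c("lung", "liver", "kidney"))) {
    M[t, "arterial_blood"] <- Qh[[t]] / V[["arterial_blood"]]
    M[t, t] <- -kout[[t]]
  }
  # kidney: perfusion plus glomerular filtration from arterial plasma
  M["kidney", "arterial_blood"] <-
    (Qh[["kidney"]] - clr_h / bp) / V[["arterial_blood"]]
  M["kidney", "kidney"] <- -kout[["kidney"]]
  M["elim_renal", "arterial_blood"] <- clr_h / bp / V[["arterial_blood"]]
  # liver: arterial + portal inflow, well-stirred elimination
  M["liver", "arterial_blood"] <- Qh[["liver_arterial"]] / V[["arterial_blood"]]
  M["liver", "spleen"] <- kout[["spleen"]]
  M["liver", "gut"] <- kout[["gut"]]
  kel_liver <- clint_h * fu_b * bp / (kp[["liver"]] * V[["liver"]])
  M["liver", "liver"] <- -(kout[["liver"]] + kel_liver)
  M["elim_hepatic", "liver"] <- kel_liver
  # spleen and gut drain into the portal vein, not the vena cava
  # (their columns in the venous row stay zero; handled above)

  if (!is.null(tumor)) {
    v_tv <- tumor$f_vascular * tumor$tumor_volume
    v_ec <- tumor$f_extracellular * tumor$tumor_volume
    v_ic <- tumor$f_intracellular * tumor$tumor_volume
    pscap_h <- tumor$ps_capillary * 60 * tumor$tumor_volume   # mL/h
    ps_h <- tumor$ps * 60 * tumor$tumor_volume
    eff_h <- tumor$cl_efflux * 60 * tumor$tumor_volume
    clt_h <- tumor$cl_tumor * 60 * tumor$tumor_volume
    fu <- cmp$fu_plasma

    M["tumor_vascular", "arterial_blood"] <- q_tumor_h / V[["arterial_blood"]]
    M["tumor_vascular", "tumor_vascular"] <-
      -q_tumor_h / v_tv - pscap_h * fu / (bp * v_tv)
    M["tumor_vascular", "tumor_ec"] <- pscap_h / v_ec
    M["venous_blood", "tumor_vascular"] <- q_tumor_h / v_tv
    M["tumor_ec", "tumor_vascular"] <- pscap_h * fu / (bp * v_tv)
    M["tumor_ec", "tumor_ec"] <- -pscap_h / v_ec - ps_h / v_ec
    M["tumor_ec", "tumor_ic"] <- ps_h / v_ic + eff_h / v_ic
    M["tumor_ic", "tumor_ec"] <- ps_h / v_ec
    M["tumor_ic", "tumor_ic"] <- -(ps_h + eff_h + clt_h) / v_ic
    M["elim_tumor", "tumor_ic"] <- clt_h / v_ic
  }
  M
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %d tissues%s\n", length(x$tissues),
              if (is.null(x$tumor)) "" else " + permeability-limited tumor"))
  cat(sprintf("  hepatic CLint,u %.4g mL/min, renal CL %.3g mL/min\n",
              x$clearances$hepatic_clint_u, x$clearances$renal_cl))
  invisible(x)
}

#' Simulate the PBPK model under a dosing regimen
#'
#' Integrates the linear whole-body system with `deSolve::lsoda`; doses
#' are handled as state discontinuities loading `fa * dose` into the depot
#' at `dose_time + lag_time`.
#'
#' @param model a `pbpk_model`.
#' @param regimen a `dose_regimen`.
#' @param t_grid output times, h; the event times are added internally.
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-10).
#' @return An object of class `pbpk_simulation` with elements `time` (h),
#'   `concentrations` (data.frame, ng/mL: `plasma`, `blood`, one column
#'   per tissue, and `tumor_total` when a tumor is attached), `amounts`
#'   (matrix, ng), `mass_balance_residual` (ng) and the regimen/model.
#' @export
simulate_pbpk <- function(model, regimen, t_grid, rtol = 1e-8,
                          atol = 1e-10) {
  stopifnot(inherits(model, "pbpk_model"), inherits(regimen, "dose_regimen"))
  M <- model$matrix
  states <- rownames(M)
  M["depot", "depot"] <- -regimen$ka
  M["venous_blood", "depot"] <- regimen$ka

  ev_times <- regimen$dose_times + regimen$lag_time
  dose_ng <- regimen$fa * regimen$dose_amount * 1e6
  if (max(t_grid) < max(ev_times)) {
    stop("t_grid must cover the dosing regimen")
  }
  times <- sort(unique(c(0, t_grid, ev_times)))
  events <- data.frame(var = "depot", time = ev_times, value = dose_ng,
                       method = "add")
  y0 <- stats::setNames(rep(0, length(states)), states)
  rhs <- function(t, y, p) list(p %*% y)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = M,
                      method = "lsoda", events = list(data = events),
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("PBPK integration failed near t = %.4g h",
                 max(out[, "time"])))
  }
  amounts <- out[, states, drop = FALSE]
  tt <- out[, "time"]

  V <- model$physiology$tissue_volumes
  bp <- model$compound$bp_ratio
  conc <- data.frame(time = tt)
  conc$blood <- amounts[, "venous_blood"] / V[["venous_blood"]]
  conc$plasma <- conc$blood / bp
  for (t in model$tissues) conc[[t]] <- amounts[, t] / V[[t]]
  if (!is.null(model$tumor)) {
    conc$tumor_total <- (amounts[, "tumor_vascular"] +
                           amounts[, "tumor_ec"] +
                           amounts[, "tumor_ic"]) / model$tumor$tumor_volume
  }
  # lsoda reports the pre-event state at an event instant, so a dose at
  # exactly t counts only for later output times
  doses_given <- vapply(tt, function(x) sum(ev_times < x - 1e-9), numeric(1))
  residual <- rowSums(amounts) - doses_given * dose_ng

  structure(list(time = tt, concentrations = conc, amounts = amounts,
                 mass_balance_residual = residual,
                 regimen = regimen, model = model),
            class = "pbpk_simulation")
}

#' @export
print.pbpk_simulation <- function(x, ...) {
  cat(sprintf("<pbpk_simulation> %d time points over %.4g h, %d outputs\n",
              length(x$time), max(x$time), ncol(x$concentrations) - 1L))
  cm <- cmax_tmax(x$time, x$concentrations$plasma)
  cat(sprintf("  plasma Cmax %.4g ng/mL at %.3g h\n", cm[["cmax"]],
              cm[["tmax"]]))
  invisible(x)
}

#' Interpolating concentration function from a simulation
#'
#' Returns a function of time (h) giving the named output concentration
#' (ng/mL), linearly interpolated from the simulation grid and held at 0
#' outside its support — the forcing-function form expected by
#' [simulate_tgi()].
#'
#' @param sim a `pbpk_simulation`.
#' @param output output column name (default `"plasma"`).
#' @return function(t_hours) -> ng/mL.
#' @export
as_profile_function <- function(sim, output = "plasma") {
  stopifnot(inherits(sim, "pbpk_simulation"))
  if (!output %in% names(sim$concentrations)) {
    stop("no such simulation output: ", output)
  }
  stats::approxfun(sim$time, sim$concentrations[[output]],
                   yleft = 0, yright = 0)
}

#' Tidy data frame of simulated concentrations
#'
#' @param sim a `pbpk_simulation`.
#' @return data.frame with columns `time`, `output`, `value`, `units`.
#' @export
simulation_as_data_frame <- function(sim) {
  stopifnot(inherits(sim, "pbpk_simulation"))
  conc <- sim$concentrations
  outputs <- setdiff(names(conc), "time")
  do.call(rbind, lapply(outputs, function(o) {
    data.frame(time = conc$time, output = o, value = conc[[o]],
               units = "ng/mL", stringsAsFactors = FALSE)
  }))
}
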