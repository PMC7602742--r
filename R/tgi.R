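#' Simeoni tumor-growth-inhibition parameters
#'
#' System parameters of the Simeoni model (exponential-to-linear growth
#' with shape factor) plus the Emax drug-effect parameters and the length
#' of the damaged-cell transit chain.  Presets for the two study cell
#' lines are available through [tgi_presets()].
#'
#' @param lambda0 first-order (exponential-phase) growth rate, 1/day.
#' @param lambda1 zero-order (linear-phase) growth rate, g/day.
#' @param psi shape factor of the exponential-to-linear switch (> 0).
#' @param w0 initial tumor mass, g.
#' @param n_transit number of damaged-cell transit compartments (1-8).
#' @param k1 transit rate of cell damage, 1/day.
#' @param kmax maximum kill rate, 1/day.
#' @param ic50 concentration at half-maximal kill, uM.
#' @param hill Hill coefficient of the Emax kill term.
#' @param drug_input which concentration drives the effect:
#'   `"total_plasma"` (study choice) or `"tumor_total"`.
#' @param tumor_density g/mL, for mass/volume interconversion.
#' @param molecular_weight g/mol, converts `ic50` to the ng/mL scale of
#'   the driving concentration.
#' @return An object of class `tgi_params`.
#' @export
tgi_params <- function(lambda0, lambda1, psi, w0, n_transit = 3,
                       k1 = 0, kmax = 0, ic50 = 1, hill = 1,
                       drug_input = c("total_plasma", "tumor_total"),
                       tumor_density = 1, molecular_weight = 338.414) {
  drug_input <- match.arg(drug_input)
  if (lambda0 < 0 || lambda1 < 0 || k1 < 0 || kmax < 0) {
    stop("rates must be non-negative")
  }
  if (psi <= 0) stop("psi must be positive")
  if (w0 <= 0) stop("w0 must be positive")
  if (ic50 <= 0) stop("ic50 must be positive")
  if (!(n_transit %in% 1:8)) stop("n_transit must be an integer in 1..8")
  if (tumor_density <= 0) stop("tumor_density must be positive")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, psi = psi, w0 = w0,
                 n_transit = as.integer(n_transit), k1 = k1, kmax = kmax,
                 ic50 = ic50, hill = hill, drug_input = drug_input,
                 tumor_density = tumor_density,
                 molecular_weight = molecular_weight),
            class = "tgi_params")
}

#' Study TGI parameter sets
#'
#' The final tumor-growth-inhibition parameters for the two xenograft
#' cell lines: HER2+ (MDA-MB-435; lambda0 0.2/day, lambda1 0.12 g/day,
#' psi 0.7, w0 0.1 mL, 3 transit compartments, k1 0.39/day, Kmax
#' 0.3683/day, IC50 0.0187 uM, H 0.5) and Triple Negative (MDA-MB-231;
#' lambda0 0.0393, lambda1 0.5457, psi 0.9985, w0 0.0384 mL, 4 transit
#' compartments, k1 0.0007, Kmax 0.0533, IC50 0.0001 uM, H 0.5).
#'
#' @param cell_line `"her2"` or `"tnbc"`.
#' @return a [tgi_params()] object.
#' @export
tgi_presets <- function(cell_line = c("her2", "tnbc")) {
  switch(match.arg(cell_line),
         her2 = tgi_params(lambda0 = 0.2, lambda1 = 0.12, psi = 0.7,
                           w0 = 0.1, n_transit = 3, k1 = 0.39,
                           kmax = 0.3683, ic50 = 0.0187, hill = 0.5),
         tnbc = tgi_params(lambda0 = 0.0393, lambda1 = 0.5457,
                           psi = 0.9985, w0 = 0.0384, n_transit = 4,
                           k1 = 0.0007, kmax = 0.0533, ic50 = 0.0001,
                           hill = 0.5))
}

#' @export
print.tgi_params <- function(x, ...) {
  cat(sprintf(
    "<tgi_params> lambda0 %.4g/d, lambda1 %.4g g/d, psi %.4g, w0 %.4g g\n",
    x$lambda0, x$lambda1, x$psi, x$w0))
  cat(sprintf(
    "  %d transit cpt, k1 %.4g/d; Emax: Kmax %.4g/d, IC50 %.4g uM, H %.3g (%s)\n",
    x$n_transit, x$k1, x$kmax, x$ic50, x$hill, x$drug_input))
  invisible(x)
}

#' Per-capita tumor growth rate
#'
#' `G(w) = lambda0 / (1 + (lambda0 * w / lambda1)^psi)^(1/psi)`:
#' exponential growth (`G -> lambda0`) for small masses, switching to a
#' zero-order phase (`G(w) * w -> lambda1`) for large masses, with
#' sharpness set by `psi`.
#'
#' @param w tumor mass, g (>= 0; vectorized).
#' @param params a `tgi_params`.
#' @return growth rate, 1/day.
#' @export
growth_rate_function <- function(w, params) {
  stopifnot(inherits(params, "tgi_params"))
  if (any(w < 0)) stop("tumor mass must be non-negative")
  params$lambda0 /
    (1 + (params$lambda0 * w / params$lambda1)^params$psi)^(1 / params$psi)
}

#' Emax kill rate from the driving concentration
#'
#' `k(C) = Kmax * C^H / (IC50^H + C^H)` with `IC50` converted from uM to
#' ng/mL via the molecular weight, so `C` is the plasma (or tumor)
#' concentration in ng/mL.  `k(IC50) = Kmax / 2` by construction.
#'
#' @param c_plasma driving concentration, ng/mL (vectorized).
#' @param params a `tgi_params`.
#' @return kill rate, 1/day.
#' @export
kill_rate <- function(c_plasma, params) {
  stopifnot(inherits(params, "tgi_params"))
  if (any(c_plasma < 0)) stop("concentration must be non-negative")
  ic50_ngml <- molar_to_mass_concentration(params$ic50,
                                           params$molecular_weight)
  ch <- c_plasma^params$hill
  params$kmax * ch / (ic50_ngml^params$hill + ch)
}

#' Net-effect ratio Kmax/IC50
#'
#' The compound's net effect on a cell line, the ratio of the maximal
#' kill rate to the potency, reported in 1/(uM day).
#'
#' @param params a `tgi_params`.
#' @return Kmax / IC50, 1/(uM day).
#' @export
net_effect_ratio <- function(params) {
  stopifnot(inherits(params, "tgi_params"))
  params$kmax / params$ic50
}

#' Simulate Simeoni tumor growth (unperturbed or perturbed)
#'
#' Integrates the proliferating compartment `x1` (growth `G(w) * x1`,
#' drug insult `k(C(t)) * x1`) and the transit chain of damaged cells
#' (`x2` fed by the insult; stages advance at `k1`; only the last stage
#' leaves the tumor mass).  Total mass `w = x1 + sum(damaged)` feeds back
#' into the growth rate.  A missing/`NULL` profile (or `kmax = 0`)
#' reproduces the unperturbed model exactly.
#'
#' @param params a `tgi_params`.
#' @param plasma_profile `NULL` for the unperturbed model, or a function
#'   of time in hours returning the driving concentration in ng/mL (e.g.
#'   from [as_profile_function()]).
#' @param duration days.
#' @param t_grid output times in days (default daily plus start/end).
#' @param hmax maximum integrator step, days; defaults to 0.02 when a
#'   profile is supplied so inter-dose concentration swings are resolved.
#' @return An object of class `tgi_simulation` with `time` (days),
#'   `weight` (g), `volume` (mL), `proliferating` (g) and
#'   `damaged_by_stage` (matrix, g).
#' @export
simulate_tgi <- function(params, plasma_profile = NULL, duration,
                         t_grid = NULL, hmax = NULL) {
  stopifnot(inherits(params, "tgi_params"))
  if (duration <= 0) stop("duration must be positive")
  if (is.null(t_grid)) t_grid <- seq(0, duration, by = 0.25)
  t_grid <- sort(unique(c(0, t_grid, duration)))
  cfun <- if (is.null(plasma_profile)) {
    function(t_h) 0
  } else {
    if (!is.function(plasma_profile)) {
      stop("plasma_profile must be NULL or a function of time in hours")
    }
    plasma_profile
  }
  if (is.null(hmax)) {
    hmax <- if (is.null(plasma_profile)) duration else 0.02
  }
  n <- params$n_transit
  y0 <- c(x1 = params$w0, stats::setNames(rep(0, n), paste0("x", 2:(n + 1))))
  rhs <- function(t, y, p) {
    w <- sum(y)
    g <- growth_rate_function(w, params)
    k <- kill_rate(max(cfun(t * 24), 0), params)
    d <- numeric(n + 1)
    d[1] <- g * y[1] - k * y[1]
    d[2] <- k * y[1] - params$k1 * y[2]
    if (n >= 2) {
      for (i in 3:(n + 1)) d[i] <- params$k1 * (y[i - 1] - y[i])
    }
    list(d)
  }
  out <- deSolve::ode(y = y0, times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", hmax = hmax,
                      rtol = 1e-8, atol = 1e-10)
  states <- out[, -1, drop = FALSE]
  if (any(states < -1e-6)) {
    warning("negative tumor state encountered; clamped to zero")
  }
  states[states < 0] <- 0
  weight <- rowSums(states)
  structure(list(time = out[, "time"], weight = weight,
                 volume = weight / params$tumor_density,
                 proliferating = states[, 1],
                 damaged_by_stage = states[, -1, drop = FALSE],
                 params = params),
            class = "tgi_simulation")
}

#' @export
print.tgi_simulation <- function(x, ...) {
  cat(sprintf(
    "<tgi_simulation> %.4g days; w0 %.4g g -> final %.4g g\n",
    max(x$time), x$weight[1], x$weight[length(x$weight)]))
  invisible(x)
}

#' Final tumor mass of a TGI simulation
#'
#' @param sim a `tgi_simulation`.
#' @return final tumor mass, g.
#' @export
final_tumor_weight <- function(sim) {
  stopifnot(inherits(sim, "tgi_simulation"))
  sim$weight[length(sim$weight)]
}

#' Relative reduction of final tumor size versus control
#'
#' `100 * (control - treated) / control`, in percent.
#'
#' @param treated_final final tumor size of the treated group (g or mL).
#' @param control_final final tumor size of the control group (same
#'   units, > 0).
#' @return percent reduction.
#' @export
relative_reduction <- function(treated_final, control_final) {
  if (control_final <= 0) stop("control_final must be positive")
  100 * (control_final - treated_final) / control_final
}
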