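#' Weighted least-squares objective
#'
#' Residual sum of squares per dataset, weighted by the reciprocal of the
#' square of that dataset's maximum observed value, summed across
#' datasets — the estimation objective of the study workflow.  The
#' weighting makes each dataset's contribution invariant to rescaling its
#' units.
#'
#' @param predicted named list of predicted series, one per dataset (same
#'   order or matched by name), each aligned with the dataset's times.
#' @param datasets list of datasets, each a list with `name`, `times`,
#'   `values`.
#' @return scalar objective value (>= 0).
#' @export
wls_objective <- function(predicted, datasets) {
  if (!length(datasets)) stop("at least one dataset is required")
  total <- 0
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (!length(d$values)) stop("empty dataset: ", d$name)
    p <- if (!is.null(names(predicted)) && !is.null(d$name) &&
             d$name %in% names(predicted)) predicted[[d$name]]
         else predicted[[i]]
    if (length(p) != length(d$values)) {
      stop("predicted series length mismatch for dataset ", d$name)
    }
    total <- total + sum((d$values - p)^2) / max(d$values)^2
  }
  total
}

#' Specification of an estimation problem
#'
#' @param free_parameters data.frame with columns `name`, `initial`,
#'   `lower`, `upper` and `transform` (`"linear"` or `"log"`).
#' @param datasets list of datasets (`name`, `times`, `values`).
#' @param termination relative objective-improvement threshold for
#'   convergence (default 0.01, i.e. stop when an update improves the
#'   objective by less than 1 percent).
#' @param max_iter maximum objective evaluations.
#' @return a `fit_spec` object.
#' @export
fit_spec <- function(free_parameters, datasets, termination = 0.01,
                     max_iter = 500L) {
  need <- c("name", "initial", "lower", "upper", "transform")
  if (!all(need %in% names(free_parameters))) {
    stop("free_parameters needs columns ", paste(need, collapse = ", "))
  }
  with(free_parameters, {
    if (any(initial < lower | initial > upper)) {
      stop("initial values must lie within their bounds")
    }
  })
  if (!length(datasets)) stop("datasets must be non-empty")
  structure(list(free_parameters = free_parameters, datasets = datasets,
                 termination = termination, max_iter = max_iter),
            class = "fit_spec")
}

#' Fit free parameters by Nelder-Mead weighted least squares
#'
#' Minimizes [wls_objective()] over the free parameters with the
#' Nelder-Mead simplex (standard reflection/expansion/contraction
#' coefficients), starting from the declared initial values,
#' log-transforming parameters so marked, and terminating when the
#' relative objective improvement drops below the spec's threshold.
#' Proposals outside the declared bounds are rejected by penalty, so the
#' estimates respect the bounds.
#'
#' @param spec a [fit_spec()].
#' @param model_factory function taking a named parameter vector and
#'   returning the predicted series for `spec$datasets` (a list in
#'   dataset order or named by dataset name).
#' @return An `estimation_result`: `estimates` (named vector), `ofv`,
#'   `n_evaluations`, `convergence_flag`.
#' @export
fit <- function(spec, model_factory) {
  stopifnot(inherits(spec, "fit_spec"))
  fp <- spec$free_parameters
  to_internal <- function(x) ifelse(fp$transform == "log", log(x), x)
  to_natural <- function(z) ifelse(fp$transform == "log", exp(z), z)
  objective <- function(z) {
    x <- to_natural(z)
    if (any(x < fp$lower | x > fp$upper)) return(1e10)
    pred <- model_factory(stats::setNames(x, fp$name))
    val <- wls_objective(pred, spec$datasets)
    if (!is.finite(val)) return(1e10)
    val
  }
  z0 <- to_internal(fp$initial)
  f0 <- objective(z0)
  if (f0 >= 1e10) stop("objective is not finite at the initial point")
  if (length(z0) == 1L) {
    # Nelder-Mead degenerates in 1-D; follow optim's advice and use Brent
    # within the (transformed) bounds.
    opt <- stats::optim(z0, objective, method = "Brent",
                        lower = to_internal(fp$lower),
                        upper = to_internal(fp$upper),
                        control = list(maxit = spec$max_iter))
  } else {
    opt <- stats::optim(z0, objective, method = "Nelder-Mead",
                        control = list(reltol = spec$termination,
                                       maxit = spec$max_iter))
  }
  est <- stats::setNames(to_natural(opt$par), fp$name)
  structure(list(estimates = est, ofv = opt$value,
                 n_evaluations = opt$counts[["function"]],
                 convergence_flag = opt$convergence == 0),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> ofv %.6g after %s evaluations (%s)\n",
              x$ofv, x$n_evaluations,
              if (x$convergence_flag) "converged" else "not converged"))
  print(signif(x$estimates, 5))
  invisible(x)
}

# Rebuild a PBPK model (and regimen) with one scalar parameter scaled by
# `factor`.  Returns list(model, regimen).
perturb_pbpk_parameter <- function(model, regimen, name, factor) {
  phys <- model$physiology
  cmp <- model$compound
  kp <- model$kpset
  cl <- model$clearances
  tum <- model$tumor
  compound_keys <- c("bp_ratio", "fu_plasma")
  clearance_keys <- c("renal_cl", "hepatic_clint_u")
  tumor_keys <- c("cl_tumor", "ps", "cl_efflux", "q_tumor", "ps_capillary")
  regimen_keys <- c("fa", "ka", "lag_time", "dose_amount")
  if (name %in% compound_keys) {
    cmp[[name]] <- cmp[[name]] * factor
  } else if (name %in% clearance_keys) {
    cl[[name]] <- cl[[name]] * factor
  } else if (name %in% tumor_keys) {
    if (is.null(tum)) stop("no tumor attached; cannot perturb ", name)
    tum[[name]] <- tum[[name]] * factor
  } else if (name %in% regimen_keys) {
    regimen[[name]] <- regimen[[name]] * factor
  } else {
    stop("unknown sensitivity parameter: ", name)
  }
  m <- build_pbpk_model(phys, cmp, kp, cl)
  if (!is.null(tum)) m <- attach_tumor(m, tum)
  list(model = m, regimen = regimen)
}

#' Local sensitivity analysis of plasma exposure
#'
#' Normalized local sensitivity coefficients
#' `(d metric / metric) / (d parameter / parameter)` of plasma `AUC_0-t`
#' and `Cmax` with respect to model (or regimen) scalars, by central
#' finite differences at +/- `perturbation`.
#'
#' @param model a `pbpk_model`.
#' @param regimen a `dose_regimen`.
#' @param parameters character vector of parameter names; supported:
#'   `bp_ratio`, `fu_plasma`, `renal_cl`, `hepatic_clint_u`, `cl_tumor`,
#'   `ps`, `cl_efflux`, `q_tumor`, `ps_capillary`, `fa`, `ka`,
#'   `lag_time`, `dose_amount`.
#' @param perturbation fractional perturbation in (0, 0.5] (default 0.2).
#' @param t_grid simulation grid, h.
#' @return a data.frame with one row per (parameter, metric):
#'   `parameter`, `perturbation`, `metric`, `coefficient`, `flagged`
#'   (TRUE when a perturbed simulation failed).
#' @export
local_sensitivity <- function(model, regimen, parameters,
                              perturbation = 0.2,
                              t_grid = seq(0, 12, by = 0.01)) {
  if (perturbation <= 0 || perturbation > 0.5) {
    stop("perturbation must lie in (0, 0.5]")
  }
  metric_values <- function(m, r) {
    sim <- simulate_pbpk(m, r, t_grid)
    c(auc_0_t = auc_trapezoid(sim$time, sim$concentrations$plasma),
      cmax = cmax_tmax(sim$time, sim$concentrations$plasma)[["cmax"]])
  }
  base <- metric_values(model, regimen)
  rows <- lapply(parameters, function(p) {
    res <- tryCatch({
      up <- perturb_pbpk_parameter(model, regimen, p, 1 + perturbation)
      dn <- perturb_pbpk_parameter(model, regimen, p, 1 - perturbation)
      m_up <- metric_values(up$model, up$regimen)
      m_dn <- metric_values(dn$model, dn$regimen)
      coefs <- (m_up - m_dn) / (2 * perturbation * base)
      data.frame(parameter = p, perturbation = perturbation,
                 metric = names(base), coefficient = unname(coefs),
                 flagged = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(parameter = p, perturbation = perturbation,
                 metric = names(base), coefficient = NA_real_,
                 flagged = TRUE, stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}
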