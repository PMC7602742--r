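#' Design of a destructive-sampling PK study
#'
#' Mirrors the tissue-distribution experiment: groups of mice are
#' sacrificed at each sampling time (destructive sampling, so every
#' record is an independent pseudo-animal with no within-animal
#' correlation).
#'
#' @param seed integer seed; stochastic generation is deterministic given
#'   the seed (required).
#' @param timepoints sampling times, h (default the study design 0.5, 1,
#'   3, 6, 9, 12, 24).
#' @param n_per_timepoint animals per time point (default 5).
#' @param outputs model outputs sampled (default `"plasma"`).
#' @param residual_model `"proportional_lognormal"` (default),
#'   `"additive"` or `"combined"`.
#' @param cv residual coefficient of variation (fraction).
#' @return a `pk_study_design` object.
#' @export
pk_study_design <- function(seed,
                            timepoints = c(0.5, 1, 3, 6, 9, 12, 24),
                            n_per_timepoint = 5L,
                            outputs = "plasma",
                            residual_model = c("proportional_lognormal",
                                               "additive", "combined"),
                            cv = 0.15) {
  if (missing(seed)) stop("an explicit integer `seed` is required")
  residual_model <- match.arg(residual_model)
  if (any(timepoints <= 0) || is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be positive and increasing")
  }
  if (n_per_timepoint < 1L) stop("n_per_timepoint must be >= 1")
  if (cv < 0) stop("cv must be non-negative")
  if (cv > 1 && residual_model != "additive") {
    warning("cv > 1 with a lognormal residual model is unusual")
  }
  structure(list(seed = as.integer(seed), timepoints = timepoints,
                 n_per_timepoint = as.integer(n_per_timepoint),
                 outputs = outputs, residual_model = residual_model,
                 cv = cv),
            class = "pk_study_design")
}

apply_residual <- function(truth, model, cv) {
  n <- length(truth)
  switch(model,
         proportional_lognormal = {
           sdlog <- sqrt(log1p(cv^2))
           truth * exp(stats::rnorm(n, 0, sdlog))
         },
         additive = truth + stats::rnorm(n, 0, cv * max(truth)),
         combined = {
           sdlog <- sqrt(log1p(cv^2))
           truth * exp(stats::rnorm(n, 0, sdlog)) +
             stats::rnorm(n, 0, cv * max(truth) / 10)
         })
}

#' Generate a synthetic destructive-sampling PK dataset
#'
#' Simulates the PBPK model, reads the true concentrations at the design
#' time points and draws `n_per_timepoint` independent noisy observations
#' per output and time point.  The simulated truth is stored alongside
#' each record for parameter-recovery testing.
#'
#' @param design a [pk_study_design()].
#' @param model a `pbpk_model`.
#' @param regimen a `dose_regimen`.
#' @return data.frame with columns `study`, `subject_id`, `group`,
#'   `output`, `time`, `time_unit`, `value`, `value_unit`, `truth`.
#' @export
generate_pk_dataset <- function(design, model, regimen) {
  stopifnot(inherits(design, "pk_study_design"),
            inherits(model, "pbpk_model"),
            inherits(regimen, "dose_regimen"))
  set.seed(design$seed)
  grid <- sort(unique(c(seq(0, max(design$timepoints), by = 0.01),
                        design$timepoints)))
  sim <- simulate_pbpk(model, regimen, grid)
  bad <- setdiff(design$outputs, names(sim$concentrations))
  if (length(bad)) {
    stop("design asks for outputs the model does not produce: ",
         paste(bad, collapse = ", "))
  }
  rows <- list()
  sid <- 0L
  for (out in design$outputs) {
    truth_at <- stats::approx(sim$time, sim$concentrations[[out]],
                              xout = design$timepoints)$y
    for (i in seq_along(design$timepoints)) {
      truth <- rep(truth_at[i], design$n_per_timepoint)
      value <- if (design$cv == 0) truth else
        apply_residual(truth, design$residual_model, design$cv)
      rows[[length(rows) + 1L]] <- data.frame(
        study = "pk", subject_id = sid + seq_along(truth),
        group = "single_dose", output = out,
        time = design$timepoints[i], time_unit = "h",
        value = value, value_unit = "ng/mL", truth = truth,
        stringsAsFactors = FALSE)
      sid <- sid + design$n_per_timepoint
    }
  }
  do.call(rbind, rows)
}

#' Design of a longitudinal tumor-growth study
#'
#' Mirrors the xenograft experiments: treatment groups of `n_per_group`
#' mice, imaged at baseline (day 1 of treatment) and weekly thereafter
#' until the study end.
#'
#' @param seed integer seed (required).
#' @param groups list of groups, each a list with `label`,
#'   `dose_mg_per_kg` (0 for vehicle) and `schedule` (a schedule name
#'   understood by [expand_regimen()]); a vehicle (dose 0) group must be
#'   present.
#' @param duration study duration, days (65 or 108 in the study).
#' @param n_per_group animals per group (default 10).
#' @param observation_interval days between imaging sessions (default 7).
#' @param residual_model,cv residual noise model on tumor volumes.
#' @param baseline_cv lognormal CV of the per-subject baseline (w0)
#'   jitter (default 0.1).
#' @return a `tgi_study_design` object.
#' @export
tgi_study_design <- function(seed,
                             groups = list(
                               list(label = "vehicle", dose_mg_per_kg = 0,
                                    schedule = "three_weekly"),
                               list(label = "10mgkg", dose_mg_per_kg = 10,
                                    schedule = "three_weekly")),
                             duration = 65,
                             n_per_group = 10L,
                             observation_interval = 7,
                             residual_model = "proportional_lognormal",
                             cv = 0.15,
                             baseline_cv = 0.1) {
  if (missing(seed)) stop("an explicit integer `seed` is required")
  if (duration <= 0) stop("duration must be positive")
  doses <- vapply(groups, function(g) g$dose_mg_per_kg, numeric(1))
  if (!any(doses == 0)) stop("a vehicle (dose 0) group must be present")
  structure(list(seed = as.integer(seed), groups = groups,
                 duration = duration, n_per_group = as.integer(n_per_group),
                 observation_interval = observation_interval,
                 residual_model = residual_model, cv = cv,
                 baseline_cv = baseline_cv),
            class = "tgi_study_design")
}

#' Imaging days of a tumor-growth design
#'
#' Day 1 of treatment (baseline) and every `observation_interval` days
#' thereafter, up to the study duration.
#'
#' @param design a `tgi_study_design`.
#' @return vector of study days.
#' @export
observation_days <- function(design) {
  stopifnot(inherits(design, "tgi_study_design"))
  seq(1, design$duration, by = design$observation_interval)
}

#' Generate a synthetic longitudinal tumor-growth dataset
#'
#' Per subject, the TGI truth (vehicle groups use the unperturbed model)
#' is simulated from a jittered baseline and observed weekly with
#' multiplicative residual noise.  Deterministic given the design seed.
#'
#' @param design a [tgi_study_design()].
#' @param tgi_params a [tgi_params()] object.
#' @param profile_factory `NULL` (all groups unperturbed) or a function
#'   `(dose_mg_per_kg, schedule, duration_days)` returning the plasma
#'   profile function (time in h -> ng/mL) for a treated group.
#' @return data.frame with columns `study`, `subject_id`, `group`,
#'   `output`, `time` (day), `time_unit`, `value` (tumor volume, mL),
#'   `value_unit`, `truth`.
#' @export
generate_tgi_dataset <- function(design, tgi_params,
                                 profile_factory = NULL) {
  stopifnot(inherits(design, "tgi_study_design"),
            inherits(tgi_params, "tgi_params"))
  set.seed(design$seed)
  days <- observation_days(design)
  t_grid <- days - 1   # model time 0 is treatment day 1
  rows <- list()
  sid <- 0L
  for (g in design$groups) {
    profile <- if (g$dose_mg_per_kg > 0 && !is.null(profile_factory)) {
      profile_factory(g$dose_mg_per_kg, g$schedule, design$duration)
    } else NULL
    base_factors <- if (design$baseline_cv > 0) {
      exp(stats::rnorm(design$n_per_group, 0,
                       sqrt(log1p(design$baseline_cv^2))))
    } else rep(1, design$n_per_group)
    group_sim <- NULL
    for (j in seq_len(design$n_per_group)) {
      sid <- sid + 1L
      if (base_factors[j] == 1) {
        if (is.null(group_sim)) {
          group_sim <- simulate_tgi(tgi_params, profile,
                                    duration = max(t_grid),
                                    t_grid = t_grid)
        }
        subj <- group_sim
      } else {
        p <- tgi_params
        p$w0 <- p$w0 * base_factors[j]
        subj <- simulate_tgi(p, profile, duration = max(t_grid),
                             t_grid = t_grid)
      }
      truth <- stats::approx(subj$time, subj$volume, xout = t_grid)$y
      value <- if (design$cv == 0) truth else
        apply_residual(truth, design$residual_model, design$cv)
      rows[[length(rows) + 1L]] <- data.frame(
        study = "tgi", subject_id = sid, group = g$label,
        output = "tumor", time = days, time_unit = "day",
        value = value, value_unit = "mL", truth = truth,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
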