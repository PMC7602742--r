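#' Area under the concentration-time curve (linear trapezoid)
#'
#' Linear trapezoidal AUC over the supplied points only; no extrapolation
#' to infinity.
#'
#' @param times sampling times, strictly increasing (h).
#' @param concentrations concentrations at `times` (>= 0, ng/mL).
#' @return AUC, ng h/mL.
#' @export
auc_trapezoid <- function(times, concentrations) {
  if (length(times) != length(concentrations)) {
    stop("times and concentrations must have the same length")
  }
  if (length(times) < 2L) stop("AUC needs at least two points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  pracma::trapz(times, concentrations)
}

#' Maximum concentration and its time
#'
#' First attainment breaks ties.
#'
#' @inheritParams auc_trapezoid
#' @return named vector `c(cmax =, tmax =)`.
#' @export
cmax_tmax <- function(times, concentrations) {
  if (!length(times) || length(times) != length(concentrations)) {
    stop("times and concentrations must be non-empty and equal length")
  }
  i <- which.max(concentrations)
  c(cmax = concentrations[i], tmax = times[i])
}

#' Terminal elimination half-life
#'
#' `ln(2) / |slope|` of the least-squares line of log concentration
#' against time over the last `n_terminal` points (which must lie after
#' Tmax and be positive).
#'
#' @inheritParams auc_trapezoid
#' @param n_terminal number of terminal points to regress on (>= 3).
#' @return half-life, h.
#' @export
terminal_half_life <- function(times, concentrations, n_terminal = 3L) {
  if (n_terminal < 3L) stop("n_terminal must be at least 3")
  if (length(times) < n_terminal) stop("not enough points")
  idx <- seq.int(length(times) - n_terminal + 1L, length(times))
  tmax <- cmax_tmax(times, concentrations)[["tmax"]]
  if (times[idx[1]] < tmax) {
    stop("terminal window must start after Tmax")
  }
  cc <- concentrations[idx]
  if (any(cc <= 0)) {
    stop("terminal concentrations must be positive for log regression")
  }
  slope <- unname(stats::coef(stats::lm(log(cc) ~ times[idx]))[2])
  if (slope >= 0) stop("terminal phase is not declining")
  log(2) / abs(slope)
}

#' Fold error of a predicted PK parameter
#'
#' The ratio predicted/observed; values in 0.8-1.2 are conventionally
#' treated as accurate predictions.
#'
#' @param predicted predicted value.
#' @param observed observed value (> 0).
#' @return predicted / observed.
#' @export
fold_error <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed value must be positive")
  predicted / observed
}

#' Percent relative error of predictions against observed means
#'
#' `100 * (pred - obs_mean) / obs_mean`, per time point; sign preserved
#' (under-prediction is negative).
#'
#' @param predicted predicted series.
#' @param observed_mean observed mean series, aligned with `predicted`
#'   (> 0 everywhere).
#' @return percent relative error series.
#' @export
relative_error_percent <- function(predicted, observed_mean) {
  if (length(predicted) != length(observed_mean)) {
    stop("series must be aligned")
  }
  if (any(observed_mean <= 0)) {
    stop("observed means must be positive everywhere")
  }
  100 * (predicted - observed_mean) / observed_mean
}

#' Mean and t-based 95 percent confidence interval per time point
#'
#' @param values list of replicate vectors, one per time point, or a
#'   data.frame with columns `time` and `value`.
#' @return data.frame with `time` (when supplied), `n`, `mean`, `lower`,
#'   `upper`; with a single replicate the bounds are `NA` and the row is
#'   flagged in `degenerate`.
#' @export
observed_ci95 <- function(values) {
  if (is.data.frame(values)) {
    split_vals <- split(values$value, values$time)
    times <- as.numeric(names(split_vals))
  } else {
    split_vals <- values
    times <- seq_along(values)
  }
  rows <- lapply(seq_along(split_vals), function(i) {
    v <- split_vals[[i]]
    n <- length(v)
    m <- mean(v)
    if (n >= 2L) {
      half <- stats::qt(0.975, df = n - 1L) * stats::sd(v) / sqrt(n)
      data.frame(time = times[i], n = n, mean = m, lower = m - half,
                 upper = m + half, degenerate = FALSE)
    } else {
      data.frame(time = times[i], n = n, mean = m, lower = NA_real_,
                 upper = NA_real_, degenerate = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Relative tumor growth normalized to baseline and vehicle
#'
#' Each subject's value at time t is divided by its own day-1 baseline,
#' then by the vehicle-group mean of the same ratio at t (the
#' fluorescence-imaging readout convention).
#'
#' @param data data.frame with columns `subject`, `group`, `time`,
#'   `value`; the baseline is the earliest time per subject.
#' @param vehicle_group label of the vehicle group in `group`.
#' @return `data` with an added `relative_growth` column.
#' @export
relative_tumor_growth <- function(data, vehicle_group = "vehicle") {
  need <- c("subject", "group", "time", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "))
  }
  if (!vehicle_group %in% data$group) {
    stop("vehicle group '", vehicle_group, "' not present in data")
  }
  data <- data[order(data$subject, data$time), ]
  baseline <- tapply(data$value, data$subject, function(v) v[1])
  if (any(baseline <= 0)) stop("baseline values must be positive")
  ratio <- data$value / as.numeric(baseline[as.character(data$subject)])
  veh <- data$group == vehicle_group
  veh_mean <- tapply(ratio[veh], data$time[veh], mean)
  key <- as.character(data$time)
  if (any(!key %in% names(veh_mean))) {
    stop("vehicle data missing at time(s): ",
         paste(unique(data$time[!key %in% names(veh_mean)]), collapse = ", "))
  }
  data$relative_growth <- ratio / as.numeric(veh_mean[key])
  data
}

#' Non-compartmental analysis of a simulated or observed profile
#'
#' @inheritParams auc_trapezoid
#' @param n_terminal points for the terminal half-life fit; `NA` skips
#'   the half-life.
#' @return An `nca_result` list: `auc_0_t`, `cmax`, `tmax`, `t_half`,
#'   `terminal_points_used`.
#' @export
nca <- function(times, concentrations, n_terminal = 3L) {
  cm <- cmax_tmax(times, concentrations)
  t_half <- if (is.na(n_terminal)) NA_real_ else
    terminal_half_life(times, concentrations, n_terminal)
  structure(list(auc_0_t = auc_trapezoid(times, concentrations),
                 cmax = cm[["cmax"]], tmax = cm[["tmax"]],
                 t_half = t_half,
                 terminal_points_used =
                   if (is.na(n_terminal)) 0L else as.integer(n_terminal)),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca_result> AUC0-t %.4g ng.h/mL, Cmax %.4g ng/mL at %.3g h, t1/2 %.3g h\n",
    x$auc_0_t, x$cmax, x$tmax, x$t_half))
  invisible(x)
}
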