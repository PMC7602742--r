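test_that("the weighted least-squares objective matches hand arithmetic", {
  ds <- list(list(name = "a", times = c(1, 2), values = c(10, 5)))
  expect_equal(wls_objective(list(a = c(10, 0)), ds), 0.25)
  expect_equal(wls_objective(list(a = c(10, 5)), ds), 0)
  # invariant under rescaling a dataset's units
  ds10 <- list(list(name = "a", times = c(1, 2), values = c(100, 50)))
  expect_equal(wls_objective(list(a = c(100, 0)), ds10), 0.25)
  expect_error(wls_objective(list(), list()), "at least one dataset")
})

test_that("growth parameters are recovered from a noise-free vehicle curve", {
  truth <- tgi_presets("her2")
  days <- seq(0, 64, by = 7)
  ctrl <- simulate_tgi(truth, NULL, 64, t_grid = days)
  ds <- list(list(name = "tumor", times = days,
                  values = stats::approx(ctrl$time, ctrl$volume,
                                         xout = days)$y))
  fp <- data.frame(name = c("lambda0", "lambda1", "psi"),
                   initial = c(0.15, 0.18, 1.0),
                   lower = c(0.01, 0.01, 0.2),
                   upper = c(1, 2, 3),
                   transform = "log")
  factory <- function(p) {
    pp <- truth
    pp$lambda0 <- p[["lambda0"]]; pp$lambda1 <- p[["lambda1"]]
    pp$psi <- p[["psi"]]
    s <- simulate_tgi(pp, NULL, 64, t_grid = days)
    list(tumor = stats::approx(s$time, s$volume, xout = days)$y)
  }
  res <- fit(fit_spec(fp, ds, termination = 1e-10, max_iter = 2000),
             factory)
  want <- c(lambda0 = 0.2, lambda1 = 0.12, psi = 0.7)
  expect_true(all(abs(res$estimates - want) / want < 0.01))
  expect_true(res$convergence_flag)
})

test_that("a perfect initial point is returned unchanged and bounds hold", {
  ds <- list(list(name = "y", times = 1:3, values = c(2, 4, 6)))
  fp <- data.frame(name = c("a", "b"), initial = c(2, 0),
                   lower = c(0, -1), upper = c(5, 1),
                   transform = "linear")
  factory <- function(p) list(y = p[["a"]] * (1:3) + p[["b"]])
  res <- fit(fit_spec(fp, ds), factory)
  expect_equal(unname(res$estimates), c(2, 0), tolerance = 1e-6)
  # optimum (a = 2) outside the box is pinned to the boundary region
  fp2 <- data.frame(name = c("a", "b"), initial = c(1, 0),
                    lower = c(0, -1), upper = c(1.5, 1),
                    transform = "linear")
  res2 <- fit(fit_spec(fp2, ds, termination = 1e-10, max_iter = 2000),
              factory)
  expect_lte(res2$estimates[["a"]], 1.5)
  # non-finite objective at the initial point is rejected
  bad_factory <- function(p) list(y = rep(NaN, 3))
  expect_error(fit(fit_spec(fp, ds), bad_factory), "initial point")
})

test_that("absorption parameters are recovered from noise-free plasma data", {
  model <- study_model()
  tp <- c(0.5, 1, 3, 6, 9, 12, 24)
  sim_at <- function(ka, lag) {
    r <- dose_regimen(0.2, 0, ka = ka, lag_time = lag)
    s <- simulate_pbpk(model, r, t_grid = tp)
    stats::approx(s$time, s$concentrations$plasma, xout = tp)$y
  }
  obs <- sim_at(3, 0.17)
  ds <- list(list(name = "plasma", times = tp, values = obs))
  fp <- data.frame(name = c("ka", "lag"), initial = c(1.5, 0.05),
                   lower = c(0.1, 0.001), upper = c(20, 1),
                   transform = "log")
  factory <- function(p) list(plasma = sim_at(p[["ka"]], p[["lag"]]))
  res <- fit(fit_spec(fp, ds, termination = 1e-9, max_iter = 400),
             factory)
  expect_equal(res$estimates[["ka"]], 3, tolerance = 0.01)
  expect_equal(res$estimates[["lag"]], 0.17, tolerance = 0.01)
})

test_that("sensitivity coefficients carry the expected structure", {
  model <- study_model_tumor()
  reg <- dose_regimen(0.2, 0)
  tab <- local_sensitivity(model, reg, c("fa", "renal_cl", "ps"),
                           t_grid = seq(0, 12, by = 0.02))
  expect_false(any(tab$flagged))
  fa_auc <- tab$coefficient[tab$parameter == "fa" &
                              tab$metric == "auc_0_t"]
  expect_equal(fa_auc, 1, tolerance = 1e-6)
  expect_lt(tab$coefficient[tab$parameter == "renal_cl" &
                              tab$metric == "auc_0_t"], 0)
  # tumor permeability barely feeds back on plasma
  expect_lt(abs(tab$coefficient[tab$parameter == "ps" &
                                  tab$metric == "auc_0_t"]), 0.01)
  expect_error(local_sensitivity(model, reg, "fa", perturbation = 0.7),
               "perturbation")
})
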