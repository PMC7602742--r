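#' Mouse system parameters for whole-body PBPK modelling
#'
#' The PBPK machinery consumes a `mouse_physiology` object holding tissue
#' volumes, regional blood flows, cardiac output, renal filtration and the
#' hepatic scaling physiology of a mouse of a given body weight.  Default
#' fractional volumes and flows are pinned from a standard rodent physiology
#' compilation shipped with the package (see
#' `system.file("extdata", "mouse_physiology.csv", package = "pbpktgi")`);
#' volumes scale linearly with body weight and flows linearly with cardiac
#' output.
#'
#' @param body_weight body weight in g (default 20, the typical study mouse).
#' @param overrides named list of parameter overrides applied after
#'   body-weight scaling.  Scalar keys: `cardiac_output`, `gfr`,
#'   `hematocrit`, `hepatocellularity`, `liver_weight`.  Map keys:
#'   `tissue_volumes`, `tissue_flows`, `tissue_density`, each a named list
#'   of per-tissue values.  When `cardiac_output` or individual
#'   `tissue_flows` are overridden, the remaining (non-overridden) systemic
#'   flows are rescaled so that they still sum to cardiac output.
#'
#' @return An object of class `mouse_physiology`: a list with elements
#'   `body_weight` (g), `cardiac_output` (mL/min), `tissue_volumes` (mL,
#'   including `arterial_blood`, `venous_blood` and `plasma`),
#'   `tissue_flows` (mL/min; liver inflow split into `liver_arterial` and
#'   `liver_portal`, the latter equal to spleen + gut outflow), `gfr`
#'   (mL/min), `liver_weight` (g), `hepatocellularity` (10^6 cells/g),
#'   `tissue_density` (g/mL, including `tumor`) and `hematocrit`.
#'
#' @details The defaults put renal clearance physiology (glomerular
#'   filtration rate) at 0.015 mL/min/g, i.e. 0.3 mL/min for a 20 g mouse,
#'   hematocrit at 0.45 and hepatocellularity at 135e6 cells per g liver.
#'   Liver weight defaults to liver volume times liver density.
#'
#' @examples
#' phys <- build_mouse_physiology(20)
#' phys$gfr                              # 0.3 mL/min
#' sum(systemic_flows(phys))             # equals cardiac output
#' @export
build_mouse_physiology <- function(body_weight = 20, overrides = list()) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("`body_weight` must be a single positive number (g)")
  }
  tab <- physiology_reference_table()

  known_scalar <- c("cardiac_output", "gfr", "hematocrit",
                    "hepatocellularity", "liver_weight")
  known_map <- c("tissue_volumes", "tissue_flows", "tissue_density")
  bad <- setdiff(names(overrides), c(known_scalar, known_map))
  if (length(bad)) {
    stop("unknown physiology override key(s): ", paste(bad, collapse = ", "))
  }

  co <- 0.4 * body_weight        # mL/min; 8 mL/min at 20 g
  gfr <- 0.015 * body_weight     # mL/min; 0.3 mL/min at 20 g
  hct <- 0.45
  hepatocellularity <- 135       # 10^6 cells / g liver

  volumes <- stats::setNames(tab$volume_frac * body_weight, tab$tissue)
  density <- stats::setNames(tab$density, tab$tissue)
  density["tumor"] <- 1.0

  if (!is.null(overrides$cardiac_output)) co <- overrides$cardiac_output
  if (!is.null(overrides$gfr)) gfr <- overrides$gfr
  if (!is.null(overrides$hematocrit)) hct <- overrides$hematocrit
  if (!is.null(overrides$hepatocellularity)) {
    hepatocellularity <- overrides$hepatocellularity
  }
  for (key in c("tissue_volumes", "tissue_density")) {
    if (!is.null(overrides[[key]])) {
      ov <- unlist(overrides[[key]])
      target <- if (key == "tissue_volumes") volumes else density
      bad <- setdiff(names(ov), names(target))
      if (length(bad)) {
        stop("unknown tissue in `", key, "` override: ",
             paste(bad, collapse = ", "))
      }
      target[names(ov)] <- ov
      if (key == "tissue_volumes") volumes <- target else density <- target
    }
  }
  if (co <= 0 || gfr <= 0 || hepatocellularity <= 0) {
    stop("cardiac_output, gfr and hepatocellularity must be positive")
  }
  if (hct <= 0 || hct >= 1) stop("hematocrit must lie in (0, 1)")
  if (any(volumes <= 0)) stop("all tissue volumes must be positive")
  if (any(density <= 0)) stop("all tissue densities must be positive")

  # Systemic arterial distribution (everything except lung, which carries
  # the full cardiac output).  Portal inflow to the liver is derived as
  # spleen + gut venous outflow, never set directly.
  sys_tissues <- tab$tissue[!is.na(tab$flow_frac)]
  flow_frac <- stats::setNames(tab$flow_frac[!is.na(tab$flow_frac)],
                               sys_tissues)
  names(flow_frac)[names(flow_frac) == "liver"] <- "liver_arterial"
  flows <- flow_frac * co

  if (!is.null(overrides$tissue_flows)) {
    ov <- unlist(overrides$tissue_flows)
    bad <- setdiff(names(ov), names(flows))
    if (length(bad)) {
      stop("unknown tissue in `tissue_flows` override: ",
           paste(bad, collapse = ", "),
           " (liver inflow keys are 'liver_arterial'; portal flow is",
           " derived from spleen + gut)")
    }
    if (any(ov <= 0)) stop("overridden tissue flows must be positive")
    flows[names(ov)] <- ov
    fixed <- names(ov)
  } else {
    fixed <- character(0)
  }
  # Renormalise non-overridden systemic flows to conserve cardiac output.
  free <- setdiff(names(flows), fixed)
  residual <- co - sum(flows[fixed])
  if (residual <= 0 && length(free)) {
    stop("overridden flows exceed cardiac output; nothing left for ",
         paste(free, collapse = ", "))
  }
  if (length(free)) flows[free] <- flows[free] * residual / sum(flows[free])

  flows <- c(lung = unname(co), flows,
             liver_portal = unname(flows[["spleen"]] + flows[["gut"]]))

  blood <- volumes[["arterial_blood"]] + volumes[["venous_blood"]]
  volumes["plasma"] <- (1 - hct) * blood

  liver_weight <- volumes[["liver"]] * density[["liver"]]
  if (!is.null(overrides$liver_weight)) liver_weight <- overrides$liver_weight
  if (liver_weight <= 0) stop("liver_weight must be positive")

  phys <- structure(
    list(body_weight = body_weight,
         cardiac_output = co,
         tissue_volumes = volumes,
         tissue_flows = flows,
         gfr = gfr,
         liver_weight = liver_weight,
         hepatocellularity = hepatocellularity,
         tissue_density = density,
         hematocrit = hct),
    class = "mouse_physiology")
  validate_physiology(phys)
  phys
}

#' Systemic tissue flows of a physiology object
#'
#' Returns the arterial distribution flows that must sum to cardiac output:
#' every systemic tissue (hepatic artery for the liver), excluding the lung
#' (which carries full cardiac output) and the derived portal inflow.
#'
#' @param phys a `mouse_physiology` object.
#' @return named numeric vector of flows (mL/min).
#' @export
systemic_flows <- function(phys) {
  stopifnot(inherits(phys, "mouse_physiology"))
  fl <- phys$tissue_flows
  fl[setdiff(names(fl), c("lung", "liver_portal"))]
}

validate_physiology <- function(phys) {
  fl <- phys$tissue_flows
  if (any(phys$tissue_volumes <= 0) || any(fl <= 0)) {
    stop("physiology volumes and flows must all be positive")
  }
  if (abs(sum(systemic_flows(phys)) - phys$cardiac_output) >
      1e-6 * phys$cardiac_output) {
    stop("systemic tissue flows do not sum to cardiac output")
  }
  if (abs(fl[["lung"]] - phys$cardiac_output) > 1e-9 * phys$cardiac_output) {
    stop("lung flow must equal cardiac output")
  }
  if (abs(fl[["liver_portal"]] - (fl[["spleen"]] + fl[["gut"]])) >
      1e-9 * phys$cardiac_output) {
    stop("portal inflow must equal spleen + gut outflow")
  }
  invisible(phys)
}

physiology_reference_table <- function() {
  path <- system.file("extdata", "mouse_physiology.csv", package = "pbpktgi")
  if (path == "") {  # during development, before installation
    path <- file.path("inst", "extdata", "mouse_physiology.csv")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Whole-liver unbound intrinsic clearance from hepatocyte data
#'
#' Scales an in vitro hepatocyte intrinsic clearance (uL/min per 10^6
#' cells) to the unbound whole-liver intrinsic clearance in mL/min, using
#' hepatocellularity and liver weight, and correcting for nonspecific
#' binding in the incubation via `fu_inc`:
#' `(clint / fu_inc) * hepatocellularity * liver_weight / 1000`.
#'
#' @param clint_per_million_cells in vitro intrinsic clearance,
#'   uL/min/10^6 cells.
#' @param fu_inc unbound fraction in the incubation, in (0, 1].
#' @param hepatocellularity 10^6 cells per g liver.
#' @param liver_weight liver weight, g.
#' @return unbound whole-liver intrinsic clearance, mL/min.
#' @examples
#' whole_liver_unbound_clint(79, 0.07, 135, 1.0)  # 152.36 mL/min
#' @export
whole_liver_unbound_clint <- function(clint_per_million_cells, fu_inc,
                                      hepatocellularity, liver_weight) {
  if (fu_inc <= 0) stop("`fu_inc` must be positive (division by zero)")
  if (fu_inc > 1) stop("`fu_inc` is a fraction and cannot exceed 1")
  if (clint_per_million_cells <= 0 || hepatocellularity <= 0 ||
      liver_weight <= 0) {
    stop("all clearance-scaling arguments must be positive")
  }
  (clint_per_million_cells / fu_inc) * hepatocellularity * liver_weight / 1000
}

#' @export
print.mouse_physiology <- function(x, ...) {
  cat(sprintf("<mouse_physiology> body weight %.3g g\n", x$body_weight))
  cat(sprintf("  cardiac output %.3g mL/min, GFR %.3g mL/min, Hct %.2f\n",
              x$cardiac_output, x$gfr, x$hematocrit))
  cat(sprintf("  liver %.3g g at %.0fe6 cells/g\n",
              x$liver_weight, x$hepatocellularity))
  cat(sprintf("  %d tissue volumes, %d flows\n",
              length(x$tissue_volumes), length(x$tissue_flows)))
  invisible(x)
}
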