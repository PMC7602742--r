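#' Compound physicochemistry and binding parameters
#'
#' Bundles the physicochemical and binding properties a PBPK model needs.
#' Defaults are the MBQ-167 values: MW 338.414 g/mol, logP(octanol:water)
#' 4.944, monoprotic base with pKa 0.27 (effectively un-ionized at
#' physiological pH), plasma unbound fraction 0.02, blood-to-plasma ratio
#' 1.8 and in vitro incubation unbound fraction 0.07.
#'
#' @param molecular_weight g/mol.
#' @param logP log10 octanol:water partition coefficient.
#' @param compound_type one of `"monoprotic_base"`, `"monoprotic_acid"`,
#'   `"neutral"`.
#' @param pKa acid dissociation constant (ignored for `"neutral"`).
#' @param fu_plasma unbound fraction in plasma, in (0, 1].
#' @param bp_ratio blood-to-plasma concentration ratio (> 0).
#' @param fu_inc unbound fraction in the in vitro hepatocyte incubation.
#' @return An object of class `compound_params`.
#' @examples
#' mbq <- compound_params()        # MBQ-167
#' mbq$molecular_weight
#' @export
compound_params <- function(molecular_weight = 338.414,
                            logP = 4.944,
                            compound_type = c("monoprotic_base",
                                              "monoprotic_acid", "neutral"),
                            pKa = 0.27,
                            fu_plasma = 0.02,
                            bp_ratio = 1.8,
                            fu_inc = 0.07) {
  compound_type <- match.arg(compound_type)
  if (molecular_weight <= 0) stop("molecular_weight must be positive")
  if (fu_plasma <= 0 || fu_plasma > 1) stop("fu_plasma must lie in (0, 1]")
  if (bp_ratio <= 0) stop("bp_ratio must be positive")
  if (fu_inc <= 0 || fu_inc > 1) stop("fu_inc must lie in (0, 1]")
  structure(list(molecular_weight = molecular_weight, logP = logP,
                 compound_type = compound_type, pKa = pKa,
                 fu_plasma = fu_plasma, bp_ratio = bp_ratio,
                 fu_inc = fu_inc),
            class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf("<compound_params> MW %.3f g/mol, logP %.3f, %s (pKa %.2f)\n",
              x$molecular_weight, x$logP, x$compound_type, x$pKa))
  cat(sprintf("  fu,plasma %.3g  B/P %.3g  fu,inc %.3g\n",
              x$fu_plasma, x$bp_ratio, x$fu_inc))
  invisible(x)
}

#' Tissue composition table for partition-coefficient prediction
#'
#' Fractional tissue water (extra-/intracellular), neutral lipid and
#' neutral phospholipid content, acidic phospholipid concentration and
#' tissue-to-plasma albumin ratio, pinned from the published
#' Rodgers-Rowland rat composition compilation (the standard surrogate for
#' mouse tissues) and shipped as a CSV data asset.
#'
#' @return data.frame with columns `tissue`, `f_ew`, `f_iw`, `f_nl`,
#'   `f_npl`, `ap_mg_g`, `albumin_ratio`; includes a `plasma` row used for
#'   the plasma-side binding balance.
#' @export
tissue_composition <- function() {
  path <- system.file("extdata", "tissue_composition.csv",
                      package = "pbpktgi")
  if (path == "") path <- file.path("inst", "extdata",
                                    "tissue_composition.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Ionized fraction by Henderson-Hasselbalch
#'
#' @param pKa acid dissociation constant.
#' @param pH medium pH.
#' @param type `"monoprotic_base"`, `"monoprotic_acid"` or `"neutral"`.
#' @return fraction of molecules carrying charge at the given pH.
#' @examples
#' fraction_ionized(0.27, 7.4, "monoprotic_base")  # ~7.4e-8
#' @export
fraction_ionized <- function(pKa, pH, type = "monoprotic_base") {
  z <- ionization_ratio(pKa, pH, type)
  z / (1 + z)
}

# ionized:neutral concentration ratio at a given pH
ionization_ratio <- function(pKa, pH, type) {
  switch(type,
         monoprotic_base = 10^(pKa - pH),
         monoprotic_acid = 10^(pH - pKa),
         neutral = 0,
         stop("unknown compound type: ", type))
}

#' Predict tissue:plasma partition coefficients (Rodgers-Rowland method 2)
#'
#' Mechanistic prediction of total tissue to total plasma partition
#' coefficients from tissue composition: the neutral species partitions
#' into tissue water, neutral lipid (scaled by P = 10^logP; vegetable
#' oil:water for adipose) and neutral phospholipid (0.3P + 0.7); ionized
#' species of moderate-to-strong bases (pKa >= 7) additionally bind acidic
#' phospholipids with an association constant back-calculated from the
#' blood-to-plasma ratio, while acids, neutrals and weak bases bind
#' albumin-class proteins with an association constant back-calculated
#' from the plasma unbound fraction (clamped at zero when plasma lipid
#' partitioning alone accounts for the observed binding).  Unbound
#' partition coefficients are converted to total with `fu_plasma`.
#'
#' @param compound a [compound_params()] object.
#' @param composition composition table as from [tissue_composition()].
#' @param tissues tissues to predict; default all non-plasma rows of the
#'   composition table.  A requested tissue missing from the table is an
#'   error naming the tissue.
#' @param ph_iw,ph_plasma,ph_bc intracellular, plasma and blood-cell pH.
#' @param hematocrit hematocrit used for the blood-cell association route.
#' @return named numeric vector of Kp (tissue:plasma, unitless).
#' @export
predict_kp_method2 <- function(compound,
                               composition = tissue_composition(),
                               tissues = NULL,
                               ph_iw = 7.0, ph_plasma = 7.4, ph_bc = 7.22,
                               hematocrit = 0.45) {
  stopifnot(inherits(compound, "compound_params"))
  rows <- composition[composition$tissue != "plasma", , drop = FALSE]
  if (is.null(tissues)) tissues <- rows$tissue
  missing <- setdiff(tissues, rows$tissue)
  if (length(missing)) {
    stop("no tissue composition available for: ",
         paste(missing, collapse = ", "))
  }
  plasma <- composition[composition$tissue == "plasma", , drop = FALSE]
  if (nrow(plasma) != 1L) stop("composition table must contain a plasma row")

  P <- 10^compound$logP
  P_adipose <- 10^(1.115 * compound$logP - 1.35)  # vegetable oil:water
  type <- compound$compound_type
  Y <- ionization_ratio(compound$pKa, ph_plasma, type)
  X_iw <- ionization_ratio(compound$pKa, ph_iw, type)

  strong_base <- identical(type, "monoprotic_base") && compound$pKa >= 7
  if (strong_base) {
    # Association to acidic phospholipids, back-calculated from B/P via the
    # blood-cell partition coefficient (pinned blood-cell composition).
    f_iw_bc <- 0.603; f_nl_bc <- 0.0017; f_npl_bc <- 0.0029; ap_bc <- 0.5
    X_bc <- ionization_ratio(compound$pKa, ph_bc, type)
    kpu_bc <- (compound$bp_ratio - (1 - hematocrit)) / hematocrit /
      compound$fu_plasma
    ka_ap <- (kpu_bc -
                f_iw_bc * (1 + X_bc) / (1 + Y) -
                (P * f_nl_bc + (0.3 * P + 0.7) * f_npl_bc) / (1 + Y)) *
      (1 + Y) / (ap_bc * X_bc)
    ka_ap <- max(ka_ap, 0)
  } else {
    # Albumin-class binding from the plasma-side mass balance.
    lipid_p <- (P * plasma$f_nl + (0.3 * P + 0.7) * plasma$f_npl) / (1 + Y)
    ka_pr <- max((1 / compound$fu_plasma - 1 - lipid_p), 0)
  }

  kp <- vapply(tissues, function(tt) {
    r <- rows[rows$tissue == tt, ]
    Pt <- if (tt == "adipose") P_adipose else P
    kpu <- r$f_ew +
      r$f_iw * (1 + X_iw) / (1 + Y) +
      (Pt * r$f_nl + (0.3 * Pt + 0.7) * r$f_npl) / (1 + Y)
    kpu <- kpu + if (strong_base) {
      ka_ap * r$ap_mg_g * X_iw / (1 + Y)
    } else {
      ka_pr * r$albumin_ratio
    }
    kpu * compound$fu_plasma
  }, numeric(1))
  stats::setNames(kp, tissues)
}

#' The optimized MBQ-167 partition coefficients
#'
#' Tissue:plasma partition coefficients for heart, kidney, liver, lung and
#' spleen that were optimized against observed tissue concentration data;
#' used verbatim (not scaled) when assembling the final Kp set.
#'
#' @return named numeric vector.
#' @export
mbq167_kp_overrides <- function() {
  c(heart = 1, kidney = 13.94, liver = 14.66, lung = 1.9, spleen = 2.1)
}

#' Assemble the final partition-coefficient set
#'
#' Overridden tissues take the supplied (optimized) value verbatim; every
#' remaining tissue takes its mechanistic prediction multiplied by the
#' global Kp scalar.
#'
#' @param predicted named vector of predicted Kp values covering all model
#'   tissues.
#' @param overrides named vector of optimized Kp values (subset of the
#'   predicted tissues), applied verbatim.
#' @param scalar unitless multiplier applied to the predicted entries
#'   (default 0.29, the optimized study value).
#' @return An object of class `kp_set` with elements `kp` (named vector),
#'   `scalar` and `provenance` (per tissue, `"optimized"` or
#'   `"predicted_scaled"`).
#' @export
assemble_final_kpset <- function(predicted, overrides = numeric(0),
                                 scalar = 0.29) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(predicted))
    if (length(bad)) {
      stop("override for tissue(s) absent from the predicted set: ",
           paste(bad, collapse = ", "))
    }
    if (any(overrides <= 0)) stop("Kp overrides must be positive")
  }
  if (scalar <= 0) stop("Kp scalar must be positive")
  kp <- predicted * scalar
  provenance <- stats::setNames(rep("predicted_scaled", length(kp)),
                                names(kp))
  kp[names(overrides)] <- overrides
  provenance[names(overrides)] <- "optimized"
  structure(list(kp = kp, scalar = scalar, provenance = provenance),
            class = "kp_set")
}

#' @export
print.kp_set <- function(x, ...) {
  cat(sprintf("<kp_set> %d tissues, scalar %.3g (%d optimized)\n",
              length(x$kp), x$scalar, sum(x$provenance == "optimized")))
  print(round(x$kp, 3))
  invisible(x)
}

#' Export a Kp set as a data frame
#'
#' @param kpset a `kp_set`.
#' @return data.frame with columns `tissue`, `kp`, `provenance`.
#' @export
kpset_as_data_frame <- function(kpset) {
  stopifnot(inherits(kpset, "kp_set"))
  data.frame(tissue = names(kpset$kp), kp = unname(kpset$kp),
             provenance = unname(kpset$provenance),
             stringsAsFactors = FALSE)
}

#' Steady-state volume of distribution
#'
#' Plasma-referenced Vss: `[V_plasma + V_ery * E:P + sum(Kp_t * V_t)] /
#' body_weight`, with the erythrocyte-to-plasma ratio derived from the
#' blood-to-plasma ratio and hematocrit, `E:P = (B/P - (1 - Hct)) / Hct`.
#' mL/g is reported as L/kg.
#'
#' @param kpset a `kp_set` covering every tissue with a volume.
#' @param phys a `mouse_physiology`.
#' @param compound a `compound_params` (for B/P).
#' @return Vss in L/kg.
#' @export
compute_vss <- function(kpset, phys, compound) {
  stopifnot(inherits(kpset, "kp_set"), inherits(phys, "mouse_physiology"),
            inherits(compound, "compound_params"))
  vols <- phys$tissue_volumes
  tissues <- setdiff(names(vols),
                     c("arterial_blood", "venous_blood", "plasma"))
  missing <- setdiff(tissues, names(kpset$kp))
  if (length(missing)) {
    stop("kp set is missing tissue(s) with volumes: ",
         paste(missing, collapse = ", "))
  }
  blood <- vols[["arterial_blood"]] + vols[["venous_blood"]]
  v_ery <- phys$hematocrit * blood
  ep <- (compound$bp_ratio - (1 - phys$hematocrit)) / phys$hematocrit
  (vols[["plasma"]] + v_ery * ep +
     sum(kpset$kp[tissues] * vols[tissues])) / phys$body_weight
}

#' Convert a molar concentration to a mass concentration
#'
#' uM times g/mol equals ng/mL, the plasma concentration unit used
#' throughout the PK side of the package.
#'
#' @param value concentration in uM (>= 0).
#' @param molecular_weight g/mol.
#' @return concentration in ng/mL.
#' @examples
#' molar_to_mass_concentration(0.0187, 338.414)  # HER2+ IC50 in ng/mL
#' @export
molar_to_mass_concentration <- function(value, molecular_weight) {
  if (any(value < 0)) stop("molar concentration must be non-negative")
  if (molecular_weight <= 0) stop("molecular_weight must be positive")
  value * molecular_weight
}
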