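# Shared fixtures, built once per test run.  Everything is generated in
# code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

study_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_study_model()
  .fixtures$model
}

study_model_tumor <- function() {
  if (is.null(.fixtures$model_tumor)) {
    .fixtures$model_tumor <- build_study_model(with_tumor = TRUE)
  }
  .fixtures$model_tumor
}

# dense single-dose (10 mg/kg, 20 g) simulation reused across tests
single_dose_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_pbpk(study_model(), dose_regimen(0.2, 0),
                                   t_grid = seq(0, 24, by = 0.005))
  }
  .fixtures$sim
}

# Independent straightforward transcription of the Rodgers-Rowland
# partitioning equations, used as the oracle for predict_kp_method2.
# Deliberately written from the equations, not from the package code.
oracle_kp <- function(compound, comp_table) {
  P <- 10^compound$logP
  ratio <- function(pH) {
    switch(compound$compound_type,
           monoprotic_base = 10^(compound$pKa - pH),
           monoprotic_acid = 10^(pH - compound$pKa),
           neutral = 0)
  }
  Y <- ratio(7.4); X <- ratio(7.0)
  pl <- comp_table[comp_table$tissue == "plasma", ]
  lipid_p <- (P * pl$f_nl + (0.3 * P + 0.7) * pl$f_npl) / (1 + Y)
  ka_pr <- max(1 / compound$fu_plasma - 1 - lipid_p, 0)
  rows <- comp_table[comp_table$tissue != "plasma", ]
  out <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    Pt <- if (r$tissue == "adipose") 10^(1.115 * compound$logP - 1.35) else P
    kpu <- r$f_ew + r$f_iw * (1 + X) / (1 + Y) +
      (Pt * r$f_nl + (0.3 * Pt + 0.7) * r$f_npl) / (1 + Y) +
      ka_pr * r$albumin_ratio
    out[i] <- kpu * compound$fu_plasma
  }
  stats::setNames(out, rows$tissue)
}

# Closed-form exposure constants used in several checks
total_plasma_cl <- function(model) {
  q_liver <- model$physiology$tissue_flows[["liver_arterial"]] +
    model$physiology$tissue_flows[["liver_portal"]]
  hepatic_clearance_well_stirred(
    q_liver,
    model$compound$fu_plasma / model$compound$bp_ratio,
    model$clearances$hepatic_clint_u,
    model$compound$bp_ratio) + model$clearances$renal_cl
}
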