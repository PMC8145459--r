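# shared fixtures built in code

adult <- reference_adult()

no_var <- variability_config(0, 0, 0, truncation_sd = 2.5)

# a subject with a prescribed total clearance for a renal-only minimal drug:
# total_cl = cl_renal_adult x gfr / 121, so setting gfr fixes CL
probe_minimal_drug <- function(cl_renal = 2, vss = 0.5) {
  drug_model(name = "probe", mw_g_mol = 100, log_p = 0,
             compound_type = "neutral", bp_ratio = 1, fu_plasma = 1,
             distribution = "minimal", cl_renal_adult_L_h = cl_renal,
             vss_L_kg = vss)
}

subject_with_cl <- function(cl_L_h, drug, age = 5, sex = "male") {
  s <- mean_subject(age, sex)
  s$gfr_mL_min <- cl_L_h / drug$cl_renal_adult_L_h * 121
  s
}

# inert full-model compound (no clearance) for conservation checks
inert_full_drug <- function(bp = 0.8) {
  drug_model(name = "inert", mw_g_mol = 100, log_p = 0,
             compound_type = "neutral", bp_ratio = bp, fu_plasma = 1,
             distribution = "full_perfusion_limited",
             cl_renal_adult_L_h = 0, vss_L_kg = 1)
}

# kp set with unit tissue:blood partitioning (Kp = BP for every tissue)
unit_kb_kpset <- function(bp = 0.8) {
  tis <- setdiff(names(adult$organ_volumes_L), "blood")
  structure(list(kp = setNames(rep(bp, length(tis)), tis),
                 scalar_lambda = 1, bp_ratio = bp),
            class = "kp_set")
}
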