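# Shared fixtures: everything is generated in code at test time.

# small default cohort reused across tests
small_cohort <- function(n = 300, seed = 11) {
  generate_cohort(n, gen_params(), seed = seed)
}

# amputed version with the default calibrated MAR mechanism
small_amputed <- function(n = 300, seed = 11, mar_seed = 12) {
  coh <- small_cohort(n, seed)
  apply_mar(coh, calibrate_intercepts(coh), seed = mar_seed)
}

# a degenerate parameter set: no noise anywhere, all slopes zero
noiseless_params <- function() {
  gen_params(age_intercept_var = 0, age_noise_var = 0,
             famstruc_coefs = c(intercept = -30, ageyr = 0, language = 0,
                                moedu = 0),
             famstruc_ri_var = 0,
             sep_coefs = c(intercept = 0, moedu = 0, famstruc = 0),
             sep_resid_var = 0,
             bmiz_coefs = c(intercept = 0, ageyr = 0, sex = 0, famstruc = 0),
             bmiz_ri_var = 0, bmiz_resid_var = 0,
             qolz_coefs = c(intercept = -0.04, sex = 0, ageyr = 0, bmiz = 0,
                            famstruc = 0, language = 0, sep = 0),
             qolz_ri_var = 0, qolz_resid_var = 0)
}

# fast iteration controls for engine smoke/property tests
fast_config <- function(method, m = 2, ...) {
  mi_config(method, m = m, burn_in = 30, between_draws = 5, fcs_cycles = 4,
            among_time_iters = 4, within_time_iters = 2,
            gibbs_iters_per_visit = 4, ...)
}

all_methods <- c("JM-MVN", "FCS-Standard", "FCS-Twofold", "FCS-MTW",
                 "JM-MLMM", "FCS-LMM", "FCS-LMM-het", "FCS-LMM-PMM")

# imputation-model columns (targets can be NA after amputation)
maskable_cols <- function(n_waves = 6) {
  c(paste0("BMIz_w", seq_len(n_waves)),
    paste0("FamStruc_w", 2:n_waves))
}
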