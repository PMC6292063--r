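#' Generative parameters for the six-wave synthetic cohort
#'
#' Bundles every coefficient and variance of the sequential data-generating
#' models: baseline binaries (sex, home language, mother's education), age in
#' months with a subject-level recruitment-age intercept, a logistic mixed
#' model for family structure (single- vs two-parent household), a baseline
#' linear model for socio-economic position (SEP), and linear mixed models
#' for the BMI z-score exposure and the quality-of-life (QoL) z-score
#' outcome. Defaults reproduce the cohort structure of a six-wave national
#' child-cohort study with 24-month wave spacing.
#'
#' Distribution second arguments are variances by default; set
#' `second_param_is_sd = TRUE` to reinterpret every `*_var` field as a
#' standard deviation (the generator squares them on use).
#'
#' @param p_sex,p_language,p_moedu baseline Bernoulli probabilities
#'   (female = 1 by default coding; English main language; mother completed
#'   year 12).
#' @param age_base_months age in months at recruitment before the subject
#'   intercept (48).
#' @param age_intercept_mean,age_intercept_var mean and variance of the
#'   subject-level recruitment-age intercept u_i (11, 1.5 months^2).
#' @param age_noise_var variance of the per-wave interview-timing noise v_ij
#'   (2 months^2); no noise at wave 1.
#' @param wave_spacing_months months between waves (24).
#' @param famstruc_coefs intercept and slopes (ageyr, language, moedu) of the
#'   single-parent logistic mixed model.
#' @param famstruc_ri_var variance of its subject random intercept (5.5).
#' @param sep_coefs intercept and slopes (moedu, wave-1 FamStruc) of the SEP
#'   model.
#' @param sep_resid_var SEP residual variance (1.2).
#' @param bmiz_coefs intercept and slopes (ageyr, sex, FamStruc) of the BMI
#'   z-score linear mixed model.
#' @param bmiz_ri_var,bmiz_resid_var its random-intercept and residual
#'   variances (0.9, 0.6).
#' @param qolz_coefs intercept and slopes (sex, ageyr, BMIz, FamStruc,
#'   language, SEP) of the QoL z-score linear mixed model.
#' @param qolz_ri_var,qolz_resid_var its random-intercept and residual
#'   variances (0.7, 0.7).
#' @param n_waves number of waves (6).
#' @param second_param_is_sd treat the `*_var` arguments as SDs instead of
#'   variances.
#' @return an object of class `gen_params`.
#' @export
#' @examples
#' p <- gen_params()
#' p$qolz_coefs[["bmiz"]]   # -0.12, the mixed-model truth for the exposure
gen_params <- function(p_sex = 0.5,
                       p_language = 0.9,
                       p_moedu = 0.6,
                       age_base_months = 48,
                       age_intercept_mean = 11,
                       age_intercept_var = 1.5,
                       age_noise_var = 2,
                       wave_spacing_months = 24,
                       famstruc_coefs = c(intercept = -6.9, ageyr = 0.15,
                                          language = 0.62, moedu = -1.9),
                       famstruc_ri_var = 5.5,
                       sep_coefs = c(intercept = -0.5, moedu = 0.94,
                                     famstruc = -0.45),
                       sep_resid_var = 1.2,
                       bmiz_coefs = c(intercept = 0.53, ageyr = -0.012,
                                      sex = -0.008, famstruc = 0.07),
                       bmiz_ri_var = 0.9,
                       bmiz_resid_var = 0.6,
                       qolz_coefs = c(intercept = -0.04, sex = 0.05,
                                      ageyr = -0.02, bmiz = -0.12,
                                      famstruc = -0.2, language = 0.20,
                                      sep = 0.09),
                       qolz_ri_var = 0.7,
                       qolz_resid_var = 0.7,
                       n_waves = 6L,
                       second_param_is_sd = FALSE) {
  p <- list(p_sex = p_sex, p_language = p_language, p_moedu = p_moedu,
            age_base_months = age_base_months,
            age_intercept_mean = age_intercept_mean,
            age_intercept_var = age_intercept_var,
            age_noise_var = age_noise_var,
            wave_spacing_months = wave_spacing_months,
            famstruc_coefs = famstruc_coefs,
            famstruc_ri_var = famstruc_ri_var,
            sep_coefs = sep_coefs, sep_resid_var = sep_resid_var,
            bmiz_coefs = bmiz_coefs, bmiz_ri_var = bmiz_ri_var,
            bmiz_resid_var = bmiz_resid_var,
            qolz_coefs = qolz_coefs, qolz_ri_var = qolz_ri_var,
            qolz_resid_var = qolz_resid_var,
            n_waves = as.integer(n_waves),
            second_param_is_sd = isTRUE(second_param_is_sd))
  class(p) <- "gen_params"
  validate_gen_params(p)
  p
}

validate_gen_params <- function(p) {
  probs <- c(p$p_sex, p$p_language, p$p_moedu)
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs >= 1))
    stop("probabilities must lie strictly in (0, 1)")
  vars <- c(p$age_intercept_var, p$age_noise_var, p$famstruc_ri_var,
            p$sep_resid_var, p$bmiz_ri_var, p$bmiz_resid_var,
            p$qolz_ri_var, p$qolz_resid_var)
  if (any(!is.finite(vars)) || any(vars < 0))
    stop("variance parameters must be finite and non-negative")
  if (p$n_waves < 1L) stop("n_waves must be at least 1")
  stopifnot(length(p$famstruc_coefs) == 4L, length(p$sep_coefs) == 3L,
            length(p$bmiz_coefs) == 4L, length(p$qolz_coefs) == 7L)
  invisible(p)
}

# resolve a dispersion field to a variance under either convention
as_var <- function(p, x) if (p$second_param_is_sd) x^2 else x

#' Closed-form moments of the generative model
#'
#' Analytic per-wave expectations and variances for age, and the
#' between/within (random-intercept vs residual) variance decompositions of
#' the BMI and QoL z-scores, used as Monte-Carlo oracles for the generator.
#'
#' @param params a [gen_params()] object.
#' @return a list with `ageyr` (data.frame: wave, mean, var in years),
#'   `bmiz` and `qolz` (each: between, within, total, icc).
#' @export
analytic_moments <- function(params) {
  p <- params
  validate_gen_params(p)
  waves <- seq_len(p$n_waves)
  mean_months <- p$age_base_months + (waves - 1) * p$wave_spacing_months +
    p$age_intercept_mean
  var_months <- as_var(p, p$age_intercept_var) +
    ifelse(waves == 1L, 0, as_var(p, p$age_noise_var))
  bmiz_b <- as_var(p, p$bmiz_ri_var); bmiz_w <- as_var(p, p$bmiz_resid_var)
  qolz_b <- as_var(p, p$qolz_ri_var); qolz_w <- as_var(p, p$qolz_resid_var)
  icc <- function(b, w) if (b + w == 0) 0 else b / (b + w)
  list(
    ageyr = data.frame(wave = waves, mean = mean_months / 12,
                       var = var_months / 144),
    bmiz = c(between = bmiz_b, within = bmiz_w, total = bmiz_b + bmiz_w,
             icc = icc(bmiz_b, bmiz_w)),
    qolz = c(between = qolz_b, within = qolz_w, total = qolz_b + qolz_w,
             icc = icc(qolz_b, qolz_w))
  )
}
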