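#' Generate a synthetic six-wave cohort
#'
#' Simulates subjects sequentially: baseline binaries (sex, home language,
#' mother's education) from independent Bernoulli draws; age in months as a
#' recruitment-age intercept plus fixed 24-month wave spacing plus per-wave
#' interview-timing noise, divided by 12 (no rounding); family structure from
#' a logistic mixed model with a subject random intercept; baseline
#' socio-economic position from mother's education and wave-1 family
#' structure; the BMI z-score exposure from a random-intercept linear mixed
#' model on age, sex and family structure; and finally the QoL z-score
#' outcome from a random-intercept linear mixed model on sex, age, BMI
#' z-score, family structure, language and SEP.
#'
#' The returned cohort is fully observed; identical `seed` gives an
#' identical table.
#'
#' @param n number of subjects (>= 1).
#' @param params a [gen_params()] object.
#' @param seed integer seed.
#' @return a fully observed [cohort_table()].
#' @export
#' @examples
#' coh <- generate_cohort(200, gen_params(), seed = 1)
#' mean(coh$data$language)  # close to 0.9
generate_cohort <- function(n, params = gen_params(), seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  validate_gen_params(params)
  with_seed(seed, generate_cohort_impl(n, params))
}

generate_cohort_impl <- function(n, p) {
  J <- p$n_waves
  sd_of <- function(x) sqrt(as_var(p, x))

  sex <- stats::rbinom(n, 1L, p$p_sex)
  language <- stats::rbinom(n, 1L, p$p_language)
  moedu <- stats::rbinom(n, 1L, p$p_moedu)

  # age in months: base + spacing + subject intercept + per-wave noise
  u <- stats::rnorm(n, p$age_intercept_mean, sd_of(p$age_intercept_var))
  age_m <- outer(u + p$age_base_months,
                 (seq_len(J) - 1) * p$wave_spacing_months, `+`)
  if (J > 1L)
    age_m[, -1L] <- age_m[, -1L] +
      matrix(stats::rnorm(n * (J - 1L), 0, sd_of(p$age_noise_var)), n, J - 1L)
  ageyr <- age_m / 12

  fc <- p$famstruc_coefs
  xi <- stats::rnorm(n, 0, sd_of(p$famstruc_ri_var))
  eta <- fc[[1L]] + fc[[2L]] * ageyr + fc[[3L]] * language +
    fc[[4L]] * moedu + xi
  famstruc <- matrix(stats::rbinom(n * J, 1L, expit(eta)), n, J)

  sc <- p$sep_coefs
  sep <- sc[[1L]] + sc[[2L]] * moedu + sc[[3L]] * famstruc[, 1L] +
    stats::rnorm(n, 0, sd_of(p$sep_resid_var))

  bc <- p$bmiz_coefs
  phi0 <- stats::rnorm(n, 0, sd_of(p$bmiz_ri_var))
  bmiz <- bc[[1L]] + bc[[2L]] * ageyr + bc[[3L]] * sex +
    bc[[4L]] * famstruc + phi0 +
    matrix(stats::rnorm(n * J, 0, sd_of(p$bmiz_resid_var)), n, J)

  qc <- p$qolz_coefs
  om0 <- stats::rnorm(n, 0, sd_of(p$qolz_ri_var))
  qolz <- qc[[1L]] + qc[[2L]] * sex + qc[[3L]] * ageyr + qc[[4L]] * bmiz +
    qc[[5L]] * famstruc + qc[[6L]] * language + qc[[7L]] * sep + om0 +
    matrix(stats::rnorm(n * J, 0, sd_of(p$qolz_resid_var)), n, J)

  name_waves <- function(m, prefix) {
    colnames(m) <- wave_cols(prefix, J)
    as.data.frame(m)
  }
  wide <- cbind(
    data.frame(subject_id = seq_len(n), sex = sex, language = language,
               moedu = moedu, SEP = sep),
    name_waves(ageyr, "ageyr"), name_waves(famstruc, "FamStruc"),
    name_waves(bmiz, "BMIz"), name_waves(qolz, "QoLz")
  )
  cohort_table(wide, J)
}
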