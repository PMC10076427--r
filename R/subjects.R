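#' Create a subject profile
#'
#' A subject profile carries the screening characteristics needed to derive
#' pharmacokinetic parameters: sex, age, height, weight and OPRM1 A118G
#' genotype. Eligibility bounds mirror the laboratory paradigm: age 25-55
#' years, body weight at most 130 kg.
#'
#' @param id character subject identifier.
#' @param sex `"male"` or `"female"`.
#' @param age age in years (25-55).
#' @param height height in cm.
#' @param weight weight in kg (at most 130).
#' @param genotype OPRM1 A118G genotype: `"AA"`, `"AG"` or `"GG"`.
#' @return An object of class `subject_profile`.
#' @examples
#' subject_profile("s01", "male", 30, 180, 80)
#' @export
subject_profile <- function(id, sex = c("male", "female"), age, height, weight,
                            genotype = c("AA", "AG", "GG")) {
  sex <- match.arg(sex)
  genotype <- match.arg(genotype)
  if (!is.numeric(age) || length(age) != 1 || age < 25 || age > 55)
    .stopf("age must be a single value in [25, 55], got %s", format(age))
  if (!is.numeric(height) || length(height) != 1 || height <= 0)
    .stopf("height must be a single positive number")
  if (!is.numeric(weight) || length(weight) != 1 || weight <= 0)
    .stopf("weight must be a single positive number")
  if (weight > 130)
    .stopf("weight %.1f kg exceeds the 130 kg eligibility bound", weight)
  structure(
    list(id = as.character(id), sex = sex, age = age, height = height,
         weight = weight, genotype = genotype),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject %s> %s, %g y, %g cm, %g kg, OPRM1 %s\n",
              x$id, x$sex, x$age, x$height, x$weight, x$genotype))
  invisible(x)
}

#' Watson total body water
#'
#' Anthropometric estimate of total body water (litres), used as the ethanol
#' distribution volume: whole-body water is the standard distribution space
#' for ethanol in intravenous clamp methodology.
#'
#' For males: 2.447 - 0.09516 age + 0.1074 height + 0.3362 weight.
#' For females: -2.097 + 0.1069 height + 0.2466 weight.
#'
#' @param profile a [subject_profile()].
#' @return Total body water in litres.
#' @examples
#' watson_tbw(subject_profile("m", "male", 30, 180, 80))    # 45.82 L
#' watson_tbw(subject_profile("f", "female", 40, 165, 60))  # 30.34 L
#' @export
watson_tbw <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  if (profile$sex == "male") {
    2.447 - 0.09516 * profile$age + 0.1074 * profile$height +
      0.3362 * profile$weight
  } else {
    -2.097 + 0.1069 * profile$height + 0.2466 * profile$weight
  }
}

#' Pharmacokinetic parameters for ethanol disposition
#'
#' Parameters of the two-compartment Michaelis-Menten disposition model:
#' a central (arterial/breath-equivalent) compartment holding a fraction
#' `1 - f_per` of the distribution volume `vd`, exchanging with a peripheral
#' compartment at rate `k_per`, with saturable elimination (`vmax`, `km`)
#' drawn from the central compartment.
#'
#' `f_per = 0` (with `k_per = 0`) degenerates to a one-compartment model in
#' which the full `vd` mixes instantaneously; this limit is useful for
#' closed-form checks.
#'
#' @param vd distribution volume, litres.
#' @param vmax maximal elimination rate, g/min.
#' @param km half-saturation concentration, g/L.
#' @param k_per central-peripheral exchange rate, 1/min.
#' @param f_per fraction of `vd` assigned to the peripheral compartment,
#'   in `[0, 1)`.
#' @return An object of class `pk_params`.
#' @seealso [default_pk_params()]
#' @export
pk_params <- function(vd, vmax, km = 0.1, k_per = 0.10, f_per = 0.70) {
  for (nm in c("vd", "vmax", "km", "k_per", "f_per")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      .stopf("%s must be a single finite number", nm)
  }
  if (vd <= 0 || vmax < 0 || km <= 0 || k_per < 0)
    .stopf("vd, km must be positive; vmax, k_per nonnegative")
  if (f_per < 0 || f_per >= 1)
    .stopf("f_per must lie in [0, 1)")
  if (f_per == 0 && k_per != 0)
    .stopf("f_per = 0 (one-compartment) requires k_per = 0")
  structure(
    list(vd = vd, vmax = vmax, km = km, k_per = k_per, f_per = f_per,
         # precomputed for the integrator
         v_c = vd * (1 - f_per),
         a = if (f_per < 1) k_per / (1 - f_per) else 0,
         b = if (f_per > 0) k_per / f_per else 0),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params> vd %.1f L, vmax %.3f g/min, km %.2f g/L, k_per %.3f /min, f_per %.2f\n",
    x$vd, x$vmax, x$km, x$k_per, x$f_per))
  invisible(x)
}

#' Default pharmacokinetic parameters for a subject
#'
#' Derives the distribution volume from Watson total body water and scales
#' `vmax` with `vd` so that the zero-infusion whole-body BrAC decline near
#' 50 mg/dL is about 15 mg/dL per hour, a typical human elimination rate.
#' The exchange rate and peripheral fraction defaults (`k_per` 0.10/min,
#' `f_per` 0.70) give a small arterial pool whose redistribution kinetics
#' support the steep post-reward declines the clamp paradigm prescribes.
#'
#' @param profile a [subject_profile()].
#' @param vmax_per_l maximal elimination per litre of `vd`, g/min/L.
#' @param km,k_per,f_per see [pk_params()].
#' @return A [pk_params()] object.
#' @examples
#' default_pk_params(subject_profile("m", "male", 30, 180, 80))
#' @export
default_pk_params <- function(profile, vmax_per_l = 0.003, km = 0.1,
                              k_per = 0.10, f_per = 0.70) {
  vd <- watson_tbw(profile)
  pk_params(vd = vd, vmax = vmax_per_l * vd, km = km,
            k_per = k_per, f_per = f_per)
}
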