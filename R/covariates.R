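# The socio-demographic data dictionary: declared level order (used for
# deterministic cross-tab layout) and the reference level of each covariate
# in the logistic risk-factor model.

#' The socio-demographic covariate dictionary
#'
#' Declares, for each covariate the analysis layer knows about, the ordered
#' set of levels (the order cross-tabs are printed in) and the reference
#' level used when the covariate enters the logistic model.
#'
#' @return Named list; each element has `levels` (character) and
#'   `reference` (one of the levels).
#' @export
fi30_covariates <- function() {
  list(
    age_group = list(
      levels = c("55-59", "60-64", "65-69", "70+"),
      reference = "55-59"),
    gender = list(
      levels = c("Male", "Female"),
      reference = "Male"),
    education = list(
      levels = c("Illiterate", "Literate"),
      reference = "Illiterate"),
    occupation = list(
      levels = c("Service", "Housewife/Others"),
      reference = "Service"),
    marital_status = list(
      levels = c("Married", "Widow/Divorce"),
      reference = "Widow/Divorce"),
    smoking = list(
      levels = c("Non-Smoker", "Smoker"),
      reference = "Non-Smoker"),
    income = list(
      levels = c("<$118.3", "$118.3-$236.6", "$236.6-$354.9",
                 "$354.9-$473.3", ">$473.3"),
      reference = "<$118.3"),
    family_type = list(
      levels = c("Nuclear", "Joint/Extended"),
      reference = "Nuclear"),
    religion = list(
      levels = c("Muslim", "Non-Muslim"),
      reference = "Muslim")
  )
}
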