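#' Specification for a synthetic cohort table
#'
#' Emulates the statistical structure of a two-group (sickle cell anemia vs
#' race-matched control) MRI cohort: nested lesion status under the Liberal,
#' Traditional and Restrictive definitions, lesion counts (zero-truncated
#' negative binomial given presence) and volumes (log-normal), demographics,
#' and Wechsler cognition scores with configurable group means/SDs and an
#' optional linear lesion effect. Per-subject status triples are monotone
#' (Restrictive implies Traditional implies Liberal) by construction: one
#' uniform draw is compared against the three nested prevalences.
#'
#' @param n_sca,n_control group sizes (defaults 106 and 48).
#' @param nested_prevalence list with numeric `sca` and `control`, each
#'   `c(L=, T=, R=)` with `L >= T >= R`; defaults are the observed
#'   prevalences 45/42/25 of 106 and 11/5/2 of 48.
#' @param count_volume_model list: `count_mu`, `count_size` (negative
#'   binomial, zero-truncated, for the Liberal count), `keep_T`, `keep_R`
#'   (thinning of the count down the nesting), `vol_meanlog`, `vol_sdlog`
#'   (log-normal Liberal volume, mm^3), `vol_frac_T`, `vol_frac_R` (nested
#'   volume fractions).
#' @param cognition_model list with `sca` and `control`, each a list of
#'   `mean = c(iq=, wmi=, psi=)` and `sd = c(iq=, wmi=, psi=)`; defaults are
#'   the observed group means/SDs (SCA 93.15/13.28, 92.04/14.18, 89.56/12.99;
#'   control 97.29/11.78, 98.90/13.34, 97.10/13.03).
#' @param lesion_effect named numeric `c(iq=, wmi=, psi=)`: coefficient on
#'   `log(1 + Liberal volume)` added to each outcome (default all 0).
#' @param covariate_model list of distribution parameters for age, sex, SpO2,
#'   hemoglobin, education decile and intracranial volume.
#' @param missingness `c(hemoglobin_sca =, spo2_control =)` fractions
#'   (defaults 4/106 and 7/48).
#' @param seed integer seed.
#' @return class `cohort_spec`.
#' @export
cohort_spec <- function(n_sca = 106L, n_control = 48L,
                        nested_prevalence = list(
                          sca = c(L = 45, T = 42, R = 25) / 106,
                          control = c(L = 11, T = 5, R = 2) / 48),
                        count_volume_model = list(
                          count_mu = 4, count_size = 1.2,
                          keep_T = 0.8, keep_R = 0.5,
                          vol_meanlog = log(75), vol_sdlog = 1.3,
                          vol_frac_T = 0.85, vol_frac_R = 0.06),
                        cognition_model = list(
                          sca = list(mean = c(iq = 93.15, wmi = 92.04, psi = 89.56),
                                     sd = c(iq = 13.28, wmi = 14.18, psi = 12.99)),
                          control = list(mean = c(iq = 97.29, wmi = 98.90, psi = 97.10),
                                         sd = c(iq = 11.78, wmi = 13.34, psi = 13.03))),
                        lesion_effect = c(iq = 0, wmi = 0, psi = 0),
                        covariate_model = list(
                          age_range = c(8, 30),
                          p_male = c(sca = 0.50, control = 0.417),
                          spo2 = list(sca = c(96.3, 2.3), control = c(98.4, 1.4)),
                          spo2_range = c(89, 100),
                          hemoglobin = list(sca = c(88, 15), control = c(125, 12)),
                          hemoglobin_range = c(60, 160),
                          education = 1:10,
                          icv = c(1.45e6, 1.3e5)),
                        missingness = c(hemoglobin_sca = 4 / 106,
                                        spo2_control = 7 / 48),
                        seed = 1L) {
  for (g in c("sca", "control")) {
    p <- nested_prevalence[[g]]
    if (any(p < 0) || any(p > 1) || p[1] < p[2] || p[2] < p[3])
      stop("nested_prevalence must satisfy 0 <= p_R <= p_T <= p_L <= 1")
  }
  if (n_sca < 1L || n_control < 1L) stop("group sizes must be >= 1")
  structure(list(n_sca = as.integer(n_sca), n_control = as.integer(n_control),
                 nested_prevalence = nested_prevalence,
                 count_volume_model = count_volume_model,
                 cognition_model = cognition_model,
                 lesion_effect = lesion_effect,
                 covariate_model = covariate_model,
                 missingness = missingness, seed = as.integer(seed)),
            class = "cohort_spec")
}

.rztnbinom <- function(n, mu, size) {
  # zero-truncated negative binomial by inverse-CDF over the positive part
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- runif(n, min = p0, max = 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Generate a synthetic cohort table
#'
#' One row per subject with group, demographics, nested lesion status under
#' the three definitions, lesion counts and volumes (0 when absent), and
#' cognitive scores. Reproducible under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `sci_cohort` with columns `subject_id`,
#'   `group`, `age_years`, `sex`, `spo2`, `hemoglobin`, `education_decile`,
#'   `icv_mm3`, `sci_L/T/R`, `n_lesions_L/T/R`, `volume_L/T/R`,
#'   `iq`, `wmi`, `psi`, `impaired`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cv <- spec$covariate_model
  cvm <- spec$count_volume_model
  rows <- lapply(c("sca", "control"), function(g) {
    n <- if (g == "sca") spec$n_sca else spec$n_control
    p <- spec$nested_prevalence[[g]]
    u <- runif(n)
    sci_L <- u < p[["L"]]; sci_T <- u < p[["T"]]; sci_R <- u < p[["R"]]
    n_L <- ifelse(sci_L, .rztnbinom(n, cvm$count_mu, cvm$count_size), 0L)
    n_T <- integer(n); n_R <- integer(n)
    pos <- which(sci_T)
    n_T[pos] <- 1L + rbinom(length(pos), pmax(n_L[pos] - 1L, 0L), cvm$keep_T)
    pos <- which(sci_R)
    n_R[pos] <- 1L + rbinom(length(pos), pmax(n_T[pos] - 1L, 0L), cvm$keep_R)
    v_L <- ifelse(sci_L, rlnorm(n, cvm$vol_meanlog, cvm$vol_sdlog), 0)
    v_T <- ifelse(sci_T, v_L * cvm$vol_frac_T, 0)
    v_R <- ifelse(sci_R, v_T * cvm$vol_frac_R, 0)
    cg <- spec$cognition_model[[g]]
    eff <- spec$lesion_effect
    metric <- log1p(v_L)
    iq <- rnorm(n, cg$mean[["iq"]], cg$sd[["iq"]]) + eff[["iq"]] * metric
    wmi <- rnorm(n, cg$mean[["wmi"]], cg$sd[["wmi"]]) + eff[["wmi"]] * metric
    psi <- rnorm(n, cg$mean[["psi"]], cg$sd[["psi"]]) + eff[["psi"]] * metric
    spo2 <- pmin(pmax(rnorm(n, cv$spo2[[g]][1], cv$spo2[[g]][2]),
                      cv$spo2_range[1]), cv$spo2_range[2])
    hb <- pmin(pmax(rnorm(n, cv$hemoglobin[[g]][1], cv$hemoglobin[[g]][2]),
                    cv$hemoglobin_range[1]), cv$hemoglobin_range[2])
    data.frame(
      group = if (g == "sca") "SCA" else "control",
      age_years = runif(n, cv$age_range[1], cv$age_range[2]),
      sex = ifelse(rbinom(n, 1, cv$p_male[[g]]) == 1, "M", "F"),
      spo2 = spo2, hemoglobin = hb,
      education_decile = sample(cv$education, n, replace = TRUE),
      icv_mm3 = rnorm(n, cv$icv[1], cv$icv[2]),
      sci_L = sci_L, sci_T = sci_T, sci_R = sci_R,
      n_lesions_L = n_L, n_lesions_T = n_T, n_lesions_R = n_R,
      volume_L = v_L, volume_T = v_T, volume_R = v_R,
      iq = iq, wmi = wmi, psi = psi, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$subject_id <- sprintf("S%03d", seq_len(nrow(tab)))
  miss_hb <- which(tab$group == "SCA")
  miss_hb <- miss_hb[runif(length(miss_hb)) < spec$missingness[["hemoglobin_sca"]]]
  tab$hemoglobin[miss_hb] <- NA_real_
  miss_sp <- which(tab$group == "control")
  miss_sp <- miss_sp[runif(length(miss_sp)) < spec$missingness[["spo2_control"]]]
  tab$spo2[miss_sp] <- NA_real_
  tab$impaired <- pmin(tab$iq, tab$wmi, tab$psi) < 70
  tab <- tab[, c("subject_id", setdiff(names(tab), "subject_id"))]
  class(tab) <- c("sci_cohort", "data.frame")
  tab
}
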