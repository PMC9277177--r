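#' Specification of one model in the lesion-metric ladder
#'
#' The ladder crosses each cognitive outcome with one lesion definition and
#' six increasingly complex predictor sets:
#' \describe{
#'   \item{1}{presence indicator}
#'   \item{2}{presence + presence x mean-centred SCA status}
#'   \item{3}{presence + log(1 + lesion count)}
#'   \item{4}{presence + presence x SCA + log count + log count x SCA}
#'   \item{5}{presence + log(1 + lesion volume)}
#'   \item{6}{presence + presence x SCA + log volume + log volume x SCA}
#' }
#' All models carry the pre-selected covariates age, sex, intracranial
#' volume, SpO2 and education decile; models restricted to the patient
#' subset add hemoglobin. Interaction terms multiply the lesion metric by
#' mean-centred SCA status (no SCA main effect is added, matching the
#' ladder's design). Count and volume predictors are `log(1 + x)`
#' transformed because zeros are ubiquitous.
#'
#' @param outcome `"iq"`, `"wmi"`, `"psi"` or `"impaired"` (logistic).
#' @param definition `"L"`, `"T"` or `"R"`.
#' @param model_id 1-6.
#' @param subset `"all"` or `"SCA"`.
#' @param presence_metric `"presence"` (SCI yes/no, default) or
#'   `"per_decade"` (more than one lesion per decade of life).
#' @return class `model_spec`.
#' @export
model_spec <- function(outcome = c("iq", "wmi", "psi", "impaired"),
                       definition = c("L", "T", "R"), model_id = 1L,
                       subset = c("all", "SCA"),
                       presence_metric = c("presence", "per_decade")) {
  outcome <- match.arg(outcome)
  definition <- match.arg(definition)
  subset <- match.arg(subset)
  presence_metric <- match.arg(presence_metric)
  if (!model_id %in% 1:6) stop("model_id must be 1..6")
  structure(list(outcome = outcome, definition = definition,
                 model_id = as.integer(model_id), subset = subset,
                 presence_metric = presence_metric),
            class = "model_spec")
}

.ladder_terms <- function(model_id) {
  switch(model_id,
         c("presence"),
         c("presence", "presence_x_sca"),
         c("presence", "log_count"),
         c("presence", "presence_x_sca", "log_count", "log_count_x_sca"),
         c("presence", "log_volume"),
         c("presence", "presence_x_sca", "log_volume", "log_volume_x_sca"))
}

# builds the model frame for one spec; interaction columns are explicit
# products with mean-centred SCA status
.ladder_frame <- function(table, spec) {
  d <- spec$definition
  df <- data.frame(outcome = table[[spec$outcome]])
  if (spec$outcome == "impaired") df$outcome <- as.integer(df$outcome)
  pres <- if (spec$presence_metric == "presence")
    as.numeric(table[[paste0("sci_", d)]])
  else as.numeric(per_decade_abnormal(table[[paste0("n_lesions_", d)]],
                                      table$age_years))
  sca_c <- as.numeric(table$group == "SCA")
  sca_c <- sca_c - mean(sca_c)
  df$presence <- pres
  df$log_count <- log1p(table[[paste0("n_lesions_", d)]])
  df$log_volume <- log1p(table[[paste0("volume_", d)]])
  df$presence_x_sca <- pres * sca_c
  df$log_count_x_sca <- df$log_count * sca_c
  df$log_volume_x_sca <- df$log_volume * sca_c
  df$age <- table$age_years
  df$sex <- as.numeric(table$sex == "M")
  df$icv <- table$icv_mm3
  df$spo2 <- table$spo2
  df$education <- table$education_decile
  if (spec$subset == "SCA") df$hemoglobin <- table$hemoglobin
  df
}

#' Fit one ladder model
#'
#' Ordinary least squares for continuous outcomes, logistic regression for
#' impairment. Variance inflation factors are computed for all predictors;
#' if any lesion term exceeds `vif_threshold` (default 5), the binary
#' indicator terms are dropped and the model refitted (the drop is
#' recorded). Reports coefficients with confidence intervals, and
#' semi-partial correlations for the lesion terms of linear models.
#'
#' @param table cohort data.frame (see [generate_cohort()]).
#' @param spec a [model_spec()].
#' @param vif_threshold multicollinearity cutoff (default 5).
#' @return class `sci_model_report`.
#' @export
fit_ladder_model <- function(table, spec, vif_threshold = 5) {
  if (spec$subset == "SCA") table <- table[table$group == "SCA", , drop = FALSE]
  df <- .ladder_frame(table, spec)
  lesion_terms <- .ladder_terms(spec$model_id)
  covars <- c("age", "sex", "icv", "spo2", "education",
              if (spec$subset == "SCA") "hemoglobin")
  terms <- c(lesion_terms, covars)
  df <- df[complete.cases(df[c("outcome", terms)]), , drop = FALSE]
  if (nrow(df) <= length(terms) + 1L)
    stop("fit_ladder_model: n does not exceed the parameter count")
  fml <- stats::as.formula(paste("outcome ~", paste(terms, collapse = " + ")))
  fit_fun <- function(f, d) {
    if (spec$outcome == "impaired") glm(f, data = d, family = binomial())
    else lm(f, data = d)
  }
  fit <- fit_fun(fml, df)
  dropped <- character(0)
  vifs <- tryCatch(car::vif(fit), error = function(e) NULL)
  lesion_vif <- if (is.null(vifs)) NULL else vifs[names(vifs) %in% lesion_terms]
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(intersect(aliased, lesion_terms)) ||
      (!is.null(lesion_vif) && any(lesion_vif > vif_threshold))) {
    dropped <- intersect(c("presence", "presence_x_sca"), lesion_terms)
    keep <- setdiff(terms, dropped)
    fml <- stats::as.formula(paste("outcome ~", paste(keep, collapse = " + ")))
    fit <- fit_fun(fml, df)
    lesion_terms <- setdiff(lesion_terms, dropped)
    vifs <- tryCatch(car::vif(fit), error = function(e) vifs)
  }
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("fit_ladder_model: singular design after drops; offending columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "stat", "p.value")
  ct$term <- rownames(ct)
  ci <- suppressMessages(stats::confint.default(fit))
  ct$ci_lo <- ci[, 1]; ct$ci_hi <- ci[, 2]
  rownames(ct) <- NULL
  sr <- rep(NA_real_, length(lesion_terms)); names(sr) <- lesion_terms
  if (spec$outcome != "impaired" && length(lesion_terms)) {
    r2 <- sm$r.squared; dfres <- fit$df.residual
    for (tm in lesion_terms) {
      tstat <- ct$stat[ct$term == tm]
      sr[tm] <- tstat * sqrt((1 - r2) / dfres)
    }
  }
  structure(list(spec = spec, n = nrow(df), coefficients = ct,
                 lesion_terms = lesion_terms, semi_partial = sr,
                 vif = vifs, dropped = dropped,
                 r.squared = if (spec$outcome != "impaired") sm$r.squared else NA,
                 fit = fit),
            class = "sci_model_report")
}

#' @export
print.sci_model_report <- function(x, digits = 3, ...) {
  s <- x$spec
  cat(sprintf("<sci_model_report> %s ~ ladder model %d (%s-SCI, %s subset), n = %d\n",
              s$outcome, s$model_id, s$definition, s$subset, x$n))
  print(cbind(round(x$coefficients[, c("estimate", "se", "stat", "p.value")], digits),
              term = x$coefficients$term))
  if (length(x$dropped))
    cat("binary indicator dropped for collinearity (VIF > 5):",
        paste(x$dropped, collapse = ", "), "\n")
  if (any(is.finite(x$semi_partial)))
    cat("semi-partial r (lesion terms):",
        paste(sprintf("%s=%.3f", names(x$semi_partial), x$semi_partial),
              collapse = ", "), "\n")
  invisible(x)
}

#' Run the regression model ladder over outcomes and definitions
#'
#' Fits every requested combination of outcome, definition and ladder model,
#' capturing per-model failures (e.g. a constant outcome) as error reports
#' rather than aborting the battery.
#'
#' @param table cohort data.frame.
#' @param outcomes,definitions,model_ids,subsets combinations to fit.
#' @param vif_threshold passed to [fit_ladder_model()].
#' @return class `sci_battery`: list of `sci_model_report` (or error stubs),
#'   with a `summary()` method returning the lesion-term coefficient table.
#' @export
regression_battery <- function(table, outcomes = c("iq", "wmi", "psi", "impaired"),
                               definitions = c("L", "T", "R"),
                               model_ids = 1:6, subsets = "all",
                               vif_threshold = 5) {
  grid <- expand.grid(outcome = outcomes, definition = definitions,
                      model_id = model_ids, subset = subsets,
                      stringsAsFactors = FALSE)
  reports <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- model_spec(grid$outcome[i], grid$definition[i], grid$model_id[i],
                     grid$subset[i])
    tryCatch(fit_ladder_model(table, sp, vif_threshold),
             error = function(e) structure(list(spec = sp,
                                                error = conditionMessage(e)),
                                           class = "sci_model_report"))
  })
  structure(reports, class = "sci_battery")
}

#' @export
summary.sci_battery <- function(object, ...) {
  rows <- lapply(object, function(r) {
    s <- r$spec
    if (!is.null(r$error))
      return(data.frame(outcome = s$outcome, definition = s$definition,
                        model_id = s$model_id, subset = s$subset,
                        term = NA, estimate = NA, p.value = NA,
                        semi_partial = NA, dropped = NA,
                        error = r$error, stringsAsFactors = FALSE))
    ct <- r$coefficients[r$coefficients$term %in% r$lesion_terms, , drop = FALSE]
    if (!nrow(ct)) return(NULL)
    data.frame(outcome = s$outcome, definition = s$definition,
               model_id = s$model_id, subset = s$subset,
               term = ct$term, estimate = ct$estimate, p.value = ct$p.value,
               semi_partial = unname(r$semi_partial[ct$term]),
               dropped = paste(r$dropped, collapse = ","),
               error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.sci_battery <- function(x, ...) {
  cat("<sci_battery>", length(x), "models; lesion-term summary:\n")
  print(utils::head(summary(x), 20))
  invisible(x)
}
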