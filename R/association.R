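## Association between the nightly sleep-disturbance index and clinical
## scale scores: 90-day window aggregation of nightly scores, then a
## mixed-effects linear model with a per-participant random intercept.

#' Aggregate nightly index scores over pre-assessment windows
#'
#' For each clinical assessment, computes the mean and the sample variance
#' (n - 1 denominator) of the nightly index scores over the half-open
#' 90-day window preceding the assessment, joined with the participant's
#' age and sex. Assessments with fewer than `min_days` scored nights are
#' dropped with a diagnostic (attribute `excluded`).
#'
#' @param scores table with `participant_id`, `night_date`, `dri_si_score`.
#' @param assessments table with `participant_id`, `assessment_date`,
#'   `scale`, `score`.
#' @param participants table with `participant_id`, `age`, `sex`.
#' @param window_days,min_days window length and minimum scored nights.
#' @return a `data.table`: `participant_id`, `assessment_date`, `scale`,
#'   `score`, `dri_mean`, `dri_var`, `age`, `sex`.
#' @export
window_aggregate_dri <- function(scores, assessments, participants,
                                 window_days = 90L, min_days = 15L) {
  s <- as.data.table(scores)
  a <- as.data.table(assessments)
  p <- as.data.table(participants)
  rows <- lapply(seq_len(nrow(a)), function(i) {
    w <- s[participant_id == a$participant_id[i] &
             night_date >= a$assessment_date[i] - window_days &
             night_date < a$assessment_date[i]]
    data.table(participant_id = a$participant_id[i],
               assessment_date = a$assessment_date[i],
               scale = a$scale[i], score = a$score[i],
               n_nights = length(unique(w$night_date)),
               dri_mean = if (nrow(w)) mean(w$dri_si_score) else NA_real_,
               dri_var = if (nrow(w) > 1L) var(w$dri_si_score) else
                 if (nrow(w) == 1L) 0 else NA_real_)
  })
  out <- rbindlist(rows)
  keep <- out$n_nights >= min_days
  excluded <- out[!keep, .(participant_id, assessment_date, scale, n_nights)]
  out <- merge(out[keep], p[, .(participant_id, age, sex)],
               by = "participant_id")
  out[, n_nights := NULL]
  setattr(out, "excluded", excluded)
  out[]
}

#' Mixed-effects association between the index and a clinical scale
#'
#' Fits, by restricted maximum likelihood, the model
#' `score ~ dri_mean + dri_var + age + sex + (1 | participant)`:
#' the scale score regressed on the 90-day mean and variance of the nightly
#' index, adjusted for age and sex, with a per-participant random intercept
#' absorbing repeated measures. Wald Z statistics and normal p-values are
#' reported for the fixed effects; non-convergence and boundary
#' (zero-variance) fits are flagged, never silently replaced.
#'
#' @param rows output of [window_aggregate_dri()].
#' @param scale which clinical scale to model.
#' @return an object of class `mixed_model_result`: `fixed` (coefficient
#'   table), `random_intercept_var`, `residual_var`, `n_obs`,
#'   `n_participants`, `converged`, `boundary`.
#' @export
fit_mixed_model <- function(rows, scale) {
  d <- as.data.table(rows)[rows$scale == scale]
  d <- d[complete.cases(d[, .(score, dri_mean, dri_var, age, sex)])]
  if (nrow(d) < 20L) stop("need at least 20 rows for scale ", scale)
  if (length(unique(d$participant_id)) < 10L) {
    stop("need at least 10 participants for scale ", scale)
  }
  fit <- withCallingHandlers(
    lme4::lmer(score ~ dri_mean + dri_var + age + sex +
                 (1 | participant_id),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                                             lme4::.makeCC("ignore", tol = 1e-4))),
    ## covariates are deliberately left on their natural scales (the index
    ## mean lives in [0,1], age in years); silence only the rescaling hint
    warning = function(w) {
      if (grepl("very different scales", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  co <- sm$coefficients
  fixed <- data.table(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      z = co[, "Estimate"] / co[, "Std. Error"])
  fixed[, p := 2 * pnorm(-abs(z))]
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "participant_id"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  structure(list(fixed = fixed, random_intercept_var = ri_var,
                 residual_var = res_var, n_obs = nrow(d),
                 n_participants = length(unique(d$participant_id)),
                 converged = conv,
                 boundary = ri_var < 1e-8,
                 scale = scale, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> %s: %d observations, %d participants%s%s\n",
              x$scale, x$n_obs, x$n_participants,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$boundary) " [boundary random-effect variance]" else ""))
  print(x$fixed, digits = 4)
  cat(sprintf("  random intercept var %.4f, residual var %.4f\n",
              x$random_intercept_var, x$residual_var))
  invisible(x)
}

utils::globalVariables(c("..scale", "term", "estimate", "se", "p"))
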