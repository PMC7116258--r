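# Longitudinal progression contrasts: per-outcome linear mixed models
# with biotype x time fixed effects and correlated per-subject random
# intercepts and slopes, plus an FDR-controlled summary across the
# outcome family.

#' Fit the progression mixed model for one outcome
#'
#' `value ~ biotype * visit_month + covariates + (1 + visit_month |
#' subject)`, estimated by REML with `lme4::lmer`. The biotype x time
#' interaction is the between-biotype slope contrast per month. Fixed
#' effects get Wald z tests. If the random-effect covariance is
#' singular the model is refitted with uncorrelated random effects and
#' the result is annotated; non-convergence is flagged, never silent.
#'
#' @param table long-format data.frame with columns `subject_id`,
#'   `visit_month`, `outcome`, `value`, `biotype` (see
#'   [simulate_longitudinal()]), plus any covariate columns.
#' @param outcome which outcome to fit.
#' @param covariates fixed-effect covariate column names present in
#'   `table` (missing ones are silently dropped).
#' @return object of class `mixed_model_result`: `fixed` data.frame
#'   (term, estimate, se, z, p), `beta_interaction` (slope contrast,
#'   biotype 2 minus biotype 1, per month), `slopes` (marginal slope
#'   per biotype), `varcomp` (intercept SD, slope SD, correlation,
#'   residual SD), `converged`, `singular`, `uncorrelated_refit`,
#'   `messages`, `n_subjects`, `n_observations`, and the `lme4` fit.
#' @export
fit_progression_lmm <- function(table, outcome,
                                covariates = c("age", "sex", "race", "site")) {
  dat <- table[table$outcome == outcome, , drop = FALSE]
  if (nrow(dat) == 0L) stop(sprintf("outcome `%s` not present", outcome),
                            call. = FALSE)
  dat$biotype <- factor(dat$biotype)
  if (nlevels(dat$biotype) < 2L) stop("both biotypes must be present",
                                      call. = FALSE)
  visits_per_subject <- table(dat$subject_id)
  if (mean(visits_per_subject >= 2) < 0.8) {
    stop("fewer than 80% of subjects have >= 2 visits", call. = FALSE)
  }
  covariates <- intersect(covariates, names(dat))
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(dat[[v]])) > 1L, logical(1))]
  rhs <- paste(c("biotype * visit_month", covariates,
                 "(1 + visit_month | subject_id)"), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))

  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = TRUE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })

  uncorrelated <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    rhs2 <- paste(c("biotype * visit_month", covariates,
                    "(1 + visit_month || subject_id)"), collapse = " + ")
    fit2 <- withCallingHandlers(
      lme4::lmer(stats::as.formula(paste("value ~", rhs2)), data = dat,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    fit <- fit2
    uncorrelated <- TRUE
  }

  converged <- !any(grepl("failed to converge", msgs, fixed = TRUE))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  fixed <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z), p = unname(p),
                      stringsAsFactors = FALSE)

  int_term <- grep("^biotype.*:visit_month$", fixed$term, value = TRUE)
  if (length(int_term) == 0L) {
    int_term <- grep("^visit_month:biotype", fixed$term, value = TRUE)
  }
  beta_int <- fixed$estimate[fixed$term == int_term[1]]
  beta_time <- fixed$estimate[fixed$term == "visit_month"]
  lev <- levels(dat$biotype)
  slopes <- stats::setNames(c(beta_time, beta_time + beta_int), lev[1:2])

  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp, v1, v2 = NA) {
    row <- vc$grp == grp & vc$var1 %in% v1 &
      (is.na(v2) & is.na(vc$var2) | !is.na(vc$var2) & vc$var2 %in% v2)
    if (any(row, na.rm = TRUE)) vc$sdcor[which(row)[1]] else NA_real_
  }
  varcomp <- c(
    intercept_sd = get_vc(unique(vc$grp[vc$grp != "Residual"])[1], "(Intercept)"),
    slope_sd = {
      r <- vc$grp != "Residual" & vc$var1 == "visit_month" & is.na(vc$var2)
      if (any(r, na.rm = TRUE)) vc$sdcor[which(r)[1]] else NA_real_
    },
    cor = {
      r <- !is.na(vc$var2)
      if (any(r)) vc$sdcor[which(r)[1]] else if (uncorrelated) 0 else NA_real_
    },
    resid_sd = vc$sdcor[vc$grp == "Residual"][1]
  )

  structure(list(
    fixed = fixed,
    beta_interaction = beta_int,
    interaction_term = int_term[1],
    slopes = slopes,
    varcomp = varcomp,
    converged = converged,
    singular = lme4::isSingular(fit, tol = 1e-5),
    uncorrelated_refit = uncorrelated,
    messages = msgs,
    n_subjects = length(unique(dat$subject_id)),
    n_observations = nrow(dat),
    outcome = outcome,
    fit = fit
  ), class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "Mixed model for %s: slope contrast %.4f/month (SE %.4f), %d subjects, %d observations%s\n",
    x$outcome, x$beta_interaction,
    x$fixed$se[x$fixed$term == x$interaction_term], x$n_subjects,
    x$n_observations,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Progression slope contrasts across outcomes
#'
#' Fits [fit_progression_lmm()] per outcome and reports the biotype x
#' time contrast with BH-FDR adjustment across the outcome family,
#' together with the faster-progressing biotype (larger marginal slope;
#' outcomes here are severity scores, so larger slope = faster
#' decline).
#'
#' @param table long-format table as in [fit_progression_lmm()].
#' @param outcomes outcomes to fit (default: all present).
#' @param q FDR level across outcomes.
#' @param covariates passed to [fit_progression_lmm()].
#' @return data.frame of class `progression_summary`: outcome,
#'   beta_interaction, se, slope per biotype, z, p, p_adj, significant,
#'   faster_biotype, converged. The per-outcome fits are attached as
#'   attribute `fits`.
#' @export
progression_summary <- function(table, outcomes = unique(table$outcome),
                                q = 0.05,
                                covariates = c("age", "sex", "race", "site")) {
  fits <- lapply(outcomes, function(o) {
    tryCatch(fit_progression_lmm(table, o, covariates = covariates),
             error = function(e) e)
  })
  names(fits) <- outcomes
  ok <- vapply(fits, inherits, logical(1), what = "mixed_model_result")
  if (!any(ok)) stop("all progression models failed", call. = FALSE)
  rows <- lapply(fits[ok], function(f) {
    se <- f$fixed$se[f$fixed$term == f$interaction_term]
    data.frame(
      outcome = f$outcome,
      beta_interaction = f$beta_interaction,
      se = se,
      slope_biotype1 = unname(f$slopes[1]),
      slope_biotype2 = unname(f$slopes[2]),
      z = f$beta_interaction / se,
      p = f$fixed$p[f$fixed$term == f$interaction_term],
      faster_biotype = names(f$slopes)[which.max(f$slopes)],
      converged = f$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= q
  attr(out, "fits") <- fits
  attr(out, "q") <- q
  class(out) <- c("progression_summary", "data.frame")
  out
}
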