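#' Mixed-effects linear regression of an outcome on PGS_T and PGS_NT
#'
#' Restricted-maximum-likelihood fit of
#' \code{y ~ pgs_t_std + pgs_nt_std + sex + Z(age) + (1 | family_id)}.
#' The outcome is z-scored before fitting (the scores are already
#' standardized) so coefficients are standardized; Wald tests and normal
#' 95\% confidence intervals are reported. A singular fit (zero family
#' variance) degenerates to ordinary least squares and is flagged.
#'
#' @param data data.frame with the outcome column, \code{pgs_t_std},
#'   \code{pgs_nt_std}, \code{sex}, \code{age}, \code{family_id}.
#' @param outcome name of the continuous outcome column.
#' @param standardizeOutcome z-score the outcome before fitting (default
#'   TRUE).
#' @return list of class \code{nurture_assoc}: outcome, family
#'   ("continuous"), n, and a data.frame \code{coef} with term, estimate,
#'   se, ci_lo, ci_hi, p for \code{pgs_t_std} and \code{pgs_nt_std}, plus
#'   \code{dgt} and \code{singular}.
#' @export
fitLinearMixed <- function(data, outcome, standardizeOutcome = TRUE) {
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  d <- d[complete.cases(d[, c("pgs_t_std", "pgs_nt_std", "sex", "age")]), ]
  if (length(unique(d$family_id)) < 2) stop("need >= 2 families")
  d$.y <- if (standardizeOutcome) zscore(d[[outcome]]) else d[[outcome]]
  d$.zage <- zscore(d$age)
  # singleton families are allowed: the family variance is then zero and
  # the fit degenerates to ordinary least squares (flagged via `singular`)
  fit <- lme4::lmer(.y ~ pgs_t_std + pgs_nt_std + sex + .zage +
                      (1 | family_id),
                    data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore",
                      check.conv.singular =
                        lme4::.makeCC(action = "ignore", tol = 1e-4)))
  singular <- lme4::isSingular(fit)
  cf <- summary(fit)$coefficients
  terms <- c("pgs_t_std", "pgs_nt_std")
  est <- cf[terms, "Estimate"]; se <- cf[terms, "Std. Error"]
  z <- est / se
  res <- data.frame(term = terms, estimate = unname(est), se = unname(se),
                    ci_lo = unname(est - qnorm(0.975) * se),
                    ci_hi = unname(est + qnorm(0.975) * se),
                    p = unname(2 * pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  structure(list(outcome = outcome, family = "continuous", n = nrow(d),
                 coef = res, dgt = dgt(unname(est[1]), unname(est[2])), singular = singular,
                 fit = fit),
            class = "nurture_assoc")
}

#' Mixed-effects logistic regression of a binary outcome
#'
#' Random-intercept logistic model fitted by Laplace-approximate maximum
#' likelihood (\code{lme4::glmer}); reports the odds ratio per SD of each
#' polygenic score with a Wald 95\% confidence interval.
#'
#' @inheritParams fitLinearMixed
#' @param outcome name of the 0/1 outcome column.
#' @param nAGQ adaptive quadrature points (1 = Laplace).
#' @return list of class \code{nurture_assoc} with family "binary";
#'   \code{coef} carries log-odds estimates plus \code{or}, \code{or_lo},
#'   \code{or_hi}.
#' @export
fitLogisticMixed <- function(data, outcome, nAGQ = 1) {
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  d <- d[complete.cases(d[, c("pgs_t_std", "pgs_nt_std", "sex", "age")]), ]
  d$.y <- d[[outcome]]
  d$.zage <- zscore(d$age)
  fit <- suppressMessages(
    lme4::glmer(.y ~ pgs_t_std + pgs_nt_std + sex + .zage + (1 | family_id),
                data = d, family = binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(
                  check.nobs.vs.nlev = "ignore",
                  check.nobs.vs.nRE = "ignore",
                  check.conv.singular =
                    lme4::.makeCC(action = "ignore", tol = 1e-4))))
  cf <- summary(fit)$coefficients
  terms <- c("pgs_t_std", "pgs_nt_std")
  est <- cf[terms, "Estimate"]; se <- cf[terms, "Std. Error"]
  z <- est / se
  res <- data.frame(term = terms, estimate = unname(est), se = unname(se),
                    ci_lo = unname(est - qnorm(0.975) * se),
                    ci_hi = unname(est + qnorm(0.975) * se),
                    p = unname(2 * pnorm(-abs(z))),
                    or = unname(exp(est)),
                    or_lo = unname(exp(est - qnorm(0.975) * se)),
                    or_hi = unname(exp(est + qnorm(0.975) * se)),
                    stringsAsFactors = FALSE)
  structure(list(outcome = outcome, family = "binary", n = nrow(d),
                 coef = res, dgt = dgt(unname(est[1]), unname(est[2])),
                 singular = lme4::isSingular(fit), fit = fit),
            class = "nurture_assoc")
}

#' Direct genetic transmission contrast
#'
#' The estimated effect of direct genetic transmission: the transmitted-score
#' coefficient minus the non-transmitted-score coefficient, always computed
#' from unrounded estimates.
#'
#' @param betaT,betaNT finite numeric scalars.
#' @return \code{betaT - betaNT}.
#' @export
dgt <- function(betaT, betaNT) {
  if (!is.finite(betaT) || !is.finite(betaNT))
    stop("both coefficients must be finite")
  betaT - betaNT
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1),
#' delegated to \code{stats::p.adjust(method = "BH")} after validating the
#' inputs.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m number of tests (defaults to \code{length(p)}).
#' @return adjusted p-values in input order.
#' @examples
#' bhFdr(c(.612, .004, .014, .034, .328))
#' @export
bhFdr <- function(p, m = length(p)) {
  stopIfNot01(p, "p-values")
  p.adjust(p, method = "BH", n = m)
}

#' Fit the five-outcome nurture/transmission table
#'
#' One model per outcome — smoking initiation (logistic), cigarettes/day,
#' pack-years, daily alcohol grams (linear), lifetime cannabis use
#' (logistic) — each regressing the offspring outcome jointly on the
#' combined transmitted and non-transmitted standardized scores with sex,
#' age and a family random intercept. Smoking-quantity outcomes include only
#' initiators (they are missing otherwise by construction). FDR adjustment
#' (Benjamini-Hochberg, m = 5) is applied across the five non-transmitted
#' tests and, separately, across the five transmitted tests.
#'
#' @param data merged data.frame of standardized scores and phenotypes.
#' @param outcomes named character vector mapping outcome column to family
#'   ("binary"/"continuous"); the default is the five study outcomes.
#' @return data.frame with one row per outcome: n, estimate/OR, CI, p and
#'   p_fdr for both scores, and the direct-transmission contrast for
#'   continuous outcomes.
#' @export
runTable2 <- function(data,
                      outcomes = c(smk_init = "binary",
                                   cig_day = "continuous",
                                   pack_years = "continuous",
                                   alc_gday = "continuous",
                                   cannabis_ever = "binary")) {
  fits <- lapply(names(outcomes), function(out) {
    if (outcomes[[out]] == "binary") fitLogisticMixed(data, out)
    else fitLinearMixed(data, out)
  })
  row1 <- function(f, term) f$coef[f$coef$term == term, , drop = FALSE]
  tab <- do.call(rbind, lapply(fits, function(f) {
    t1 <- row1(f, "pgs_t_std"); t2 <- row1(f, "pgs_nt_std")
    isBin <- f$family == "binary"
    data.frame(
      outcome = f$outcome, family = f$family, n = f$n,
      est_t = if (isBin) t1$or else t1$estimate,
      ci_lo_t = if (isBin) t1$or_lo else t1$ci_lo,
      ci_hi_t = if (isBin) t1$or_hi else t1$ci_hi,
      p_t = t1$p,
      est_nt = if (isBin) t2$or else t2$estimate,
      ci_lo_nt = if (isBin) t2$or_lo else t2$ci_lo,
      ci_hi_nt = if (isBin) t2$or_hi else t2$ci_hi,
      p_nt = t2$p,
      dgt = if (isBin) NA_real_ else f$dgt,
      stringsAsFactors = FALSE)
  }))
  tab$p_fdr_t <- bhFdr(tab$p_t)
  tab$p_fdr_nt <- bhFdr(tab$p_nt)
  tab
}
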