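medSpec <- function() pathModel(list(
  med = c("pgs_t_std", "pgs_nt_std", "sex", "age"),
  y = c("med", "pgs_t_std", "pgs_nt_std", "sex", "age")))

test_that("path model specification enforces recursion", {
  expect_error(pathModel(list(a = "b", b = "a")), "not recursive")
  expect_error(pathModel(list(a = "a")), "recursive|itself")
  spec <- medSpec()
  expect_setequal(spec$exo, c("pgs_t_std", "pgs_nt_std", "sex", "age"))
  expect_equal(spec$endo, c("med", "y"))
})

test_that("FIML equals equation-wise OLS under complete data", {
  d <- makeMediationData(1200, seed = 11)
  fit <- fimlFit(medSpec(), d)
  expect_true(fit$converged)
  olsM <- lm(med ~ pgs_t_std + pgs_nt_std + sex + age, d)
  olsY <- lm(y ~ med + pgs_t_std + pgs_nt_std + sex + age, d)
  expect_equal(fit$paths$est[fit$paths$lhs == "med"],
               unname(coef(olsM)[-1]), tolerance = 1e-6)
  expect_equal(fit$paths$est[fit$paths$lhs == "y"],
               unname(coef(olsY)[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$theta["int.y"]), unname(coef(olsY)[1]),
               tolerance = 1e-6)
  # implied covariance reproduces the sample ML covariance of the data
  S <- cov(d[, fit$spec$vars]) * (nrow(d) - 1) / nrow(d)
  expect_equal(unname(fit$Sigma), unname(as.matrix(S)), tolerance = 1e-6)
})

test_that("FIML recovers generative paths under MCAR missingness", {
  d <- makeMediationData(5000, aT = 0.3, aNT = 0.1, b = 0.4, cT = 0.2,
                         cNT = 0.05, seed = 12)
  set.seed(13)
  d$pgs_nt_std[sample(5000, 1500)] <- NA # 30% MCAR on one exogenous score
  fit <- fimlFit(medSpec(), d)
  expect_true(fit$converged)
  est <- setNames(fit$paths$est, paste0(fit$paths$lhs, "~", fit$paths$rhs))
  mcse <- 3 * 1.5 / sqrt(5000) # generous 3-SE Monte-Carlo band
  expect_lt(abs(est["med~pgs_t_std"] - 0.3), mcse)
  expect_lt(abs(est["med~pgs_nt_std"] - 0.1), mcse)
  expect_lt(abs(est["y~med"] - 0.4), mcse)
  expect_lt(abs(est["y~pgs_t_std"] - 0.2), mcse)

  # optimality: fitted log-likelihood beats the population-parameter theta
  pop <- nurtureR:::.pmStartFromMoments(
    fit$spec, colMeans(d[, fit$spec$vars], na.rm = TRUE),
    cov(d[, fit$spec$vars], use = "pairwise.complete.obs"))
  expect_gte(fit$loglik, -fit$negll(pop) - 1e-6)
})

test_that("rows missing every model variable are dropped with a count", {
  d <- makeMediationData(300, seed = 14)
  d[1:5, c("pgs_t_std", "pgs_nt_std", "sex", "age", "med", "y")] <- NA
  fit <- fimlFit(medSpec(), d)
  expect_equal(fit$nDropped, 5)
  expect_equal(fit$n, 295)
})

test_that("Wald equality test separates unequal and equal coefficients", {
  d <- makeMediationData(4000, cT = 0.3, cNT = 0.05, seed = 15)
  fit <- fimlFit(medSpec(), d)
  wNeq <- waldEquality(fit, "y~pgs_t_std", "y~pgs_nt_std")
  expect_gt(wNeq$chisq, 3.84)
  expect_lt(wNeq$p, 0.05)

  # symmetric generator: coefficients equal within sampling error
  dSym <- makeMediationData(4000, cT = 0.15, cNT = 0.15, seed = 16)
  fitS <- fimlFit(medSpec(), dSym)
  wEq <- waldEquality(fitS, "y~pgs_t_std", "y~pgs_nt_std")
  expect_gt(wEq$p, 0.01)

  wSelf <- waldEquality(fit, "y~pgs_t_std", "y~pgs_t_std")
  expect_true(wSelf$degenerate)
  expect_equal(wSelf$chisq, 0)
  expect_error(waldEquality(fit, "y~nope", "y~med"), "no such path")
})

test_that("mediation decomposition satisfies the linear identity", {
  d <- makeMediationData(2000, seed = 17)
  m <- fitMediation(d, mediator = "med", outcome = "y")
  expect_equal(m$totalT - m$cT - m$indirectT, 0)
  expect_equal(m$totalNT - m$cNT - m$indirectNT, 0)
  expect_equal(m$indirectT, m$aT * m$b)

  # b = 0 in the generator: indirect effects vanish
  d0 <- makeMediationData(4000, b = 0, seed = 18)
  m0 <- fitMediation(d0, mediator = "med", outcome = "y")
  expect_lt(abs(m0$indirectT), 3 * 0.3 / sqrt(4000))

  # full mediation (c' = 0): proportion mediated near 100%
  dF <- makeMediationData(6000, aT = 0.4, aNT = 0.2, b = 0.5, cT = 0,
                          cNT = 0, seed = 19)
  mF <- fitMediation(dF, mediator = "med", outcome = "y")
  expect_lt(abs(mF$propMediatedT - 100), 10)

  expect_equal(proportionMediated(0.032, 0.043), 100 * 0.032 / 0.043)
  expect_true(is.na(proportionMediated(-0.01, 0.05)))
  expect_true(is.na(proportionMediated(0.01, 0)))
})

test_that("parent-of-origin model reflects symmetry and assortment", {
  # symmetric maternal/paternal nurture with correlated parental scores
  set.seed(20)
  n <- 4000
  rho <- 0.5
  mT <- rnorm(n)
  pT <- rho * mT + sqrt(1 - rho^2) * rnorm(n)
  mNT <- rnorm(n); pNT <- rnorm(n)
  sex <- rbinom(n, 1, 0.5); age <- runif(n, 18, 67)
  y <- 0.15 * mT + 0.15 * pT + 0.05 * mNT + 0.05 * pNT + rnorm(n)
  d <- data.frame(mT_std = mT, pT_std = pT, mNT_std = mNT, pNT_std = pNT,
                  sex = sex, age = age, y = y)
  fit <- fitParentOfOrigin(d, "y")
  w <- waldEquality(fit, "y~mNT_std", "y~pNT_std")
  expect_gt(w$p, 0.01)
  # the free exogenous covariance recovers the mate-score correlation
  expect_lt(abs(fit$Sigma["mT_std", "pT_std"] - rho), 3 / sqrt(n))
})

test_that("cluster bootstrap is reproducible and guards degenerate input", {
  d <- makeMediationData(300, seed = 21)
  d$family_id <- rep(1:100, 3)
  stat <- function(dd) c(m = mean(dd$y), b = coef(lm(y ~ med, dd))[[2]])
  b1 <- bootstrapCis(stat, d, B = 25, seed = 5)
  b2 <- bootstrapCis(stat, d, B = 25, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(b1$ci[1, ] <= b1$estimate & b1$estimate <= b1$ci[2, ]))

  one <- d[d$family_id == 1, ]
  expect_error(bootstrapCis(stat, one, B = 5, seed = 1), "two clusters")

  # individual-level resampling also works
  bi <- bootstrapCis(stat, d, B = 10, unit = "individual", seed = 2)
  expect_equal(ncol(bi$replicates), 2)
})

test_that("fit indices report exact fit for saturated models", {
  d <- makeMediationData(500, seed = 22)
  sat <- fimlFit(pathModel(vars = c("pgs_t_std", "med", "y")), d)
  fi <- fitIndices(sat, d)
  expect_equal(fi$chisq, 0)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)

  # a restricted true model: chi-square near its df, healthy indices
  dR <- makeMediationData(2000, cT = 0, cNT = 0, seed = 23)
  spec <- pathModel(list(med = c("pgs_t_std", "pgs_nt_std", "sex", "age"),
                         y = c("med", "sex", "age")))
  fit <- fimlFit(spec, dR)
  fiR <- fitIndices(fit, dR)
  expect_equal(fiR$df, 2)
  expect_gt(fiR$p, 0.001)
  expect_lt(fiR$rmsea, 0.05)
  expect_gt(fiR$cfi, 0.95)
})

test_that("likelihood-ratio p-values are calibrated under the true model", {
  # data generated from the restricted model: the chi-square difference
  # p-value should be uniform across replications
  spec <- pathModel(list(med = c("pgs_t_std", "pgs_nt_std", "sex", "age"),
                         y = c("med", "sex", "age")))
  ps <- vapply(1:60, function(s) {
    d <- makeMediationData(800, cT = 0, cNT = 0, seed = 400 + s)
    fitIndices(fimlFit(spec, d), d)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
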