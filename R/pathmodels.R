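#' Specify a recursive linear path model
#'
#' Observed-variable path model: each endogenous variable is a linear
#' regression on exogenous variables and/or earlier endogenous variables
#' (the system must be acyclic). All variances and covariances among
#' exogenous variables are freely estimated; endogenous residuals are
#' mutually uncorrelated.
#'
#' @param paths named list: endogenous variable name -> character vector of
#'   predictor names, in causal order.
#' @param vars optional extra variables with no paths (used for saturated /
#'   independence models).
#' @return object of class \code{path_model}.
#' @examples
#' pathModel(list(med = c("pgs_t", "pgs_nt"),
#'                y = c("med", "pgs_t", "pgs_nt")))
#' @export
pathModel <- function(paths = list(), vars = NULL) {
  endo <- names(paths)
  if (length(paths) && (is.null(endo) || any(endo == "")))
    stop("every equation must be named by its outcome variable")
  allv <- unique(c(unlist(paths), endo, vars))
  exo <- setdiff(allv, endo)
  seen <- exo
  for (v in endo) {
    if (!all(paths[[v]] %in% seen))
      stop("model is not recursive: predictors of ", v,
           " must be exogenous or earlier endogenous variables")
    if (v %in% paths[[v]]) stop("variable ", v, " cannot predict itself")
    seen <- c(seen, v)
  }
  structure(list(paths = paths, endo = endo, exo = exo,
                 vars = c(exo, endo)), class = "path_model")
}

# parameter vector layout and names
.pmParNames <- function(spec, independence = FALSE) {
  nE <- length(spec$exo)
  nm <- paste0("mean.", spec$exo)
  if (independence) nm <- c(nm, paste0("logsd.", spec$exo))
  else for (cc in seq_len(nE)) for (rr in cc:nE)
    nm <- c(nm, sprintf("chol.%d.%d", rr, cc))
  for (v in spec$endo)
    nm <- c(nm, paste0("int.", v), paste0(v, "~", spec$paths[[v]]),
            paste0("logsd.", v))
  nm
}

# model-implied mean vector and covariance matrix at theta
.pmImplied <- function(spec, theta, independence = FALSE) {
  vars <- spec$vars; p <- length(vars); nE <- length(spec$exo)
  i <- 0L
  exoMean <- theta[i + seq_len(nE)]; i <- i + nE
  if (independence) {
    SigmaE <- diag(exp(theta[i + seq_len(nE)])^2, nE)
    i <- i + nE
  } else {
    L <- matrix(0, nE, nE)
    for (cc in seq_len(nE)) for (rr in cc:nE) {
      i <- i + 1L
      L[rr, cc] <- if (rr == cc) exp(theta[i]) else theta[i]
    }
    SigmaE <- L %*% t(L)
  }
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  m <- numeric(p)
  m[seq_len(nE)] <- exoMean
  S <- matrix(0, p, p)
  if (nE > 0) S[seq_len(nE), seq_len(nE)] <- SigmaE
  for (k in seq_along(spec$endo)) {
    v <- spec$endo[k]; vi <- match(v, vars)
    i <- i + 1L; m[vi] <- theta[i]
    for (q in spec$paths[[v]]) {
      i <- i + 1L
      A[vi, match(q, vars)] <- theta[i]
    }
    i <- i + 1L; S[vi, vi] <- exp(theta[i])^2
  }
  IA <- solve(diag(p) - A)
  list(mu = as.numeric(IA %*% m), Sigma = IA %*% S %*% t(IA), A = A)
}

# group rows by missingness pattern; per-pattern sufficient statistics
.pmPatterns <- function(X) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0
  X <- X[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  out <- lapply(split(seq_len(nrow(X)), key), function(idx) {
    cols <- which(obs[idx[1], ])
    Y <- X[idx, cols, drop = FALSE]
    n <- length(idx)
    ybar <- colMeans(Y)
    S <- if (n > 1) crossprod(sweep(Y, 2, ybar)) / n
         else matrix(0, length(cols), length(cols))
    list(cols = cols, n = n, k = length(cols), ybar = ybar, S = S)
  })
  attr(out, "nDropped") <- sum(!keep)
  attr(out, "nUsed") <- nrow(X)
  out
}

# negative log-likelihood over missingness patterns
.pmNegLL <- function(spec, patterns, independence = FALSE) {
  function(theta) {
    imp <- tryCatch(.pmImplied(spec, theta, independence),
                    error = function(e) NULL)
    if (is.null(imp)) return(1e12)
    total <- 0
    for (g in patterns) {
      SO <- imp$Sigma[g$cols, g$cols, drop = FALSE]
      ch <- tryCatch(chol(SO), error = function(e) NULL)
      if (is.null(ch)) return(1e12)
      SOinv <- chol2inv(ch)
      d <- g$ybar - imp$mu[g$cols]
      q <- sum(SOinv * g$S) + drop(crossprod(d, SOinv %*% d))
      total <- total + g$n *
        (g$k * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
    }
    if (!is.finite(total)) return(1e12)
    total / 2
  }
}

# clip a symmetric matrix to positive definiteness (eigenvalue floor)
.pdClip <- function(S, eps = 1e-6) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, eps * max(e$values, eps))
  e$vectors %*% diag(lam, length(lam)) %*% t(e$vectors)
}

# pack theta from first/second moments (means mu0, covariance S0):
# equation-wise regression coefficients from the moment matrices
.pmStartFromMoments <- function(spec, mu0, S0, independence = FALSE) {
  vars <- spec$vars; nE <- length(spec$exo)
  theta <- numeric(0)
  theta <- c(theta, mu0[spec$exo])
  if (nE > 0) {
    SE <- .pdClip(S0[spec$exo, spec$exo, drop = FALSE])
    if (independence) theta <- c(theta, log(sqrt(diag(SE))))
    else {
      L <- t(chol(SE))
      for (cc in seq_len(nE)) for (rr in cc:nE)
        theta <- c(theta, if (rr == cc) log(L[rr, cc]) else L[rr, cc])
    }
  }
  for (v in spec$endo) {
    pr <- spec$paths[[v]]
    Sxx <- .pdClip(S0[pr, pr, drop = FALSE])
    sxy <- S0[pr, v]
    b <- solve(Sxx, sxy)
    rv <- S0[v, v] - drop(crossprod(b, S0[pr, pr] %*% b))
    rv <- max(rv, 1e-4 * max(S0[v, v], 1e-4))
    theta <- c(theta, mu0[v] - sum(b * mu0[pr]), b, log(sqrt(rv)))
  }
  theta
}

#' Fit a path model by full-information maximum likelihood
#'
#' Maximizes the sum over rows of the multivariate-normal log-density of each
#' row's observed subvector under the model-implied mean and covariance
#' (rows grouped by missingness pattern). With complete data the maximum is
#' available in closed form — equation-wise ordinary least squares with ML
#' variance scaling and sample moments for the exogenous block — and is used
#' directly; otherwise a quasi-Newton search (\code{nlminb}) starts from
#' pairwise-moment estimates. Rows missing every model variable are dropped
#' with their count recorded.
#'
#' @param spec a \code{\link{pathModel}}.
#' @param data data.frame containing the model variables (numeric).
#' @param independence constrain all exogenous covariances to zero (used for
#'   the CFI baseline model).
#' @param control list overriding \code{nlminb} control (rel.tol defaults to
#'   1e-10, iter.max 1000).
#' @return object of class \code{fiml_fit}: named parameter vector
#'   \code{theta}, \code{loglik}, \code{npar}, \code{n}, \code{nDropped},
#'   \code{converged}, implied \code{mu} and \code{Sigma}, a \code{paths}
#'   data.frame (lhs, rhs, est, std), and the negative-log-likelihood
#'   closure for downstream standard errors.
#' @export
fimlFit <- function(spec, data, independence = FALSE, control = list()) {
  stopifnot(inherits(spec, "path_model"))
  miss <- setdiff(spec$vars, names(data))
  if (length(miss)) stop("variables absent from data: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(lapply(data[spec$vars], as.numeric)))
  colnames(X) <- spec$vars
  patterns <- .pmPatterns(X)
  negll <- .pmNegLL(spec, patterns, independence)
  complete <- length(patterns) == 1 &&
    patterns[[1]]$k == length(spec$vars)

  n <- attr(patterns, "nUsed")
  mu0 <- colMeans(X, na.rm = TRUE)
  S0 <- cov(X, use = "pairwise.complete.obs") * (n - 1) / n
  S0[is.na(S0)] <- 0
  dimnames(S0) <- list(spec$vars, spec$vars)
  start <- .pmStartFromMoments(spec, mu0, S0, independence)
  names(start) <- .pmParNames(spec, independence)

  if (complete) {
    # under completeness the likelihood factorizes: equation-wise OLS with
    # ML variance scaling and sample moments for the exogenous block are the
    # exact maximum, no search needed
    theta <- start
    converged <- TRUE
    iter <- 0L
  } else {
    # quasi-Newton with central-difference gradients; BFGS first, PORT as a
    # fallback when BFGS stalls
    gr <- function(p) numGrad(negll, p)
    ctrl <- modifyList(list(maxit = 500, reltol = 1e-12), control)
    opt <- optim(start, negll, gr, method = "BFGS", control = ctrl)
    theta <- setNames(opt$par, names(start))
    obj <- opt$value
    converged <- opt$convergence == 0 &&
      max(abs(gr(theta))) < 1e-3 * (1 + abs(obj))
    iter <- opt$counts[["function"]]
    if (!converged) {
      opt2 <- nlminb(theta, negll, gradient = gr,
                     control = list(rel.tol = 1e-10, iter.max = 1000,
                                    eval.max = 5000))
      theta <- setNames(opt2$par, names(start))
      obj <- opt2$objective
      converged <- opt2$convergence == 0 ||
        max(abs(gr(theta))) < 1e-3 * (1 + abs(obj))
      iter <- iter + opt2$iterations
    }
    if (!converged) {
      err <- simpleError("FIML optimizer failed to converge")
      err$theta <- theta
      stop(err)
    }
  }
  ll <- -negll(theta)
  imp <- .pmImplied(spec, theta, independence)
  vars <- spec$vars
  pathsDF <- do.call(rbind, lapply(spec$endo, function(v) {
    pr <- spec$paths[[v]]
    if (!length(pr)) return(NULL)
    est <- theta[paste0(v, "~", pr)]
    vi <- match(v, vars); qi <- match(pr, vars)
    std <- est * sqrt(diag(imp$Sigma)[qi] / imp$Sigma[vi, vi])
    data.frame(lhs = v, rhs = pr, est = unname(est), std = unname(std),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pathsDF))
    pathsDF <- data.frame(lhs = character(0), rhs = character(0),
                          est = numeric(0), std = numeric(0))
  structure(list(spec = spec, independence = independence, theta = theta,
                 loglik = ll, npar = length(theta), n = n,
                 nDropped = attr(patterns, "nDropped"),
                 nPatterns = length(patterns), converged = converged,
                 iterations = iter, mu = setNames(imp$mu, vars),
                 Sigma = structure(imp$Sigma, dimnames = list(vars, vars)),
                 paths = pathsDF, negll = negll),
            class = "fiml_fit")
}

#' @export
print.fiml_fit <- function(x, ...) {
  cat(sprintf("FIML path model: %d variables, %d parameters, n = %d",
              length(x$spec$vars), x$npar, x$n))
  if (x$nDropped) cat(sprintf(" (%d all-missing rows dropped)", x$nDropped))
  cat(sprintf("\nlog-likelihood = %.3f over %d missingness pattern(s)\n",
              x$loglik, x$nPatterns))
  if (nrow(x$paths)) {
    cat("paths (est / standardized):\n")
    print(x$paths, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
logLik.fiml_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

# central-difference numerical gradient
numGrad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h * max(1, abs(x[j]))
    (f(x + e) - f(x - e)) / (2 * e[j])
  }, numeric(1))
}

# parameter covariance from the observed information (numeric Hessian)
fimlVcov <- function(fit) {
  H <- optimHess(fit$theta, fit$negll)
  V <- tryCatch(solve(H), error = function(e)
    solve(.pdClip(H, 1e-10)))
  dimnames(V) <- list(names(fit$theta), names(fit$theta))
  V
}

# standardized (or raw) coefficient of path "lhs~rhs" as a function of theta
.coefFun <- function(fit, label, standardized = TRUE) {
  if (!label %in% paste0(fit$paths$lhs, "~", fit$paths$rhs))
    stop("no such path in the fitted model: ", label)
  parts <- strsplit(label, "~", fixed = TRUE)[[1]]
  vi <- match(parts[1], fit$spec$vars); qi <- match(parts[2], fit$spec$vars)
  function(theta) {
    b <- theta[label]
    if (!standardized) return(unname(b))
    imp <- .pmImplied(fit$spec, theta, fit$independence)
    unname(b * sqrt(imp$Sigma[qi, qi] / imp$Sigma[vi, vi]))
  }
}

#' Wald test of equality of two path coefficients
#'
#' Tests whether two (by default standardized) regression coefficients of a
#' fitted path model are equal: the squared difference divided by its
#' delta-method variance is referred to a 1-df chi-square.
#'
#' @param fit a \code{fiml_fit}.
#' @param coefA,coefB path labels of the form \code{"outcome~predictor"}.
#' @param standardized compare standardized coefficients (default TRUE).
#' @return list of class \code{wald_result}: \code{chisq}, \code{df},
#'   \code{p}, the contrast value, and a \code{degenerate} flag when the two
#'   labels are identical.
#' @export
waldEquality <- function(fit, coefA, coefB, standardized = TRUE) {
  if (identical(coefA, coefB))
    return(structure(list(chisq = 0, df = 1L, p = 1, contrast = 0,
                          degenerate = TRUE), class = "wald_result"))
  fa <- .coefFun(fit, coefA, standardized)
  fb <- .coefFun(fit, coefB, standardized)
  g <- function(theta) fa(theta) - fb(theta)
  V <- fimlVcov(fit)
  gr <- numGrad(g, fit$theta)
  vg <- drop(crossprod(gr, V %*% gr))
  if (!is.finite(vg) || vg <= 0)
    stop("contrast variance is not positive; covariance unavailable")
  d <- g(fit$theta)
  chisq <- d^2 / vg
  structure(list(chisq = chisq, df = 1L,
                 p = pchisq(chisq, 1, lower.tail = FALSE),
                 contrast = d, degenerate = FALSE), class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("Wald equality test: delta-chisq = %.3f, df = %d, p = %.4g%s\n",
              x$chisq, x$df, x$p,
              if (x$degenerate) " (degenerate self-contrast)" else ""))
  invisible(x)
}

#' Parent-of-origin path model
#'
#' Regresses an offspring outcome on the four parent-specific standardized
#' scores (maternal/paternal x transmitted/non-transmitted) plus sex and age,
#' with all pairwise covariances among the exogenous variables freely
#' estimated (accommodating genetic assortative mating), fitted by FIML so
#' offspring with a missing parental score or outcome still contribute.
#'
#' @param data data.frame with the score columns, outcome and covariates.
#' @param outcome outcome column name.
#' @param scores the four parent-specific score columns.
#' @param covariates covariate columns.
#' @return a \code{fiml_fit}.
#' @export
fitParentOfOrigin <- function(data, outcome,
                              scores = c("mT_std", "mNT_std",
                                         "pT_std", "pNT_std"),
                              covariates = c("sex", "age")) {
  spec <- pathModel(setNames(list(c(scores, covariates)), outcome))
  fimlFit(spec, data)
}

#' Parallel two-equation mediation model
#'
#' Fits \code{mediator ~ aT*PGS_T + aNT*PGS_NT + covariates} and
#' \code{outcome ~ b*mediator + c'T*PGS_T + c'NT*PGS_NT + covariates} by
#' FIML, and decomposes (on the standardized solution) the indirect effects
#' \code{aT*b}, \code{aNT*b}, total effects \code{c' + a*b} and the
#' proportion mediated (reported only when indirect and total effects share
#' sign). Linear-model algebra makes total - direct - indirect identically
#' zero.
#'
#' @param data data.frame.
#' @param mediator,outcome column names (continuous).
#' @param exposureT,exposureNT transmitted / non-transmitted score columns.
#' @param covariates covariate columns entering both equations.
#' @return list of class \code{mediation_result} with paths aT, aNT, b, cT,
#'   cNT (standardized), indirect/total/proportion for T and NT, and the
#'   underlying \code{fit}.
#' @export
fitMediation <- function(data, mediator, outcome,
                         exposureT = "pgs_t_std", exposureNT = "pgs_nt_std",
                         covariates = c("sex", "age")) {
  paths <- list(c(exposureT, exposureNT, covariates),
                c(mediator, exposureT, exposureNT, covariates))
  names(paths) <- c(mediator, outcome)
  fit <- fimlFit(pathModel(paths), data)
  std <- function(lhs, rhs)
    fit$paths$std[fit$paths$lhs == lhs & fit$paths$rhs == rhs]
  aT <- std(mediator, exposureT); aNT <- std(mediator, exposureNT)
  b <- std(outcome, mediator)
  cT <- std(outcome, exposureT); cNT <- std(outcome, exposureNT)
  res <- list(aT = aT, aNT = aNT, b = b, cT = cT, cNT = cNT,
              indirectT = aT * b, indirectNT = aNT * b,
              totalT = cT + aT * b, totalNT = cNT + aNT * b)
  res$propMediatedT <- proportionMediated(res$indirectT, res$totalT)
  res$propMediatedNT <- proportionMediated(res$indirectNT, res$totalNT)
  res$fit <- fit
  class(res) <- "mediation_result"
  res
}

#' Proportion of a total effect explained by mediation
#'
#' \code{100 * indirect / total}, reported only when the two share sign
#' (otherwise NA: the ratio is not interpretable as a proportion).
#'
#' @param indirect,total effect estimates.
#' @return percentage, or NA when signs differ or the total is zero.
#' @examples
#' proportionMediated(0.032, 0.043) # 74.42
#' @export
proportionMediated <- function(indirect, total) {
  if (!is.finite(indirect) || !is.finite(total) || total == 0 ||
      sign(indirect) * sign(total) < 0)
    return(NA_real_)
  100 * indirect / total
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Parallel mediation (standardized solution):\n")
  cat(sprintf("  aT = %.4f, aNT = %.4f, b = %.4f, c'T = %.4f, c'NT = %.4f\n",
              x$aT, x$aNT, x$b, x$cT, x$cNT))
  cat(sprintf("  indirect: T = %.4f, NT = %.4f; total: T = %.4f, NT = %.4f\n",
              x$indirectT, x$indirectNT, x$totalT, x$totalNT))
  cat(sprintf("  proportion mediated: T = %.2f%%, NT = %.2f%%\n",
              x$propMediatedT, x$propMediatedNT))
  invisible(x)
}

#' Cluster bootstrap confidence intervals
#'
#' Resamples clusters (families by default; optionally individual rows) with
#' replacement, re-evaluates a statistic, and returns percentile 95\%
#' confidence intervals and bootstrap standard errors. Replicate failures
#' are logged and excluded; more than 10\% failures is an error.
#'
#' @param statistic function(data) returning a named numeric vector.
#' @param data data.frame.
#' @param B number of replicates (>= 2).
#' @param unit "family" (cluster) or "individual".
#' @param clusterCol cluster id column for family resampling.
#' @param seed integer seed (required for reproducibility).
#' @param level confidence level.
#' @return list of class \code{bootstrap_result}: \code{estimate} (on the
#'   original data), \code{replicates} matrix, \code{ci} (two-row matrix),
#'   \code{se}, \code{B}, \code{nFailed}.
#' @export
bootstrapCis <- function(statistic, data, B = 1000,
                         unit = c("family", "individual"),
                         clusterCol = "family_id", seed, level = 0.95) {
  unit <- match.arg(unit)
  if (B < 2) stop("B must be >= 2")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  if (unit == "family") {
    cl <- unique(data[[clusterCol]])
    if (length(cl) < 2)
      stop("cannot bootstrap: fewer than two clusters to resample")
    rowsOf <- split(seq_len(nrow(data)), data[[clusterCol]])
  } else if (nrow(data) < 2) stop("cannot bootstrap fewer than two rows")
  est <- statistic(data)
  reps <- matrix(NA_real_, B, length(est),
                 dimnames = list(NULL, names(est)))
  nFailed <- 0
  for (b in seq_len(B)) {
    idx <- if (unit == "family")
      unlist(rowsOf[sample(names(rowsOf), length(rowsOf), replace = TRUE)],
             use.names = FALSE)
    else sample(nrow(data), replace = TRUE)
    r <- tryCatch(statistic(data[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(r)) nFailed <- nFailed + 1 else reps[b, ] <- r
  }
  if (nFailed > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed", nFailed, B))
  ok <- !apply(reps, 1, anyNA)
  a <- (1 - level) / 2
  ci <- apply(reps[ok, , drop = FALSE], 2, quantile, probs = c(a, 1 - a),
              na.rm = TRUE)
  se <- apply(reps[ok, , drop = FALSE], 2, sd)
  structure(list(estimate = est, replicates = reps[ok, , drop = FALSE],
                 ci = ci, se = se, B = B, nFailed = nFailed, unit = unit),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%s resampling, %d replicates, %d failed):\n",
              x$unit, x$B, x$nFailed))
  out <- data.frame(estimate = x$estimate, se = x$se,
                    ci_lo = x$ci[1, ], ci_hi = x$ci[2, ])
  print(out, digits = 4)
  invisible(x)
}

#' Fit indices against saturated and independence models
#'
#' Likelihood-ratio chi-square of the fitted model against the saturated
#' model (free means, variances and covariances of all model variables,
#' estimated under the same FIML treatment of missingness), with RMSEA
#' (\code{sqrt(max(0, (chisq - df) / (df * n)))}, n-multiplier convention)
#' and CFI against the independence baseline.
#'
#' @param fit a \code{fiml_fit}.
#' @param data the data the model was fitted to.
#' @return list of class \code{fit_indices}: chisq, df, p, rmsea, cfi, the
#'   three log-likelihoods, and parameter counts.
#' @export
fitIndices <- function(fit, data) {
  vars <- fit$spec$vars
  sat <- fimlFit(pathModel(vars = vars), data)
  base <- fimlFit(pathModel(vars = vars), data, independence = TRUE)
  chisq <- max(0, 2 * (sat$loglik - fit$loglik))
  df <- sat$npar - fit$npar
  chisqB <- max(0, 2 * (sat$loglik - base$loglik))
  dfB <- sat$npar - base$npar
  n <- fit$n
  if (df == 0) {
    out <- list(chisq = 0, df = 0L, p = NA_real_, rmsea = 0, cfi = 1,
                exactFit = TRUE)
  } else {
    rmsea <- sqrt(max(0, (chisq - df) / (df * n)))
    cfi <- 1 - max(0, chisq - df) / max(max(0, chisqB - dfB), 1e-12)
    out <- list(chisq = chisq, df = as.integer(df),
                p = pchisq(chisq, df, lower.tail = FALSE),
                rmsea = rmsea, cfi = min(1, cfi), exactFit = FALSE)
  }
  out$loglik <- fit$loglik
  out$loglikSaturated <- sat$loglik
  out$loglikBaseline <- base$loglik
  out$nparModel <- fit$npar; out$nparSaturated <- sat$npar
  out$n <- n
  class(out) <- "fit_indices"
  out
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "chisq = %.3f (df = %d, p = %s), RMSEA = %.4f, CFI = %.4f, n = %d\n",
    x$chisq, x$df, if (is.na(x$p)) "NA" else sprintf("%.4g", x$p),
    x$rmsea, x$cfi, x$n))
  invisible(x)
}
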