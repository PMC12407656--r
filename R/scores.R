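#' Align a SNP weight table to a genetic map
#'
#' Matches weight rows to map markers by id and orients each weight to the
#' map's coded (alternate) allele: when the effect allele is the alternate
#' allele the weight applies to the allele code directly; when it is the
#' reference allele the contribution is \code{w * (1 - code)}, i.e. a signed
#' weight \code{-w} plus a per-haplotype constant \code{w}. Markers in the
#' weight table absent from the map are excluded with a message; a weight row
#' whose alleles match neither map allele pair orientation is an error.
#'
#' @param weights data.frame with columns marker_id, effect_allele,
#'   other_allele, weight.
#' @param map a \linkS4class{GeneticMap}.
#' @return list: \code{w} signed weight per map marker (0 where unweighted),
#'   \code{offset} per-haplotype constant per marker, \code{nMatched},
#'   \code{nDropped}.
#' @export
alignWeights <- function(weights, map) {
  idx <- match(weights$marker_id, map@marker)
  dropped <- sum(is.na(idx))
  if (dropped > 0)
    message(dropped, " weight row(s) not present in the map were excluded")
  keep <- !is.na(idx)
  wtab <- weights[keep, , drop = FALSE]
  idx <- idx[keep]

  m <- nMarkers(map)
  w <- numeric(m); offset <- numeric(m)
  isAlt <- wtab$effect_allele == map@alt[idx] &
    wtab$other_allele == map@ref[idx]
  isRef <- wtab$effect_allele == map@ref[idx] &
    wtab$other_allele == map@alt[idx]
  if (any(!isAlt & !isRef))
    stop("weight alleles match neither orientation of the map alleles for: ",
         paste(head(wtab$marker_id[!isAlt & !isRef], 5), collapse = ", "))
  w[idx[isAlt]] <- wtab$weight[isAlt]
  w[idx[isRef]] <- -wtab$weight[isRef]
  offset[idx[isRef]] <- wtab$weight[isRef]
  list(w = w, offset = offset, nMatched = sum(keep), nDropped = dropped)
}

#' Polygenic score of a single haplotype
#'
#' Additive score: the sum over weighted markers of the weight times the
#' effect-allele count carried by the haplotype (0 or 1). Missing alleles
#' contribute the marker's mean haplotype dosage times the weight.
#'
#' @param hap integer allele vector (0/1, NA allowed) in map order.
#' @param weights SNP weight table (see \code{\link{alignWeights}}).
#' @param map the \linkS4class{GeneticMap}.
#' @param meanDosage optional numeric vector of mean haplotype allele codes
#'   used for missing values (defaults to 0.5 where needed).
#' @return numeric score.
#' @export
scoreHaplotype <- function(hap, weights, map, meanDosage = NULL) {
  al <- alignWeights(weights, map)
  .scoreHapMatrix(matrix(hap, nrow = 1), al, meanDosage)[1]
}

# score rows of a haplotype allele matrix given aligned weights
.scoreHapMatrix <- function(h, al, meanDosage = NULL) {
  if (anyNA(h)) {
    if (is.null(meanDosage)) meanDosage <- colMeans(h, na.rm = TRUE)
    meanDosage[is.nan(meanDosage)] <- 0.5
    na <- which(is.na(h), arr.ind = TRUE)
    h[na] <- meanDosage[na[, 2]]
  }
  as.numeric(h %*% al$w) + sum(al$offset)
}

#' Per-parent transmitted and non-transmitted polygenic scores
#'
#' Computes the four component scores per offspring from a
#' \linkS4class{TransmissionMap}: maternal/paternal x
#' transmitted/non-transmitted, plus the combined
#' \code{pgs_t = mT + pT} and \code{pgs_nt = mNT + pNT}. For parent-offspring
#' pairs the missing parent's transmitted alleles are the unassigned
#' offspring haplotype (so \code{pgs_t} is always complete) and its
#' non-transmitted score is missing. Scores are computed on raw allele
#' counts; standardization happens later so the conservation identity
#' (transmitted + non-transmitted = the parent's own diploid score) holds
#' exactly.
#'
#' @param tmap a \linkS4class{TransmissionMap}.
#' @param weights SNP weight table.
#' @return data.frame: offspring_id, mT, pT, mNT, pNT, pgs_t, pgs_nt,
#'   mNT_missing, pNT_missing (logical), mNT_imputed, pNT_imputed (all FALSE
#'   here; see \code{\link{imputeMissingNT}}).
#' @export
computeComponents <- function(tmap, weights) {
  al <- alignWeights(weights, tmap@map)
  sc <- function(mat) {
    out <- rep(NA_real_, nrow(mat))
    use <- rowSums(!is.na(mat)) > 0 # all-NA rows (missing parent) stay NA
    if (any(use)) {
      md <- colMeans(mat[use, , drop = FALSE], na.rm = TRUE)
      out[use] <- .scoreHapMatrix(mat[use, , drop = FALSE], al, md)
    }
    out
  }
  mT <- sc(tmap@transMother); pT <- sc(tmap@transFather)
  mNT <- sc(tmap@nontransMother); pNT <- sc(tmap@nontransFather)
  data.frame(
    offspring_id = tmap@offspringIds,
    mT = mT, pT = pT, mNT = mNT, pNT = pNT,
    pgs_t = mT + pT, pgs_nt = mNT + pNT,
    mNT_missing = is.na(mNT), pNT_missing = is.na(pNT),
    mNT_imputed = FALSE, pNT_imputed = FALSE,
    stringsAsFactors = FALSE)
}

#' Impute missing non-transmitted scores
#'
#' In parent-offspring pairs the ungenotyped parent has no non-transmitted
#' score; it is imputed with the average non-transmitted score of the
#' observed parents. The default strategy is role-specific (a missing
#' father's score is the observed-father mean); alternatives are the overall
#' observed-parent mean or no imputation. Combined \code{pgs_nt} is
#' recomputed and imputation flags are set.
#'
#' @param components data.frame from \code{\link{computeComponents}}.
#' @param strategy one of "role", "overall", "none".
#' @return the components data.frame with imputed values and flags.
#' @export
imputeMissingNT <- function(components, strategy = c("role", "overall",
                                                     "none")) {
  strategy <- match.arg(strategy)
  x <- components
  if (strategy == "none") return(x)
  overall <- mean(c(x$mNT[!x$mNT_missing], x$pNT[!x$pNT_missing]))
  fill <- function(v, miss) {
    mu <- if (strategy == "role") mean(v[!miss]) else overall
    if (!is.finite(mu)) {
      warning("no observed parents of the required role; ",
              "falling back to the overall observed-parent mean")
      mu <- overall
    }
    v[miss] <- mu
    v
  }
  x$mNT <- fill(x$mNT, x$mNT_missing)
  x$pNT <- fill(x$pNT, x$pNT_missing)
  x$mNT_imputed <- x$mNT_missing
  x$pNT_imputed <- x$pNT_missing
  x$pgs_nt <- x$mNT + x$pNT
  x
}

#' Residualize scores on principal components and standardize within batch
#'
#' Within each batch, each score column is replaced by the residual of an
#' ordinary least squares regression on an intercept and the first
#' \code{nPcs} principal components, then z-scored. With zero PCs and a
#' single batch this is a plain z-score. Output columns are suffixed
#' \code{_std}.
#'
#' @param scores data.frame containing the columns in \code{cols}.
#' @param cols character vector of score columns to standardize.
#' @param pcs numeric matrix of principal components (rows aligned with
#'   \code{scores}), or NULL for none.
#' @param batches factor/character of batch labels (NULL = single batch).
#' @param nPcs number of leading PC columns to regress out.
#' @return \code{scores} with added \code{*_std} columns.
#' @export
residualizeStandardize <- function(scores,
                                   cols = c("mT", "pT", "mNT", "pNT",
                                            "pgs_t", "pgs_nt"),
                                   pcs = NULL, batches = NULL, nPcs = 10) {
  n <- nrow(scores)
  if (is.null(batches)) batches <- rep("batch1", n)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    nPcs <- min(nPcs, ncol(pcs))
  } else nPcs <- 0
  for (col in cols) {
    out <- rep(NA_real_, n)
    for (b in unique(batches)) {
      sel <- which(batches == b & !is.na(scores[[col]]))
      if (length(sel) < nPcs + 2)
        stop(sprintf("batch %s has fewer observations than PCs + 2", b))
      y <- scores[[col]][sel]
      r <- if (nPcs > 0) resid(lm(y ~ pcs[sel, seq_len(nPcs), drop = FALSE]))
           else y - mean(y)
      s <- sd(r)
      if (s < 1e-10)
        stop(sprintf("degenerate variance after residualization in %s (%s)",
                     col, b))
      out[sel] <- r / s
    }
    scores[[paste0(col, "_std")]] <- out
  }
  scores
}
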