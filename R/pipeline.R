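#' Pipeline run configuration
#'
#' Defaults mirror the study's analysis settings: 150-marker tiles with
#' breakpoint refinement, ten principal components (none are emitted by the
#' simulator, so scores reduce to within-batch z-scores), role-specific
#' mean imputation of missing non-transmitted scores, 1,000 bootstrap
#' replicates and a five-test FDR family.
#'
#' @param nFamilies number of simulated families.
#' @param nChromosomes,markersPerChromosome,lengthCM map geometry.
#' @param params generative parameters (\code{\link{phenoModelParams}}).
#' @param pairFraction,fatherMaskedShare family-structure controls.
#' @param nOffspring offspring per family (NULL = 1-3 uniform).
#' @param tileSize,refine,minInformative inference controls.
#' @param nPcs,imputeStrategy scoring controls.
#' @param bootstrapB bootstrap replicates for mediation CIs (0 disables).
#' @param mediators named list: mediator column -> outcome column for the
#'   mediation stage.
#' @param seed master seed (required).
#' @return a validated config list of class \code{run_config}.
#' @export
runConfig <- function(nFamilies = 500, nChromosomes = 2,
                      markersPerChromosome = 3000, lengthCM = 100,
                      params = phenoModelParams(), pairFraction = 0.8,
                      fatherMaskedShare = 0.5, nOffspring = NULL,
                      tileSize = 150, refine = TRUE, minInformative = 10,
                      nPcs = 10, imputeStrategy = "role", bootstrapB = 1000,
                      mediators = list(mother_cig_day = "cig_day",
                                       father_pack_years = "pack_years"),
                      seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Table-1-style descriptives comparing pairs and trios
#'
#' Per outcome: sample size and mean +/- SD (continuous) or count (%)
#' (binary), overall and split by family type, with a two-sample t-test
#' (continuous) or chi-square test (binary) comparing pairs versus trios.
#'
#' @param pheno offspring phenotype data.frame.
#' @param pedigree pedigree data.frame (used to label each offspring's
#'   family as pair or trio by the number of genotyped parents).
#' @param outcomes named character vector: column -> "binary"/"continuous".
#' @return data.frame, one row per variable.
#' @export
descriptives <- function(pheno, pedigree,
                         outcomes = c(age = "continuous",
                                      sex = "binary",
                                      smk_init = "binary",
                                      cig_day = "continuous",
                                      pack_years = "continuous",
                                      alc_gday = "continuous",
                                      cannabis_ever = "binary")) {
  par <- pedigree[pedigree$role %in% c("mother", "father"), ]
  nGeno <- tapply(par$genotyped, par$family_id, sum)
  grp <- ifelse(nGeno[pheno$family_id] >= 2, "trio", "pair")

  summ <- function(x, type) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (type == "binary")
      sprintf("%d (%.1f)", sum(x), 100 * mean(x))
    else sprintf("%.2f ± %.2f", mean(x), sd(x))
  }
  rows <- lapply(names(outcomes), function(v) {
    type <- outcomes[[v]]
    x <- pheno[[v]]
    xp <- x[grp == "pair"]; xt <- x[grp == "trio"]
    p <- tryCatch({
      if (all(is.na(xp)) || all(is.na(xt))) NA_real_
      else if (type == "binary") {
        tb <- table(factor(grp[!is.na(x)], c("pair", "trio")),
                    factor(x[!is.na(x)], c(0, 1)))
        suppressWarnings(chisq.test(tb, correct = FALSE)$p.value)
      } else t.test(xp, xt)$p.value
    }, error = function(e) NA_real_)
    data.frame(variable = v, type = type,
               n = sum(!is.na(x)), all = summ(x, type),
               n_pair = sum(!is.na(xp)), pair = summ(xp, type),
               n_trio = sum(!is.na(xt)), trio = summ(xt, type),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline: simulate, infer, score, associate, path models
#'
#' Executes every stage on one synthetic dataset: simulation with ground
#' truth, transmission inference, transmitted/non-transmitted scoring
#' (with imputation for the combined scores and FIML-ready per-parent
#' scores left unimputed), the five-outcome mixed-model table, the
#' parent-of-origin path model with Wald equality tests, mediation
#' decompositions with optional bootstrap CIs, fit indices against the
#' saturated model, descriptives, and a concordance check against
#' simulator truth. Deterministic given the config seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir optional directory: intermediates (VCF, TSV) and the report
#'   JSON are persisted there.
#' @return list of class \code{run_report}.
#' @export
runAll <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  sim <- simulateDataset(
    nFamilies = config$nFamilies, nChromosomes = config$nChromosomes,
    markersPerChromosome = config$markersPerChromosome,
    lengthCM = config$lengthCM, params = config$params,
    pairFraction = config$pairFraction,
    fatherMaskedShare = config$fatherMaskedShare,
    nOffspring = config$nOffspring, seed = config$seed)

  tmap <- inferTransmission(sim@haplotypes, sim@pedigree,
                            tileSize = config$tileSize,
                            refine = config$refine,
                            minInformative = config$minInformative)
  conc <- concordance(tmap, sim)

  comp <- computeComponents(tmap, sim@weights)
  # per-parent scores stay unimputed: the path models handle missingness by
  # FIML; the combined scores for the mixed models are mean-imputed
  perParent <- residualizeStandardize(comp,
                                      cols = c("mT", "pT", "mNT", "pNT"),
                                      nPcs = config$nPcs)
  combined <- residualizeStandardize(
    imputeMissingNT(comp, config$imputeStrategy),
    cols = c("pgs_t", "pgs_nt"), nPcs = config$nPcs)

  scores <- merge(perParent[, c("offspring_id", "mT_std", "pT_std",
                                "mNT_std", "pNT_std")],
                  combined[, c("offspring_id", "pgs_t_std", "pgs_nt_std",
                               "mNT_imputed", "pNT_imputed")],
                  by = "offspring_id")
  dat <- merge(scores, sim@phenotypes,
               by.x = "offspring_id", by.y = "individual_id")

  table2 <- runTable2(dat)

  poe <- list()
  for (out in c("cig_day", "pack_years")) {
    fit <- fitParentOfOrigin(dat, out)
    poe[[out]] <- list(
      paths = fit$paths,
      wald_T = waldEquality(fit, paste0(out, "~mT_std"),
                            paste0(out, "~pT_std")),
      wald_NT = waldEquality(fit, paste0(out, "~mNT_std"),
                             paste0(out, "~pNT_std")))
  }

  mediation <- list()
  for (med in names(config$mediators)) {
    out <- config$mediators[[med]]
    mres <- fitMediation(dat, mediator = med, outcome = out)
    entry <- list(result = mres,
                  indices = fitIndices(mres$fit, dat))
    if (config$bootstrapB >= 2) {
      statFun <- function(d) {
        r <- fitMediation(d, mediator = med, outcome = out)
        c(aT = r$aT, aNT = r$aNT, b = r$b, cT = r$cT, cNT = r$cNT,
          indirectT = r$indirectT, indirectNT = r$indirectNT,
          totalT = r$totalT, totalNT = r$totalNT)
      }
      entry$bootstrap <- bootstrapCis(statFun, dat, B = config$bootstrapB,
                                      unit = "family",
                                      seed = substreamSeed(config$seed,
                                                           paste0("boot_",
                                                                  med)))
    }
    mediation[[paste(med, out, sep = "->")]] <- entry
  }

  desc <- descriptives(sim@phenotypes, sim@pedigree)

  report <- list(
    config = config,
    descriptives = desc,
    concordance = conc[c("compared", "concordant", "rate")],
    table2 = table2,
    parent_of_origin = poe,
    mediation = mediation,
    meta = list(seed = config$seed,
                n_offspring_scored = nrow(scores),
                n_offspring_analyzed = nrow(dat),
                n_ambiguous = sum(tmap@assignment$ambiguous),
                elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))))
  class(report) <- "run_report"

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePhasedVcf(sim@haplotypes, file.path(outDir, "phased.vcf"))
    writeTsv(sim@pedigree, file.path(outDir, "pedigree.tsv"))
    writeTsv(sim@phenotypes, file.path(outDir, "phenotypes.tsv"))
    writeTsv(sim@weights, file.path(outDir, "weights.tsv"))
    writeTransmissionDatasets(tmap, file.path(outDir, "transmission"))
    writeTsv(scores, file.path(outDir, "scores.tsv"))
    writeTsv(table2, file.path(outDir, "table2.tsv"))
    writeTsv(desc, file.path(outDir, "descriptives.tsv"))
    jsonlite::write_json(reportToJson(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# serializable view of a run report (fits and closures stripped)
reportToJson <- function(report) {
  medOut <- lapply(report$mediation, function(e) {
    r <- e$result
    out <- list(aT = r$aT, aNT = r$aNT, b = r$b, cT = r$cT, cNT = r$cNT,
                indirectT = r$indirectT, indirectNT = r$indirectNT,
                totalT = r$totalT, totalNT = r$totalNT,
                prop_mediated_T = r$propMediatedT,
                prop_mediated_NT = r$propMediatedNT,
                fit_indices = unclass(e$indices))
    if (!is.null(e$bootstrap))
      out$bootstrap <- list(B = e$bootstrap$B,
                            n_failed = e$bootstrap$nFailed,
                            ci = as.data.frame(t(e$bootstrap$ci)),
                            se = as.list(e$bootstrap$se))
    out
  })
  poeOut <- lapply(report$parent_of_origin, function(e) list(
    paths = e$paths,
    wald_T = unclass(e$wald_T), wald_NT = unclass(e$wald_NT)))
  list(descriptives = report$descriptives,
       concordance = report$concordance,
       table2 = report$table2,
       parent_of_origin = poeOut,
       mediation = medOut,
       meta = report$meta)
}

#' @export
print.run_report <- function(x, ...) {
  cat("nurtureR pipeline report\n")
  cat(sprintf("  seed %d; %d offspring analyzed; NT concordance %.4f\n",
              x$meta$seed, x$meta$n_offspring_analyzed, x$concordance$rate))
  cat("  five-outcome association table:\n")
  print(x$table2[, c("outcome", "n", "est_t", "p_fdr_t", "est_nt",
                     "p_fdr_nt", "dgt")], row.names = FALSE, digits = 3)
  invisible(x)
}
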