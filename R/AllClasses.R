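#' @import methods
#' @importFrom stats rbinom rnorm rpois runif qnorm pnorm pchisq sd var cor
#'   complete.cases lm resid coef vcov setNames aggregate quantile rbeta
#'   pt qchisq nlminb optimHess cov chisq.test t.test p.adjust na.omit
#'   confint binomial
#' @importFrom utils head tail write.table read.table modifyList
NULL

#' Genetic map of typed markers
#'
#' Marker order and genetic (centimorgan) positions per chromosome. Positions
#' must be non-decreasing within a chromosome and marker ids unique
#' genome-wide; the map defines the marker support shared by every
#' \linkS4class{HaplotypeSet} built on it.
#'
#' @slot chrom character vector, chromosome id per marker.
#' @slot marker character vector of unique marker ids.
#' @slot posCM numeric vector of genetic positions in centimorgans.
#' @slot ref,alt character vectors of reference / alternate alleles per
#'   marker (haplotype allele code 1 carries the alternate allele).
#'
#' @export
setClass("GeneticMap",
  representation(chrom = "character", marker = "character",
                 posCM = "numeric", ref = "character", alt = "character")
)

setValidity("GeneticMap", function(object) {
  n <- length(object@marker)
  if (length(object@chrom) != n || length(object@posCM) != n)
    return("chrom, marker and posCM must have equal length")
  if (length(object@ref) != n || length(object@alt) != n)
    return("ref and alt must have one allele per marker")
  if (any(object@ref == object@alt))
    return("ref and alt alleles must differ at every marker")
  if (anyDuplicated(object@marker))
    return("marker ids must be unique genome-wide")
  if (any(object@posCM < 0)) return("genetic positions must be non-negative")
  for (ch in unique(object@chrom)) {
    p <- object@posCM[object@chrom == ch]
    if (is.unsorted(p)) return(sprintf("positions not non-decreasing on %s", ch))
  }
  TRUE
})

#' Phased haplotypes for a set of individuals
#'
#' Two haplotype allele matrices (individuals x markers, codes 0/1) on a
#' common \linkS4class{GeneticMap}. The genotype dosage of an individual is
#' \code{hap1 + hap2}. Phase is taken as known; switch errors can be layered
#' on with \code{\link{addSwitchErrors}}.
#'
#' @slot ids character vector of individual ids (rownames of both matrices).
#' @slot map the \linkS4class{GeneticMap} giving marker support.
#' @slot hap1,hap2 integer matrices of allele codes in \{0, 1\} (NA allowed
#'   for missing genotypes).
#'
#' @export
setClass("HaplotypeSet",
  representation(ids = "character", map = "GeneticMap",
                 hap1 = "matrix", hap2 = "matrix")
)

setValidity("HaplotypeSet", function(object) {
  n <- length(object@ids)
  m <- length(object@map@marker)
  if (!all(dim(object@hap1) == c(n, m)) || !all(dim(object@hap2) == c(n, m)))
    return("haplotype matrices must be n_individuals x n_markers")
  ok <- function(h) all(h %in% c(0L, 1L, NA))
  if (!ok(object@hap1) || !ok(object@hap2))
    return("allele codes must be 0, 1 or NA")
  if (anyDuplicated(object@ids)) return("individual ids must be unique")
  TRUE
})

#' Ground-truth transmission record from the simulator
#'
#' For every simulated offspring and each parent, the per-marker source
#' haplotype (1 or 2) that the meiosis actually copied from, plus the
#' crossover positions of each meiosis. This is the oracle the transmission
#' inference is validated against.
#'
#' @slot offspringIds character vector.
#' @slot sourceMother,sourceFather integer matrices (offspring x markers) of
#'   source haplotype indices in \{1, 2\}.
#' @slot crossovers named list; per offspring, a list with elements
#'   \code{mother} and \code{father}, each a list of numeric crossover
#'   positions (cM) per chromosome.
#'
#' @export
setClass("TransmissionTruth",
  representation(offspringIds = "character", sourceMother = "matrix",
                 sourceFather = "matrix", crossovers = "list")
)

setValidity("TransmissionTruth", function(object) {
  n <- length(object@offspringIds)
  if (nrow(object@sourceMother) != n || nrow(object@sourceFather) != n)
    return("source matrices must have one row per offspring")
  if (!all(object@sourceMother %in% c(1L, 2L)) ||
      !all(object@sourceFather %in% c(1L, 2L)))
    return("source haplotype indices must be 1 or 2")
  TRUE
})

#' Inferred transmitted / non-transmitted allele sets
#'
#' Result of \code{\link{inferTransmission}}: per offspring and parent, the
#' transmitted allele (the parental haplotype copy passed on) and the
#' non-transmitted complement at every marker. For a parent who is not
#' genotyped the transmitted alleles are the unassigned offspring haplotype
#' and the non-transmitted alleles are all missing. For a genotyped parent,
#' transmitted + non-transmitted alleles are a permutation of that parent's
#' two alleles at every marker.
#'
#' @slot offspringIds character vector.
#' @slot map the \linkS4class{GeneticMap}.
#' @slot transMother,nontransMother,transFather,nontransFather integer
#'   matrices (offspring x markers); NA where unavailable.
#' @slot motherGenotyped,fatherGenotyped logical vectors per offspring.
#' @slot assignment data.frame with offspring id, which offspring haplotype
#'   was assigned to the mother, the genome-wide mismatch margin and an
#'   ambiguity flag.
#' @slot breakpoints data.frame of inferred source changes (offspring id,
#'   parent role, chromosome, marker index of the first marker with the new
#'   source, 0-based).
#'
#' @export
setClass("TransmissionMap",
  representation(offspringIds = "character", map = "GeneticMap",
                 transMother = "matrix", nontransMother = "matrix",
                 transFather = "matrix", nontransFather = "matrix",
                 motherGenotyped = "logical", fatherGenotyped = "logical",
                 assignment = "data.frame", breakpoints = "data.frame")
)

#' Synthetic family dataset with ground truth
#'
#' Container returned by \code{\link{simulateDataset}}: everything the
#' downstream pipeline consumes (haplotypes, pedigree, phenotypes, SNP
#' weights) plus the simulator's ground truth (transmission sources, true
#' scores, generative parameters) used only by validation code.
#'
#' @slot map \linkS4class{GeneticMap}.
#' @slot haplotypes \linkS4class{HaplotypeSet} covering all genotyped
#'   individuals (masked parents removed).
#' @slot pedigree data.frame: family_id, individual_id, role, genotyped,
#'   phenotyped.
#' @slot truth \linkS4class{TransmissionTruth}.
#' @slot truthHaplotypes \linkS4class{HaplotypeSet} including masked parents
#'   (simulator-internal oracle).
#' @slot phenotypes data.frame of offspring rows with parental phenotype
#'   columns.
#' @slot truePheno data.frame of latent generative variables (true scores,
#'   liabilities) for oracle regressions.
#' @slot weights data.frame SNP weight table.
#' @slot params list of generative parameters (see
#'   \code{\link{phenoModelParams}}).
#'
#' @export
setClass("SyntheticDataset",
  representation(map = "GeneticMap", haplotypes = "HaplotypeSet",
                 pedigree = "data.frame", truth = "TransmissionTruth",
                 truthHaplotypes = "HaplotypeSet",
                 phenotypes = "data.frame", truePheno = "data.frame",
                 weights = "data.frame", params = "list")
)

## ---- show methods ----

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d markers on %d chromosome(s), span %.1f cM\n",
              length(object@marker), length(unique(object@chrom)),
              max(object@posCM)))
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet: %d individuals x %d markers (phased)\n",
              length(object@ids), length(object@map@marker)))
})

setMethod("show", "TransmissionMap", function(object) {
  cat(sprintf(paste0("TransmissionMap: %d offspring, %d markers; ",
                     "%d mothers / %d fathers genotyped; %d ambiguous\n"),
              length(object@offspringIds), length(object@map@marker),
              sum(object@motherGenotyped), sum(object@fatherGenotyped),
              sum(object@assignment$ambiguous)))
})

setMethod("show", "SyntheticDataset", function(object) {
  ped <- object@pedigree
  offs <- ped[ped$role == "offspring", , drop = FALSE]
  cat(sprintf(paste0("SyntheticDataset: %d families, %d offspring, ",
                     "%d markers; %d genotyped individuals\n"),
              length(unique(ped$family_id)), nrow(offs),
              length(object@map@marker), sum(ped$genotyped)))
})

## ---- accessors ----

#' Number of markers / individuals
#'
#' @param x a \linkS4class{HaplotypeSet} or \linkS4class{GeneticMap}.
#' @return integer count.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "GeneticMap", function(x) length(x@marker))

#' @rdname nMarkers
#' @export
setMethod("nMarkers", "HaplotypeSet", function(x) length(x@map@marker))

#' @rdname nMarkers
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname nMarkers
#' @export
setMethod("nIndividuals", "HaplotypeSet", function(x) length(x@ids))

#' Genotype dosage matrix (hap1 + hap2)
#'
#' @param x a \linkS4class{HaplotypeSet}.
#' @return integer matrix, individuals x markers, values 0/1/2 (NA where a
#'   haplotype allele is missing).
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "HaplotypeSet", function(x) x@hap1 + x@hap2)

#' Subset a HaplotypeSet by individual ids
#'
#' @param x a \linkS4class{HaplotypeSet}.
#' @param i character vector of individual ids (or integer/logical index).
#' @param j,...,drop ignored.
#' @return a \linkS4class{HaplotypeSet} restricted to the chosen individuals.
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@ids)
    if (anyNA(idx)) stop("unknown individual id(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
  } else idx <- i
  new("HaplotypeSet", ids = x@ids[idx], map = x@map,
      hap1 = x@hap1[idx, , drop = FALSE], hap2 = x@hap2[idx, , drop = FALSE])
})

#' Map accessor
#' @param x a HaplotypeSet.
#' @return the \linkS4class{GeneticMap}.
#' @export
setGeneric("geneticMap", function(x) standardGeneric("geneticMap"))

#' @rdname geneticMap
#' @export
setMethod("geneticMap", "HaplotypeSet", function(x) x@map)
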