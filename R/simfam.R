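#' Build an evenly spaced genetic map
#'
#' Constructs a marker map with \code{markersPerChromosome} markers per
#' chromosome, evenly spaced on \code{[0, lengthCM]} centimorgans.
#' Deterministic for fixed inputs.
#'
#' @param nChromosomes number of chromosomes (>= 1).
#' @param markersPerChromosome markers per chromosome (>= 1).
#' @param lengthCM genetic length of each chromosome in cM (>= 0).
#' @return a \linkS4class{GeneticMap}.
#' @examples
#' buildGeneticMap(1, 3, 100)  # positions 0, 50, 100
#' @export
buildGeneticMap <- function(nChromosomes, markersPerChromosome, lengthCM) {
  if (nChromosomes < 1 || markersPerChromosome < 1)
    stop("nChromosomes and markersPerChromosome must be >= 1")
  if (lengthCM < 0) stop("lengthCM must be non-negative")
  pos <- if (markersPerChromosome == 1) 0
         else seq(0, lengthCM, length.out = markersPerChromosome)
  chrom <- rep(paste0("chr", seq_len(nChromosomes)),
               each = markersPerChromosome)
  marker <- paste0(chrom, "_m", rep(seq_len(markersPerChromosome),
                                    times = nChromosomes))
  n <- nChromosomes * markersPerChromosome
  new("GeneticMap", chrom = chrom, marker = marker,
      posCM = rep(pos, times = nChromosomes),
      ref = rep("A", n), alt = rep("G", n))
}

#' Simulate founder haplotypes from allele frequencies
#'
#' Each haplotype allele is an independent Bernoulli draw with its marker's
#' effect-allele frequency (no background linkage disequilibrium): the tile
#' matcher downstream must not rely on LD, so none is simulated by default.
#'
#' @param n number of individuals.
#' @param freqs numeric vector of allele frequencies in (0, 1), one per
#'   marker of \code{map}.
#' @param map a \linkS4class{GeneticMap}.
#' @param seed integer seed (optional; when NULL the current RNG state is
#'   used).
#' @param prefix id prefix for the generated individuals.
#' @return a \linkS4class{HaplotypeSet}.
#' @export
simulateFounders <- function(n, freqs, map, seed = NULL, prefix = "ind") {
  if (n < 1) stop("n must be >= 1")
  if (length(freqs) != nMarkers(map))
    stop("freqs must have one entry per marker")
  if (any(freqs <= 0) || any(freqs >= 1))
    stop("allele frequencies must lie in the open interval (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- nMarkers(map)
  draw <- function() matrix(rbinom(n * m, 1L, rep(freqs, each = n)),
                            nrow = n, ncol = m)
  ids <- paste0(prefix, seq_len(n))
  h1 <- draw(); h2 <- draw()
  rownames(h1) <- rownames(h2) <- ids
  new("HaplotypeSet", ids = ids, map = map, hap1 = h1, hap2 = h2)
}

#' Pair mothers and fathers with controllable genetic assortative mating
#'
#' Mothers sorted by true score are matched to fathers sorted by a noisy copy
#' of their own score, \code{rhoAM * z_f + sqrt(1 - rhoAM^2) * noise}. With
#' \code{rhoAM = 0} pairing is random; with \code{rhoAM = 1} it is perfect
#' rank matching; for intermediate values the realized mate-score correlation
#' is approximately \code{rhoAM} at large n (rank matching of the noisy
#' index is nearly perfect, and the index correlates \code{rhoAM} with the
#' father's score).
#'
#' @param motherScores,fatherScores numeric vectors of equal length (true
#'   polygenic scores of the two parent pools).
#' @param rhoAM target mate correlation in [0, 1].
#' @param seed optional integer seed.
#' @return data.frame with integer columns \code{mother} and \code{father}:
#'   indices into the two pools, one row per couple.
#' @export
pairMates <- function(motherScores, fatherScores, rhoAM = 0, seed = NULL) {
  n <- length(motherScores)
  if (length(fatherScores) != n)
    stop("mother and father pools must have equal size")
  if (rhoAM < 0 || rhoAM > 1) stop("rhoAM must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  zf <- zscore(fatherScores, allowConstant = TRUE)
  idx <- rhoAM * zf + sqrt(1 - rhoAM^2) * rnorm(n)
  data.frame(mother = order(motherScores), father = order(idx))
}

# one meiosis on one chromosome: returns per-marker source (1/2) and
# crossover positions, Haldane model (Poisson count, uniform positions,
# no interference)
.meiosisChrom <- function(posCM) {
  L <- max(posCM)
  ncross <- rpois(1, L / 100)
  xpos <- if (ncross > 0) sort(runif(ncross, 0, L)) else numeric(0)
  start <- sample(1:2, 1)
  k <- findInterval(posCM, xpos)
  src <- ((start - 1L + k) %% 2L) + 1L
  list(source = src, crossovers = xpos)
}

#' Simulate one meiosis (Haldane model)
#'
#' Draws a gamete from a parent's two phased haplotypes. Per chromosome the
#' crossover count is Poisson(length_cM / 100) with positions uniform on the
#' centimorgan scale (no interference); the gamete copies from haplotype 1
#' or 2, starting from a fair coin and switching source at each crossover.
#'
#' @param hap1,hap2 integer allele vectors (the parent's two haplotypes, in
#'   map order).
#' @param map a \linkS4class{GeneticMap} matching the haplotypes.
#' @param seed optional integer seed.
#' @return list with \code{gamete} (integer allele vector), \code{source}
#'   (integer vector of 1/2: which haplotype each allele came from) and
#'   \code{crossovers} (named list of cM positions per chromosome).
#' @export
meiosis <- function(hap1, hap2, map, seed = NULL) {
  if (length(hap1) != nMarkers(map) || length(hap2) != nMarkers(map))
    stop("haplotypes must match the map's marker support")
  if (!is.null(seed)) set.seed(seed)
  src <- integer(nMarkers(map))
  xo <- list()
  for (ch in unique(map@chrom)) {
    sel <- which(map@chrom == ch)
    res <- .meiosisChrom(map@posCM[sel])
    src[sel] <- res$source
    xo[[ch]] <- res$crossovers
  }
  gam <- ifelse(src == 1L, hap1, hap2)
  list(gamete = as.integer(gam), source = src, crossovers = xo)
}

#' Build families: offspring via meiosis, pedigree, ground truth
#'
#' Each couple produces offspring by one maternal and one paternal meiosis;
#' the per-marker source haplotypes are recorded as ground truth. In a
#' \code{pairFraction} share of families one parent's genotyped flag is
#' cleared (the father with probability \code{fatherMaskedShare}), turning
#' the trio into a parent-offspring pair. Offspring haplotype order
#' (maternal/paternal first) is randomized so inference cannot exploit it.
#'
#' @param parents \linkS4class{HaplotypeSet} containing all parents.
#' @param couples data.frame from \code{\link{pairMates}} (columns
#'   \code{mother}, \code{father}, indices into \code{motherIds} /
#'   \code{fatherIds}).
#' @param motherIds,fatherIds character vectors of parent ids in pool order.
#' @param nOffspring offspring per couple; a single integer, or NULL for the
#'   default of 1-3 drawn uniformly per family.
#' @param pairFraction fraction of families reduced to pairs, in [0, 1].
#' @param fatherMaskedShare probability the masked parent is the father.
#' @param seed optional integer seed.
#' @return list with \code{pedigree} (data.frame: family_id, individual_id,
#'   role, genotyped, phenotyped), \code{offspring}
#'   (\linkS4class{HaplotypeSet}) and \code{truth}
#'   (\linkS4class{TransmissionTruth}).
#' @export
buildFamilies <- function(parents, couples, motherIds, fatherIds,
                          nOffspring = NULL, pairFraction = 0,
                          fatherMaskedShare = 0.5, seed = NULL) {
  if (pairFraction < 0 || pairFraction > 1)
    stop("pairFraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  map <- parents@map
  m <- nMarkers(map)
  nFam <- nrow(couples)
  kids <- if (is.null(nOffspring)) sample(1:3, nFam, replace = TRUE)
          else rep(as.integer(nOffspring), nFam)
  nOff <- sum(kids)

  offIds <- character(nOff)
  h1 <- matrix(0L, nOff, m); h2 <- matrix(0L, nOff, m)
  srcM <- matrix(1L, nOff, m); srcF <- matrix(1L, nOff, m)
  xov <- vector("list", nOff)
  ped <- vector("list", nFam)

  row <- 0
  for (f in seq_len(nFam)) {
    mid <- motherIds[couples$mother[f]]
    fid <- fatherIds[couples$father[f]]
    mi <- match(mid, parents@ids); fi <- match(fid, parents@ids)
    fam <- sprintf("fam%04d", f)
    offThisFam <- character(kids[f])
    for (k in seq_len(kids[f])) {
      row <- row + 1
      oid <- sprintf("%s_o%d", fam, k)
      offThisFam[k] <- oid
      gm <- meiosis(parents@hap1[mi, ], parents@hap2[mi, ], map)
      gf <- meiosis(parents@hap1[fi, ], parents@hap2[fi, ], map)
      maternalFirst <- runif(1) < 0.5
      if (maternalFirst) { h1[row, ] <- gm$gamete; h2[row, ] <- gf$gamete }
      else               { h1[row, ] <- gf$gamete; h2[row, ] <- gm$gamete }
      srcM[row, ] <- gm$source
      srcF[row, ] <- gf$source
      xov[[row]] <- list(mother = gm$crossovers, father = gf$crossovers,
                         maternal_hap = if (maternalFirst) 1L else 2L)
      offIds[row] <- oid
    }
    ped[[f]] <- data.frame(
      family_id = fam,
      individual_id = c(mid, fid, offThisFam),
      role = c("mother", "father", rep("offspring", kids[f])),
      genotyped = TRUE, phenotyped = TRUE,
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, ped)

  # reduce a share of families to single-genotyped-parent pairs
  fams <- unique(ped$family_id)
  nPair <- round(pairFraction * length(fams))
  if (nPair > 0) {
    pairFams <- sample(fams, nPair)
    maskFather <- runif(nPair) < fatherMaskedShare
    for (i in seq_len(nPair)) {
      role <- if (maskFather[i]) "father" else "mother"
      ped$genotyped[ped$family_id == pairFams[i] & ped$role == role] <- FALSE
    }
  }

  rownames(h1) <- rownames(h2) <- offIds
  names(xov) <- offIds
  rownames(srcM) <- rownames(srcF) <- offIds
  list(
    pedigree = ped,
    offspring = new("HaplotypeSet", ids = offIds, map = map,
                    hap1 = h1, hap2 = h2),
    truth = new("TransmissionTruth", offspringIds = offIds,
                sourceMother = srcM, sourceFather = srcF, crossovers = xov)
  )
}

#' Generative phenotype model parameters
#'
#' Returns the validated parameter list of the family phenotype model. The
#' offspring linear predictor is
#' \code{delta * Z(G_o) + eta_m * Z(P_m) + eta_f * Z(P_f) + nu_m * Z(G_m) +
#' nu_f * Z(G_f) + betaSex * sex + betaAge * Z(age)}, where \code{G} are
#' weight-based true scores, \code{P} parental latent phenotypes
#' (\code{P = gamma * Z(G_parent) + e}, unit variance), and \code{nu} a small
#' residual nurture path that bypasses the measured parental phenotype (so
#' mediation is partial, not total). Binary traits threshold a latent
#' liability at the quantile matching the target prevalence; smoking-quantity
#' traits are emitted only for initiators.
#'
#' @param delta direct genetic effect of the offspring true score (per SD).
#' @param eta_m,eta_f nurture effect of the maternal / paternal phenotype.
#' @param gamma effect of a parent's own true score on their phenotype.
#' @param nu_m,nu_f residual nurture paths not through the mediator.
#' @param rho_am target mate-score correlation in [0, 1].
#' @param prev_smk,prev_cannabis target prevalences of smoking initiation and
#'   lifetime cannabis use.
#' @param betaSex,betaAge covariate effects.
#' @param sigma residual SD of the continuous outcome liabilities.
#' @param quantCor residual correlation between the two smoking-quantity
#'   outcomes (cigarettes/day and pack-years share exposure).
#' @param gateQuantities when TRUE (default) smoking-quantity traits are
#'   missing for non-initiators, for offspring and parents alike.
#' @return named list with class checks applied.
#' @export
phenoModelParams <- function(delta = 0.12, eta_m = 0.05, eta_f = 0.05,
                             gamma = 0.4, nu_m = 0.01, nu_f = 0.01,
                             rho_am = 0, prev_smk = 0.414,
                             prev_cannabis = 0.227,
                             betaSex = -0.1, betaAge = 0.05, sigma = 1,
                             quantCor = 0.7, gateQuantities = TRUE) {
  p <- list(delta = delta, eta_m = eta_m, eta_f = eta_f, gamma = gamma,
            nu_m = nu_m, nu_f = nu_f, rho_am = rho_am, prev_smk = prev_smk,
            prev_cannabis = prev_cannabis, betaSex = betaSex,
            betaAge = betaAge, sigma = sigma, quantCor = quantCor,
            gateQuantities = gateQuantities)
  if (sigma <= 0) stop("residual SD must be positive")
  stopIfNot01(rho_am, "rho_am")
  if (prev_smk <= 0 || prev_smk >= 1 || prev_cannabis <= 0 ||
      prev_cannabis >= 1)
    stop("prevalences must lie in (0, 1)")
  if (abs(gamma) > 1) stop("gamma must lie in [-1, 1]")
  p
}

#' Simulate family phenotypes with direct-genetic and nurture paths
#'
#' Generates the five study outcomes for every offspring — smoking initiation
#' (binary, liability threshold at the target prevalence), cigarettes/day and
#' pack-years (continuous, observed only in initiators), daily alcohol grams
#' (continuous, all), lifetime cannabis use (binary) — plus parental smoking
#' quantity columns as mediator candidates. Continuous outcomes are scaled to
#' cohort-like units (cigarettes/day mean 10.24 sd 6.00; pack-years 7.03 sd
#' 6.73; alcohol 6.74 sd 8.46).
#'
#' @param pedigree pedigree data.frame from \code{\link{buildFamilies}}.
#' @param haps \linkS4class{HaplotypeSet} covering all parents and offspring
#'   (including parents later masked: the generative model uses true
#'   genotypes).
#' @param weights SNP weight table (see \code{\link{simulateDataset}}).
#' @param params list from \code{\link{phenoModelParams}}.
#' @param seed optional integer seed.
#' @return list with \code{phenotypes} (one row per offspring: sex, age, the
#'   five outcomes, parental phenotype columns, family_id) and
#'   \code{truePheno} (latent generative variables for oracle regressions).
#' @export
simulatePhenotypes <- function(pedigree, haps, weights, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  al <- alignWeights(weights, haps@map)
  G <- as.numeric(dosage(haps) %*% al$w) + 2 * sum(al$offset)
  names(G) <- haps@ids

  off <- pedigree[pedigree$role == "offspring", , drop = FALSE]
  mo <- pedigree[pedigree$role == "mother", , drop = FALSE]
  fa <- pedigree[pedigree$role == "father", , drop = FALSE]
  momOf <- setNames(mo$individual_id, mo$family_id)
  dadOf <- setNames(fa$individual_id, fa$family_id)
  n <- nrow(off)

  parents <- unique(c(mo$individual_id, fa$individual_id))
  zGpar <- zscore(G[parents])
  Ppar <- params$gamma * zGpar +
    sqrt(max(0, 1 - params$gamma^2)) * rnorm(length(parents))
  names(Ppar) <- parents
  # parent's own initiation gates their observed smoking quantity
  liabPar <- 0.8 * Ppar + 0.6 * rnorm(length(parents))
  smkPar <- liabPar > quantile(liabPar, 1 - params$prev_smk)

  zGo <- zscore(G[off$individual_id])
  momId <- momOf[off$family_id]; dadId <- dadOf[off$family_id]
  zPm <- zscore(Ppar[momId]); zPf <- zscore(Ppar[dadId])
  zGm <- zscore(G[momId]);    zGf <- zscore(G[dadId])

  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 18, 67)
  zAge <- zscore(age)

  lp <- function() params$delta * zGo + params$eta_m * zPm +
    params$eta_f * zPf + params$nu_m * zGm + params$nu_f * zGf +
    params$betaSex * sex + params$betaAge * zAge

  liabSmk <- lp() + params$sigma * rnorm(n)
  smkInit <- as.integer(liabSmk > quantile(liabSmk, 1 - params$prev_smk))

  e2 <- rnorm(n)
  cigLat <- lp() + params$sigma * e2
  pyLat <- lp() + params$sigma * (params$quantCor * e2 +
                                  sqrt(1 - params$quantCor^2) * rnorm(n))
  alcLat <- lp() + params$sigma * rnorm(n)
  liabCan <- lp() + params$sigma * rnorm(n)
  canEver <- as.integer(liabCan > quantile(liabCan, 1 - params$prev_cannabis))

  cigDay <- 10.24 + 6.00 * zscore(cigLat)
  packYr <- 7.03 + 6.73 * zscore(pyLat)
  alcG <- 6.74 + 8.46 * zscore(alcLat)
  if (params$gateQuantities) {
    cigDay[smkInit == 0] <- NA_real_
    packYr[smkInit == 0] <- NA_real_
  }

  parQuant <- function(ids) {
    q <- 10.24 + 6.00 * Ppar[ids]
    py <- 7.03 + 6.73 * Ppar[ids]
    if (params$gateQuantities) {
      q[!smkPar[ids]] <- NA_real_
      py[!smkPar[ids]] <- NA_real_
    }
    list(cig = unname(q), py = unname(py))
  }
  pm <- parQuant(momId); pf <- parQuant(dadId)

  phen <- data.frame(
    individual_id = off$individual_id, family_id = off$family_id,
    sex = sex, age = age,
    smk_init = smkInit, cig_day = cigDay, pack_years = packYr,
    alc_gday = alcG, cannabis_ever = canEver,
    mother_cig_day = pm$cig, mother_pack_years = pm$py,
    father_cig_day = pf$cig, father_pack_years = pf$py,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    individual_id = off$individual_id, family_id = off$family_id,
    true_score = unname(G[off$individual_id]), zg = unname(zGo),
    zg_m = unname(zGm), zg_f = unname(zGf),
    zp_m = unname(zPm), zp_f = unname(zPf),
    liab_smk = liabSmk, stringsAsFactors = FALSE)

  list(phenotypes = phen, truePheno = truth)
}

#' Inject phase switch errors
#'
#' At each marker independently with probability \code{rate}, the remaining
#' suffix of an individual's two haplotypes is swapped (within the marker's
#' chromosome, as phasing operates per chromosome). Genotype dosages are
#' unchanged.
#'
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param rate per-marker switch probability in [0, 1).
#' @param seed optional integer seed.
#' @return a \linkS4class{HaplotypeSet} with perturbed phase.
#' @export
addSwitchErrors <- function(haps, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(haps)
  if (!is.null(seed)) set.seed(seed)
  h1 <- haps@hap1; h2 <- haps@hap2
  m <- nMarkers(haps); n <- nIndividuals(haps)
  chrom <- haps@map@chrom
  for (i in seq_len(n)) {
    sw <- rbinom(m, 1L, rate)
    flip <- logical(m)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      flip[sel] <- (cumsum(sw[sel]) %% 2L) == 1L
    }
    if (any(flip)) {
      tmp <- h1[i, flip]
      h1[i, flip] <- h2[i, flip]
      h2[i, flip] <- tmp
    }
  }
  new("HaplotypeSet", ids = haps@ids, map = haps@map, hap1 = h1, hap2 = h2)
}

# stack two HaplotypeSets on the same map
.rbindHaps <- function(a, b) {
  new("HaplotypeSet", ids = c(a@ids, b@ids), map = a@map,
      hap1 = rbind(a@hap1, b@hap1), hap2 = rbind(a@hap2, b@hap2))
}

#' Simulate a complete synthetic family dataset
#'
#' One-stop generator: map, founder parents, assortative mating, families
#' with Haldane meiosis and recorded transmission truth, SNP weights, and
#' phenotypes with direct-genetic and nurture paths. A single master seed
#' drives named substreams (founders, mating, meiosis, phenotypes, masking)
#' so a fixed seed yields a byte-identical dataset.
#'
#' @param nFamilies number of families.
#' @param nChromosomes,markersPerChromosome,lengthCM map geometry (defaults:
#'   2 chromosomes x 3,000 markers, 100 cM).
#' @param freqRange allele frequencies drawn uniformly from this range.
#' @param params phenotype model parameters (\code{\link{phenoModelParams}}).
#' @param pairFraction fraction of families reduced to pairs.
#' @param fatherMaskedShare probability the masked parent is the father.
#' @param nOffspring offspring per family (NULL = 1-3 uniform).
#' @param refFlipFraction fraction of weight-table rows whose effect allele
#'   is the reference allele (exercises allele alignment in scoring).
#' @param switchErrorRate per-marker phase switch error rate applied to the
#'   emitted haplotypes (0 = truth-phased).
#' @param seed master seed (required).
#' @return a \linkS4class{SyntheticDataset}.
#' @export
simulateDataset <- function(nFamilies, nChromosomes = 2,
                            markersPerChromosome = 3000, lengthCM = 100,
                            freqRange = c(0.05, 0.95),
                            params = phenoModelParams(),
                            pairFraction = 0, fatherMaskedShare = 0.5,
                            nOffspring = 1, refFlipFraction = 0.2,
                            switchErrorRate = 0, seed) {
  if (missing(seed)) stop("a master seed is required")
  map <- buildGeneticMap(nChromosomes, markersPerChromosome, lengthCM)
  m <- nMarkers(map)

  freqs <- withSubstream(seed, "freqs",
                         runif(m, freqRange[1], freqRange[2]))
  mothers <- withSubstream(seed, "founders_m",
                           simulateFounders(nFamilies, freqs, map,
                                            prefix = "mother"))
  fathers <- withSubstream(seed, "founders_f",
                           simulateFounders(nFamilies, freqs, map,
                                            prefix = "father"))

  weights <- withSubstream(seed, "weights", {
    eff <- rnorm(m) / sqrt(m)
    flip <- runif(m) < refFlipFraction
    data.frame(
      marker_id = map@marker, chrom = map@chrom,
      pos = unlist(lapply(table(factor(map@chrom, unique(map@chrom))),
                          function(k) seq_len(k) * 1000L),
                   use.names = FALSE),
      effect_allele = ifelse(flip, "A", "G"),
      other_allele = ifelse(flip, "G", "A"),
      weight = eff, stringsAsFactors = FALSE)
  })

  al <- alignWeights(weights, map)
  scoreOf <- function(hs) as.numeric(dosage(hs) %*% al$w)
  couples <- withSubstream(seed, "mating",
                           pairMates(scoreOf(mothers), scoreOf(fathers),
                                     params$rho_am))

  parents <- .rbindHaps(mothers, fathers)
  fam <- withSubstream(seed, "meiosis",
                       buildFamilies(parents, couples, mothers@ids,
                                     fathers@ids, nOffspring = nOffspring,
                                     pairFraction = pairFraction,
                                     fatherMaskedShare = fatherMaskedShare))

  allHaps <- .rbindHaps(parents, fam$offspring)
  ph <- withSubstream(seed, "phenotypes",
                      simulatePhenotypes(fam$pedigree, allHaps, weights,
                                         params))

  emitted <- allHaps
  if (switchErrorRate > 0)
    emitted <- withSubstream(seed, "switch",
                             addSwitchErrors(emitted, switchErrorRate))
  gIds <- fam$pedigree$individual_id[fam$pedigree$genotyped]
  new("SyntheticDataset", map = map, haplotypes = emitted[gIds],
      pedigree = fam$pedigree, truth = fam$truth, truthHaplotypes = allHaps,
      phenotypes = ph$phenotypes, truePheno = ph$truePheno,
      weights = weights, params = params)
}
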