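test_that("genetic map construction spaces markers evenly", {
  m <- buildGeneticMap(1, 3, 100)
  expect_equal(m@posCM, c(0, 50, 100))

  m0 <- buildGeneticMap(2, 150, 0)
  expect_equal(length(unique(m0@chrom)), 2)
  expect_true(all(m0@posCM == 0))

  big <- buildGeneticMap(22, 1000, 120)
  expect_equal(nMarkers(big), 22000)
  expect_equal(max(tapply(big@posCM, big@chrom, max)), 120)
  expect_equal(min(tapply(big@posCM, big@chrom, max)), 120)

  expect_error(buildGeneticMap(1, 0, 100), "must be >= 1")
})

test_that("founder haplotypes follow the allele frequencies", {
  map <- buildGeneticMap(1, 50, 100)
  hs <- simulateFounders(2000, rep(0.5, 50), map, seed = 5)
  # mean dosage per marker ~ Binomial(2, 0.5): 3 SEs of the mean over 2000
  se <- sqrt(2 * 0.5 * 0.5 / 2000)
  expect_true(all(abs(colMeans(dosage(hs)) - 1) < 3 * se + 1e-12))

  hi <- simulateFounders(50, rep(0.999, 50), map, seed = 5)
  expect_gt(mean(hi@hap1), 0.99)

  a <- simulateFounders(10, rep(0.3, 50), map, seed = 9)
  b <- simulateFounders(10, rep(0.3, 50), map, seed = 9)
  expect_identical(a@hap1, b@hap1)
  expect_identical(a@hap2, b@hap2)

  expect_error(simulateFounders(5, rep(1, 50), map), "open interval")
})

test_that("assortative mating calibration matches the target correlation", {
  set.seed(2)
  gm <- rnorm(2000); gf <- rnorm(2000)
  cp0 <- pairMates(gm, gf, rhoAM = 0, seed = 1)
  expect_lt(abs(cor(gm[cp0$mother], gf[cp0$father])), 0.05)

  cp1 <- pairMates(gm, gf, rhoAM = 1, seed = 1)
  r1 <- cor(gm[cp1$mother], gf[cp1$father])
  expect_equal(r1, cor(sort(gm), sort(gf))) # perfect rank matching

  gm5 <- rnorm(5000); gf5 <- rnorm(5000)
  cp4 <- pairMates(gm5, gf5, rhoAM = 0.4, seed = 3)
  expect_lt(abs(cor(gm5[cp4$mother], gf5[cp4$father]) - 0.4), 0.05)

  expect_error(pairMates(rnorm(3), rnorm(4)), "equal size")
})

test_that("meiosis follows the Haldane model", {
  map0 <- buildGeneticMap(1, 20, 0)
  h1 <- rep(0L, 20); h2 <- rep(1L, 20)
  g <- meiosis(h1, h2, map0, seed = 4)
  expect_equal(length(g$crossovers$chr1), 0)
  expect_true(identical(g$gamete, h1) || identical(g$gamete, h2))

  # homozygous parent: gamete invariant to recombination
  map <- buildGeneticMap(1, 30, 200)
  hom <- rep(c(0L, 1L), 15)
  g2 <- meiosis(hom, hom, map, seed = 8)
  expect_identical(g2$gamete, hom)

  # crossover count ~ Poisson(1) on a 100 cM chromosome
  map100 <- buildGeneticMap(1, 5, 100)
  set.seed(11)
  counts <- replicate(4000, length(meiosis(rep(0L, 5), rep(1L, 5),
                                           map100)$crossovers$chr1))
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 4000))
  # chi-square goodness of fit against Poisson(1)
  obs <- table(factor(pmin(counts, 4), levels = 0:4))
  pr <- dpois(0:3, 1); pr <- c(pr, 1 - sum(pr))
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("families are Mendelian-consistent with recorded truth", {
  map <- buildGeneticMap(2, 200, 80)
  freqs <- runif(400, 0.2, 0.8)
  set.seed(21)
  mothers <- simulateFounders(30, freqs, map, prefix = "m")
  fathers <- simulateFounders(30, freqs, map, prefix = "f")
  couples <- pairMates(rnorm(30), rnorm(30), 0)
  fam <- buildFamilies(nurtureR:::.rbindHaps(mothers, fathers), couples,
                       mothers@ids, fathers@ids, nOffspring = 2,
                       pairFraction = 0, seed = 2)
  truth <- fam$truth
  ped <- fam$pedigree
  momOf <- with(ped[ped$role == "mother", ], setNames(individual_id, family_id))
  dadOf <- with(ped[ped$role == "father", ], setNames(individual_id, family_id))
  famOf <- setNames(ped$family_id, ped$individual_id)
  for (k in seq_along(truth@offspringIds)) {
    oid <- truth@offspringIds[k]
    mi <- match(momOf[famOf[oid]], mothers@ids)
    fi <- match(dadOf[famOf[oid]], fathers@ids)
    tm <- ifelse(truth@sourceMother[k, ] == 1L,
                 mothers@hap1[mi, ], mothers@hap2[mi, ])
    tf <- ifelse(truth@sourceFather[k, ] == 1L,
                 fathers@hap1[fi, ], fathers@hap2[fi, ])
    oi <- match(oid, fam$offspring@ids)
    expect_equal(unname(dosage(fam$offspring)[oi, ]), unname(tm + tf))
  }
})

test_that("pair masking respects the configured fractions", {
  map <- buildGeneticMap(1, 50, 50)
  freqs <- rep(0.5, 50)
  mk <- function(pf, fms) {
    set.seed(31)
    mo <- simulateFounders(40, freqs, map, prefix = "m")
    fa <- simulateFounders(40, freqs, map, prefix = "f")
    buildFamilies(nurtureR:::.rbindHaps(mo, fa),
                  pairMates(rnorm(40), rnorm(40), 0), mo@ids, fa@ids,
                  nOffspring = 1, pairFraction = pf,
                  fatherMaskedShare = fms, seed = 3)$pedigree
  }
  ped <- mk(0, 0.5)
  expect_true(all(ped$genotyped))
  ped <- mk(1, 1)
  expect_true(all(!ped$genotyped[ped$role == "father"]))
  expect_true(all(ped$genotyped[ped$role != "father"]))
})

test_that("phenotype generator hits target prevalence and null structure", {
  sim <- simulateDataset(nFamilies = 4000, nChromosomes = 1,
                         markersPerChromosome = 100, lengthCM = 50,
                         nOffspring = 1, seed = 17)
  prev <- mean(sim@phenotypes$smk_init)
  se <- sqrt(0.414 * 0.586 / 4000)
  expect_lt(abs(prev - 0.414), 3 * se + 1 / 4000)
  expect_lt(abs(mean(sim@phenotypes$cannabis_ever) - 0.227),
            3 * sqrt(0.227 * 0.773 / 4000) + 1 / 4000)

  # null generator: outcome uncorrelated with the true score
  nullSim <- simulateDataset(nFamilies = 2000, nChromosomes = 1,
                             markersPerChromosome = 100, lengthCM = 50,
                             nOffspring = 1, seed = 18,
                             params = phenoModelParams(delta = 0, eta_m = 0,
                                                       eta_f = 0, nu_m = 0,
                                                       nu_f = 0))
  r <- cor(nullSim@phenotypes$alc_gday, nullSim@truePheno$zg)
  expect_lt(abs(r), 3 / sqrt(2000))

  # pure transmission: OLS on the latent liability recovers delta
  dsim <- simulateDataset(nFamilies = 4000, nChromosomes = 1,
                          markersPerChromosome = 100, lengthCM = 50,
                          nOffspring = 1, seed = 19,
                          params = phenoModelParams(delta = 0.2, eta_m = 0,
                                                    eta_f = 0, nu_m = 0,
                                                    nu_f = 0))
  tp <- dsim@truePheno
  fit <- lm(liab_smk ~ zg + zp_m + zp_f, data = tp)
  expect_lt(abs(coef(fit)["zg"] - 0.2), 3 * summary(fit)$coefficients["zg", 2])
})

test_that("fixed seed reproduces the dataset exactly", {
  a <- simulateDataset(nFamilies = 15, nChromosomes = 1,
                       markersPerChromosome = 80, nOffspring = NULL,
                       pairFraction = 0.5, seed = 99)
  b <- simulateDataset(nFamilies = 15, nChromosomes = 1,
                       markersPerChromosome = 80, nOffspring = NULL,
                       pairFraction = 0.5, seed = 99)
  expect_identical(a@haplotypes@hap1, b@haplotypes@hap1)
  expect_identical(a@pedigree, b@pedigree)
  expect_identical(a@phenotypes, b@phenotypes)
  expect_identical(a@truth@sourceMother, b@truth@sourceMother)
})

test_that("switch errors preserve dosage and occur at the expected rate", {
  map <- buildGeneticMap(1, 3000, 100)
  n <- 200
  h1 <- matrix(0L, n, 3000); h2 <- matrix(1L, n, 3000) # het everywhere
  rownames(h1) <- rownames(h2) <- paste0("i", 1:n)
  hs <- new("HaplotypeSet", ids = paste0("i", 1:n), map = map,
            hap1 = h1, hap2 = h2)
  expect_identical(addSwitchErrors(hs, 0), hs)

  sw <- addSwitchErrors(hs, 0.001, seed = 12)
  expect_identical(dosage(sw), dosage(hs))
  # with an all-heterozygous individual, each suffix swap is visible as one
  # transition in hap1; mean transitions ~ Binomial(3000, 0.001) mean = 3
  transitions <- apply(sw@hap1, 1, function(x) sum(diff(x) != 0))
  expect_lt(abs(mean(transitions) - 3), 3 * sqrt(3 / n))
  expect_error(addSwitchErrors(hs, 1), "rate")
})
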