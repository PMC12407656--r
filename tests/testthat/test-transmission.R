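test_that("tile partition handles remainders by the half-tile rule", {
  t1 <- tilePartition(450, 150)
  expect_equal(t1$start, c(0, 150, 300))
  expect_equal(t1$end, c(150, 300, 450))
  # remainder 10 < 75 merges into the last tile
  t2 <- tilePartition(160, 150)
  expect_equal(nrow(t2), 1)
  expect_equal(t2$end, 160)
  # short chromosome is a single tile
  t3 <- tilePartition(100, 150)
  expect_equal(t3, data.frame(start = 0L, end = 100L))
  # remainder >= half tile stands alone
  t4 <- tilePartition(380, 150)
  expect_equal(t4$end, c(150, 300, 380))
  expect_error(tilePartition(100, 1), "tileSize")
  # tiles always partition the marker range
  for (nm in c(7, 149, 150, 151, 299, 300, 2999)) {
    tt <- tilePartition(nm, 150)
    expect_equal(tt$start[1], 0)
    expect_equal(tt$end[nrow(tt)], nm)
    if (nrow(tt) > 1) expect_true(all(tt$start[-1] == head(tt$end, -1)))
  }
})

test_that("tile matching finds the source haplotype and honors tie rules", {
  set.seed(41)
  p1 <- rbinom(300, 1, 0.5); p2 <- rbinom(300, 1, 0.5)
  tiles <- tilePartition(300, 150)

  mt <- matchTiles(p1, p1, p2, tiles)
  expect_true(all(mt$source == 1L))
  expect_true(all(mt$mm1 == 0))

  # single crossover exactly at marker 150: tile 1 from hap1, tile 2 hap2
  off <- c(p1[1:150], p2[151:300])
  mt2 <- matchTiles(off, p1, p2, tiles)
  expect_equal(mt2$source, c(1L, 2L))

  # ties keep the previous tile's source and are flagged
  pa <- rep(0L, 300); pb <- rep(0L, 300) # identical haplotypes: all ties
  mt3 <- matchTiles(rep(0L, 300), pa, pb, tiles)
  expect_true(all(mt3$tie))
  expect_true(all(mt3$source == 1L)) # first-tile default then continuity

  # brute-force per-tile argmin oracle on random fixtures
  for (s in 1:5) {
    set.seed(s)
    q1 <- rbinom(300, 1, 0.5); q2 <- rbinom(300, 1, 0.5)
    o <- ifelse(rbinom(300, 1, 0.5) == 1, q1, q2)
    mt4 <- matchTiles(o, q1, q2, tiles, minInformative = 0)
    for (i in seq_len(nrow(tiles))) {
      idx <- (tiles$start[i] + 1):tiles$end[i]
      expect_equal(mt4$mm1[i], sum(o[idx] != q1[idx]))
      expect_equal(mt4$mm2[i], sum(o[idx] != q2[idx]))
      if (mt4$mm1[i] != mt4$mm2[i])
        expect_equal(mt4$source[i], which.min(c(mt4$mm1[i], mt4$mm2[i])))
    }
  }
})

test_that("breakpoint refinement localizes a mid-tile crossover", {
  # fully informative parent (heterozygous everywhere)
  p1 <- rep(0L, 300); p2 <- rep(1L, 300)
  off <- c(rep(0L, 75), rep(1L, 225)) # true crossover after marker 75
  tiles <- tilePartition(300, 150)
  mt <- matchTiles(off, p1, p2, tiles)
  expect_equal(mt$source, c(1L, 2L))
  rf <- refineBreakpoints(mt, off, p1, p2, refine = TRUE)
  expect_equal(rf$cuts, 75)
  expect_equal(rf$source, c(rep(1L, 75), rep(2L, 225)))

  # refinement off leaves the change at the tile boundary
  rf0 <- refineBreakpoints(mt, off, p1, p2, refine = FALSE)
  expect_equal(rf0$cuts, 150)
  expect_equal(rf0$source, c(rep(1L, 150), rep(2L, 150)))

  # partially informative flanks: the cut lands inside the uninformative
  # gap bracketing the true crossover (mid-tile at marker 225 of 450)
  set.seed(5)
  q1 <- rbinom(450, 1, 0.5); q2 <- rbinom(450, 1, 0.5)
  o <- c(q1[1:225], q2[226:450])
  tiles3 <- tilePartition(450, 150)
  mtq <- matchTiles(o, q1, q2, tiles3)
  rfq <- refineBreakpoints(mtq, o, q1, q2)
  het <- which(q1 != q2)
  lo <- max(het[het <= 225]); hi <- min(het[het > 225])
  expect_length(rfq$cuts, 1)
  expect_true(rfq$cuts >= lo && rfq$cuts < hi)

  # no source change: per-marker output equals tile-level assignment
  mt1 <- matchTiles(q1, q1, q2, tiles3)
  rf1 <- refineBreakpoints(mt1, q1, q1, q2)
  expect_equal(length(rf1$cuts), 0)
  expect_true(all(rf1$source == 1L))
})

test_that("parent-of-origin assignment is exact on clean trios", {
  set.seed(6)
  m1 <- rbinom(400, 1, 0.5); m2 <- rbinom(400, 1, 0.5)
  f1 <- rbinom(400, 1, 0.5); f2 <- rbinom(400, 1, 0.5)
  tiles <- tilePartition(400, 150)
  asg <- assignParentOfOrigin(m1, f2, mother = list(h1 = m1, h2 = m2),
                              father = list(h1 = f1, h2 = f2), tiles)
  expect_equal(asg$hapToMother, 1L)
  expect_false(asg$ambiguous)

  # genotypically identical parents cannot be told apart
  asg2 <- assignParentOfOrigin(m1, m2, mother = list(h1 = m1, h2 = m2),
                               father = list(h1 = m1, h2 = m2), tiles)
  expect_true(asg2$ambiguous)
  expect_equal(asg2$hapToMother, 1L) # fixed rule

  # simulated trios, error-free phase: assignment matches simulator truth
  sim <- simulateDataset(nFamilies = 60, nChromosomes = 1,
                         markersPerChromosome = 900, lengthCM = 100,
                         nOffspring = 1, pairFraction = 0, seed = 23)
  tm <- inferTransmission(sim@haplotypes, sim@pedigree)
  truthHap <- vapply(sim@truth@crossovers[tm@offspringIds],
                     function(x) x$maternal_hap, integer(1))
  expect_equal(unname(tm@assignment$hap_to_mother), unname(truthHap))
})

test_that("transmitted plus non-transmitted alleles recover each parent", {
  sim <- simulateDataset(nFamilies = 40, nChromosomes = 2,
                         markersPerChromosome = 450, lengthCM = 90,
                         nOffspring = 2, pairFraction = 0.5, seed = 29)
  tm <- inferTransmission(sim@haplotypes, sim@pedigree)
  ped <- sim@pedigree
  momOf <- with(ped[ped$role == "mother", ],
                setNames(individual_id, family_id))
  dadOf <- with(ped[ped$role == "father", ],
                setNames(individual_id, family_id))
  famOf <- setNames(ped$family_id, ped$individual_id)
  for (i in seq_along(tm@offspringIds)) {
    oid <- tm@offspringIds[i]
    if (tm@motherGenotyped[i]) {
      mi <- match(momOf[famOf[oid]], sim@haplotypes@ids)
      expect_equal(unname(tm@transMother[i, ] + tm@nontransMother[i, ]),
                   unname(dosage(sim@haplotypes)[mi, ]))
    } else {
      expect_true(all(is.na(tm@nontransMother[i, ])))
    }
    if (tm@fatherGenotyped[i]) {
      fi <- match(dadOf[famOf[oid]], sim@haplotypes@ids)
      expect_equal(unname(tm@transFather[i, ] + tm@nontransFather[i, ]),
                   unname(dosage(sim@haplotypes)[fi, ]))
    }
  }
})

test_that("inference is exact without recombination and error-free phase", {
  sim <- simulateDataset(nFamilies = 25, nChromosomes = 1,
                         markersPerChromosome = 400, lengthCM = 0,
                         nOffspring = 1, pairFraction = 0, seed = 31)
  tm <- inferTransmission(sim@haplotypes, sim@pedigree)
  cc <- concordance(tm, sim)
  expect_equal(cc$rate, 1)
  expect_equal(cc$compared, cc$concordant)
})

test_that("pair-mode inference agrees with trio-mode on the shared parent", {
  sim <- simulateDataset(nFamilies = 40, nChromosomes = 1,
                         markersPerChromosome = 1500, lengthCM = 100,
                         nOffspring = 1, pairFraction = 0, seed = 37)
  trioMap <- inferTransmission(sim@haplotypes, sim@pedigree)
  # mask every father to form mother-offspring pairs
  ped <- sim@pedigree
  ped$genotyped[ped$role == "father"] <- FALSE
  pairMap <- inferTransmission(sim@haplotypes, ped)
  agree <- mean(pairMap@nontransMother == trioMap@nontransMother)
  expect_gte(agree, 0.99)
})

test_that("a homozygous parent transmits what it withholds", {
  p <- rep(1L, 200)
  off1 <- rep(1L, 200); off2 <- rbinom(200, 1, 0.5)
  hs <- makeHaps(rbind(off1, p), rbind(off2, p), ids = c("fam1_o1", "mom1"))
  ped <- data.frame(family_id = "fam1",
                    individual_id = c("mom1", "dad1", "fam1_o1"),
                    role = c("mother", "father", "offspring"),
                    genotyped = c(TRUE, FALSE, TRUE), phenotyped = TRUE)
  tm <- suppressWarnings(inferTransmission(hs, ped, tileSize = 100))
  expect_equal(unname(tm@transMother[1, ]), unname(tm@nontransMother[1, ]))
})

test_that("concordance counts flips only at heterozygous parent markers", {
  sim <- simulateDataset(nFamilies = 20, nChromosomes = 1,
                         markersPerChromosome = 600, lengthCM = 50,
                         nOffspring = 1, pairFraction = 0, seed = 43)
  tm <- inferTransmission(sim@haplotypes, sim@pedigree)
  base <- concordance(tm, sim)
  expect_equal(base$rate, 1) # error-free phase, exact marker correction
  # flip the inferred non-transmitted alleles at heterozygous-parent
  # markers: remaining agreement is exactly the homozygous fraction
  ped <- sim@pedigree
  hs <- sim@haplotypes
  momOf <- with(ped[ped$role == "mother", ],
                setNames(individual_id, family_id))
  dadOf <- with(ped[ped$role == "father", ],
                setNames(individual_id, family_id))
  famOf <- setNames(ped$family_id, ped$individual_id)
  flipped <- tm
  hetFrac <- numeric(0)
  for (i in seq_along(tm@offspringIds)) {
    oid <- tm@offspringIds[i]
    mj <- match(momOf[famOf[oid]], hs@ids)
    fj <- match(dadOf[famOf[oid]], hs@ids)
    hetM <- hs@hap1[mj, ] != hs@hap2[mj, ]
    hetF <- hs@hap1[fj, ] != hs@hap2[fj, ]
    flipped@nontransMother[i, hetM] <- 1L - tm@nontransMother[i, hetM]
    flipped@nontransFather[i, hetF] <- 1L - tm@nontransFather[i, hetF]
    hetFrac <- c(hetFrac, mean(hetM), mean(hetF))
  }
  cc <- concordance(flipped, sim)
  expect_equal(cc$rate, 1 - mean(hetFrac), tolerance = 1e-10)
})

test_that("concordance degrades smoothly with phase switch errors", {
  rates <- c(0, 0.003, 0.02)
  avg <- vapply(rates, function(r) {
    mean(vapply(1:3, function(s) {
      sim <- simulateDataset(nFamilies = 30, nChromosomes = 1,
                             markersPerChromosome = 600, lengthCM = 60,
                             nOffspring = 1, pairFraction = 0,
                             switchErrorRate = r, seed = 100 + s)
      tm <- inferTransmission(sim@haplotypes, sim@pedigree)
      concordance(tm, sim)$rate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg) < 0))
  expect_gt(avg[1], 0.99)
})

test_that("ungenotyped offspring are skipped with a warning", {
  sim <- simulateDataset(nFamilies = 4, nChromosomes = 1,
                         markersPerChromosome = 300, nOffspring = 1,
                         pairFraction = 0, seed = 51)
  ped <- sim@pedigree
  ped$genotyped[ped$role == "offspring"][1] <- FALSE
  expect_warning(tm <- inferTransmission(sim@haplotypes[
    ped$individual_id[ped$genotyped]], ped), "skipped")
  expect_equal(length(tm@offspringIds), 3)
})
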