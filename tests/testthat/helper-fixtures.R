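# shared fixture builders (everything generated in code; no stored data)

# a HaplotypeSet built from explicit matrices on an evenly spaced map
makeHaps <- function(h1, h2, lengthCM = 100, ids = NULL) {
  h1 <- rbind(h1); h2 <- rbind(h2)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  map <- buildGeneticMap(1, ncol(h1), lengthCM)
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(h1)))
  rownames(h1) <- rownames(h2) <- ids
  new("HaplotypeSet", ids = ids, map = map, hap1 = h1, hap2 = h2)
}

# uniform weight table matched to a map (effect allele = map alt)
unitWeights <- function(map, w = 1) {
  data.frame(marker_id = map@marker, chrom = map@chrom,
             pos = seq_along(map@marker), effect_allele = map@alt,
             other_allele = map@ref, weight = rep(w, nMarkers(map)),
             stringsAsFactors = FALSE)
}

# direct structural mediation data (no genotypes): known aT, aNT, b, cT, cNT
makeMediationData <- function(n, aT = 0.3, aNT = 0.1, b = 0.4, cT = 0.2,
                              cNT = 0.05, seed = 1) {
  set.seed(seed)
  T <- rnorm(n); NT <- rnorm(n)
  sex <- rbinom(n, 1, 0.5); age <- runif(n, 18, 67)
  M <- aT * T + aNT * NT + 0.05 * sex + rnorm(n)
  Y <- b * M + cT * T + cNT * NT - 0.1 * sex + 0.005 * age + rnorm(n)
  data.frame(pgs_t_std = T, pgs_nt_std = NT, sex = sex, age = age,
             med = M, y = Y, family_id = seq_len(n))
}

zscoreOracle <- function(x) (x - mean(x)) / sd(x)

# brute-force Benjamini-Hochberg step-up oracle
bhOracle <- function(p, m = length(p)) {
  o <- order(p)
  adj <- p[o] * m / seq_along(p)
  adj <- rev(cummin(rev(adj)))
  out <- pmin(adj, 1)
  out[order(o)]
}
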