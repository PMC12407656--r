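#' Partition a chromosome's markers into tiles
#'
#' Consecutive, non-overlapping blocks of \code{tileSize} adjacent markers
#' (0-based half-open index ranges). A trailing remainder shorter than half a
#' tile is merged into the previous tile; otherwise it stands as its own
#' (short) tile. A chromosome shorter than one tile is a single tile.
#'
#' @param nMarkers marker count (>= 1).
#' @param tileSize tile size (>= 2); the default follows the method's
#'   150-adjacent-marker tiles.
#' @return data.frame with integer columns \code{start}, \code{end}
#'   (half-open).
#' @examples
#' tilePartition(450, 150)  # three tiles
#' tilePartition(160, 150)  # one tile [0, 160): remainder 10 < 75 merges
#' @export
tilePartition <- function(nMarkers, tileSize = 150) {
  if (tileSize < 2) stop("tileSize must be >= 2")
  if (nMarkers < 1) stop("nMarkers must be >= 1")
  nFull <- nMarkers %/% tileSize
  rem <- nMarkers %% tileSize
  if (nFull == 0)
    return(data.frame(start = 0L, end = as.integer(nMarkers)))
  starts <- as.integer(seq(0L, by = tileSize, length.out = nFull))
  ends <- starts + as.integer(tileSize)
  if (rem > 0) {
    if (rem < tileSize / 2) {
      ends[nFull] <- as.integer(nMarkers)
    } else {
      starts <- c(starts, as.integer(nFull * tileSize))
      ends <- c(ends, as.integer(nMarkers))
    }
  }
  data.frame(start = starts, end = ends)
}

# genome-wide tile table: per-chromosome tilePartition offset to global
# marker indices, with the chromosome label kept for continuity resets
.tileTable <- function(map, tileSize) {
  out <- list()
  for (ch in unique(map@chrom)) {
    sel <- which(map@chrom == ch)
    t <- tilePartition(length(sel), tileSize)
    t$start <- t$start + sel[1] - 1L
    t$end <- t$end + sel[1] - 1L
    t$chrom <- ch
    out[[ch]] <- t
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Match offspring-haplotype tiles against a parent's two haplotypes
#'
#' Per tile, the Hamming mismatch count of the offspring haplotype against
#' parental haplotype 1 and 2 over non-missing markers, and the assigned
#' source haplotype (argmin). Ties keep the previous tile's assignment
#' (continuity minimizes spurious breakpoints); a tie on the first tile of a
#' chromosome defaults to haplotype 1 and is flagged. Tiles with fewer than
#' \code{minInformative} informative markers (parent heterozygous,
#' non-missing) inherit the nearest preceding informative tile's assignment
#' (leading ones inherit the first informative tile) and are flagged
#' low-information.
#'
#' @param offHap integer allele vector (one offspring haplotype).
#' @param parentHap1,parentHap2 the parent's two haplotype allele vectors.
#' @param tiles tile table (from \code{\link{tilePartition}} or internal
#'   genome-wide construction; optional \code{chrom} column resets the
#'   continuity rule at chromosome starts).
#' @param minInformative informative-marker threshold per tile.
#' @return data.frame: start, end, mm1, mm2, informative, source, tie,
#'   lowInfo.
#' @export
matchTiles <- function(offHap, parentHap1, parentHap2, tiles,
                       minInformative = 10) {
  d1 <- as.integer(!is.na(offHap) & !is.na(parentHap1) &
                     offHap != parentHap1)
  d2 <- as.integer(!is.na(offHap) & !is.na(parentHap2) &
                     offHap != parentHap2)
  het <- as.integer(!is.na(parentHap1) & !is.na(parentHap2) &
                      parentHap1 != parentHap2 & !is.na(offHap))
  c1 <- c(0L, cumsum(d1)); c2 <- c(0L, cumsum(d2)); ci <- c(0L, cumsum(het))
  s <- tiles$start; e <- tiles$end
  mm1 <- c1[e + 1L] - c1[s + 1L]
  mm2 <- c2[e + 1L] - c2[s + 1L]
  info <- ci[e + 1L] - ci[s + 1L]
  nT <- nrow(tiles)
  chrom <- if ("chrom" %in% names(tiles)) tiles$chrom else rep("c", nT)
  src <- integer(nT); tie <- logical(nT)
  prev <- 1L
  for (i in seq_len(nT)) {
    if (i > 1 && chrom[i] != chrom[i - 1]) prev <- 1L
    if (mm1[i] < mm2[i]) src[i] <- 1L
    else if (mm2[i] < mm1[i]) src[i] <- 2L
    else { src[i] <- prev; tie[i] <- TRUE }
    prev <- src[i]
  }
  lowInfo <- info < minInformative
  if (any(lowInfo) && !all(lowInfo)) {
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch)
      li <- lowInfo[sel]
      if (!any(li) || all(li)) next
      # forward fill from the previous informative tile
      last <- NA_integer_
      for (i in seq_along(sel)) {
        if (!li[i]) last <- src[sel[i]]
        else if (!is.na(last)) src[sel[i]] <- last
      }
      # leading low-information tiles inherit the first informative tile
      firstInf <- sel[which(!li)[1]]
      lead <- sel[seq_len(which(!li)[1] - 1)]
      if (length(lead)) src[lead] <- src[firstInf]
    }
  }
  data.frame(start = s, end = e, mm1 = mm1, mm2 = mm2, informative = info,
             source = src, tie = tie, lowInfo = lowInfo,
             stringsAsFactors = FALSE)
}

# genome-wide best-tile mismatch of one offspring haplotype vs one parent
.bestTileCost <- function(offHap, pH1, pH2, tiles) {
  mt <- matchTiles(offHap, pH1, pH2, tiles)
  sum(pmin(mt$mm1, mt$mm2))
}

#' Assign offspring haplotypes to parents
#'
#' Trios: the 2x2 assignment (offspring haplotype 1/2 to mother/father)
#' minimizing total genome-wide best-tile mismatch. Pairs: the offspring
#' haplotype with smaller genome-wide mismatch against the genotyped parent
#' is assigned to that parent. The margin is the mismatch difference between
#' the two assignments; a zero margin falls back to the fixed rule
#' (haplotype 1 to the mother) and is flagged ambiguous.
#'
#' @param offHap1,offHap2 the offspring's two haplotype allele vectors.
#' @param mother,father lists with elements \code{h1}, \code{h2} (parental
#'   haplotype vectors), or NULL for an ungenotyped parent (at least one
#'   required).
#' @param tiles genome-wide tile table.
#' @return list: \code{hapToMother} (1 or 2: which offspring haplotype is
#'   maternal), \code{margin}, \code{ambiguous}.
#' @export
assignParentOfOrigin <- function(offHap1, offHap2, mother = NULL,
                                 father = NULL, tiles) {
  if (is.null(mother) && is.null(father))
    stop("at least one genotyped parent is required")
  if (!is.null(mother) && !is.null(father)) {
    costA <- .bestTileCost(offHap1, mother$h1, mother$h2, tiles) +
      .bestTileCost(offHap2, father$h1, father$h2, tiles)
    costB <- .bestTileCost(offHap2, mother$h1, mother$h2, tiles) +
      .bestTileCost(offHap1, father$h1, father$h2, tiles)
    margin <- abs(costA - costB)
    hapToMother <- if (costA <= costB) 1L else 2L
  } else {
    p <- if (is.null(father)) mother else father
    c1 <- .bestTileCost(offHap1, p$h1, p$h2, tiles)
    c2 <- .bestTileCost(offHap2, p$h1, p$h2, tiles)
    margin <- abs(c1 - c2)
    hapToParent <- if (c1 == c2) {
      # fixed rule: haplotype 1 to the mother
      if (is.null(father)) 1L else 2L
    } else if (c1 < c2) 1L else 2L
    hapToMother <- if (is.null(father)) hapToParent
                   else (3L - hapToParent)
  }
  list(hapToMother = hapToMother, margin = margin, ambiguous = margin == 0)
}

# refine tile-level sources to marker resolution on one chromosome.
# src: per-tile source; tiles: local 0-based tile table for the chromosome;
# d1, d2: per-marker mismatch indicators of the offspring haplotype vs the
# parent's haplotype 1 / 2 (local). Returns list(source = per-marker vector,
# cuts = 0-based local indices of the first marker under each new source).
.refineChrom <- function(src, tiles, d1, d2, refine = TRUE) {
  nm <- tiles$end[nrow(tiles)]
  perMarker <- integer(nm)
  for (i in seq_len(nrow(tiles)))
    perMarker[(tiles$start[i] + 1L):tiles$end[i]] <- src[i]
  changes <- which(diff(src) != 0)
  cuts <- integer(0)
  if (!refine) return(list(source = perMarker,
                           cuts = tiles$start[changes + 1L]))
  prevCut <- 0L
  for (k in changes) {
    a <- max(tiles$start[k], prevCut)
    b <- tiles$end[k + 1L]
    sL <- src[k]; sR <- src[k + 1L]
    dL <- if (sL == 1L) d1 else d2
    dR <- if (sR == 1L) d1 else d2
    L <- b - a
    cumL <- c(0L, cumsum(dL[(a + 1L):b]))
    cumR <- c(0L, cumsum(dR[(a + 1L):b]))
    cost <- cumL + (cumR[L + 1L] - cumR) # cut after j left markers, j=0..L
    j <- which.min(cost) - 1L
    cut <- a + j
    if (cut > a) perMarker[(a + 1L):cut] <- sL
    if (cut < b) perMarker[(cut + 1L):b] <- sR
    cuts <- c(cuts, cut)
    prevCut <- cut
  }
  list(source = perMarker, cuts = cuts)
}

#' Refine tile-boundary breakpoints to marker resolution
#'
#' For each source change between adjacent tiles, scans the union of the two
#' tiles for the change point minimizing total mismatches (left segment
#' matched to the left tile's source haplotype, right segment to the right
#' tile's). With refinement off, changes stay at tile boundaries.
#'
#' @param tileMatch data.frame from \code{\link{matchTiles}} for one
#'   chromosome (local 0-based tile coordinates).
#' @param offHap,parentHap1,parentHap2 local allele vectors.
#' @param refine logical.
#' @return list: \code{source} (per-marker source vector, values 1/2) and
#'   \code{cuts} (0-based indices of the first marker under each new source).
#' @export
refineBreakpoints <- function(tileMatch, offHap, parentHap1, parentHap2,
                              refine = TRUE) {
  d1 <- as.integer(!is.na(offHap) & !is.na(parentHap1) &
                     offHap != parentHap1)
  d2 <- as.integer(!is.na(offHap) & !is.na(parentHap2) &
                     offHap != parentHap2)
  .refineChrom(tileMatch$source, tileMatch[, c("start", "end")], d1, d2,
               refine = refine)
}

#' Infer transmitted and non-transmitted parental alleles
#'
#' For every genotyped offspring with at least one genotyped parent: assigns
#' the offspring's haplotypes to parents (genome-wide best-tile match), then
#' per genotyped parent matches the assigned offspring haplotype tile-by-tile
#' against the parent's two haplotypes, refines source changes to marker
#' resolution, and records the transmitted allele (the source haplotype's
#' allele) and the non-transmitted allele (the other haplotype's). For a
#' parent who is not genotyped, the transmitted alleles are taken as the
#' unassigned offspring haplotype and the non-transmitted alleles are set
#' missing. Offspring without any genotyped parent (or not genotyped
#' themselves) are skipped with a warning.
#'
#' @param haps \linkS4class{HaplotypeSet} of all genotyped individuals.
#' @param pedigree pedigree data.frame (family_id, individual_id, role,
#'   genotyped).
#' @param tileSize tile size in markers (default 150).
#' @param refine refine breakpoints inside tiles (default TRUE).
#' @param minInformative informative-marker threshold per tile.
#' @return a \linkS4class{TransmissionMap}.
#' @export
inferTransmission <- function(haps, pedigree, tileSize = 150, refine = TRUE,
                              minInformative = 10) {
  map <- haps@map
  m <- nMarkers(map)
  tiles <- .tileTable(map, tileSize)
  chroms <- unique(map@chrom)
  chromIdx <- lapply(chroms, function(ch) which(map@chrom == ch))
  names(chromIdx) <- chroms

  off <- pedigree[pedigree$role == "offspring", , drop = FALSE]
  momOf <- with(pedigree[pedigree$role == "mother", ],
                setNames(ifelse(genotyped, individual_id, NA), family_id))
  dadOf <- with(pedigree[pedigree$role == "father", ],
                setNames(ifelse(genotyped, individual_id, NA), family_id))

  keep <- logical(nrow(off))
  for (i in seq_len(nrow(off))) {
    oid <- off$individual_id[i]
    hasParent <- !is.na(momOf[off$family_id[i]]) ||
      !is.na(dadOf[off$family_id[i]])
    if (!off$genotyped[i] || !oid %in% haps@ids) {
      warning("offspring ", oid, " not genotyped; skipped")
    } else if (!hasParent) {
      warning("offspring ", oid, " has no genotyped parent; skipped")
    } else keep[i] <- TRUE
  }
  off <- off[keep, , drop = FALSE]
  n <- nrow(off)

  naMat <- function() matrix(NA_integer_, n, m,
                             dimnames = list(off$individual_id, NULL))
  tM <- naMat(); ntM <- naMat(); tF <- naMat(); ntF <- naMat()
  mGeno <- logical(n); fGeno <- logical(n)
  assign <- data.frame(offspring_id = off$individual_id,
                       hap_to_mother = NA_integer_, margin = NA_real_,
                       ambiguous = FALSE, stringsAsFactors = FALSE)
  bps <- list()

  parentHaps <- function(pid) {
    if (is.na(pid)) return(NULL)
    j <- match(pid, haps@ids)
    list(h1 = haps@hap1[j, ], h2 = haps@hap2[j, ])
  }

  for (i in seq_len(n)) {
    oid <- off$individual_id[i]
    oi <- match(oid, haps@ids)
    o1 <- haps@hap1[oi, ]; o2 <- haps@hap2[oi, ]
    mom <- parentHaps(momOf[off$family_id[i]])
    dad <- parentHaps(dadOf[off$family_id[i]])
    asg <- assignParentOfOrigin(o1, o2, mom, dad, tiles)
    assign$hap_to_mother[i] <- asg$hapToMother
    assign$margin[i] <- asg$margin
    assign$ambiguous[i] <- asg$ambiguous
    oM <- if (asg$hapToMother == 1L) o1 else o2
    oF <- if (asg$hapToMother == 1L) o2 else o1

    doParent <- function(oHap, par, role) {
      trans <- integer(m); nontrans <- integer(m)
      for (ch in chroms) {
        sel <- chromIdx[[ch]]
        lt <- tiles[tiles$chrom == ch, c("start", "end")]
        lt$start <- lt$start - sel[1] + 1L
        lt$end <- lt$end - sel[1] + 1L
        mt <- matchTiles(oHap[sel], par$h1[sel], par$h2[sel], lt,
                         minInformative = minInformative)
        rf <- refineBreakpoints(mt, oHap[sel], par$h1[sel], par$h2[sel],
                                refine = refine)
        src <- rf$source
        # marker-wise correction: the transmitted allele must match the
        # offspring, so where the assigned source mismatches and the parent
        # is heterozygous the other haplotype is the source (fixes, e.g.,
        # double crossovers inside one tile)
        p1 <- par$h1[sel]; p2 <- par$h2[sel]; oh <- oHap[sel]
        cur <- ifelse(src == 1L, p1, p2)
        flip <- !is.na(oh) & !is.na(p1) & !is.na(p2) & p1 != p2 & cur != oh
        src[flip] <- 3L - src[flip]
        trans[sel] <- ifelse(src == 1L, par$h1[sel], par$h2[sel])
        nontrans[sel] <- ifelse(src == 1L, par$h2[sel], par$h1[sel])
        if (length(rf$cuts))
          bps[[length(bps) + 1]] <<- data.frame(
            offspring_id = oid, parent = role, chrom = ch,
            marker_index = rf$cuts + sel[1] - 1L, stringsAsFactors = FALSE)
      }
      list(trans = trans, nontrans = nontrans)
    }

    if (!is.null(mom)) {
      r <- doParent(oM, mom, "mother")
      tM[i, ] <- r$trans; ntM[i, ] <- r$nontrans; mGeno[i] <- TRUE
    } else {
      tM[i, ] <- oM # maternal transmitted = the unassigned offspring hap
    }
    if (!is.null(dad)) {
      r <- doParent(oF, dad, "father")
      tF[i, ] <- r$trans; ntF[i, ] <- r$nontrans; fGeno[i] <- TRUE
    } else {
      tF[i, ] <- oF
    }
  }

  bps <- if (length(bps)) do.call(rbind, bps)
    else data.frame(offspring_id = character(0), parent = character(0),
                    chrom = character(0), marker_index = integer(0))
  new("TransmissionMap", offspringIds = off$individual_id, map = map,
      transMother = tM, nontransMother = ntM,
      transFather = tF, nontransFather = ntF,
      motherGenotyped = mGeno, fatherGenotyped = fGeno,
      assignment = assign, breakpoints = bps)
}

#' Concordance of inferred non-transmitted alleles with simulator truth
#'
#' Compares every non-missing inferred non-transmitted allele of a genotyped
#' parent against the ground truth recorded by the simulator (the allele of
#' the parental haplotype the meiosis did not copy from).
#'
#' @param tmap a \linkS4class{TransmissionMap} inferred from a synthetic
#'   dataset.
#' @param dataset the \linkS4class{SyntheticDataset} the map was inferred
#'   from.
#' @return list: \code{compared}, \code{concordant}, \code{rate} (in [0, 1])
#'   and \code{perChromosome} data.frame.
#' @export
concordance <- function(tmap, dataset) {
  truth <- dataset@truth
  thaps <- dataset@truthHaplotypes
  ids <- intersect(tmap@offspringIds, truth@offspringIds)
  if (!length(ids)) stop("no shared offspring between map and truth")
  ped <- dataset@pedigree
  momOf <- with(ped[ped$role == "mother", ],
                setNames(individual_id, family_id))
  dadOf <- with(ped[ped$role == "father", ],
                setNames(individual_id, family_id))
  famOf <- setNames(ped$family_id, ped$individual_id)

  m <- nMarkers(tmap@map)
  chrom <- tmap@map@chrom
  comp <- conc <- setNames(numeric(length(unique(chrom))), unique(chrom))

  truthNT <- function(oid, role) {
    ti <- match(oid, truth@offspringIds)
    src <- if (role == "mother") truth@sourceMother[ti, ]
           else truth@sourceFather[ti, ]
    pid <- if (role == "mother") momOf[famOf[oid]] else dadOf[famOf[oid]]
    pi <- match(pid, thaps@ids)
    ifelse(src == 1L, thaps@hap2[pi, ], thaps@hap1[pi, ])
  }

  for (oid in ids) {
    i <- match(oid, tmap@offspringIds)
    for (role in c("mother", "father")) {
      inferred <- if (role == "mother") tmap@nontransMother[i, ]
                  else tmap@nontransFather[i, ]
      if (all(is.na(inferred))) next
      tr <- truthNT(oid, role)
      ok <- !is.na(inferred)
      agree <- ok & inferred == tr
      comp <- comp + tapply(as.integer(ok), chrom, sum)[names(comp)]
      conc <- conc + tapply(as.integer(agree), chrom, sum)[names(conc)]
    }
  }
  perChrom <- data.frame(chrom = names(comp), compared = as.numeric(comp),
                         concordant = as.numeric(conc),
                         rate = as.numeric(conc / comp),
                         stringsAsFactors = FALSE)
  list(compared = sum(comp), concordant = sum(conc),
       rate = sum(conc) / sum(comp), perChromosome = perChrom)
}
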