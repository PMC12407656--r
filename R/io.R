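# Readers and writers for the pipeline's tab-separated and VCF-like files.

#' Write a HaplotypeSet as a phased VCF
#'
#' Minimal VCF 4.2 with pipe-separated GT fields, 1-based physical positions
#' (synthetic: marker rank within chromosome x 1000) and the genetic position
#' carried in the INFO field as \code{CM=} so a round-trip preserves the map.
#'
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePhasedVcf <- function(haps, file) {
  map <- haps@map
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic position (cM)\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", haps@ids), collapse = "\t"), con)
  pos <- unlist(lapply(split(seq_along(map@chrom),
                             factor(map@chrom, unique(map@chrom))),
                       seq_along), use.names = FALSE) * 1000L
  gtcode <- function(a) ifelse(is.na(a), ".", as.character(a))
  gt <- matrix(paste(gtcode(t(haps@hap1)), gtcode(t(haps@hap2)), sep = "|"),
               nrow = nMarkers(haps)) # markers x individuals
  lines <- paste(map@chrom, pos, map@marker, map@ref, map@alt, ".", "PASS",
                 sprintf("CM=%.12g", map@posCM), "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(file)
}

#' Read a phased VCF into a HaplotypeSet
#'
#' Parses pipe-phased GT fields; "." allele codes become NA. Genetic
#' positions are taken from a \code{CM=} INFO key when present, else zero.
#'
#' @param file path to an uncompressed VCF.
#' @return a \linkS4class{HaplotypeSet}.
#' @export
readPhasedVcf <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line found")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  f <- strsplit(body, "\t")
  chrom <- vapply(f, `[[`, "", 1)
  marker <- vapply(f, `[[`, "", 3)
  ref <- vapply(f, `[[`, "", 4)
  alt <- vapply(f, `[[`, "", 5)
  info <- vapply(f, `[[`, "", 8)
  cm <- suppressWarnings(as.numeric(sub(".*CM=([0-9eE.+-]+).*", "\\1", info)))
  cm[is.na(cm)] <- 0
  m <- length(f); n <- length(ids)
  h1 <- matrix(NA_integer_, n, m); h2 <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    gt <- vapply(f[[j]][-(1:9)], `[[`, "", 1)
    parts <- strsplit(gt, "|", fixed = TRUE)
    a1 <- vapply(parts, `[[`, "", 1); a2 <- vapply(parts, `[[`, "", 2)
    h1[, j] <- suppressWarnings(as.integer(a1))
    h2[, j] <- suppressWarnings(as.integer(a2))
  }
  rownames(h1) <- rownames(h2) <- ids
  map <- new("GeneticMap", chrom = chrom, marker = marker, posCM = cm,
             ref = ref, alt = alt)
  new("HaplotypeSet", ids = ids, map = map, hap1 = h1, hap2 = h2)
}

#' Write the transmitted and non-transmitted allele datasets
#'
#' Emits two phased-VCF-like files per offspring set — transmitted alleles
#' as \code{maternal|paternal} and non-transmitted alleles likewise, with
#' missing alleles written as "." — plus a breakpoints TSV and a JSON run
#' log.
#'
#' @param tmap a \linkS4class{TransmissionMap}.
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
writeTransmissionDatasets <- function(tmap, prefix) {
  mkHaps <- function(hm, hf) new("HaplotypeSet", ids = tmap@offspringIds,
                                 map = tmap@map, hap1 = hm, hap2 = hf)
  files <- c(transmitted = paste0(prefix, "_transmitted.vcf"),
             nontransmitted = paste0(prefix, "_nontransmitted.vcf"),
             breakpoints = paste0(prefix, "_breakpoints.tsv"),
             log = paste0(prefix, "_run.json"))
  writePhasedVcf(mkHaps(tmap@transMother, tmap@transFather),
                 files["transmitted"])
  writePhasedVcf(mkHaps(tmap@nontransMother, tmap@nontransFather),
                 files["nontransmitted"])
  write.table(tmap@breakpoints, files["breakpoints"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    n_offspring = length(tmap@offspringIds),
    n_markers = nMarkers(tmap@map),
    mothers_genotyped = sum(tmap@motherGenotyped),
    fathers_genotyped = sum(tmap@fatherGenotyped),
    ambiguous_assignments = sum(tmap@assignment$ambiguous),
    n_breakpoints = nrow(tmap@breakpoints)),
    files["log"], auto_unbox = TRUE)
  invisible(files)
}

#' Write / read the pipeline's tab-separated tables
#'
#' Plain UTF-8 TSV with a header row; used for pedigree, phenotype, weight
#' and score tables.
#'
#' @param x data.frame.
#' @param file path.
#' @return the path (writer) or a data.frame (reader).
#' @export
writeTsv <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTsv
#' @export
readTsv <- function(file) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
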