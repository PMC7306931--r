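#' Write / read a haplotype genotype table
#'
#' Lossless TSV round-trip format for \linkS4class{HaplotypeMatrix}: a
#' `#locus_length=` header line, then columns `site_id`, `position` and one
#' 0/1 column per strain (NA for missing calls).
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param path file path.
#' @return `readGenotypeTable` returns a \linkS4class{HaplotypeMatrix};
#'   `writeGenotypeTable` returns `path` invisibly.
#' @export
writeGenotypeTable <- function(H, path) {
  st <- stateMatrix(H)
  df <- data.frame(site_id = sprintf("site%05d", seq_along(sitePositions(H))),
                   position = sitePositions(H), t(st), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#locus_length=%.17g", locusLength(H)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeTable
#' @export
readGenotypeTable <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#locus_length="))
    stop("not a genotype table: missing #locus_length header")
  L <- as.numeric(sub("#locus_length=", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, colClasses = NA)
  strains <- setdiff(colnames(df), c("site_id", "position"))
  st <- t(as.matrix(df[, strains, drop = FALSE]))
  rownames(st) <- strains
  HaplotypeMatrix(st, df$position, L)
}

#' Write / read haplotypes as FASTA
#'
#' One record per strain; segregating sites only, ancestral state written as
#' `A` and derived as `G`, missing as `N`. Positions and locus length are not
#' representable in FASTA: the reader assigns positions 0..S-1 on a locus of
#' length S unless `positions`/`locusLength` are supplied. Use
#' [writeGenotypeTable()] for a lossless round trip.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param path file path.
#' @param positions,locusLength optional coordinates for the reader.
#' @return `readHaplotypeFasta` returns a \linkS4class{HaplotypeMatrix};
#'   the writer returns `path` invisibly.
#' @export
writeHaplotypeFasta <- function(H, path) {
  st <- stateMatrix(H)
  chars <- matrix("A", nrow(st), ncol(st))
  chars[st == 1L] <- "G"
  chars[is.na(st)] <- "N"
  seqs <- Biostrings::DNAStringSet(apply(chars, 1L, paste0, collapse = ""))
  if (ncol(st) == 0L)
    seqs <- Biostrings::DNAStringSet(rep("", nrow(st)))
  names(seqs) <- rownames(st)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeHaplotypeFasta
#' @export
readHaplotypeFasta <- function(path, positions = NULL, locusLength = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  m <- do.call(rbind, strsplit(as.character(seqs), ""))
  if (is.null(m)) stop("empty FASTA")
  st <- matrix(NA_integer_, length(seqs), ncol(m))
  st[m == "A"] <- 0L
  st[m == "G"] <- 1L
  rownames(st) <- names(seqs)
  if (is.null(positions)) positions <- seq_len(ncol(st)) - 1L
  if (is.null(locusLength)) locusLength <- max(ncol(st), 1L)
  HaplotypeMatrix(st, positions, locusLength)
}

#' Write / read a gene presence/absence matrix
#'
#' TSV with genomes as rows and family ids as columns, 0/1 entries.
#'
#' @param M a \linkS4class{GenePAMatrix}.
#' @param path file path.
#' @return `readPAMatrix` returns a \linkS4class{GenePAMatrix}; the writer
#'   returns `path` invisibly.
#' @export
writePAMatrix <- function(M, path) {
  utils::write.table(paMatrix(M), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname writePAMatrix
#' @export
readPAMatrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  GenePAMatrix(m)
}

#' Write / read a sample metadata table
#'
#' TSV with columns strain_id, pond, environment, clade.
#'
#' @param meta metadata data.frame.
#' @param path file path.
#' @return `readMetadata` returns the validated data.frame; the writer
#'   returns `path` invisibly.
#' @export
writeMetadata <- function(meta, path) {
  validateMetadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetadata
#' @export
readMetadata <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  validateMetadata(meta)
  meta
}

#' Write / read a recombination-event list
#'
#' TSV with columns event_id, strain_a, strain_b and optional family_id /
#' category. Alternatively the file may carry an event per row with a
#' comma-separated `strains` column (as multi-sequence detectors report);
#' such events are decomposed into all unordered pairs on read.
#'
#' @param events event data.frame.
#' @param path file path.
#' @return `readEventList` returns an event data.frame with one strain pair
#'   per row; the writer returns `path` invisibly.
#' @export
writeEventList <- function(events, path) {
  ev <- events
  attr(ev, "planted_truth") <- NULL
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventList
#' @export
readEventList <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if ("strains" %in% colnames(df)) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      ss <- sort(strsplit(df$strains[i], ",")[[1L]])
      if (length(ss) < 2L) return(NULL)
      pr <- utils::combn(ss, 2L)
      out <- data.frame(event_id = df$event_id[i], strain_a = pr[1L, ],
                        strain_b = pr[2L, ], stringsAsFactors = FALSE)
      if ("family_id" %in% colnames(df)) out$family_id <- df$family_id[i]
      out
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
  }
  df
}

#' Write / read a planted-truth sidecar
#'
#' JSON serialization of a generator's `plantedTruth()` list.
#'
#' @param truth list of planted parameters.
#' @param path file path.
#' @return `readPlantedTruth` returns the list; the writer returns `path`
#'   invisibly.
#' @export
writePlantedTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writePlantedTruth
#' @export
readPlantedTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a square distance matrix
#'
#' TSV with ids as both header row and first column.
#'
#' @param D distance matrix.
#' @param path file path.
#' @return `readDistanceMatrix` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
writeDistanceMatrix <- function(D, path) {
  utils::write.table(D, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1L, check.names = FALSE))
}

#' Write a SNP dataset as a minimal VCF-like site file
#'
#' Haploid genotypes; CHROM is the alignment, POS is 1-based (VCF dialect;
#' the package uses 0-based positions internally), REF is the majority
#' allele, ALT the minor allele(s), GT indexes REF=0/ALT=1, `.` missing.
#'
#' @param S a \linkS4class{SNPDataset}.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(S, path) {
  calls <- snpCalls(S)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=strainscape",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(rownames(calls), collapse = "\t"))), con)
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    tab <- sort(table(x[!is.na(x)]), decreasing = TRUE)
    ref <- names(tab)[1L]
    alt <- setdiff(names(tab), ref)
    gt <- ifelse(is.na(x), ".", match(x, c(ref, alt)) - 1L)
    writeLines(paste(c("alignment", sitePositions(S)[j] + 1L,
                       sprintf("snp%05d", j), ref,
                       paste(alt, collapse = ","), ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}
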