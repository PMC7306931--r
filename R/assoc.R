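#' Extract SNPs from a multiple alignment
#'
#' Emits alignment columns with at least two distinct unambiguous bases
#' (A/C/G/T, case-insensitive). Gaps and ambiguity codes are recorded as
#' missing calls. Positions are 0-based alignment columns.
#'
#' @param alignment a `Biostrings::DNAStringSet` of equal-length sequences,
#'   or a character matrix (samples x columns).
#' @param meta optional metadata table (see [validateMetadata()]); row order
#'   is matched to the alignment by strain id when provided.
#' @return A \linkS4class{SNPDataset}.
#' @export
extractSnps <- function(alignment, meta = data.frame()) {
  if (inherits(alignment, "DNAStringSet") ||
      inherits(alignment, "BStringSet")) {
    if (length(unique(Biostrings::width(alignment))) > 1L)
      stop("ragged alignment: sequences differ in length")
    m <- do.call(rbind, strsplit(as.character(alignment), ""))
    rownames(m) <- names(alignment)
  } else if (is.matrix(alignment)) {
    m <- alignment
  } else stop("alignment must be a DNAStringSet or a character matrix")
  if (nrow(m) < 2L) stop("need >= 2 samples")
  m <- toupper(m)
  m[!m %in% c("A", "C", "G", "T")] <- NA_character_
  nAll <- apply(m, 2L, function(x) length(unique(x[!is.na(x)])))
  keep <- which(nAll >= 2L)
  if (nrow(meta)) {
    validateMetadata(meta)
    if (!setequal(meta$strain_id, rownames(m)))
      stop("metadata strains do not match alignment names")
    meta <- meta[match(rownames(m), meta$strain_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  SNPDataset(m[, keep, drop = FALSE], positions = keep - 1L, meta = meta)
}

#' Keep biallelic sites
#'
#' Retains sites with exactly two distinct alleles among non-missing calls.
#' Idempotent.
#'
#' @param S a \linkS4class{SNPDataset}.
#' @return A filtered \linkS4class{SNPDataset}.
#' @export
filterBiallelic <- function(S) {
  calls <- snpCalls(S)
  nAll <- apply(calls, 2L, function(x) length(unique(x[!is.na(x)])))
  .subset_sites(S, which(nAll == 2L))
}

#' Filter on minor allele frequency and carrier count
#'
#' Drops sites whose minor-allele frequency over non-missing calls is below
#' `maf`, or whose minor allele is carried by fewer than `minCarriers`
#' samples. Sites at exactly the MAF threshold are kept (removal is strictly
#' below threshold); set `keepAtThreshold = FALSE` for the strict reading.
#'
#' @param S a biallelic \linkS4class{SNPDataset}.
#' @param maf minimum minor allele frequency (default 0.05).
#' @param minCarriers minimum samples carrying the minor allele (default 3).
#' @param keepAtThreshold keep sites with MAF exactly equal to `maf`
#'   (default TRUE).
#' @return A filtered \linkS4class{SNPDataset}.
#' @export
filterMaf <- function(S, maf = 0.05, minCarriers = 3L,
                      keepAtThreshold = TRUE) {
  calls <- snpCalls(S)
  keep <- vapply(seq_len(ncol(calls)), function(j) {
    x <- calls[!is.na(calls[, j]), j]
    tab <- sort(table(x))
    minor <- tab[1L]
    f <- minor / length(x)
    mafOk <- if (keepAtThreshold) f >= maf else f > maf
    mafOk && minor >= minCarriers
  }, logical(1))
  .subset_sites(S, which(keep))
}

.subset_sites <- function(S, idx) {
  SNPDataset(snpCalls(S)[, idx, drop = FALSE],
             positions = sitePositions(S)[idx], meta = sampleMeta(S),
             metadata = S@metadata)
}

#' Private alleles per group
#'
#' An allele at a site is private to group g when it is observed in at least
#' one sample of g and in no sample of any other group.
#'
#' @param S a \linkS4class{SNPDataset}.
#' @param grouping metadata column: "pond", "environment" or "clade".
#' @return list with `counts` (named, per group) and `mean` across groups.
#' @export
privateAlleles <- function(S, grouping = c("pond", "environment", "clade")) {
  grouping <- match.arg(grouping)
  meta <- sampleMeta(S)
  if (!grouping %in% colnames(meta)) stop("unknown grouping field: ", grouping)
  g <- as.character(meta[[grouping]])
  lev <- sort(unique(g))
  calls <- snpCalls(S)
  counts <- stats::setNames(numeric(length(lev)), lev)
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    ok <- !is.na(x)
    for (a in unique(x[ok])) {
      inGroups <- unique(g[ok & x == a])
      if (length(inGroups) == 1L)
        counts[inGroups] <- counts[inGroups] + 1
    }
  }
  list(counts = counts, mean = mean(counts))
}

#' Fisher-exact SNP-environment association
#'
#' Per biallelic site, a 2x2 table of allele counts (one allele observation
#' per haploid sample) by environment is tested with the two-sided Fisher
#' exact test (point-probability summation); p-values are
#' Bonferroni-adjusted over the sites actually tested. Sites with all calls
#' missing in one environment are excluded and recorded.
#'
#' @param S a biallelic \linkS4class{SNPDataset} whose metadata has exactly
#'   two environment levels.
#' @param alpha significance level on the adjusted p (default 0.01).
#' @param midP use the mid-p variant (default FALSE).
#' @return list with `result` (data.frame: site, position, alleles, p,
#'   p_adj, significant), `m` (sites tested), `excluded` (site indices).
#' @export
fisherAssoc <- function(S, alpha = 0.01, midP = FALSE) {
  meta <- sampleMeta(S)
  env <- as.character(meta$environment)
  lev <- sort(unique(env))
  if (length(lev) != 2L) stop("need exactly 2 environment levels")
  calls <- snpCalls(S)
  nSites <- ncol(calls)
  p <- rep(NA_real_, nSites)
  alleleLab <- character(nSites)
  excluded <- integer(0)
  for (j in seq_len(nSites)) {
    x <- calls[, j]
    ok <- !is.na(x)
    if (!any(ok & env == lev[1L]) || !any(ok & env == lev[2L])) {
      excluded <- c(excluded, j)
      next
    }
    al <- sort(unique(x[ok]))
    if (length(al) != 2L) stop("site ", j, " is not biallelic")
    alleleLab[j] <- paste(al, collapse = "/")
    tab <- table(factor(x[ok], levels = al), factor(env[ok], levels = lev))
    p[j] <- if (midP) .fisher_midp(tab) else
      stats::fisher.test(tab)$p.value
  }
  tested <- setdiff(seq_len(nSites), excluded)
  m <- length(tested)
  pAdj <- pmin(1, p * m)
  res <- data.frame(site = tested, position = sitePositions(S)[tested],
                    alleles = alleleLab[tested], p = p[tested],
                    p_adj = pAdj[tested],
                    significant = pAdj[tested] < alpha,
                    stringsAsFactors = FALSE)
  list(result = res, m = m, excluded = excluded, alpha = alpha)
}

# two-sided mid-p: half the observed table's point probability
.fisher_midp <- function(tab) {
  x <- tab[1L, 1L]
  m <- sum(tab[, 1L]); n <- sum(tab[, 2L]); k <- sum(tab[1L, ])
  supp <- max(0L, k - n):min(k, m)
  pr <- stats::dhyper(supp, m, n, k)
  obs <- stats::dhyper(x, m, n, k)
  sum(pr[pr < obs * (1 - 1e-7)]) + obs / 2
}

#' Map significant SNPs into fixed windows
#'
#' Bins positions into half-open windows `[k*w, (k+1)*w)` (0-based
#' coordinates, default 1 kb) and reports the occupied windows. Gene families
#' whose half-open intervals overlap an occupied window are attached.
#'
#' @param positions significant SNP positions (0-based).
#' @param window window size in bp (default 1000).
#' @param annotations optional data.frame of gene intervals: family_id,
#'   start, end (0-based, half-open).
#' @param alignmentLength optional upper bound; positions beyond it error.
#' @return list with `windows` (data.frame: window index, start, end,
#'   n_snps, families), `nWindows` (occupied count) and `families`
#'   (distinct overlapping family ids).
#' @export
mapWindows <- function(positions, window = 1000L, annotations = NULL,
                       alignmentLength = NULL) {
  if (window <= 0) stop("window must be positive")
  if (!is.null(alignmentLength) && length(positions) &&
      max(positions) >= alignmentLength)
    stop("positions beyond the alignment length")
  if (!length(positions)) {
    return(list(windows = data.frame(window = integer(0), start = numeric(0),
                                     end = numeric(0), n_snps = integer(0),
                                     families = character(0)),
                nWindows = 0L, families = character(0)))
  }
  if (any(positions < 0)) stop("positions must be >= 0")
  w <- floor(positions / window)
  occ <- sort(unique(w))
  nsnp <- vapply(occ, function(k) sum(w == k), integer(1))
  famPer <- rep("", length(occ))
  allFam <- character(0)
  if (!is.null(annotations) && nrow(annotations)) {
    winR <- IRanges::IRanges(start = occ * window + 1L, width = window)
    annR <- IRanges::IRanges(start = annotations$start + 1L,
                             end = annotations$end)
    hits <- IRanges::findOverlaps(winR, annR)
    fh <- split(annotations$family_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(fh)) famPer[as.integer(q)] <-
      paste(sort(unique(fh[[q]])), collapse = ",")
    allFam <- sort(unique(annotations$family_id[S4Vectors::subjectHits(hits)]))
  }
  list(windows = data.frame(window = occ, start = occ * window,
                            end = (occ + 1) * window, n_snps = nsnp,
                            families = famPer, stringsAsFactors = FALSE),
       nWindows = length(occ), families = allFam)
}
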