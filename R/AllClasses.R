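#' @import methods
NULL

#' Binary haplotype matrix from an infinite-sites locus
#'
#' Strains-by-sites matrix of 0 (ancestral) / 1 (derived) states, with the
#' site positions on a locus of length `locusLength`. `NA` encodes a missing
#' call. Under the infinite-sites model every segregating site records exactly
#' one historical mutation.
#'
#' @slot states integer matrix, strains in rows (rownames are strain ids),
#'   segregating sites in columns; entries 0, 1 or NA.
#' @slot positions numeric, strictly increasing site positions in
#'   `[0, locusLength)`.
#' @slot locusLength numeric(1), locus length in bp.
#' @slot metadata list of free-form annotations (e.g. planted ground truth).
#' @export
setClass("HaplotypeMatrix",
  slots = c(states = "matrix", positions = "numeric",
            locusLength = "numeric", metadata = "list"))

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  st <- object@states
  if (ncol(st) != length(object@positions))
    msg <- c(msg, "ncol(states) must equal length(positions)")
  if (length(object@locusLength) != 1L || object@locusLength <= 0)
    msg <- c(msg, "locusLength must be a single positive number")
  if (anyNA(object@positions) ||
      (length(object@positions) > 1L && any(diff(object@positions) <= 0)))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@positions) &&
      (min(object@positions) < 0 || max(object@positions) >= object@locusLength))
    msg <- c(msg, "positions must lie in [0, locusLength)")
  vals <- st[!is.na(st)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "states must be 0, 1 or NA")
  if (is.null(rownames(st)) || anyDuplicated(rownames(st)))
    msg <- c(msg, "states must have unique rownames (strain ids)")
  if (length(msg)) msg else TRUE
})

#' Gene-family presence/absence matrix
#'
#' The pan-genome substrate: genomes in rows, gene families in columns,
#' entries 0/1. No family may be absent from every genome.
#'
#' @slot pa integer matrix with unique row (genome) and column (family) names.
#' @slot metadata list of free-form annotations.
#' @export
setClass("GenePAMatrix",
  slots = c(pa = "matrix", metadata = "list"))

setValidity("GenePAMatrix", function(object) {
  msg <- character()
  pa <- object@pa
  if (!all(pa %in% c(0L, 1L))) msg <- c(msg, "entries must be 0 or 1")
  if (is.null(rownames(pa)) || anyDuplicated(rownames(pa)))
    msg <- c(msg, "genome ids (rownames) must be unique and present")
  if (is.null(colnames(pa)) || anyDuplicated(colnames(pa)))
    msg <- c(msg, "family ids (colnames) must be unique and present")
  if (ncol(pa) && any(colSums(pa) == 0))
    msg <- c(msg, "no family may be absent from all genomes")
  if (length(msg)) msg else TRUE
})

#' SNP dataset with per-sample metadata
#'
#' Samples-by-sites matrix of allele calls (single characters, `NA` missing),
#' 0-based alignment positions, and a metadata table with one row per sample
#' (columns `strain_id`, `pond`, `environment`, `clade`). Every retained site
#' has at least two distinct observed alleles.
#'
#' @slot calls character matrix, samples in rows (rownames are strain ids).
#' @slot positions numeric, strictly increasing 0-based site positions.
#' @slot meta data.frame of per-sample metadata, rows aligned with `calls`.
#' @slot metadata list of free-form annotations (e.g. planted ground truth).
#' @export
setClass("SNPDataset",
  slots = c(calls = "matrix", positions = "numeric", meta = "data.frame",
            metadata = "list"))

setValidity("SNPDataset", function(object) {
  msg <- character()
  cl <- object@calls
  if (ncol(cl) != length(object@positions))
    msg <- c(msg, "ncol(calls) must equal length(positions)")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (is.null(rownames(cl)) || anyDuplicated(rownames(cl)))
    msg <- c(msg, "sample ids (rownames) must be unique and present")
  if (nrow(object@meta) && nrow(object@meta) != nrow(cl))
    msg <- c(msg, "meta must have one row per sample")
  if (ncol(cl)) {
    nall <- apply(cl, 2L, function(x) length(unique(x[!is.na(x)])))
    if (any(nall < 2L))
      msg <- c(msg, "every site must have >= 2 observed alleles")
  }
  if (length(msg)) msg else TRUE
})

#' Rejection-ABC posterior summary
#'
#' @slot accepted data.frame of accepted draws: one column per parameter,
#'   the simulated summary statistics and the standardized distance.
#' @slot posteriorMedian named numeric, per-parameter posterior median.
#' @slot ci95 numeric matrix (2 x P), 2.5 and 97.5 percentiles per parameter.
#' @slot nSims integer(1), number of simulations performed.
#' @slot tol numeric(1), acceptance proportion.
#' @slot priors list of prior specifications used.
#' @slot stage1 the first-stage \linkS4class{AbcResult} for two-stage runs,
#'   or NULL.
#' @export
setClass("AbcResult",
  slots = c(accepted = "data.frame", posteriorMedian = "numeric",
            ci95 = "matrix", nSims = "integer", tol = "numeric",
            priors = "list", stage1 = "ANY"))

setValidity("AbcResult", function(object) {
  msg <- character()
  if (nrow(object@accepted) != ceiling(object@tol * object@nSims))
    msg <- c(msg, "accepted set size must be ceiling(tol * nSims)")
  if (object@tol <= 0 || object@tol > 1)
    msg <- c(msg, "tol must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Heaps-law fit of pan-genome openness
#'
#' New-family discovery is modelled as `kappa * N^(-alpha)` for the N-th
#' genome added in random order. `alpha > 1` means a closed pan-genome,
#' `alpha < 1` an open one. A matrix with no new families beyond the first
#' genome yields the degenerate closed fit (`alpha = Inf`, `kappa = NA`).
#'
#' @slot kappa numeric(1), fitted intercept (expected new families at N = 1).
#' @slot alpha numeric(1), fitted decay exponent.
#' @slot classification "open" or "closed".
#' @slot nPermutations integer(1), genome orderings used.
#' @slot nPoints integer(1), (permutation, position) points entering the fit.
#' @slot zeroFraction numeric(1), fraction of N >= 2 points with zero new
#'   families (excluded from the log-log fit).
#' @export
setClass("HeapsFit",
  slots = c(kappa = "numeric", alpha = "numeric", classification = "character",
            nPermutations = "integer", nPoints = "integer",
            zeroFraction = "numeric"))

setValidity("HeapsFit", function(object) {
  msg <- character()
  if (!object@classification %in% c("open", "closed"))
    msg <- c(msg, "classification must be 'open' or 'closed'")
  closed <- !is.na(object@alpha) && object@alpha > 1
  if ((object@classification == "closed") != closed)
    msg <- c(msg, "classification must be 'closed' iff alpha > 1")
  if (!is.na(object@kappa) && object@kappa <= 0)
    msg <- c(msg, "kappa must be positive")
  if (length(msg)) msg else TRUE
})
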