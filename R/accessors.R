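#' Construct a HaplotypeMatrix
#'
#' @param states 0/1/NA matrix, strains in rows.
#' @param positions site positions in `[0, locusLength)`.
#' @param locusLength locus length in bp.
#' @param strainIds optional strain ids (defaults to existing rownames or
#'   `hap1..hapN`).
#' @param metadata list of annotations.
#' @return A \linkS4class{HaplotypeMatrix}.
#' @export
HaplotypeMatrix <- function(states, positions, locusLength,
                            strainIds = NULL, metadata = list()) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (!is.null(strainIds)) rownames(states) <- strainIds
  if (is.null(rownames(states)))
    rownames(states) <- paste0("hap", seq_len(nrow(states)))
  colnames(states) <- NULL
  new("HaplotypeMatrix", states = states, positions = as.numeric(positions),
      locusLength = as.numeric(locusLength), metadata = metadata)
}

#' Construct a GenePAMatrix
#'
#' @param pa 0/1 matrix, genomes in rows, gene families in columns.
#' @param metadata list of annotations.
#' @return A \linkS4class{GenePAMatrix}.
#' @export
GenePAMatrix <- function(pa, metadata = list()) {
  pa <- as.matrix(pa)
  storage.mode(pa) <- "integer"
  if (is.null(rownames(pa))) rownames(pa) <- paste0("g", seq_len(nrow(pa)))
  if (is.null(colnames(pa))) colnames(pa) <- paste0("fam", seq_len(ncol(pa)))
  new("GenePAMatrix", pa = pa, metadata = metadata)
}

#' Construct a SNPDataset
#'
#' @param calls character matrix of allele calls, samples in rows, NA missing.
#' @param positions 0-based site positions, strictly increasing.
#' @param meta per-sample metadata data.frame (see [sampleMetadata()]).
#' @param metadata list of annotations.
#' @return A \linkS4class{SNPDataset}.
#' @export
SNPDataset <- function(calls, positions, meta = data.frame(),
                       metadata = list()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(rownames(calls)) && nrow(meta))
    rownames(calls) <- meta$strain_id
  new("SNPDataset", calls = calls, positions = as.numeric(positions),
      meta = meta, metadata = metadata)
}

#' @rdname strainIds
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' Strain / sample / genome identifiers
#'
#' @param x a package data object.
#' @return Character vector of ids.
#' @export
setMethod("strainIds", "HaplotypeMatrix", function(x) rownames(x@states))

#' @rdname strainIds
#' @export
setMethod("strainIds", "SNPDataset", function(x) rownames(x@calls))

#' @rdname strainIds
#' @export
setMethod("strainIds", "GenePAMatrix", function(x) rownames(x@pa))

#' @rdname sitePositions
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' Site positions
#' @param x a \linkS4class{HaplotypeMatrix} or \linkS4class{SNPDataset}.
#' @return Numeric positions (0-based alignment coordinates).
#' @export
setMethod("sitePositions", "HaplotypeMatrix", function(x) x@positions)

#' @rdname sitePositions
#' @export
setMethod("sitePositions", "SNPDataset", function(x) x@positions)

#' @rdname stateMatrix
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' Underlying matrices
#' @param x a package data object.
#' @return The 0/1 state matrix, presence/absence matrix, or call matrix.
#' @export
setMethod("stateMatrix", "HaplotypeMatrix", function(x) x@states)

#' @rdname stateMatrix
#' @export
setGeneric("paMatrix", function(x) standardGeneric("paMatrix"))

#' @rdname stateMatrix
#' @export
setMethod("paMatrix", "GenePAMatrix", function(x) x@pa)

#' @rdname stateMatrix
#' @export
setGeneric("snpCalls", function(x) standardGeneric("snpCalls"))

#' @rdname stateMatrix
#' @export
setMethod("snpCalls", "SNPDataset", function(x) x@calls)

#' @rdname locusLength
#' @export
setGeneric("locusLength", function(x) standardGeneric("locusLength"))

#' Locus length in bp
#' @param x a \linkS4class{HaplotypeMatrix}.
#' @return numeric(1).
#' @export
setMethod("locusLength", "HaplotypeMatrix", function(x) x@locusLength)

#' @rdname sampleMeta
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' Per-sample metadata table
#' @param x a \linkS4class{SNPDataset}.
#' @return data.frame with strain_id, pond, environment, clade.
#' @export
setMethod("sampleMeta", "SNPDataset", function(x) x@meta)

#' @rdname plantedTruth
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' Planted ground truth of a synthetic object
#'
#' Generators record the parameters they planted (true Ne, Heaps alpha,
#' associated site indices, category rates) under `metadata$planted_truth`.
#'
#' @param x a synthetic data object.
#' @return A list, or NULL if the object carries no planted truth.
#' @export
setMethod("plantedTruth", "HaplotypeMatrix", function(x) x@metadata$planted_truth)

#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "GenePAMatrix", function(x) x@metadata$planted_truth)

#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "SNPDataset", function(x) x@metadata$planted_truth)

#' @rdname posteriorMedian
#' @export
setGeneric("posteriorMedian", function(x) standardGeneric("posteriorMedian"))

#' ABC posterior summaries
#' @param x an \linkS4class{AbcResult}.
#' @return Named numeric of per-parameter posterior medians, or a 2 x P matrix
#'   of 95% credible bounds.
#' @export
setMethod("posteriorMedian", "AbcResult", function(x) x@posteriorMedian)

#' @rdname posteriorMedian
#' @export
setGeneric("credibleInterval", function(x) standardGeneric("credibleInterval"))

#' @rdname posteriorMedian
#' @export
setMethod("credibleInterval", "AbcResult", function(x) x@ci95)

#' @rdname posteriorMedian
#' @export
setGeneric("acceptedDraws", function(x) standardGeneric("acceptedDraws"))

#' @rdname posteriorMedian
#' @export
setMethod("acceptedDraws", "AbcResult", function(x) x@accepted)

#' @rdname heapsAlpha
#' @export
setGeneric("heapsAlpha", function(x) standardGeneric("heapsAlpha"))

#' Heaps-law fit components
#' @param x a \linkS4class{HeapsFit}.
#' @return The decay exponent alpha, the intercept kappa, or the
#'   open/closed classification.
#' @export
setMethod("heapsAlpha", "HeapsFit", function(x) x@alpha)

#' @rdname heapsAlpha
#' @export
setGeneric("heapsKappa", function(x) standardGeneric("heapsKappa"))

#' @rdname heapsAlpha
#' @export
setMethod("heapsKappa", "HeapsFit", function(x) x@kappa)

#' @rdname heapsAlpha
#' @export
setGeneric("openness", function(x) standardGeneric("openness"))

#' @rdname heapsAlpha
#' @export
setMethod("openness", "HeapsFit", function(x) x@classification)

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix:", nrow(object@states), "haplotypes x",
      ncol(object@states), "segregating sites on a",
      format(object@locusLength, big.mark = ","), "bp locus\n")
})

setMethod("show", "GenePAMatrix", function(object) {
  cat("GenePAMatrix:", nrow(object@pa), "genomes x", ncol(object@pa),
      "gene families\n")
})

setMethod("show", "SNPDataset", function(object) {
  cat("SNPDataset:", nrow(object@calls), "samples x", ncol(object@calls),
      "variant sites\n")
  if (nrow(object@meta))
    cat("  metadata:", paste(colnames(object@meta), collapse = ", "), "\n")
})

setMethod("show", "AbcResult", function(object) {
  cat("AbcResult:", object@nSims, "simulations, tol =", object@tol,
      if (!is.null(object@stage1)) "(two-stage)" else "", "\n")
  for (p in names(object@posteriorMedian)) {
    cat(sprintf("  %s: median %.4g, 95%% CI [%.4g, %.4g]\n", p,
                object@posteriorMedian[[p]], object@ci95[1L, p],
                object@ci95[2L, p]))
  }
})

setMethod("show", "HeapsFit", function(object) {
  cat(sprintf("HeapsFit: kappa = %.4f, alpha = %.4f -> %s pan-genome (%d permutations)\n",
              object@kappa, object@alpha, object@classification,
              object@nPermutations))
})
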