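#' Partition gene families into core, accessory and unique
#'
#' Core families are present in at least `ceiling(coreFraction * G)` of the
#' G genomes ("at least 95%" by default, a lower bound, hence the ceiling);
#' unique families are present in exactly one genome; accessory families are
#' the rest. Core wins over accessory when both definitions apply, so the
#' partition is exhaustive and disjoint.
#'
#' @param M a \linkS4class{GenePAMatrix}.
#' @param coreFraction minimum presence fraction for core (default 0.95).
#' @return list with `partition` (factor per family: core/accessory/unique),
#'   `counts` (named counts incl. total) and `threshold` (genomes needed for
#'   core).
#' @export
classifyFamilies <- function(M, coreFraction = 0.95) {
  pa <- paMatrix(M)
  G <- nrow(pa)
  if (G < 1L || ncol(pa) < 1L) stop("empty presence/absence matrix")
  thr <- ceiling(coreFraction * G)
  pres <- colSums(pa)
  part <- ifelse(pres >= thr, "core", ifelse(pres == 1L, "unique", "accessory"))
  part <- factor(part, levels = c("core", "accessory", "unique"))
  names(part) <- colnames(pa)
  counts <- c(table(part), total = ncol(pa))
  list(partition = part, counts = counts, threshold = thr)
}

#' Gene accumulation under random genome orderings
#'
#' For each of `nPerm` random orderings of the genomes, counts the gene
#' families first seen at each position N; the per-permutation counts sum to
#' the pan-genome size.
#'
#' @param M a \linkS4class{GenePAMatrix}.
#' @param nPerm number of random orderings (default 1000).
#' @param seed optional integer seed.
#' @return Integer matrix `nPerm x G` of new-family counts by position.
#' @export
geneAccumulation <- function(M, nPerm = 1000L, seed = NULL) {
  pa <- paMatrix(M)
  G <- nrow(pa)
  if (G < 2L) stop("need >= 2 genomes")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Fam <- ncol(pa)
  out <- matrix(0L, nPerm, G)
  # first-seen position of family f in ordering = min rank over genomes
  # carrying f; computed as a column max of rank-reversed weights
  wbase <- G:1
  for (p in seq_len(nPerm)) {
    ord <- sample.int(G)
    wp <- pa[ord, , drop = FALSE] * wbase
    tw <- t(wp)
    idx <- max.col(tw, ties.method = "first")
    firstpos <- G + 1L - as.integer(tw[cbind(seq_len(Fam), idx)])
    out[p, ] <- tabulate(firstpos, nbins = G)
  }
  out
}

#' Fit the Heaps decay to accumulation counts
#'
#' Models the number of new gene families contributed by the N-th genome as
#' `kappa * N^(-alpha)` and fits it by least squares of `log(count)` on
#' `log(N)` over the pooled (permutation, position) points with N >= 2,
#' excluding zero counts (log-undefined); their fraction is recorded. When
#' (almost) all points beyond the first genome are zero the fit is the
#' degenerate closed pan-genome (`alpha = Inf`). `alpha > 1` classifies the
#' pan-genome as closed, `alpha < 1` as open.
#'
#' @param accumulation matrix from [geneAccumulation()].
#' @param degenerateZeroFraction fraction of zero points at N >= 2 beyond
#'   which the degenerate closed fit is returned (default 0.95).
#' @return A \linkS4class{HeapsFit}.
#' @export
fitHeaps <- function(accumulation, degenerateZeroFraction = 0.95) {
  G <- ncol(accumulation)
  if (G < 2L) stop("need >= 2 order positions")
  nPerm <- nrow(accumulation)
  counts <- as.vector(accumulation[, -1L, drop = FALSE])
  N <- rep(2L:G, each = nPerm)
  zeroFrac <- mean(counts == 0L)
  pos <- counts > 0L
  if (!any(pos) || zeroFrac >= degenerateZeroFraction ||
      length(unique(N[pos])) < 2L) {
    return(new("HeapsFit", kappa = NA_real_, alpha = Inf,
               classification = "closed", nPermutations = as.integer(nPerm),
               nPoints = sum(pos), zeroFraction = zeroFrac))
  }
  x <- log(N[pos]); y <- log(counts[pos])
  fit <- stats::lsfit(x, y)
  alpha <- -unname(fit$coefficients[2L])
  kappa <- exp(unname(fit$coefficients[1L]))
  new("HeapsFit", kappa = kappa, alpha = alpha,
      classification = if (alpha > 1) "closed" else "open",
      nPermutations = as.integer(nPerm), nPoints = as.integer(sum(pos)),
      zeroFraction = zeroFrac)
}

#' Heaps openness of a presence/absence matrix
#'
#' Convenience wrapper: [geneAccumulation()] then [fitHeaps()].
#'
#' @inheritParams geneAccumulation
#' @inheritParams fitHeaps
#' @return A \linkS4class{HeapsFit}.
#' @export
heapsFit <- function(M, nPerm = 1000L, seed = NULL,
                     degenerateZeroFraction = 0.95) {
  fitHeaps(geneAccumulation(M, nPerm, seed), degenerateZeroFraction)
}

#' Openness robustness by k-genome subsampling
#'
#' Each replicate samples `k` genomes without replacement, drops families
#' absent from all of them, and fits the Heaps decay on that submatrix using
#' all (or up to `nPermSub`) orderings. Returns the alpha distribution and
#' the majority open/closed call (degenerate closed fits count as closed).
#'
#' @param M a \linkS4class{GenePAMatrix}.
#' @param k genomes per replicate (default 3).
#' @param reps replicates (default 1000).
#' @param nPermSub orderings per replicate (default 6 = all orderings of 3).
#' @param seed optional integer seed.
#' @return list with `alpha` (numeric, possibly Inf), `calls` (factor),
#'   `majority` ("open"/"closed") and `openFraction`.
#' @export
subsampleAlpha <- function(M, k = 3L, reps = 1000L, nPermSub = 6L,
                           seed = NULL) {
  pa <- paMatrix(M)
  G <- nrow(pa)
  if (G < k) stop("fewer genomes than the subsample size")
  if (!is.null(seed)) set.seed(seed)
  alpha <- numeric(reps)
  calls <- character(reps)
  for (r in seq_len(reps)) {
    rows <- sample.int(G, k)
    sub <- pa[rows, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0L, drop = FALSE]
    subM <- new("GenePAMatrix", pa = sub, metadata = list())
    fit <- fitHeaps(geneAccumulation(subM, nPerm = nPermSub))
    alpha[r] <- fit@alpha
    calls[r] <- fit@classification
  }
  openFrac <- mean(calls == "open")
  list(alpha = alpha, calls = factor(calls, levels = c("open", "closed")),
       majority = if (openFrac > 0.5) "open" else "closed",
       openFraction = openFrac)
}

#' Pan-genome summary table
#'
#' One row per group: genome count, core/flexible(accessory)/unique/total
#' family counts and the fitted Heaps intercept and alpha.
#'
#' @param M a \linkS4class{GenePAMatrix}.
#' @param group group label.
#' @param nPerm orderings for the Heaps fit.
#' @param coreFraction core presence threshold.
#' @param seed optional integer seed.
#' @return A one-row data.frame.
#' @export
pangenomeTable <- function(M, group = NA_character_, nPerm = 1000L,
                           coreFraction = 0.95, seed = NULL) {
  cl <- classifyFamilies(M, coreFraction)
  fit <- heapsFit(M, nPerm, seed)
  data.frame(group = group, genomes = nrow(paMatrix(M)),
             core = unname(cl$counts["core"]),
             flexible = unname(cl$counts["accessory"]),
             unique = unname(cl$counts["unique"]),
             total = unname(cl$counts["total"]),
             intercept = fit@kappa, alpha = fit@alpha,
             classification = fit@classification, stringsAsFactors = FALSE)
}
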