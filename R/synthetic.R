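#' Generate a sample-metadata table
#'
#' Emulates the study design: strains sampled from `nPonds` ponds in two
#' habitats (water, sediment), assigned to clades round-robin.
#'
#' @param nStrains number of strains.
#' @param nPonds ponds (default 9).
#' @param environments habitat levels (default water/sediment).
#' @param clades clade labels to cycle through (default I..VI).
#' @param seed optional integer seed.
#' @return data.frame with strain_id, pond, environment, clade.
#' @export
genSampleMetadata <- function(nStrains, nPonds = 9L,
                              environments = c("water", "sediment"),
                              clades = c("I", "II", "III", "IV", "V", "VI"),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meta <- data.frame(
    strain_id = sprintf("strain%03d", seq_len(nStrains)),
    pond = sample(seq_len(nPonds), nStrains, replace = TRUE),
    environment = sample(environments, nStrains, replace = TRUE),
    clade = rep_len(clades, nStrains),
    stringsAsFactors = FALSE)
  validateMetadata(meta)
  meta
}

#' Generate neutral haplotypes
#'
#' Constant-size neutral coalescent haplotypes: delegates to
#' [simulateLocus()] with a single-population demography.
#'
#' @param n sample count (>= 1).
#' @param ne effective population size.
#' @param mu per-site per-generation mutation rate.
#' @param L locus length in bp.
#' @param seed optional integer seed.
#' @return A \linkS4class{HaplotypeMatrix}; `plantedTruth()` records the
#'   generating parameters.
#' @export
genNeutralHaplotypes <- function(n, ne, mu = 2.2e-10, L, seed = NULL) {
  if (n < 1 || ne <= 0 || mu <= 0 || L <= 0)
    stop("parameters must be positive (n >= 1)")
  cfg <- demographyConfig("single", ne = ne, sampleSizes = n, mu = mu, L = L)
  H <- simulateLocus(cfg, seed)
  H@metadata$planted_truth <- list(true_ne = ne, mu = mu, L = L, n = n)
  H
}

# P(family present in exactly m of G genomes is first seen at order position
# N) for a uniformly random genome subset of size m and a uniformly random
# ordering: the first N-1 positions all miss the family, position N hits it.
.first_seen_prob <- function(G) {
  H <- matrix(0, G, G)
  for (m in seq_len(G)) {
    for (N in seq_len(G - m + 1L)) {
      H[N, m] <- exp(lchoose(G - m, N - 1L) - lchoose(G, N - 1L)) *
        m / (G - N + 1L)
    }
  }
  H
}

# non-negative least squares by cyclic coordinate descent; the design matrix
# here is small (G x G) and ill-conditioned, which trips Lawson-Hanson
# implementations, while coordinate descent is robust
.nnls <- function(A, b, iters = 2000L, tol = 1e-12) {
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  x <- rep(0, ncol(A))
  d <- diag(AtA)
  for (it in seq_len(iters)) {
    delta <- 0
    for (m in which(d > 0)) {
      new <- max(0, x[m] + (Atb[m] - sum(AtA[m, ] * x)) / d[m])
      delta <- max(delta, abs(new - x[m]))
      x[m] <- new
    }
    if (delta < tol * (1 + max(x))) break
  }
  x
}

# solve a non-negative presence-count spectrum f (expected families per
# presence class m) so that the expected first-discovery curve is
# kappa * N^(-alpha) at every order position N; memoized (deterministic)
.spectrum_cache <- new.env(parent = emptyenv())

.heaps_spectrum <- function(G, kappa, alpha) {
  key <- paste(G, kappa, alpha, sep = "|")
  hit <- .spectrum_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- .first_seen_prob(G)
  target <- kappa * seq_len(G)^(-alpha)
  f <- .nnls(H, target)
  f[f < 1e-12] <- 0
  .spectrum_cache[[key]] <- f
  f
}

#' Generate a pan-genome presence/absence matrix with planted Heaps decay
#'
#' Core families are present in every genome. Accessory families are drawn
#' from a Poisson family-size spectrum: the number of families present in
#' exactly m genomes is Poisson with a mean solved so that the expected
#' number of families first seen by the N-th genome equals
#' `kappa * N^(-alpha)` under every genome ordering (each family occupies a
#' uniformly random genome subset of its size, so the matrix is
#' exchangeable). In particular the first genome contributes `kappa`
#' accessory families in expectation and genome N introduces a
#' Poisson(kappa * N^(-alpha)) number of previously unseen families.
#' `kappa = 0` (or `accessory = FALSE`) yields the degenerate closed
#' pan-genome of identical genomes.
#'
#' @param nGenomes genomes (>= 3).
#' @param coreSize core families (default 1254, a realistic core size for a
#'   46-genome Vibrionaceae collection).
#' @param kappa expected new families from the first genome (default 1000,
#'   the order of magnitude of fitted pan-genome intercepts in such
#'   collections).
#' @param alpha planted Heaps decay exponent (> 0).
#' @param accessory set FALSE for the "alpha = infinity" limit with no
#'   accessory genome at all.
#' @param seed optional integer seed.
#' @return A \linkS4class{GenePAMatrix}; `plantedTruth()` records
#'   `true_alpha` and `kappa`.
#' @export
genPangenomeMatrix <- function(nGenomes, coreSize = 1254L, kappa = 1000,
                               alpha = 1, accessory = TRUE, seed = NULL) {
  if (nGenomes < 3L) stop("need >= 3 genomes")
  if (coreSize < 0) stop("coreSize must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  if (!is.null(seed)) set.seed(seed)
  G <- as.integer(nGenomes)
  acc <- NULL
  if (accessory && kappa > 0) {
    f <- .heaps_spectrum(G, kappa, alpha)
    nFam <- stats::rpois(G, f)  # families per presence-class m = 1..G
    cols <- vector("list", sum(nFam))
    idx <- 0L
    for (m in seq_len(G)) {
      for (i in seq_len(nFam[m])) {
        idx <- idx + 1L
        col <- integer(G)
        col[sample.int(G, m)] <- 1L
        cols[[idx]] <- col
      }
    }
    if (idx > 0L) acc <- do.call(cbind, cols[seq_len(idx)])
  }
  core <- matrix(1L, G, coreSize)
  pa <- cbind(core, acc)
  if (ncol(pa) == 0L) stop("empty pan-genome: no core and no accessory")
  rownames(pa) <- sprintf("genome%02d", seq_len(G))
  colnames(pa) <- c(sprintf("core%05d", seq_len(coreSize)),
                    if (!is.null(acc)) sprintf("acc%05d", seq_len(ncol(acc))))
  GenePAMatrix(pa, metadata = list(planted_truth = list(
    true_alpha = if (accessory && kappa > 0) alpha else Inf,
    kappa = kappa, core_size = coreSize)))
}

#' Generate a SNP dataset with planted environment associations
#'
#' Background sites draw one shared derived-allele frequency per site from
#' `Uniform(mafFloor, 1 - mafFloor)`. Each of the `nAssoc` planted sites gets
#' water and sediment frequencies differing by exactly `effect`, with the
#' water frequency drawn uniformly over the interval that keeps both group
#' frequencies in `[0, 1]` and the pooled frequency inside
#' `[mafFloor, 1 - mafFloor]` (so planted sites pass a MAF filter at
#' `mafFloor`); at `effect = 1` this forces complete separation (0 vs 1).
#' Sites that come out monomorphic are redrawn so every site is a SNP.
#'
#' @param metadata sample metadata (see [validateMetadata()]); needs two
#'   environment levels.
#' @param nSites total sites.
#' @param nAssoc planted associated sites (<= nSites).
#' @param effect allele-frequency difference between environments, in
#'   `[0, 1]`.
#' @param mafFloor frequency floor (default 0.05).
#' @param alleles two allele labels (ancestral, derived).
#' @param seed optional integer seed.
#' @return A \linkS4class{SNPDataset}; `plantedTruth()$associated_sites`
#'   holds the planted site indices (1-based columns).
#' @export
genSnpDataset <- function(metadata, nSites, nAssoc = 0L, effect = 0,
                          mafFloor = 0.05, alleles = c("A", "G"),
                          seed = NULL) {
  validateMetadata(metadata)
  if (nAssoc > nSites) stop("nAssoc must be <= nSites")
  if (effect < 0 || effect > 1) stop("effect must be in [0, 1]")
  env <- as.character(metadata$environment)
  lev <- sort(unique(env))
  if (length(lev) < 2L) stop("need >= 2 environment levels in metadata")
  if (length(lev) > 2L) stop("need exactly 2 environment levels")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(metadata)
  isWater <- env == lev[2L]  # lev = sort(c("sediment","water"))
  assocIdx <- if (nAssoc > 0) sort(sample.int(nSites, nAssoc)) else integer(0)
  calls <- matrix(alleles[1L], n, nSites)
  loWater <- max(0, mafFloor - effect / 2)
  hiWater <- min(1 - effect, 1 - mafFloor - effect / 2)
  if (hiWater < loWater) {  # interval empty: clamp to the nearest point
    loWater <- hiWater <- max(0, min(1 - effect, 0.5 - effect / 2))
  }
  for (j in seq_len(nSites)) {
    planted <- j %in% assocIdx
    repeat {
      if (planted) {
        pw <- stats::runif(1, loWater, hiWater)
        ps <- pw + effect
        freq <- ifelse(isWater, pw, ps)
      } else {
        freq <- rep(stats::runif(1, mafFloor, 1 - mafFloor), n)
      }
      x <- stats::rbinom(n, 1L, freq)
      if (any(x == 1L) && any(x == 0L)) break  # keep every site polymorphic
    }
    calls[x == 1L, j] <- alleles[2L]
  }
  rownames(calls) <- metadata$strain_id
  SNPDataset(calls, positions = seq_len(nSites) - 1L, meta = metadata,
             metadata = list(planted_truth = list(
               associated_sites = assocIdx, effect = effect,
               maf_floor = mafFloor)))
}

#' Generate recombination events with planted category rates
#'
#' Draws a Poisson(rate) number of events per category (SPSE, SPDE, DPSE,
#' DPDE); each event names a uniformly chosen strain pair whose metadata
#' satisfies the category definition. A positive rate for a category with no
#' eligible pair is a design error.
#'
#' @param metadata sample metadata (see [validateMetadata()]).
#' @param rates named numeric: expected event counts for SPSE, SPDE, DPSE
#'   and DPDE (all four required, >= 0).
#' @param seed optional integer seed.
#' @return data.frame with event_id, strain_a, strain_b, category (the
#'   planted category, for round-trip checks) and attribute
#'   `planted_truth` holding the drawn per-category counts.
#' @export
genRecombEvents <- function(metadata, rates, seed = NULL) {
  validateMetadata(metadata)
  cats <- c("SPSE", "SPDE", "DPSE", "DPDE")
  if (!all(cats %in% names(rates))) stop("rates must name all four categories")
  if (any(rates[cats] < 0)) stop("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(metadata)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  samePond <- metadata$pond[pairs[, 1L]] == metadata$pond[pairs[, 2L]]
  sameEnv <- metadata$environment[pairs[, 1L]] ==
    metadata$environment[pairs[, 2L]]
  catOf <- ifelse(samePond, ifelse(sameEnv, "SPSE", "SPDE"),
                  ifelse(sameEnv, "DPSE", "DPDE"))
  out <- list()
  drawn <- stats::setNames(integer(4), cats)
  for (k in cats) {
    elig <- which(catOf == k)
    nk <- stats::rpois(1L, rates[[k]])
    if (nk > 0L && !length(elig))
      stop("category ", k, " has rate > 0 but no eligible strain pair")
    drawn[k] <- nk
    if (nk > 0L) {
      pick <- elig[sample.int(length(elig), nk, replace = TRUE)]
      out[[k]] <- data.frame(
        strain_a = metadata$strain_id[pairs[pick, 1L]],
        strain_b = metadata$strain_id[pairs[pick, 2L]],
        category = k, stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(strain_a = character(0), strain_b = character(0),
               category = character(0), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev <- cbind(event_id = if (nrow(ev)) sprintf("ev%05d", seq_len(nrow(ev)))
              else character(0), ev, stringsAsFactors = FALSE)
  attr(ev, "planted_truth") <- list(category_rates = rates[cats],
                                    drawn_counts = drawn)
  ev
}
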