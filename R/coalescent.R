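#' Demography configuration for the coalescent simulator
#'
#' Two demographies are supported. `"single"`: one constant-size haploid
#' population of size `ne`. `"split"`: two or more sub-populations of size
#' `ne` each, whose lineages coalesce internally until the deme's divergence
#' time `tDiv` (generations), then join an ancestral pool of size `neAnc`
#' (default `ne`) that coalesces to the root. Coalescence rate for k lineages
#' in a pool of size N is `choose(k, 2) / N` (haploid scaling), so the
#' per-site diversity parameter is `theta = 2 * ne * mu`.
#'
#' @param model "single" or "split".
#' @param ne effective population size per extant deme (individuals).
#' @param sampleSizes integer vector of sampled lineages per deme (length 1
#'   for the single model).
#' @param mu per-site per-generation mutation rate (default 2.2e-10, the
#'   E. coli rate conventionally applied to environmental bacteria).
#' @param L locus length in bp.
#' @param tDiv divergence time in generations per deme (split model only).
#' @param neAnc ancestral pool size (split model; default `ne`).
#' @return A validated `DemographyConfig` list.
#' @export
demographyConfig <- function(model = c("single", "split"), ne, sampleSizes,
                             mu = 2.2e-10, L, tDiv = NULL, neAnc = ne) {
  model <- match.arg(model)
  sampleSizes <- as.integer(sampleSizes)
  if (any(sampleSizes < 0) || sum(sampleSizes) < 1)
    stop("need at least one sampled lineage")
  if (ne <= 0 || neAnc <= 0) stop("population sizes must be positive")
  if (mu <= 0) stop("mutation rate must be positive")
  if (L <= 0) stop("locus length must be positive")
  if (model == "single") {
    if (length(sampleSizes) != 1L)
      stop("single model takes one sample size")
    tDiv <- numeric(0)
  } else {
    if (length(sampleSizes) < 2L)
      stop("split model needs >= 2 demes")
    if (is.null(tDiv) || length(tDiv) != length(sampleSizes))
      stop("split model needs one tDiv per deme")
    if (any(tDiv < 0)) stop("divergence times must be >= 0")
  }
  structure(list(model = model, ne = ne, neAnc = neAnc,
                 sampleSizes = sampleSizes, tDiv = as.numeric(tDiv),
                 mu = mu, L = as.numeric(L)),
            class = "DemographyConfig")
}

.deme_labels <- function(sampleSizes) {
  n <- sum(sampleSizes)
  if (length(sampleSizes) == 1L) return(rep(1L, n))
  rep(seq_along(sampleSizes), sampleSizes)
}

.strain_ids <- function(sampleSizes) {
  if (length(sampleSizes) == 1L) return(paste0("s", seq_len(sampleSizes)))
  unlist(lapply(seq_along(sampleSizes), function(d)
    paste0("d", d, "_s", seq_len(sampleSizes[d]))))
}

# parent/time arrays (0-based, tips first) -> ape phylo with branch lengths
# in generations
.tree_to_phylo <- function(parent, time, n, tipLabels) {
  if (n < 2L) stop("need >= 2 lineages for a genealogy")
  m <- 2L * n - 1L
  mapId <- function(v) ifelse(v < n, v + 1L, n + 1L + (m - 1L - v))
  child <- 0:(m - 2L)
  edge <- cbind(mapId(parent[child + 1L]), mapId(child))
  len <- time[parent[child + 1L] + 1L] - time[child + 1L]
  tr <- list(edge = edge, edge.length = len, tip.label = tipLabels,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a coalescent genealogy
#'
#' Draws one genealogy under the configured demography. In the single model,
#' while k >= 2 lineages remain, an Exponential(choose(k,2)/ne) waiting time
#' is drawn and a uniformly random pair merges. In the split model each deme
#' coalesces internally until its divergence time, when its surviving
#' lineages join the ancestral pool.
#'
#' @param config a [demographyConfig()].
#' @param seed optional integer seed.
#' @return An `ape::phylo` tree with branch lengths in generations and the
#'   deme of each tip in `attr(tree, "deme")`.
#' @export
simulateGenealogy <- function(config, seed = NULL) {
  stopifnot(inherits(config, "DemographyConfig"))
  if (!is.null(seed)) set.seed(seed)
  g <- cpp_sim_genealogy(config$sampleSizes, config$ne, config$neAnc,
                         config$tDiv)
  tr <- .tree_to_phylo(g$parent, g$time, g$n, .strain_ids(config$sampleSizes))
  attr(tr, "deme") <- .deme_labels(config$sampleSizes)
  tr
}

# tips below the child node of each edge
.edge_descendants <- function(tree) {
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  kids <- vector("list", m)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  desc <- vector("list", m)
  tipsUnder <- function(v) {
    if (!is.null(desc[[v]])) return(desc[[v]])
    out <- if (v <= n) v else unlist(lapply(kids[[v]], tipsUnder))
    desc[[v]] <<- out
    out
  }
  lapply(tree$edge[, 2L], tipsUnder)
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Each branch of length t receives Poisson(mu * L * t) mutations; every
#' mutation creates a new segregating site at a uniform position in `[0, L)`
#' whose derived state is carried by all tips descending from that branch.
#'
#' @param tree an `ape::phylo` genealogy with branch lengths in generations.
#' @param mu per-site per-generation mutation rate.
#' @param L locus length in bp.
#' @param seed optional integer seed.
#' @return A \linkS4class{HaplotypeMatrix}.
#' @export
dropMutations <- function(tree, mu, L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (mu < 0 || L <= 0) stop("mu must be >= 0 and L > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  nmut <- stats::rpois(length(tree$edge.length), mu * L * tree$edge.length)
  total <- sum(nmut)
  states <- matrix(0L, n, total)
  rownames(states) <- tree$tip.label
  if (total > 0L) {
    desc <- .edge_descendants(tree)
    col <- 0L
    for (e in seq_along(nmut)) {
      if (nmut[e] == 0L) next
      for (j in seq_len(nmut[e])) {
        col <- col + 1L
        states[desc[[e]], col] <- 1L
      }
    }
    positions <- stats::runif(total, 0, L)
    o <- order(positions)
    states <- states[, o, drop = FALSE]
    positions <- positions[o]
  } else {
    positions <- numeric(0)
  }
  HaplotypeMatrix(states, positions, L)
}

#' Simulate a locus: genealogy plus infinite-sites mutations
#'
#' Composition of [simulateGenealogy()] and [dropMutations()], run in
#' compiled code for speed. For a fixed seed the output is reproducible.
#'
#' @param config a [demographyConfig()].
#' @param seed optional integer seed.
#' @return A \linkS4class{HaplotypeMatrix}; `metadata$deme` records each
#'   strain's deme.
#' @export
simulateLocus <- function(config, seed = NULL) {
  stopifnot(inherits(config, "DemographyConfig"))
  if (sum(config$sampleSizes) < 1) stop("need at least one lineage")
  if (!is.null(seed)) set.seed(seed)
  sim <- cpp_simulate_locus(config$sampleSizes, config$ne, config$neAnc,
                            config$tDiv, config$mu, config$L)
  states <- sim$states
  rownames(states) <- .strain_ids(config$sampleSizes)
  HaplotypeMatrix(states, sim$positions, config$L,
                  metadata = list(deme = .deme_labels(config$sampleSizes)))
}
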