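#' Nei (1972) genetic distance between groups
#'
#' From per-locus allele-frequency profiles, `D(x, y) = -log(Jxy /
#' sqrt(Jx * Jy))` where `Jx`, `Jy` and `Jxy` are the within- and
#' between-group homozygosity/identity terms averaged over loci
#' (`J = mean over loci of sum over alleles of p * q`). Groups sharing no
#' alleles at any locus get an infinite-distance sentinel (`Inf`).
#'
#' @param freqs named list, one element per group; each element a list of
#'   per-locus numeric vectors of allele frequencies. All groups must have
#'   the same loci with the same allele sets, each summing to 1.
#' @return A symmetric matrix with zero diagonal and attribute
#'   `metric = "nei"`.
#' @export
neiDistance <- function(freqs) {
  ng <- length(freqs)
  if (ng < 2L) stop("need >= 2 groups")
  if (is.null(names(freqs))) names(freqs) <- paste0("group", seq_len(ng))
  nl <- length(freqs[[1L]])
  for (g in freqs) {
    if (length(g) != nl) stop("groups must share the same loci")
    for (l in seq_len(nl)) {
      if (abs(sum(g[[l]]) - 1) > 1e-8)
        stop("allele frequencies must sum to 1 at every locus")
    }
  }
  J <- function(x, y) mean(vapply(seq_len(nl),
    function(l) sum(x[[l]] * y[[l]]), numeric(1)))
  D <- matrix(0, ng, ng, dimnames = list(names(freqs), names(freqs)))
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
    jxy <- J(freqs[[i]], freqs[[j]])
    d <- if (jxy <= 0) Inf
         else -log(jxy / sqrt(J(freqs[[i]], freqs[[i]]) *
                              J(freqs[[j]], freqs[[j]])))
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "metric") <- "nei"
  D
}

#' Per-group allele frequencies of a SNP dataset
#'
#' Helper to feed [neiDistance()]: per grouping level and site, the
#' frequencies of all alleles observed at that site across the whole dataset
#' (zero for alleles absent from a group), using non-missing calls.
#'
#' @param S a \linkS4class{SNPDataset}.
#' @param grouping metadata column to group by (default "clade").
#' @return Named list of per-group lists of per-site frequency vectors.
#' @export
alleleFrequencies <- function(S, grouping = "clade") {
  meta <- sampleMeta(S)
  if (!grouping %in% colnames(meta)) stop("unknown grouping field: ", grouping)
  calls <- snpCalls(S)
  groups <- split(seq_len(nrow(calls)), meta[[grouping]])
  alleles <- lapply(seq_len(ncol(calls)), function(j)
    sort(unique(calls[!is.na(calls[, j]), j])))
  lapply(groups, function(rows) {
    lapply(seq_len(ncol(calls)), function(j) {
      x <- calls[rows, j]
      x <- x[!is.na(x)]
      p <- vapply(alleles[[j]], function(a) mean(x == a), numeric(1))
      if (!length(x)) p[] <- NA_real_
      p
    })
  })
}

#' Bitwise SNP distance
#'
#' Pairwise proportion of sites with differing alleles among
#' pairwise-complete sites. Pairs with no complete site get `NA` (a
#' missing-distance sentinel).
#'
#' @param S a \linkS4class{SNPDataset} or a \linkS4class{HaplotypeMatrix}.
#' @return A symmetric matrix with zero diagonal and attribute
#'   `metric = "bitwise"`.
#' @export
bitwiseDistance <- function(S) {
  x <- if (is(S, "SNPDataset")) snpCalls(S) else stateMatrix(S)
  n <- nrow(x)
  if (n < 2L) stop("need >= 2 samples")
  D <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    D[i, j] <- D[j, i] <-
      if (!any(ok)) NA_real_ else mean(x[i, ok] != x[j, ok])
  }
  attr(D, "metric") <- "bitwise"
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the output tree is ultrametric, with node
#' heights equal to half the merge distance. Ties are broken by lexicographic
#' pair order.
#'
#' @param D symmetric distance matrix with ids as dimnames.
#' @return An `ape::phylo` tree.
#' @export
upgmaTree <- function(D) {
  .check_dist(D)
  o <- order(rownames(D))
  D <- D[o, o, drop = FALSE]
  ape::as.phylo(stats::hclust(stats::as.dist(D), method = "average"))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei Q-criterion agglomeration (via `ape::nj`); unrooted. On
#' additive distances the generating tree is recovered exactly.
#'
#' @param D symmetric distance matrix with ids as dimnames, >= 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
njTree <- function(D) {
  .check_dist(D)
  if (nrow(D) < 3L) stop("neighbour joining needs >= 3 taxa")
  ape::nj(stats::as.dist(D))
}

.check_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("need a square matrix")
  if (anyNA(D) || any(!is.finite(D)))
    stop("distance matrix contains missing or infinite sentinels")
  if (any(abs(D - t(D)) > 1e-12)) stop("distance matrix must be symmetric")
  if (is.null(rownames(D))) stop("distance matrix needs ids as dimnames")
  invisible(TRUE)
}

#' Group samples at a distance threshold
#'
#' Single-linkage reading of "grouped below a distance threshold": connected
#' components of the graph with an edge wherever `d < t`. With
#' `linkage = "complete"`, groups are instead cut from the complete-linkage
#' dendrogram at height `t`. Group labels are deterministic: groups are
#' numbered by their smallest member id.
#'
#' @param D symmetric distance matrix with ids as dimnames.
#' @param t grouping threshold (default 0.001, the sub-clade convention for
#'   Nei distances).
#' @param linkage "single" (default) or "complete".
#' @return Named integer vector of group labels.
#' @export
thresholdGroups <- function(D, t = 0.001, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (t <= 0) stop("threshold must be positive")
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("need a square matrix")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(D)))
  n <- nrow(D)
  if (linkage == "complete") {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    grp <- stats::cutree(hc, h = t)
  } else {
    # connected components via label propagation
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        dij <- D[i, j]
        if (!is.na(dij) && dij < t && grp[i] != grp[j]) {
          g <- min(grp[i], grp[j])
          grp[grp == grp[i] | grp == grp[j]] <- g
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # renumber by smallest member id (lexicographic)
  first <- vapply(split(ids, grp), min, character(1))
  out <- match(as.character(grp), names(sort(first)))
  names(out) <- ids
  out
}

#' Validate a sample metadata table
#'
#' @param meta data.frame with columns strain_id, pond, environment, clade.
#' @return The table, invisibly, after checks.
#' @export
validateMetadata <- function(meta) {
  need <- c("strain_id", "pond", "environment", "clade")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$strain_id)) stop("strain ids must be unique")
  for (col in need) {
    v <- as.character(meta[[col]])
    if (anyNA(v) || any(v == "")) stop("empty values in column ", col)
  }
  invisible(meta)
}

#' Classify recombination events by pond and environment
#'
#' Each pairwise event lands in exactly one of four categories by whether the
#' two strains share a pond and an environment: SPSE (same pond, same
#' environment), SPDE, DPSE, DPDE. Events naming more than two strains should
#' be decomposed into unordered pairs first (see [readEventList()]).
#' Normalized counts divide raw counts by the product of pan-genome size,
#' strain count and the category's mean patristic distance between event
#' pairs on a supplied tree; the factors are injected, not recomputed.
#'
#' @param events data.frame with columns event_id, strain_a, strain_b.
#' @param meta metadata table (see [validateMetadata()]).
#' @param panSize pan-genome size normalization factor (default 1).
#' @param nStrains strain-count normalization factor (default 1).
#' @param tree optional `ape::phylo` with the event strains as tips; per
#'   category the mean patristic distance between event pairs enters the
#'   denominator.
#' @return data.frame with one row per category: raw and normalized counts.
#' @export
classifyRecombEvents <- function(events, meta, panSize = 1, nStrains = 1,
                                 tree = NULL) {
  validateMetadata(meta)
  cats <- c("SPSE", "SPDE", "DPSE", "DPDE")
  if (nrow(events)) {
    unknown <- setdiff(unique(c(events$strain_a, events$strain_b)),
                       meta$strain_id)
    if (length(unknown)) stop("event strain(s) not in metadata: ",
                              paste(unknown, collapse = ", "))
    ia <- match(events$strain_a, meta$strain_id)
    ib <- match(events$strain_b, meta$strain_id)
    samePond <- meta$pond[ia] == meta$pond[ib]
    sameEnv <- meta$environment[ia] == meta$environment[ib]
    cat <- ifelse(samePond, ifelse(sameEnv, "SPSE", "SPDE"),
                  ifelse(sameEnv, "DPSE", "DPDE"))
  } else {
    cat <- character(0)
  }
  raw <- vapply(cats, function(k) sum(cat == k), numeric(1))
  meanBL <- rep(1, 4)
  names(meanBL) <- cats
  if (!is.null(tree) && nrow(events)) {
    pat <- ape::cophenetic.phylo(tree)
    bl <- pat[cbind(events$strain_a, events$strain_b)]
    for (k in cats) if (any(cat == k)) meanBL[k] <- mean(bl[cat == k])
  }
  data.frame(category = cats, raw = unname(raw),
             normalized = unname(raw / (panSize * nStrains * meanBL)),
             stringsAsFactors = FALSE)
}

#' Jaccard dissimilarity of recombination-event profiles
#'
#' Per strain, the binary profile of event ids it participates in; pairwise
#' dissimilarity `1 - |intersection| / |union|`. Two strains with identical
#' profiles get 0; strains with no events at all are at distance 1 from
#' everyone (including each other) by convention, since their profiles carry
#' no shared signal. Profiles can alternatively be taken over recombinant
#' gene families (`profile = "family"`).
#'
#' @param events data.frame with columns event_id, strain_a, strain_b and
#'   optionally family_id.
#' @param meta metadata table; all its strains appear in the output.
#' @param profile "event" (default) or "family".
#' @return A symmetric matrix with zero diagonal and attribute
#'   `metric = "jaccard"`.
#' @export
recombJaccard <- function(events, meta, profile = c("event", "family")) {
  profile <- match.arg(profile)
  validateMetadata(meta)
  ids <- meta$strain_id
  key <- if (profile == "event") "event_id" else "family_id"
  if (profile == "family" && is.null(events$family_id))
    stop("events carry no family_id")
  prof <- lapply(ids, function(s) {
    sel <- nrow(events) > 0 &
      (events$strain_a == s | events$strain_b == s)
    unique(events[[key]][sel])
  })
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- length(union(prof[[i]], prof[[j]]))
    D[i, j] <- D[j, i] <-
      if (u == 0L) 1 else 1 - length(intersect(prof[[i]], prof[[j]])) / u
  }
  attr(D, "metric") <- "jaccard"
  D
}
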