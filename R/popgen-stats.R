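#' @useDynLib strainscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# per-site counts of derived alleles and observed calls
.site_counts <- function(H) {
  st <- stateMatrix(H)
  list(c1 = colSums(st == 1L, na.rm = TRUE),
       nobs = colSums(!is.na(st)))
}

# per-site contribution to total pi, pairwise-complete at sites with missing
# calls: 2 * c * (nobs - c) / (nobs * (nobs - 1))
.pi_contrib <- function(c1, nobs) {
  out <- numeric(length(c1))
  ok <- nobs >= 2L
  out[ok] <- 2 * c1[ok] * (nobs[ok] - c1[ok]) / (nobs[ok] * (nobs[ok] - 1))
  out
}

.harmonic <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k))

# Tajima (1989) normalization constants
.tajima_constants <- function(n) {
  a1 <- .harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajima_d_from <- function(S, piTot, n) {
  # the variance constants c1 and c2 vanish identically at n = 3, so D is
  # undefined below n = 4 (3-sequence groups need resampling instead)
  if (S <= 0 || n < 4L) return(NA_real_)
  k <- .tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (piTot - S / k$a1) / sqrt(v)
}

#' Number of segregating sites
#'
#' Sites with at least two states among non-missing calls.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @return integer(1).
#' @export
segregatingSites <- function(H) {
  if (nrow(stateMatrix(H)) < 2L) stop("need >= 2 haplotypes")
  sc <- .site_counts(H)
  sum(sc$c1 >= 1L & sc$c1 < sc$nobs)
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise difference between haplotypes, summed over sites and divided
#' by the locus length: `pi = [sum_{i<j} d_ij / choose(n, 2)] / L`. Sites with
#' missing calls contribute their pairwise-complete average.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param perSite divide by the locus length (default) or return the total.
#' @return numeric(1).
#' @export
nucleotideDiversity <- function(H, perSite = TRUE) {
  if (nrow(stateMatrix(H)) < 2L) stop("need >= 2 haplotypes")
  sc <- .site_counts(H)
  piTot <- sum(.pi_contrib(sc$c1, sc$nobs))
  if (perSite) piTot / locusLength(H) else piTot
}

#' Watterson's theta
#'
#' `theta_w = S / (a_{n-1} * L)` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param perSite divide by the locus length (default) or return the total.
#' @return numeric(1).
#' @export
wattersonTheta <- function(H, perSite = TRUE) {
  n <- nrow(stateMatrix(H))
  if (n < 2L) stop("need >= 2 haplotypes")
  th <- segregatingSites(H) / .harmonic(n - 1L)
  if (perSite) th / locusLength(H) else th
}

#' Tajima's D
#'
#' `D = (pi_total - theta_total) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' Tajima (1989) constants. Undefined (returned as `NA` with a warning) when
#' there is no variation, and also at n = 3, where the variance constants
#' vanish identically -- the reason 3-sequence groups are summarised through
#' [subsampledD()] instead.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @return numeric(1), `NA` when S = 0.
#' @export
tajimasD <- function(H) {
  n <- nrow(stateMatrix(H))
  if (n < 3L) stop("Tajima's D needs n >= 3")
  S <- segregatingSites(H)
  if (S == 0L) {
    warning("Tajima's D is undefined with no segregating sites")
    return(NA_real_)
  }
  if (n == 3L) {
    warning("the Tajima variance constants vanish at n = 3; ",
            "use subsampledD() for 3-sequence groups")
    return(NA_real_)
  }
  sc <- .site_counts(H)
  .tajima_d_from(S, sum(.pi_contrib(sc$c1, sc$nobs)), n)
}

#' Windowed Tajima's D
#'
#' Partitions `[0, L)` into `nWindows` equal contiguous windows and computes
#' D per window from the sites falling in it. Windows without variation are
#' excluded from the mean and SD (D is undefined there).
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param nWindows number of windows (default 1000).
#' @return list with `mean`, `sd`, per-window `d`, and the 1-based indices
#'   `windows` of the windows used. `sd` is `NA` when fewer than two windows
#'   carry variation.
#' @export
windowedD <- function(H, nWindows = 1000L) {
  n <- nrow(stateMatrix(H))
  if (nWindows < 1L) stop("nWindows must be >= 1")
  L <- locusLength(H)
  sc <- .site_counts(H)
  seg <- sc$c1 >= 1L & sc$c1 < sc$nobs
  contrib <- .pi_contrib(sc$c1, sc$nobs)
  w <- pmin(floor(sitePositions(H) / (L / nWindows)), nWindows - 1L) + 1L
  wS <- numeric(nWindows); wPi <- numeric(nWindows)
  if (any(seg)) {
    tab <- tapply(rep(1, sum(seg)), w[seg], sum)
    wS[as.integer(names(tab))] <- tab
    tabp <- tapply(contrib[seg], w[seg], sum)
    wPi[as.integer(names(tabp))] <- tabp
  }
  used <- which(wS > 0)
  d <- vapply(used, function(i) .tajima_d_from(wS[i], wPi[i], n), numeric(1))
  keep <- !is.na(d)
  used <- used[keep]; d <- d[keep]
  list(mean = if (length(d)) mean(d) else NA_real_,
       sd = if (length(d) >= 2L) stats::sd(d) else NA_real_,
       d = d, windows = used)
}

#' Median Tajima's D over haplotype resamples
#'
#' Each replicate resamples `k` haplotype rows with replacement (duplicates
#' counted as distinct samples, so the constants use n = k) and computes D;
#' the median over replicates with variation is returned. Used to obtain a D
#' value for groups with too few sequences for a direct estimate.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param k haplotypes per replicate (default 10).
#' @param reps replicates (default 1000).
#' @param seed optional integer seed.
#' @param replace resample with replacement (default). `replace = FALSE`
#'   with `k = nrow(H)` reduces every replicate to the full-sample D.
#' @return numeric(1) median D; `NA` with a warning if every replicate is
#'   invariant.
#' @export
subsampledD <- function(H, k = 10L, reps = 1000L, seed = NULL,
                        replace = TRUE) {
  st <- stateMatrix(H)
  if (nrow(st) < 2L) stop("need >= 2 haplotypes")
  if (!replace && k > nrow(st)) stop("k > n without replacement")
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    rows <- sample.int(nrow(st), k, replace = replace)
    sub <- st[rows, , drop = FALSE]
    c1 <- colSums(sub == 1L, na.rm = TRUE)
    nobs <- colSums(!is.na(sub))
    S <- sum(c1 >= 1L & c1 < nobs)
    vals[r] <- if (S > 0) .tajima_d_from(S, sum(.pi_contrib(c1, nobs)), k)
               else NA_real_
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    warning("Tajima's D undefined in every resample (no variation)")
    return(NA_real_)
  }
  stats::median(vals)
}

#' Diversity summary table for one group of haplotypes
#'
#' One row with sample size, segregating sites, per-site pi, per-site
#' Watterson's theta, Tajima's D and the windowed-D mean and SD, in that
#' column order.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param nWindows windows for the windowed-D moments.
#' @param group optional group label for the first column.
#' @return A one-row data.frame.
#' @export
diversityStats <- function(H, nWindows = 1000L, group = NA_character_) {
  wd <- windowedD(H, nWindows)
  d <- suppressWarnings(tajimasD(H))
  data.frame(group = group, n = nrow(stateMatrix(H)),
             S = segregatingSites(H), pi = nucleotideDiversity(H),
             theta_w = wattersonTheta(H), tajima_d = d,
             d_window_mean = wd$mean, d_window_sd = wd$sd,
             L = locusLength(H), stringsAsFactors = FALSE)
}

#' Empirical p-value for Tajima's D under the neutral null
#'
#' Simulates the constant-size neutral coalescent at the observed sample size
#' and Watterson's theta, and reports the two-sided empirical probability of
#' a |D| at least as extreme as observed. This is an interpretation aid; the
#' null is conditional on the estimated theta, not on S.
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param reps null replicates (default 10000).
#' @param seed optional integer seed.
#' @return numeric(1) two-sided empirical p-value.
#' @export
tajimaDNullP <- function(H, reps = 10000L, seed = NULL) {
  n <- nrow(stateMatrix(H))
  d <- tajimasD(H)
  if (is.na(d)) return(NA_real_)
  if (!is.null(seed)) set.seed(seed)
  thetaLocus <- wattersonTheta(H, perSite = FALSE)
  # simulate with ne chosen so 2*ne*mu*L = thetaLocus; scale is arbitrary
  ne <- 1e4
  mu <- thetaLocus / (2 * ne * locusLength(H))
  params <- matrix(rep(ne, reps), ncol = 1)
  sm <- cpp_abc_batch(as.integer(n), params, 0L, mu, locusLength(H), 1L)
  dn <- sm[, "D"]
  dn <- dn[!is.na(dn)]
  (sum(abs(dn) >= abs(d)) + 1) / (length(dn) + 1)
}
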