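#' Prior specification for ABC
#'
#' @param name parameter id (e.g. "ne", "tdiv1").
#' @param low,high bounds. For a log-uniform prior both must be positive.
#' @param scale "log-uniform" (default for population sizes and times) or
#'   "uniform".
#' @return A `Prior` list.
#' @export
priorSpec <- function(name, low, high, scale = c("log-uniform", "uniform")) {
  scale <- match.arg(scale)
  if (!is.finite(low) || !is.finite(high) || low > high)
    stop("invalid prior bounds")
  if (scale == "log-uniform" && low <= 0)
    stop("log-uniform prior needs 0 < low <= high")
  structure(list(name = name, low = low, high = high, scale = scale),
            class = "Prior")
}

#' Draw from a prior
#'
#' Log-uniform draws are `exp(Uniform(log(low), log(high)))`; uniform draws
#' are `Uniform(low, high)`.
#'
#' @param p a [priorSpec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric(n).
#' @export
samplePrior <- function(p, n, seed = NULL) {
  stopifnot(inherits(p, "Prior"))
  if (!is.null(seed)) set.seed(seed)
  if (p$low == p$high) return(rep(p$low, n))
  if (p$scale == "log-uniform")
    exp(stats::runif(n, log(p$low), log(p$high)))
  else stats::runif(n, p$low, p$high)
}

#' Summary-statistic vector for ABC
#'
#' `(S, genome-wide Tajima's D, windowed-D mean, windowed-D SD)`, delegating
#' to [segregatingSites()], [tajimasD()] and [windowedD()]. Components that
#' are undefined on invariant data are `NA`; the ABC distance treats them as
#' a sentinel (see [rejectionAbc()]).
#'
#' @param H a \linkS4class{HaplotypeMatrix}.
#' @param nWindows windows for the windowed moments (default 1000).
#' @return Named numeric of length 4.
#' @export
summaryVector <- function(H, nWindows = 1000L) {
  S <- segregatingSites(H)
  d <- if (S > 0 && nrow(stateMatrix(H)) >= 3L)
    suppressWarnings(tajimasD(H)) else NA_real_
  wd <- windowedD(H, nWindows)
  c(S = S, D = d, D_win_mean = wd$mean, D_win_sd = wd$sd)
}

# simulate n draws from each prior into a parameter matrix (ne first)
.draw_params <- function(priors, n) {
  draws <- vapply(priors, samplePrior, numeric(n), n = n)
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- vapply(priors, `[[`, character(1), "name")
  draws
}

# standardized Euclidean distance with MAD scaling; simulations whose D
# components are undefined get infinite distance unless the observation is
# undefined there too (in which case the component is dropped)
.abc_distances <- function(obs, sims) {
  useComp <- !is.na(obs)
  dist2 <- numeric(nrow(sims))
  anyComp <- FALSE
  for (j in which(useComp)) {
    x <- sims[, j]
    scale <- stats::mad(x, na.rm = TRUE)
    if (!is.finite(scale) || scale == 0) next
    anyComp <- TRUE
    comp <- ((x - obs[j]) / scale)^2
    comp[is.na(x)] <- Inf
    dist2 <- dist2 + comp
  }
  if (!anyComp) stop("no usable summary-statistic component")
  sqrt(dist2)
}

#' Rejection ABC
#'
#' For each draw from the priors, simulates a locus under the demography
#' template, computes the summary vector, and measures a Euclidean distance
#' to the observed summaries after per-component standardization by the
#' simulated pool's median absolute deviation. The `tol` fraction of draws
#' with smallest distance is accepted; per-parameter posterior medians and
#' 2.5/97.5 percentile intervals are reported.
#'
#' @param obs observed summary vector from [summaryVector()].
#' @param template a [demographyConfig()] providing sample sizes, mutation
#'   rate and locus length. Parameters named in `priors` override it per
#'   draw: `"ne"` replaces the population size, `"tdiv<d>"` the d-th deme's
#'   divergence time.
#' @param priors list of [priorSpec()]s.
#' @param nSims simulations (full-protocol default 100000).
#' @param tol acceptance proportion (default 0.0005, the 0.05% threshold).
#' @param nWindows windows for the summary vector.
#' @param seed optional integer seed.
#' @return An \linkS4class{AbcResult}.
#' @export
rejectionAbc <- function(obs, template, priors, nSims = 100000L,
                         tol = 0.0005, nWindows = 1000L, seed = NULL) {
  stopifnot(inherits(template, "DemographyConfig"))
  if (tol <= 0 || tol > 1) stop("tol must be in (0, 1]")
  if (nSims < 1 / tol) stop("nSims too small for tol: no draw would be accepted")
  if (!is.null(seed)) set.seed(seed)
  if (is.list(priors) && inherits(priors, "Prior")) priors <- list(priors)
  nm <- vapply(priors, `[[`, character(1), "name")
  nTdiv <- length(template$tDiv)
  expect <- c("ne", if (nTdiv > 0) paste0("tdiv", seq_len(nTdiv)))
  if (length(setdiff(nm, expect)))
    stop("unknown prior parameter(s): ",
         paste(setdiff(nm, expect), collapse = ", "))
  draws <- .draw_params(priors, nSims)
  params <- matrix(template$ne, nSims, 1L + nTdiv)
  if (nTdiv > 0) params[, 2L:(1L + nTdiv)] <- rep(template$tDiv, each = nSims)
  if ("ne" %in% nm) params[, 1L] <- draws[, "ne"]
  for (d in seq_len(nTdiv)) {
    cn <- paste0("tdiv", d)
    if (cn %in% nm) params[, 1L + d] <- draws[, cn]
  }
  sims <- cpp_abc_batch(template$sampleSizes, params, nTdiv,
                        template$mu, template$L, nWindows)
  if (all(sims[, "S"] == 0))
    stop("inference failure: every simulation was invariant")
  dist <- .abc_distances(obs[c("S", "D", "D_win_mean", "D_win_sd")],
                         sims[, c("S", "D", "D_win_mean", "D_win_sd"),
                              drop = FALSE])
  nAcc <- as.integer(ceiling(tol * nSims))
  keep <- order(dist, seq_along(dist))[seq_len(nAcc)]
  accepted <- data.frame(draws[keep, , drop = FALSE],
                         sims[keep, , drop = FALSE],
                         distance = dist[keep], check.names = FALSE)
  med <- vapply(nm, function(p) stats::median(accepted[[p]]), numeric(1))
  ci <- vapply(nm, function(p)
    stats::quantile(accepted[[p]], c(0.025, 0.975), names = FALSE),
    numeric(2))
  dimnames(ci) <- list(c("2.5%", "97.5%"), nm)
  new("AbcResult", accepted = accepted, posteriorMedian = med, ci95 = ci,
      nSims = as.integer(nSims), tol = tol, priors = priors, stage1 = NULL)
}

#' Narrow a prior to the accepted range
#'
#' New bounds are the min and max of the accepted draws for that parameter,
#' on the same scale. A degenerate accepted set (a single value) is widened
#' by +/-10% with a warning.
#'
#' @param r an \linkS4class{AbcResult}.
#' @param p the [priorSpec()] to narrow.
#' @return A narrowed [priorSpec()].
#' @export
narrowPrior <- function(r, p) {
  stopifnot(is(r, "AbcResult"), inherits(p, "Prior"))
  x <- r@accepted[[p$name]]
  if (is.null(x) || length(x) < 2L)
    stop("need >= 2 accepted draws for parameter ", p$name)
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    warning("accepted draws collapsed to a single value; widening by 10%")
    pad <- if (lo == 0) 1e-8 else 0.1 * abs(lo)
    lo <- lo - pad
    hi <- hi + pad
  }
  priorSpec(p$name, max(p$low, lo), min(p$high, hi), p$scale)
}

#' Two-stage rejection ABC with prior narrowing
#'
#' Runs [rejectionAbc()], narrows every prior to the accepted range, and
#' runs a second stage of the same size with the narrowed priors. The
#' returned result is the second stage, with the first kept in `@stage1`.
#'
#' @inheritParams rejectionAbc
#' @param nSimsPerStage simulations per stage.
#' @return An \linkS4class{AbcResult}.
#' @export
twoStageAbc <- function(obs, template, priors, nSimsPerStage = 100000L,
                        tol = 0.0005, nWindows = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s1 <- rejectionAbc(obs, template, priors, nSimsPerStage, tol, nWindows)
  priors2 <- lapply(priors, function(p) narrowPrior(s1, p))
  s2 <- rejectionAbc(obs, template, priors2, nSimsPerStage, tol, nWindows)
  s2@stage1 <- s1
  s2
}

#' Format ABC estimates as a results table
#'
#' One row per parameter: group label, sample size, posterior median and the
#' 95% credible bounds.
#'
#' @param r an \linkS4class{AbcResult}.
#' @param group group label.
#' @param sampleSize number of sequences the observation came from.
#' @return data.frame with columns group, parameter, sample_size, median,
#'   lower, upper.
#' @export
abcTable <- function(r, group = NA_character_, sampleSize = NA_integer_) {
  nm <- names(r@posteriorMedian)
  data.frame(group = group, parameter = nm, sample_size = sampleSize,
             median = unname(r@posteriorMedian),
             lower = r@ci95["2.5%", nm], upper = r@ci95["97.5%", nm],
             row.names = NULL, stringsAsFactors = FALSE)
}
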