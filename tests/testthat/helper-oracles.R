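# Independent brute-force oracles. These deliberately re-derive every
# statistic from first principles (explicit pair loops, hand-written Tajima
# constants) and share no code with the package implementations.

oracle_segsites <- function(states) {
  sum(apply(states, 2L, function(x) length(unique(x[!is.na(x)])) >= 2L))
}

oracle_pi_total <- function(states) {
  n <- nrow(states)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + sum(states[i, ] != states[j, ])
  }
  tot / choose(n, 2)
}

oracle_theta_total <- function(states) {
  n <- nrow(states)
  oracle_segsites(states) / sum(1 / seq_len(n - 1L))
}

oracle_tajima_d <- function(states) {
  n <- nrow(states)
  S <- oracle_segsites(states)
  # at n = 3 the c1/c2 constants are exactly zero, so D is undefined
  if (S == 0 || n < 4) return(NA_real_)
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (oracle_pi_total(states) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- sum(tab[, 1]); n2 <- sum(tab[, 2]); k <- sum(tab[1, ])
  supp <- max(0, k - n2):min(k, m)
  pr <- dhyper(supp, m, n2, k)
  obs <- dhyper(tab[1, 1], m, n2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

oracle_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 1 else 1 - length(intersect(a, b)) / u
}

# connected components below threshold t, by union-find
oracle_components <- function(D, t) {
  n <- nrow(D)
  par <- seq_len(n)
  find <- function(i) { while (par[i] != i) i <- par[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (D[i, j] < t) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) par[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# random binary haplotype matrix with complete data; segregating and
# monomorphic columns both allowed
random_hap <- function(n, S, L = 100) {
  states <- matrix(rbinom(n * S, 1L, runif(1, 0.2, 0.8)), n, S)
  pos <- sort(runif(S, 0, L))
  while (anyDuplicated(pos)) pos <- sort(runif(S, 0, L))
  HaplotypeMatrix(states, pos, L)
}

# the worked 4-haplotype example: h1=(1,1,1) h2=(0,1,1) h3=(0,0,1) h4=(0,0,0)
worked_example <- function(L = 3) {
  HaplotypeMatrix(rbind(h1 = c(1, 1, 1), h2 = c(0, 1, 1),
                        h3 = c(0, 0, 1), h4 = c(0, 0, 0)),
                  positions = c(0.5, 1.5, 2.5), locusLength = L)
}

# metadata with balanced environments across ponds
balanced_meta <- function(nPerEnv = 20, nPonds = 9) {
  n <- 2 * nPerEnv
  data.frame(strain_id = sprintf("strain%03d", 1:n),
             pond = rep_len(1:nPonds, n),
             environment = rep(c("water", "sediment"), each = nPerEnv),
             clade = rep_len(c("I", "II"), n),
             stringsAsFactors = FALSE)
}

# SNP fixture with the printed filter arithmetic: `total` sites of which
# `biallelic` have exactly two alleles, and among those `subMaf` fall below
# the MAF/carrier rules (minor count 1-2 of 42); the rest have minor count
# >= 3. Non-biallelic sites are triallelic.
make_filter_fixture <- function(nSamples = 42, total = 38533,
                                biallelic = 26663, subMaf = 771,
                                seed = 1) {
  set.seed(seed)
  calls <- matrix("A", nSamples, total)
  kept <- biallelic - subMaf
  type <- sample(rep(c("kept", "sub", "tri"),
                     c(kept, subMaf, total - biallelic)))
  for (j in seq_len(total)) {
    if (type[j] == "tri") {
      k <- sample(3:10, 1)
      rows <- sample.int(nSamples, k)
      calls[rows[1], j] <- "C"
      calls[rows[-1], j] <- "G"
    } else {
      k <- if (type[j] == "sub") sample(1:2, 1) else
        sample(3:floor(nSamples / 2), 1)
      calls[sample.int(nSamples, k), j] <- "G"
    }
  }
  rownames(calls) <- sprintf("s%02d", seq_len(nSamples))
  meta <- data.frame(strain_id = rownames(calls),
                     pond = rep_len(1:9, nSamples),
                     environment = rep_len(c("water", "sediment"), nSamples),
                     clade = rep_len(c("I", "II", "III"), nSamples),
                     stringsAsFactors = FALSE)
  SNPDataset(calls, positions = seq_len(total) - 1, meta = meta)
}
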