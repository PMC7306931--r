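meta3 <- function() {
  data.frame(strain_id = c("s1", "s2", "s3"), pond = c(1, 1, 2),
             environment = c("water", "water", "sediment"), clade = "I",
             stringsAsFactors = FALSE)
}

test_that("SNP extraction finds variant columns and records missingness", {
  aln <- Biostrings::DNAStringSet(c(s1 = "ACGT", s2 = "ACCT", s3 = "ACGT"))
  S <- extractSnps(aln, meta3())
  expect_equal(ncol(snpCalls(S)), 1L)
  expect_equal(sitePositions(S), 2)  # 0-based column
  expect_equal(sort(unique(snpCalls(S)[, 1])), c("C", "G"))
  # identical rows: no sites
  same <- Biostrings::DNAStringSet(c(s1 = "ACGT", s2 = "ACGT"))
  expect_equal(ncol(snpCalls(extractSnps(same))), 0L)
  # ragged alignment is a format error
  expect_error(extractSnps(Biostrings::DNAStringSet(c(s1 = "ACGT",
                                                      s2 = "ACG"))),
               "ragged")
})

test_that("extraction matches a brute-force column scan with gaps", {
  set.seed(71)
  for (r in 1:20) {
    n <- sample(3:6, 1); L <- sample(10:40, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.06, 0.06)), n, L)
    rownames(m) <- paste0("s", 1:n)
    S <- extractSnps(m)
    oracle <- which(vapply(seq_len(L), function(j) {
      x <- m[, j]; x <- x[x %in% c("A", "C", "G", "T")]
      length(unique(x)) >= 2
    }, logical(1)))
    expect_equal(sitePositions(S), oracle - 1)
    if (length(oracle))
      expect_true(all(is.na(snpCalls(S)[m[, oracle] %in% c("-", "N")])))
  }
})

test_that("biallelic filtering drops multi-allelic sites and is idempotent", {
  calls <- rbind(s1 = c("A", "A", "A"), s2 = c("C", "G", "A"),
                 s3 = c("G", "G", "C"), s4 = c("G", "A", "C"))
  S <- SNPDataset(calls, positions = 0:2)
  fb <- filterBiallelic(S)
  expect_equal(sitePositions(fb), c(1, 2))  # column 0 is triallelic
  fb2 <- filterBiallelic(fb)
  expect_identical(snpCalls(fb2), snpCalls(fb))
})

test_that("MAF and carrier filters follow the stated rules", {
  # 40 samples; minor allele in 2 samples has MAF 0.05 exactly:
  # kept by the frequency rule but dropped by the 3-carrier rule
  calls <- matrix("A", 40, 3)
  calls[1:2, 1] <- "G"   # MAF = 0.05, carriers 2
  calls[1:3, 2] <- "G"   # MAF = 0.075, carriers 3
  calls[1, 3] <- "G"     # MAF = 0.025, carriers 1
  rownames(calls) <- sprintf("s%02d", 1:40)
  S <- SNPDataset(calls, positions = 0:2)
  f <- filterMaf(S)
  expect_equal(sitePositions(f), 1)
  # threshold site survives the frequency rule alone
  f2 <- filterMaf(S, minCarriers = 1L)
  expect_equal(sitePositions(f2), c(0, 1))
  f3 <- filterMaf(S, minCarriers = 1L, keepAtThreshold = FALSE)
  expect_equal(sitePositions(f3), 1)
  # maf = 0 and minCarriers = 1 is the identity
  f4 <- filterMaf(S, maf = 0, minCarriers = 1L)
  expect_identical(snpCalls(f4), snpCalls(S))
})

test_that("the filter chain reproduces the printed site arithmetic", {
  S <- make_filter_fixture(seed = 42)
  expect_equal(ncol(snpCalls(S)), 38533L)
  fb <- filterBiallelic(S)
  expect_equal(ncol(snpCalls(fb)), 26663L)
  fm <- filterMaf(fb, maf = 0.05, minCarriers = 3L)
  expect_equal(ncol(snpCalls(fm)), 25892L)
})

test_that("private alleles are counted per group", {
  calls <- rbind(s1 = c("A", "A"), s2 = c("A", "G"),
                 s3 = c("G", "G"), s4 = c("G", "G"))
  meta <- data.frame(strain_id = paste0("s", 1:4), pond = c(1, 1, 2, 2),
                     environment = c("water", "water", "sediment",
                                     "sediment"),
                     clade = "I", stringsAsFactors = FALSE)
  S <- SNPDataset(calls, positions = 0:1, meta = meta)
  # site 1: A in pond 1 only (private), G in pond 2 only (private)
  # site 2: A in pond 1 only (private), G in both ponds
  pv <- privateAlleles(S, "pond")
  expect_equal(unname(pv$counts["1"]), 2)
  expect_equal(unname(pv$counts["2"]), 1)
  expect_equal(pv$mean, 1.5)
  # a single group owns every allele
  metaOne <- meta; metaOne$pond <- 1
  pvOne <- privateAlleles(SNPDataset(calls, positions = 0:1, meta = metaOne),
                          "pond")
  expect_equal(unname(pvOne$counts["1"]), 4)
})

test_that("private-allele counts match an exhaustive scan on random data", {
  set.seed(72)
  meta <- balanced_meta(8)
  S <- genSnpDataset(meta, nSites = 60, nAssoc = 5, effect = 0.6, seed = 73)
  pv <- privateAlleles(S, "environment")
  calls <- snpCalls(S)
  env <- meta$environment
  counts <- c(sediment = 0, water = 0)
  for (j in seq_len(ncol(calls))) {
    for (a in unique(calls[, j])) {
      gs <- unique(env[calls[, j] == a])
      if (length(gs) == 1) counts[gs] <- counts[gs] + 1
    }
  }
  expect_equal(pv$counts[sort(names(counts))], counts[sort(names(counts))])
})

test_that("Fisher p for the fully separated 20/20 table is 2/C(40,20)", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(fisher.test(tab)$p.value, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(oracle_fisher_p(tab), 2 / choose(20, 10), tolerance = 1e-12)
  # through the pipeline: effect = 1 with 20 samples per environment
  meta <- balanced_meta(20)
  S <- genSnpDataset(meta, nSites = 40, nAssoc = 5, effect = 1, seed = 74)
  fa <- fisherAssoc(S)
  planted <- plantedTruth(S)$associated_sites
  pPlanted <- fa$result$p[match(planted, fa$result$site)]
  expect_equal(pPlanted, rep(2 / choose(40, 20), 5), tolerance = 1e-12)
  expect_true(all(fa$result$significant[match(planted, fa$result$site)]))
})

test_that("Fisher p-values match the enumeration oracle site by site", {
  set.seed(75)
  meta <- balanced_meta(10)
  S <- genSnpDataset(meta, nSites = 50, nAssoc = 10, effect = 0.5, seed = 76)
  fa <- fisherAssoc(S)
  calls <- snpCalls(S)
  env <- factor(meta$environment)
  for (k in seq_len(nrow(fa$result))) {
    j <- fa$result$site[k]
    al <- sort(unique(calls[, j]))
    tab <- table(factor(calls[, j], levels = al), env)
    expect_equal(fa$result$p[k], oracle_fisher_p(tab), tolerance = 1e-9)
  }
  # Bonferroni bookkeeping
  expect_equal(fa$m, 50L)
  expect_equal(fa$result$p_adj, pmin(1, fa$result$p * 50))
})

test_that("p-values are invariant under allele and environment relabeling", {
  meta <- balanced_meta(8)
  S <- genSnpDataset(meta, nSites = 30, nAssoc = 5, effect = 0.7, seed = 77)
  fa <- fisherAssoc(S)
  # swap allele labels
  callsSw <- snpCalls(S)
  callsSw[] <- c(A = "G", G = "A")[callsSw]
  faSw <- fisherAssoc(SNPDataset(callsSw, sitePositions(S), meta))
  expect_equal(fa$result$p, faSw$result$p, tolerance = 1e-12)
  # swap environment labels
  metaSw <- meta
  metaSw$environment <- c(water = "sediment", sediment = "water")[
    meta$environment]
  faEnv <- fisherAssoc(SNPDataset(snpCalls(S), sitePositions(S), metaSw))
  expect_equal(fa$result$p, faEnv$result$p, tolerance = 1e-12)
})

test_that("balanced identical frequencies give p = 1", {
  calls <- rbind(s1 = "A", s2 = "G", s3 = "A", s4 = "G")
  meta <- data.frame(strain_id = paste0("s", 1:4), pond = 1,
                     environment = c("water", "water", "sediment",
                                     "sediment"),
                     clade = "I", stringsAsFactors = FALSE)
  fa <- fisherAssoc(SNPDataset(calls, positions = 0, meta = meta))
  expect_equal(fa$result$p, 1)
})

test_that("sites with one environment all-missing are excluded and recorded", {
  calls <- rbind(s1 = c("A", NA), s2 = c("G", NA), s3 = c("A", "A"),
                 s4 = c("G", "G"))
  meta <- data.frame(strain_id = paste0("s", 1:4), pond = 1,
                     environment = c("water", "water", "sediment",
                                     "sediment"),
                     clade = "I", stringsAsFactors = FALSE)
  fa <- fisherAssoc(SNPDataset(calls, positions = 0:1, meta = meta))
  expect_equal(fa$excluded, 2L)
  expect_equal(fa$m, 1L)
})

test_that("window mapping bins half-open 1-kb windows", {
  mw <- mapWindows(c(10, 990, 1010))
  expect_equal(mw$nWindows, 2L)  # [0,1000) and [1000,2000)
  expect_equal(mw$windows$window, c(0, 1))
  expect_equal(mw$windows$n_snps, c(2L, 1L))
  expect_equal(mapWindows(numeric(0))$nWindows, 0L)
  expect_error(mapWindows(c(10, 5000), alignmentLength = 4000), "beyond")
})

test_that("window-gene overlap matches brute-force interval intersection", {
  set.seed(78)
  for (r in 1:10) {
    pos <- sort(sample(0:9999, sample(5:30, 1)))
    ann <- data.frame(family_id = paste0("fam", 1:15),
                      start = sample(0:9500, 15))
    ann$end <- ann$start + sample(50:800, 15, replace = TRUE)
    mw <- mapWindows(pos, window = 1000, annotations = ann)
    occ <- unique(floor(pos / 1000))
    oracle <- sort(unique(unlist(lapply(occ, function(k) {
      lo <- k * 1000; hi <- (k + 1) * 1000
      ann$family_id[ann$start < hi & ann$end > lo]
    }))))
    expect_equal(mw$families, oracle)
    expect_equal(mw$nWindows, length(occ))
  }
})
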