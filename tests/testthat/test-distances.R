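test_that("Nei distance reproduces the hand-evaluated example", {
  # two biallelic loci; x fixed at both, y at (0.5, 0.5) and fixed:
  # Jx = 1, Jy = 0.75, Jxy = 0.75 -> D = -log(0.75 / sqrt(0.75)) = -log(0.75)/2
  fx <- list(c(1, 0), c(1, 0))
  fy <- list(c(0.5, 0.5), c(1, 0))
  D <- neiDistance(list(x = fx, y = fy))
  expect_equal(D["x", "y"], -0.5 * log(0.75), tolerance = 1e-12)
  expect_equal(D["x", "y"], 0.1438, tolerance = 1e-3)
  expect_equal(diag(D), c(x = 0, y = 0))
  # identical profiles: distance 0
  expect_equal(neiDistance(list(a = fx, b = fx))["a", "b"], 0)
  # fixed opposite alleles at all loci: infinite sentinel
  fz <- list(c(0, 1), c(0, 1))
  expect_equal(neiDistance(list(x = fx, z = fz))["x", "z"], Inf)
  # malformed frequencies are rejected
  expect_error(neiDistance(list(a = list(c(0.6, 0.6)), b = fx)), "sum to 1")
})

test_that("bitwise distance is the differing fraction of complete sites", {
  calls <- rbind(a = c("A", "A", "G", "G", "A", "A", "G", "A", "A", "A"),
                 b = c("A", "G", "A", "G", "G", "A", "G", "A", "A", "A"),
                 c = rep("T", 10))  # keeps every site polymorphic
  S <- SNPDataset(calls, positions = 0:9)
  D <- bitwiseDistance(S)
  expect_equal(D["a", "b"], 0.3)  # 3 of 10 sites differ
  expect_equal(D["a", "a"], 0)
  expect_equal(D["a", "c"], 1)
  expect_true(all(abs(D - t(D)) < 1e-15))
  # missing data: pairwise-complete; no complete site -> NA sentinel
  calls2 <- rbind(u = c("A", NA), v = c(NA, "G"), w = c("G", "A"))
  expect_true(is.na(bitwiseDistance(SNPDataset(
    calls2, positions = 0:1))["u", "v"]))
})

test_that("bitwise distance matches a brute-force Hamming oracle", {
  set.seed(61)
  for (r in 1:20) {
    H <- random_hap(sample(3:6, 1), sample(5:20, 1))
    D <- bitwiseDistance(H)
    st <- stateMatrix(H)
    for (i in 1:(nrow(st) - 1)) for (j in (i + 1):nrow(st)) {
      expect_equal(D[i, j], sum(st[i, ] != st[j, ]) / ncol(st))
    }
  }
})

test_that("UPGMA agglomerates by average linkage with ultrametric output", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(D)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.ultrametric(tr))
  dep <- ape::node.depth.edgelength(tr)
  heights <- max(dep) - dep
  # A,B merge at height 1; C joins at height 3
  expect_equal(sort(unique(round(heights[4:5], 10))), c(1, 3))
  pat <- ape::cophenetic.phylo(tr)
  expect_equal(pat["A", "B"], 2)
  expect_equal(pat["A", "C"], 6)
  # sentinel distances are refused
  D2 <- D; D2[1, 2] <- D2[2, 1] <- Inf
  expect_error(upgmaTree(D2), "sentinel")
})

test_that("UPGMA root-to-tip path lengths are equal on random matrices", {
  set.seed(62)
  for (r in 1:10) {
    n <- sample(4:8, 1)
    x <- matrix(runif(n * 5), n)
    D <- as.matrix(dist(x))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgmaTree(D)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  }
})

test_that("neighbour joining recovers a four-taxon additive tree exactly", {
  # ((A:1,B:2):1,(C:3,D:1):1) as an unrooted additive metric
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 6
  D["A", "D"] <- D["D", "A"] <- 4
  D["B", "C"] <- D["C", "B"] <- 7
  D["B", "D"] <- D["D", "B"] <- 5
  D["C", "D"] <- D["D", "C"] <- 4
  tr <- njTree(D)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-12)
  # AB|CD split present
  splits <- ape::prop.part(ape::unroot(tr))
  expect_true(any(vapply(splits, function(p)
    setequal(tr$tip.label[p], c("A", "B")) ||
    setequal(tr$tip.label[p], c("C", "D")), logical(1))))
  # three taxa: unique tree solving the three-point equations
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- njTree(D3)
  pat3 <- ape::cophenetic.phylo(tr3)
  expect_equal(pat3[c("x", "y", "z"), c("x", "y", "z")], D3,
               tolerance = 1e-12)
  expect_error(njTree(D3[1:2, 1:2]), ">= 3")
})

test_that("taxon order does not change the NJ topology", {
  set.seed(63)
  n <- 6
  x <- matrix(runif(n * 4), n)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  tr1 <- njTree(D)
  o <- sample(n)
  tr2 <- njTree(D[o, o])
  expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2))[1], 0)
})

test_that("threshold grouping takes connected components below t", {
  ids <- c("a", "b", "c")
  D <- matrix(c(0, 5e-4, 2e-3, 5e-4, 0, 5e-4, 2e-3, 5e-4, 0), 3, 3,
              dimnames = list(ids, ids))
  g <- thresholdGroups(D, t = 0.001)
  expect_equal(unname(g), c(1L, 1L, 1L))  # chain a-b, b-c links all three
  # all distances above t: singletons
  D2 <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(D2) <- 0
  expect_equal(unname(thresholdGroups(D2, t = 0.001)), 1:3)
  # complete linkage splits the chain
  gc <- thresholdGroups(D, t = 0.001, linkage = "complete")
  expect_gt(max(gc), 1L)
})

test_that("threshold grouping matches a union-find oracle", {
  set.seed(64)
  for (r in 1:20) {
    n <- sample(4:10, 1)
    D <- as.matrix(dist(matrix(runif(n * 2), n)))
    dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
    t <- runif(1, 0.1, 0.8)
    g <- thresholdGroups(D, t)
    o <- oracle_components(D, t)
    # same partition up to label names
    expect_equal(length(unique(g)), length(unique(o)))
    expect_true(all(tapply(o, g, function(x) length(unique(x))) == 1))
  }
})

test_that("recombination events classify by pond/environment agreement", {
  meta <- data.frame(strain_id = c("s1", "s2", "s3", "s4"),
                     pond = c(4, 4, 7, 4),
                     environment = c("water", "water", "sediment", "sediment"),
                     clade = "II", stringsAsFactors = FALSE)
  ev <- data.frame(event_id = c("e1", "e2", "e3", "e4"),
                   strain_a = c("s1", "s1", "s1", "s2"),
                   strain_b = c("s2", "s3", "s4", "s3"),
                   stringsAsFactors = FALSE)
  cc <- classifyRecombEvents(ev, meta)
  expect_equal(cc$raw[cc$category == "SPSE"], 1)  # s1-s2: pond 4 water both
  expect_equal(cc$raw[cc$category == "DPDE"], 2)  # s1-s3 and s2-s3
  expect_equal(cc$raw[cc$category == "SPDE"], 1)  # s1-s4
  expect_equal(sum(cc$raw), nrow(ev))
  expect_error(classifyRecombEvents(
    data.frame(event_id = "x", strain_a = "s1", strain_b = "nope"), meta),
    "not in metadata")
  # normalization divides by the injected factors
  cc2 <- classifyRecombEvents(ev, meta, panSize = 10, nStrains = 4)
  expect_equal(cc2$normalized, cc2$raw / 40)
})

test_that("planted category rates round-trip through classification", {
  set.seed(65)
  meta <- balanced_meta(10)
  rates <- c(SPSE = 50, SPDE = 0, DPSE = 0, DPDE = 0)
  ev <- genRecombEvents(meta, rates, seed = 66)
  cc <- classifyRecombEvents(ev, meta)
  expect_equal(cc$raw[cc$category == "SPSE"], nrow(ev))
  expect_equal(sum(cc$raw[cc$category != "SPSE"]), 0)
  truth <- attr(ev, "planted_truth")
  expect_equal(unname(truth$drawn_counts["SPSE"]), nrow(ev))
  # two planted categories recovered exactly per draw
  ev2 <- genRecombEvents(meta, c(SPSE = 40, SPDE = 5, DPSE = 5, DPDE = 10),
                         seed = 67)
  cc2 <- classifyRecombEvents(ev2, meta)
  drawn <- attr(ev2, "planted_truth")$drawn_counts
  expect_equal(cc2$raw, unname(drawn[cc2$category]))
})

test_that("Poisson event counts match planted rates on average", {
  meta <- balanced_meta(10)
  rates <- c(SPSE = 40, SPDE = 0, DPSE = 0, DPDE = 10)
  set.seed(68)
  tot <- c(SPSE = 0, DPDE = 0)
  reps <- 300
  for (r in 1:reps) {
    ev <- genRecombEvents(meta, rates)
    cc <- classifyRecombEvents(ev, meta)
    tot["SPSE"] <- tot["SPSE"] + cc$raw[cc$category == "SPSE"]
    tot["DPDE"] <- tot["DPDE"] + cc$raw[cc$category == "DPDE"]
  }
  # Poisson SE of the mean = sqrt(rate / reps)
  expect_lt(abs(tot["SPSE"] / reps - 40), 3 * sqrt(40 / reps))
  expect_lt(abs(tot["DPDE"] / reps - 10), 3 * sqrt(10 / reps))
})

test_that("Jaccard event profiles match set arithmetic", {
  meta <- data.frame(strain_id = c("s1", "s2", "s3"), pond = 1,
                     environment = "water", clade = "I",
                     stringsAsFactors = FALSE)
  ev <- data.frame(event_id = c("e1", "e2", "e2", "e3"),
                   strain_a = c("s1", "s1", "s2", "s2"),
                   strain_b = c("s2", "s2", "s3", "s3"),
                   stringsAsFactors = FALSE)
  # profiles: s1 {e1,e2}, s2 {e1,e2,e3}, s3 {e2,e3}
  D <- recombJaccard(ev, meta)
  expect_equal(D["s1", "s3"], 1 - 1 / 3)
  expect_equal(D["s1", "s2"], 1 - 2 / 3)
  expect_equal(diag(D), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(D["s1", "s3"], oracle_jaccard(c("e1", "e2"), c("e2", "e3")))
  # strains with no events sit at distance 1 from everyone
  meta2 <- rbind(meta, data.frame(strain_id = "s4", pond = 1,
                                  environment = "water", clade = "I"))
  D2 <- recombJaccard(ev, meta2)
  expect_true(all(D2["s4", c("s1", "s2", "s3")] == 1))
  # identical profiles at distance 0
  evSame <- data.frame(event_id = c("e1", "e1"), strain_a = c("s1", "s2"),
                       strain_b = c("s3", "s3"), stringsAsFactors = FALSE)
  expect_equal(recombJaccard(evSame, meta)["s1", "s2"], 0)
})

test_that("random event lists agree with the brute-force Jaccard oracle", {
  set.seed(69)
  meta <- balanced_meta(10)
  for (r in 1:10) {
    ev <- genRecombEvents(meta, c(SPSE = 10, SPDE = 10, DPSE = 10,
                                  DPDE = 10))
    D <- recombJaccard(ev, meta)
    ids <- meta$strain_id
    prof <- lapply(ids, function(s)
      unique(ev$event_id[ev$strain_a == s | ev$strain_b == s]))
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      expect_equal(D[ids[i], ids[j]], oracle_jaccard(prof[[i]], prof[[j]]))
    }
    expect_true(all(D >= 0 & D <= 1))
  }
})
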