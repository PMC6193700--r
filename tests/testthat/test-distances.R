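random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

test_that("TN93 distance matches its closed-form oracles", {
  s <- "ACGTACGTACGTACGTACGT"
  expect_equal(tn93_distance(s, s), 0)

  # toy pair, 2 transitions + 1 transversion over 100 sites, alpha = 0.325:
  # compare against an independent evaluation of the published formula
  set.seed(1)
  a <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  b <- a
  b[1] <- "G"; b[6] <- "T"; b[11] <- "T"   # A->G, C->T transitions; G->T tv
  f <- (table(factor(a, levels = c("A","C","G","T"))) +
        table(factor(b, levels = c("A","C","G","T")))) / 200
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- 1/100; P2 <- 1/100; Q <- 1/100; alpha <- 0.325
  gl <- function(w) alpha * (w^(-1/alpha) - 1)
  k1 <- 2*gA*gG/gR; k2 <- 2*gT*gC/gY
  k3 <- 2*(gR*gY - gA*gG*gY/gR - gT*gC*gR/gY)
  expected <- k1 * gl(1 - P1/k1 - Q/(2*gR)) +
    k2 * gl(1 - P2/k2 - Q/(2*gY)) + k3 * gl(1 - Q/(2*gR*gY))
  expect_equal(tn93_distance(paste(a, collapse = ""), paste(b, collapse = ""),
                             tn93_params(0.325)), expected, tolerance = 1e-12)

  # alpha -> Inf, transversions only, equal base frequencies (A->C and
  # C->A swaps keep the pooled composition uniform): closed-form limit with
  # k1 = k2 = k3 = 1/4, so d = -1/2 log(1-Q) - 1/4 log(1-2Q)
  b2 <- a; b2[1] <- "C"; b2[6] <- "A"
  d <- tn93_distance(paste(a, collapse = ""), paste(b2, collapse = ""),
                     tn93_params(Inf))
  Q2 <- 2 / 100
  expect_equal(d, -0.5 * log(1 - Q2) - 0.25 * log(1 - 2 * Q2),
               tolerance = 1e-9)
})

test_that("TN93 agrees with the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(10)
  for (rep in 1:10) {
    a <- random_seq(400)
    bc <- strsplit(a, "")[[1]]
    idx <- sample(400, 12)
    bc[idx] <- sapply(bc[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1))
    b <- paste(bc, collapse = "")
    bin <- ape::as.DNAbin(list(a = strsplit(tolower(a), "")[[1]],
                               b = strsplit(tolower(b), "")[[1]]))
    expect_equal(tn93_distance(a, b, tn93_params(Inf)),
                 as.numeric(ape::dist.dna(bin, model = "TN93")),
                 tolerance = 1e-8)
    expect_equal(tn93_distance(a, b, tn93_params(0.325)),
                 as.numeric(ape::dist.dna(bin, model = "TN93",
                                          gamma = 0.325)),
                 tolerance = 1e-8)
  }
})

test_that("TN93 excludes ambiguous sites pairwise", {
  a <- "ACGTACGTAC"
  b <- "ACGTNCGTAC"                      # N site dropped, no differences
  expect_equal(tn93_distance(a, b), 0)
  expect_error(tn93_distance("NNNN", "ACGT"), "comparable")
})

test_that("pairwise Fst matches the explicit AMOVA partition on 4+4 toys", {
  set.seed(3)
  seqs <- c(a1 = "ACGTACGTAA", a2 = "ACGTACGTAC", a3 = "ACGTACGTAG",
            a4 = "ACGTACGTAT", b1 = "ACGAACGAAA", b2 = "ACGAACGAAC",
            b3 = "ACGAACGAAG", b4 = "ACGAACGCAT")
  groups <- setNames(rep(c("A", "B"), each = 4), names(seqs))
  res <- pairwise_fst(seqs, groups, n_permutations = 200, seed = 5)
  d <- tn93_matrix(seqs)
  expect_equal(res$fst["A", "B"],
               brute_force_phist(d, unname(groups)), tolerance = 1e-9)
  expect_equal(res$fst, t(res$fst))
  expect_equal(diag(res$fst), setNames(c(0, 0), c("A", "B")))
  expect_true(all(res$pvalues >= 0 & res$pvalues <= 1))
  expect_error(pairwise_fst(seqs, setNames(c(rep("A", 7), "B"), names(seqs))),
               "fewer than 2")
})

test_that("fixed-difference populations give Fst = 1", {
  seqs <- c(a1 = "AAAA", a2 = "AAAA", b1 = "TTTT", b2 = "TTTT")
  groups <- setNames(c("A", "A", "B", "B"), names(seqs))
  res <- pairwise_fst(seqs, groups, n_permutations = 50, seed = 2)
  expect_equal(res$fst["A", "B"], 1)
})

test_that("Fst is invariant under relabeling and locus permutation", {
  set.seed(8)
  mk_rows <- function(n, hap) t(replicate(n, hap))
  hapA <- strsplit("ACGTACGTGG", "")[[1]]
  hapB <- strsplit("ACCTACGTGA", "")[[1]]
  rows <- rbind(mk_rows(4, hapA), mk_rows(4, hapB))
  # add within-population variation
  rows[2, 1] <- "T"; rows[6, 2] <- "A"
  ids <- paste0("s", 1:8)
  seqs <- setNames(apply(rows, 1, paste, collapse = ""), ids)
  groups <- setNames(rep(c("A", "B"), each = 4), ids)
  base <- pairwise_fst(seqs, groups, n_permutations = 10, seed = 1)$fst["A", "B"]
  # shuffle samples within populations
  perm <- c(sample(1:4), sample(5:8))
  expect_equal(pairwise_fst(seqs[perm], groups, n_permutations = 10,
                            seed = 1)$fst["A", "B"], base)
  # permute loci columns
  cols <- sample(10)
  seqs2 <- setNames(apply(rows[, cols], 1, paste, collapse = ""), ids)
  expect_equal(pairwise_fst(seqs2, groups, n_permutations = 10,
                            seed = 1)$fst["A", "B"], base)
})

test_that("null populations give near-zero Fst and calibrated p-values", {
  # two populations drawn from one pool: |Fst| < 0.05 and p > 0.05 in at
  # least 90% of replicates
  set.seed(30)
  haps <- replicate(20, random_seq(60))
  ok <- 0
  n_rep <- 20
  for (r in 1:n_rep) {
    seqs <- setNames(sample(haps, 160, replace = TRUE), paste0("s", 1:160))
    groups <- setNames(rep(c("X", "Y"), each = 80), names(seqs))
    res <- pairwise_fst(seqs, groups, n_permutations = 200, seed = 100 + r)
    if (abs(res$fst["X", "Y"]) < 0.05 && res$pvalues["X", "Y"] > 0.05)
      ok <- ok + 1
  }
  expect_gte(ok, 0.9 * n_rep)
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(31)
  haps <- replicate(5, random_seq(50))
  pvals <- sapply(1:50, function(r) {
    seqs <- setNames(sample(haps, 16, replace = TRUE), paste0("s", 1:16))
    groups <- setNames(rep(c("X", "Y"), each = 8), names(seqs))
    pairwise_fst(seqs, groups, n_permutations = 100,
                 seed = 500 + r)$pvalues["X", "Y"]
  })
  ks <- max(abs(sort(pvals) - (1:50) / 50))
  expect_lt(ks, 1.358 / sqrt(50))   # 5% Kolmogorov-Smirnov band
})

test_that("Fst increases along a synthetic divergence ladder", {
  set.seed(32)
  base <- strsplit(random_seq(80), "")[[1]]
  mean_fst <- sapply(c(1, 4, 8), function(k) {
    reps <- sapply(1:10, function(r) {
      hapA <- base
      hapB <- base
      idx <- sample(80, k)
      hapB[idx] <- sapply(hapB[idx], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1))
      noisy <- function(h, n) t(sapply(1:n, function(i) {
        j <- sample(80, 1)
        h[j] <- sample(setdiff(c("A", "C", "G", "T"), h[j]), 1)
        h
      }))
      rows <- rbind(noisy(hapA, 6), noisy(hapB, 6))
      ids <- paste0("s", 1:12)
      seqs <- setNames(apply(rows, 1, paste, collapse = ""), ids)
      groups <- setNames(rep(c("A", "B"), each = 6), ids)
      pairwise_fst(seqs, groups, n_permutations = 10,
                   seed = r)$fst["A", "B"]
    })
    mean(reps)
  })
  expect_true(all(diff(mean_fst) > 0))
})

test_that("Slatkin linearization transforms and clamps as documented", {
  expect_equal(slatkin_linearize(matrix(0, 1, 1)), matrix(0, 1, 1))
  expect_equal(slatkin_linearize(matrix(c(0, 0.5, 0.5, 0), 2, 2)),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(slatkin_linearize(matrix(c(0, -0.02, -0.02, 0), 2, 2)),
               matrix(0, 2, 2))
  expect_error(slatkin_linearize(matrix(c(0, 1, 1, 0), 2, 2)), "infinity")
})

test_that("classical MDS recovers planar configurations", {
  # three mutually equidistant points form an equilateral triangle
  d3 <- matrix(2, 3, 3); diag(d3) <- 0
  rownames(d3) <- colnames(d3) <- c("a", "b", "c")
  mds3 <- classical_mds(d3)
  expect_equal(as.matrix(dist(mds3$coords)), d3, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(colMeans(mds3$coords), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)

  # planar round-trip at 1e-6
  set.seed(12)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:8)
  mds <- classical_mds(d)
  expect_lt(max(abs(as.matrix(dist(mds$coords)) - d)), 1e-6)

  # two points at distance d map to +/- d/2 on the first axis
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  m2 <- classical_mds(d2, k = 1)
  expect_equal(sort(m2$coords[, 1]), c(-1.5, 1.5), ignore_attr = TRUE)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(classical_mds(asym), "symmetric")
})
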