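# Independent oracles used across the suite.  None of them call the code
# paths they check: alignment is scored by exhaustive enumeration of all
# global alignments, AMOVA by an explicit sum-of-squares partition, SHD by
# the half-L1 identity, and the admixture search by a plain enumerator.

IUPAC6 <- c("A", "C", "G", "T", "R", "N")

# 15x15 column-score lookup built directly from the published weight table
# (not from the package's matrix builder).
oracle_submatrix <- function(w = list(match = 6, i2 = 3, i3 = 2, i4 = 1,
                                      mismatch = -12)) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"),
               W = c("A", "T"), S = c("C", "G"), K = c("G", "T"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  cls <- c(w$match, w$i2, w$i3, w$i4)
  m <- matrix(NA_real_, 15, 15, dimnames = list(names(sets), names(sets)))
  for (a in names(sets)) for (b in names(sets))
    m[a, b] <- if (length(intersect(sets[[a]], sets[[b]])) > 0)
      cls[max(length(sets[[a]]), length(sets[[b]]))] else w$mismatch
  m
}

# Maximum score over ALL global alignments, by exhaustive recursion with
# affine gap runs costed as open + (L-1) * extend.
brute_force_align_score <- function(ref, qry, sub = oracle_submatrix(),
                                    gap_open = -24, gap_extend = -6) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(qry, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, sub[a[i], b[j]] + rec(i + 1, j + 1, 0L))
    if (i <= length(a))   # gap in query row, ref base consumed
      best <- max(best,
                  (if (state == 1L) gap_extend else gap_open) +
                    rec(i + 1, j, 1L))
    if (j <= length(b))   # gap in reference row
      best <- max(best,
                  (if (state == 2L) gap_extend else gap_open) +
                    rec(i, j + 1, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# Re-score a returned alignment from its gapped rows: column scores plus
# affine gap-run costs, independent of the DP's internal bookkeeping.
rescore_alignment <- function(aln, sub = oracle_submatrix(),
                              gap_open = -24, gap_extend = -6) {
  ra <- strsplit(aln$aligned_ref, "")[[1]]
  qa <- strsplit(aln$aligned_query, "")[[1]]
  s <- 0; run <- 0L   # 0 none, 1 gap-in-query, 2 gap-in-ref
  for (k in seq_along(ra)) {
    if (ra[k] == "-") {
      s <- s + if (run == 2L) gap_extend else gap_open; run <- 2L
    } else if (qa[k] == "-") {
      s <- s + if (run == 1L) gap_extend else gap_open; run <- 1L
    } else {
      s <- s + sub[ra[k], qa[k]]; run <- 0L
    }
  }
  s
}

# Phi-st by explicit sum-of-squares partition (two groups), written from
# the variance-component definitions with plain loops.
brute_force_phist <- function(d, groups) {
  n <- length(groups)
  pops <- unique(groups)
  ss_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (p in pops) {
    idx <- which(groups == p)
    acc <- 0
    if (length(idx) >= 2)
      for (x in 1:(length(idx) - 1)) for (y in (x + 1):length(idx))
        acc <- acc + d[idx[x], idx[y]]
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  np <- sapply(pops, function(p) sum(groups == p))
  s2_within <- ss_within / (n - length(pops))
  n0 <- (n - sum(np^2) / n) / (length(pops) - 1)
  s2_among <- (ss_among / (length(pops) - 1) - s2_within) / n0
  s2_among / (s2_among + s2_within)
}

# SHD by the half-L1 identity over the union of haplogroups.
oracle_shd <- function(a, b) {
  hgs <- union(names(a$freqs), names(b$freqs))
  fa <- setNames(numeric(length(hgs)), hgs); fa[names(a$freqs)] <- a$freqs
  fb <- setNames(numeric(length(hgs)), hgs); fb[names(b$freqs)] <- b$freqs
  sum(abs(fa - fb)) / 2
}

# Plain enumerator over subsets and grids for the admixture search.
brute_force_mitomix <- function(test, pool, k_min, k_max, grid_step) {
  labels <- sapply(pool, function(p) p$population)
  units <- round(1 / grid_step)
  comps <- function(u, k) {
    if (k == 1) return(list(u))
    out <- list()
    for (f in 1:(u - k + 1))
      for (rest in comps(u - f, k - 1)) out[[length(out) + 1]] <- c(f, rest)
    out
  }
  best <- NULL
  for (K in k_min:k_max) {
    for (sub in utils::combn(length(pool), K, simplify = FALSE)) {
      for (w in comps(units, K)) {
        ww <- w * grid_step
        hgs <- sort(unique(unlist(c(list(names(test$freqs)),
                                    lapply(pool[sub],
                                           function(p) names(p$freqs))))))
        mix <- setNames(numeric(length(hgs)), hgs)
        for (x in seq_along(sub)) {
          f <- pool[[sub[x]]]$freqs
          mix[names(f)] <- mix[names(f)] + ww[x] * f
        }
        tv <- setNames(numeric(length(hgs)), hgs)
        tv[names(test$freqs)] <- test$freqs
        d <- sum(abs(tv - mix)) / 2
        if (is.null(best) || d < best$shd - 1e-12)
          best <- list(shd = d, K = K, labels = labels[sub], w = ww)
      }
    }
  }
  best
}

# Small three-population synthetic fixture used by pipeline tests.
make_synthetic_fixture <- function(dir, seed = 11L, n_per_pop = 6L,
                                   reference_length = 400L,
                                   missing_rate = 0.002) {
  tree <- generate_tree(3, 3, 2, seed = seed)
  model <- generate_haplotype_model(tree, reference_length = reference_length,
                                    snps_per_node = 2L, indel_fraction = 0.25,
                                    private_mutation_rate = 0.5,
                                    missing_rate = missing_rate, seed = seed + 1L)
  leaves <- setdiff(tree$nodes, tree$parent)
  majors <- tree$nodes[tree$parent == tree$root & !is.na(tree$parent)]
  prof <- lapply(seq_along(majors), function(i) {
    lv <- leaves[startsWith(leaves, majors[i])]
    hg_profile(setNames(rep(1 / length(lv), length(lv)), lv),
               population = paste0("P", i))
  })
  pops <- lapply(seq_along(prof), function(i)
    sample_population(prof[[i]], n_per_pop, model, seed = seed + 10L + i))
  files <- write_population_files(pops, dir)
  ref_fa <- file.path(dir, "reference.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(reference = model$reference)), ref_fa)
  list(tree = tree, model = model, profiles = prof, pops = pops,
       files = c(files, reference = ref_fa))
}
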