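# Sequence-based population differentiation: Tamura-Nei (1993) distances
# with gamma rate heterogeneity, distance-based AMOVA pairwise Fst (Phi-st)
# with permutation p-values, Slatkin linearization, and classical MDS.

#' Tamura-Nei 1993 parameters
#'
#' @param gamma_alpha Gamma shape for among-site rate heterogeneity
#'   (default 0.325); `Inf` disables the gamma correction.
#' @param deletion `"pairwise"` (default) drops sites with `N`/ambiguity or
#'   gaps per sequence pair; `"complete"` drops them across all sequences.
#' @return An object of class `tn93_params`.
#' @export
tn93_params <- function(gamma_alpha = 0.325, deletion = c("pairwise", "complete")) {
  abort_if(!is.numeric(gamma_alpha) || gamma_alpha <= 0,
           "gamma_alpha must be positive")
  structure(list(gamma_alpha = gamma_alpha,
                 deletion = match.arg(deletion)),
            class = "tn93_params")
}

# gamma-corrected analogue of -log(w): alpha * (w^(-1/alpha) - 1).
# At substitution saturation the estimator diverges (w <= 0); w is floored
# at 1e-8 so saturated pairs get a large finite distance instead of NaN
# (recoded variable-position strings of fixed haplotypes are fully
# divergent by construction, and AMOVA only needs the distances' order).
tn93_log <- function(w, alpha) {
  w <- pmax(w, 1e-8)
  if (is.infinite(alpha)) -log(w) else alpha * (w^(-1 / alpha) - 1)
}

#' Tamura-Nei 1993 distance between two sequences
#'
#' Closed-form TN93 distance distinguishing the two transition classes
#' (A<->G and C<->T) from transversions, with gamma-distributed rate
#' heterogeneity.  Base frequencies are estimated from the two sequences
#' pooled.  Sites where either letter is not an unambiguous A/C/G/T are
#' excluded pairwise.
#'
#' @param seq_a,seq_b Equal-length character strings (or character vectors
#'   of single letters).
#' @param params A [tn93_params] object.
#' @return The distance (substitutions per site); `0` iff no differences at
#'   comparable sites.
#' @export
tn93_distance <- function(seq_a, seq_b, params = tn93_params()) {
  a <- if (length(seq_a) == 1) seq_chars(seq_a)[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1) seq_chars(seq_b)[[1]] else toupper(seq_b)
  abort_if(length(a) != length(b), "sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  abort_if(!any(ok), "no comparable (unambiguous) sites")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (all(a == b)) return(0)

  f <- (table(factor(a, levels = c("A", "C", "G", "T"))) +
        table(factor(b, levels = c("A", "C", "G", "T")))) / (2 * n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT

  diff <- a != b
  pair <- paste0(pmin(a, b), pmax(a, b))
  P1 <- sum(diff & pair == "AG") / n          # purine transitions
  P2 <- sum(diff & pair == "CT") / n          # pyrimidine transitions
  Q  <- sum(diff & !(pair %in% c("AG", "CT"))) / n  # transversions

  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  alpha <- params$gamma_alpha

  # a class with no possible pairs (k = 0) contributes nothing
  d <- 0
  if (k1 > 0) d <- d + k1 * tn93_log(1 - P1 / k1 - Q / (2 * gR), alpha)
  if (k2 > 0) d <- d + k2 * tn93_log(1 - P2 / k2 - Q / (2 * gY), alpha)
  if (gR > 0 && gY > 0)
    d <- d + k3 * tn93_log(1 - Q / (2 * gR * gY), alpha)
  max(d, 0)
}

#' Pairwise TN93 distance matrix for a set of sequences
#'
#' @param seqs Named character vector of equal-length sequences (recoded
#'   variant strings or full genomes).
#' @param params A [tn93_params] object.
#' @return A symmetric numeric matrix.
#' @export
tn93_matrix <- function(seqs, params = tn93_params()) {
  chars <- seq_chars(seqs)
  if (params$deletion == "complete") {
    keep <- Reduce(`&`, lapply(chars, function(ch) ch %in% c("A", "C", "G", "T")))
    abort_if(!any(keep), "no site is unambiguous in all sequences")
    chars <- lapply(chars, `[`, keep)
  }
  n <- length(chars)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in 1:(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- tn93_distance(chars[[i]], chars[[j]], params)
  d
}

# Distance-based AMOVA (two or more groups) on a distance matrix whose
# entries act as squared inter-individual deviations; returns Phi-st.
amova_phist <- function(d2, groups) {
  n <- nrow(d2)
  pops <- unique(groups)
  P <- length(pops)
  np <- vapply(pops, function(p) sum(groups == p), numeric(1))
  ssd_total <- sum(d2[upper.tri(d2)]) / n
  ssd_within <- 0
  for (p in pops) {
    idx <- which(groups == p)
    dpp <- d2[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(dpp[upper.tri(dpp)]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1
  df_within <- n - P
  sigma_w <- ssd_within / df_within
  n0 <- (n - sum(np^2) / n) / (P - 1)
  sigma_a <- (ssd_among / df_among - sigma_w) / n0
  if (sigma_a + sigma_w == 0) return(0)
  sigma_a / (sigma_a + sigma_w)
}

#' Pairwise population Fst with permutation p-values
#'
#' For every pair of populations, computes the distance-based AMOVA
#' fixation index (Phi-st) from the TN93 distance matrix of their samples'
#' recoded sequences: the among-population variance component over the
#' total.  Significance is assessed by permuting individuals between the
#' two populations and recomputing Phi-st; the p-value is the fraction of
#' permuted replicates at least as large as the observed value.
#'
#' @param table A `variant_table` (or a named character vector of
#'   equal-length sequences).
#' @param groups Named vector mapping sample to population; every
#'   population needs >= 2 samples.
#' @param params A [tn93_params] object.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return An object of class `fst_result`: `populations`, symmetric `fst`
#'   and `pvalues` matrices, `n_permutations`.  Negative Fst estimates are
#'   reported as computed.
#' @export
pairwise_fst <- function(table, groups, params = tn93_params(),
                         n_permutations = 10000L, seed = 0L) {
  seqs <- if (inherits(table, "variant_table"))
    apply(table$matrix, 1, paste, collapse = "")
  else table
  abort_if(is.null(names(seqs)), "samples must be named")
  miss <- setdiff(names(seqs), names(groups))
  abort_if(length(miss) > 0, "samples without population: ",
           paste(miss, collapse = ", "))
  groups <- groups[names(seqs)]
  pops <- unique(unname(groups))
  small <- pops[vapply(pops, function(p) sum(groups == p) < 2, logical(1))]
  abort_if(length(small) > 0, "populations with fewer than 2 samples: ",
           paste(small, collapse = ", "))
  d <- tn93_matrix(seqs, params)
  P <- length(pops)
  fst <- matrix(0, P, P, dimnames = list(pops, pops))
  pval <- matrix(1, P, P, dimnames = list(pops, pops))
  with_seed(seed, {
    for (i in seq_len(P - 1)) {
      for (j in (i + 1):P) {
        idx <- which(groups %in% c(pops[i], pops[j]))
        dij <- d[idx, idx, drop = FALSE]
        g <- unname(groups[idx])
        obs <- amova_phist(dij, g)
        perm <- vapply(seq_len(n_permutations), function(k)
          amova_phist(dij, sample(g)), numeric(1))
        fst[i, j] <- fst[j, i] <- obs
        pval[i, j] <- pval[j, i] <- mean(perm >= obs - 1e-12)
      }
    }
  })
  structure(list(populations = pops, fst = fst, pvalues = pval,
                 n_permutations = n_permutations),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("fst_result over", length(x$populations), "populations (",
      x$n_permutations, "permutations )\n")
  print(round(x$fst, 5))
  invisible(x)
}

#' Slatkin linearization of an Fst matrix
#'
#' Elementwise `Fst / (1 - Fst)`, making Fst approximately linear in
#' divergence time.  Negative Fst estimates are clamped to 0 first so the
#' result is a valid distance input for ordination.
#'
#' @param fst Numeric matrix (or `fst_result`) with entries < 1.
#' @return Matrix of linearized values.
#' @export
slatkin_linearize <- function(fst) {
  if (inherits(fst, "fst_result")) fst <- fst$fst
  abort_if(any(fst >= 1), "Fst = 1 linearizes to infinity")
  fst <- pmax(fst, 0)
  fst / (1 - fst)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric distance matrix into `k` Euclidean dimensions via the
#' eigendecomposition of the double-centered Gram matrix (`stats::cmdscale`).
#'
#' @param dist Square symmetric matrix, zero diagonal.
#' @param k Output dimensionality (default 2).
#' @return An object of class `mds_coordinates`: `populations`, `coords`
#'   (n x k, column-centered) and `eigenvalues`.
#' @export
classical_mds <- function(dist, k = 2L) {
  if (inherits(dist, "fst_result")) dist <- slatkin_linearize(dist)
  abort_if(nrow(dist) != ncol(dist) ||
             !isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)),
           "distance matrix must be square and symmetric")
  abort_if(any(diag(dist) != 0), "distance matrix must have a zero diagonal")
  res <- cmdscale(as.dist(dist), k = k, eig = TRUE)
  structure(list(populations = rownames(dist),
                 coords = res$points,
                 eigenvalues = res$eig),
            class = "mds_coordinates")
}

#' Write Fst, p-value and MDS results as tab-separated files
#'
#' @param fst An `fst_result`.
#' @param mds An `mds_coordinates` (optional).
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_fst_outputs <- function(fst, mds = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  f <- file.path(dir, "fst_matrix.tsv")
  write.table(fst$fst, f, sep = "\t", quote = FALSE, col.names = NA)
  p <- file.path(dir, "fst_pvalues.tsv")
  write.table(fst$pvalues, p, sep = "\t", quote = FALSE, col.names = NA)
  paths <- c(fst = f, pvalues = p)
  if (!is.null(mds)) {
    m <- file.path(dir, "mds_coordinates.tsv")
    df <- data.frame(population = mds$populations, mds$coords)
    write.table(df, m, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, mds = m)
  }
  invisible(paths)
}
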