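# MITOMIX: exhaustive search over combinations and mixing proportions of K
# candidate source populations minimizing SHD to a test population.

#' MITOMIX search configuration
#'
#' @param k_min,k_max Range of source-set sizes searched (defaults 1 and 6).
#' @param grid_step Proportion grid resolution (default 0.01, i.e. integer
#'   percentages); must satisfy `0 < grid_step <= 0.5` and divide 1 evenly.
#' @param exclude_self Drop the test population from the candidate pool
#'   (default `TRUE`).
#' @param top_n Number of best solutions reported (default 20).
#' @param corrected Evaluate with [shd_corrected] instead of raw [shd].
#' @param correction_weight Credit for the corrected variant.
#' @param tree Optional haplogroup tree for the corrected variant.
#' @param prune Use the admissible L1 lower bound to skip source subsets
#'   that cannot beat the current `top_n` (never changes the result).
#' @return An object of class `mix_search_config`.
#' @export
mix_search_config <- function(k_min = 1L, k_max = 6L, grid_step = 0.01,
                              exclude_self = TRUE, top_n = 20L,
                              corrected = FALSE, correction_weight = 0.5,
                              tree = NULL, prune = TRUE) {
  abort_if(grid_step <= 0 || grid_step > 0.5, "grid_step must be in (0, 0.5]")
  m <- round(1 / grid_step)
  abort_if(abs(m * grid_step - 1) > 1e-9, "grid_step must divide 1 evenly")
  abort_if(k_min < 1 || k_min > k_max, "need 1 <= k_min <= k_max")
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 grid_step = grid_step, grid_units = as.integer(m),
                 exclude_self = isTRUE(exclude_self),
                 top_n = as.integer(top_n), corrected = isTRUE(corrected),
                 correction_weight = correction_weight, tree = tree,
                 prune = isTRUE(prune)),
            class = "mix_search_config")
}

#' Evaluate one admixture hypothesis
#'
#' SHD (or corrected SHD) between the test profile and the convex
#' combination of the given source profiles.
#'
#' @param test An [hg_profile].
#' @param sources List of source [hg_profile]s.
#' @param weights Mixing proportions (non-negative, summing to 1).
#' @param corrected Use the corrected SHD.
#' @param tree,correction_weight Passed to [shd_corrected].
#' @return The achieved distance in `[0, 1]`.
#' @export
evaluate_mix <- function(test, sources, weights, corrected = FALSE,
                         tree = NULL, correction_weight = 0.5) {
  mix <- admix_profiles(sources, weights, population = "mix")
  if (corrected) shd_corrected(test, mix, tree, correction_weight)
  else shd(test, mix)
}

# all compositions of `units` into k strictly positive integer parts,
# returned as a (choose(units-1, k-1)) x k integer matrix in lexicographic
# order.
compositions <- function(units, k) {
  if (k == 1) return(matrix(units, 1, 1))
  out <- list()
  for (first in seq_len(units - k + 1)) {
    rest <- compositions(units - first, k - 1)
    out[[first]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# frequency matrix (profiles x union-of-haplogroups) for fast vectorized SHD
profile_matrix <- function(profiles, hgs) {
  m <- matrix(0, length(profiles), length(hgs),
              dimnames = list(NULL, hgs))
  for (i in seq_along(profiles)) {
    f <- profiles[[i]]$freqs
    m[i, names(f)] <- f
  }
  m
}

#' Exhaustive admixture search (MITOMIX)
#'
#' For each source-set size K from `k_min` to `k_max`, enumerates every
#' K-subset of the candidate pool and every mixing-proportion vector on the
#' grid (positive multiples of `grid_step` summing to 1), and reports the
#' `top_n` hypotheses with the smallest SHD to the test population.  Ties
#' are broken deterministically by smaller K, then lexicographic source
#' labels, then lexicographic weights.
#'
#' With raw SHD the achieved distance of the true mixture is analytically
#' bounded by the grid resolution, so constructed mixtures are recovered to
#' within one grid step.  An admissible lower bound (the SHD against the
#' elementwise maximum of the subset's profiles, which no convex
#' combination can beat) optionally prunes hopeless subsets without
#' affecting the optimum.
#'
#' @param test An [hg_profile]; the population to decompose.
#' @param pool Named list of candidate source [hg_profile]s.
#' @param config A [mix_search_config].
#' @return A data frame of class `admixture_solutions`, one row per
#'   solution: `rank`, `shd`, `K`, `sources` (comma-joined
#'   `label:proportion` pairs, descending proportion) and list column
#'   `weights` (named numeric vectors).
#' @export
mitomix_search <- function(test, pool, config = mix_search_config()) {
  abort_if(length(pool) == 0, "candidate pool is empty")
  labels <- vapply(pool, `[[`, character(1), "population")
  names(pool) <- labels
  if (config$exclude_self)
    pool <- pool[labels != test$population]
  labels <- names(pool)
  abort_if(config$k_max > length(pool),
           "k_max exceeds the candidate pool size (", length(pool), ")")
  hgs <- sort(unique(c(names(test$freqs),
                       unlist(lapply(pool, function(p) names(p$freqs))))))
  S <- profile_matrix(pool, hgs)
  tvec <- profile_matrix(list(test), hgs)[1, ]
  units <- config$grid_units

  sols <- list()
  worst <- Inf
  for (K in config$k_min:config$k_max) {
    subsets <- combn(length(pool), K)
    comp <- compositions(units, K) * config$grid_step
    for (c_i in seq_len(ncol(subsets))) {
      idx <- subsets[, c_i]
      Ssub <- S[idx, , drop = FALSE]
      if (config$prune && !config$corrected && is.finite(worst)) {
        ub <- apply(Ssub, 2, max)   # mix_h <= max_k source_kh
        lb <- 1 - sum(pmin(tvec, ub))
        if (lb > worst + 1e-12) next
      }
      mixes <- comp %*% Ssub      # each row: one candidate mixture profile
      if (config$corrected) {
        d <- vapply(seq_len(nrow(mixes)), function(r) {
          f <- mixes[r, ]
          shd_corrected(test, hg_profile(f[f > 0] / sum(f), "mix"),
                        config$tree, config$correction_weight)
        }, numeric(1))
      } else {
        tm <- matrix(tvec, nrow(mixes), length(tvec), byrow = TRUE)
        d <- 1 - rowSums(pmin(mixes, tm))
      }
      keep <- which(d <= worst + 1e-12)
      if (length(keep) == 0) next
      sols[[length(sols) + 1L]] <- data.frame(
        shd = d[keep], K = K,
        subset = c_i, row = keep,
        stringsAsFactors = FALSE,
        labels = I(replicate(length(keep), labels[idx], simplify = FALSE)),
        w = I(lapply(keep, function(r) comp[r, ])))
      # track the current top_n cutoff to enable pruning
      allshd <- sort(unlist(lapply(sols, `[[`, "shd")))
      if (length(allshd) >= config$top_n)
        worst <- allshd[config$top_n]
    }
  }
  all <- do.call(rbind, sols)
  lab_key <- vapply(seq_len(nrow(all)), function(i)
    paste(all$labels[[i]], collapse = ","), character(1))
  w_key <- vapply(seq_len(nrow(all)), function(i)
    paste(sprintf("%.6f", all$w[[i]]), collapse = ","), character(1))
  ord <- order(all$shd, all$K, lab_key, w_key)
  all <- all[ord, , drop = FALSE][seq_len(min(config$top_n, nrow(all))), ,
                                  drop = FALSE]
  weights <- lapply(seq_len(nrow(all)), function(i) {
    w <- stats::setNames(as.numeric(all$w[[i]]), all$labels[[i]])
    sort(w, decreasing = TRUE)
  })
  out <- data.frame(
    rank = seq_len(nrow(all)),
    shd = all$shd,
    K = all$K,
    sources = vapply(weights, function(w)
      paste(sprintf("%s:%.2f", names(w), w), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out$weights <- weights
  attr(out, "test_population") <- test$population
  class(out) <- c("admixture_solutions", "data.frame")
  out
}

#' Per-source proportion ranges across the top solutions
#'
#' The study reports admixture components as ranges (min-max proportion of
#' each source across the near-optimal solutions); this summarizes a
#' [mitomix_search] result the same way.
#'
#' @param solutions An `admixture_solutions` data frame.
#' @return Data frame with `source`, `min`, `max`, `n_solutions`.
#' @export
mitomix_ranges <- function(solutions) {
  all <- unlist(lapply(solutions$weights, names))
  src <- sort(unique(all))
  do.call(rbind, lapply(src, function(s) {
    w <- vapply(solutions$weights, function(x) x[s][[1]] %||% NA_real_,
                numeric(1))
    w <- w[!is.na(w)]
    data.frame(source = s, min = min(w), max = max(w),
               n_solutions = length(w), stringsAsFactors = FALSE)
  }))
}

#' Restrict the candidate pool to contemporaneous-or-older populations
#'
#' When decomposing an ancient population, later populations cannot be its
#' sources; this keeps only pool members whose epoch is not later than the
#' test epoch (equal epochs are retained).
#'
#' @param pool Named list of [hg_profile]s.
#' @param epochs Named numeric vector: population label to epoch (larger =
#'   more recent, e.g. years CE).
#' @param test_epoch Epoch of the test population.
#' @return The filtered pool (possibly empty).
#' @export
ancient_only_filter <- function(pool, epochs, test_epoch) {
  labels <- vapply(pool, `[[`, character(1), "population")
  miss <- setdiff(labels, names(epochs))
  abort_if(length(miss) > 0, "populations without epoch tag: ",
           paste(miss, collapse = ", "))
  pool[epochs[labels] <= test_epoch]
}
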