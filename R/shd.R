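# Shared Haplogroup Distance: population distance in [0,1] from the overlap
# of sub-haplogroup frequency profiles, with a corrected variant crediting
# direct progenitor/progeny lineages.

#' Build haplogroup frequency profiles from assignment tables
#'
#' @param assignments Named character vector mapping sample to
#'   sub-haplogroup.
#' @param groups Named character vector mapping sample to population.
#' @return A named list of [hg_profile] objects, one per population, each
#'   with the per-population relative sub-haplogroup frequencies and the
#'   sample count in `n_samples`.
#' @export
profile_from_assignments <- function(assignments, groups) {
  abort_if(is.null(names(assignments)) || is.null(names(groups)),
           "assignments and groups must be named by sample")
  miss <- setdiff(names(assignments), names(groups))
  abort_if(length(miss) > 0, "samples without population: ",
           paste(miss, collapse = ", "))
  pops <- unique(unname(groups[names(assignments)]))
  profs <- lapply(pops, function(p) {
    ids <- names(assignments)[unname(groups[names(assignments)]) == p]
    abort_if(length(ids) == 0, "empty population: ", p)
    tab <- table(assignments[ids])
    hg_profile(stats::setNames(as.numeric(tab) / length(ids), names(tab)),
               population = p, n_samples = length(ids))
  })
  stats::setNames(profs, pops)
}

#' Shared Haplogroup Distance between two populations
#'
#' `1 - sum_h min(f_a(h), f_b(h))`: one minus the shared frequency mass.
#' Equals 0 iff the two profiles carry the same sub-haplogroups at
#' identical frequencies and 1 iff they share no sub-haplogroup; symmetric,
#' and equal to half the L1 distance between the frequency vectors, so the
#' triangle inequality holds.  For a target mixed as `w A + (1-w) B` with
#' disjoint A and B, `shd(target, A) = 1 - w` exactly: the distance is
#' proportional to the admixing ratio.
#'
#' @param a,b [hg_profile] objects.
#' @return Distance in `[0, 1]`.
#' @export
shd <- function(a, b) {
  abort_if(!inherits(a, "hg_profile") || !inherits(b, "hg_profile"),
           "arguments must be hg_profile objects")
  shared <- intersect(names(a$freqs), names(b$freqs))
  1 - sum(pmin(a$freqs[shared], b$freqs[shared]))
}

# parent of a haplogroup label: explicit tree edge if available, otherwise
# mtDNA-nomenclature prefix stripping (drop the trailing digit- or
# letter-run: "N1a1a1a1a" -> "N1a1a1a1").
hg_parent <- function(label, tree = NULL) {
  if (!is.null(tree) && label %in% names(tree$parent)) {
    p <- unname(tree$parent[[label]])
    if (is.na(p) || identical(p, tree$root)) return(NA_character_)
    return(p)
  }
  p <- sub("([0-9]+|[a-z]+|['*]+)$", "", label)
  if (identical(p, label) || !nzchar(p)) NA_character_ else p
}

#' Corrected Shared Haplogroup Distance
#'
#' Like [shd], but frequency mass left unmatched at a sub-haplogroup may
#' match mass of its direct progenitor or progeny lineage (one nomenclature
#' step) at partial credit `correction_weight`, reflecting that a
#' population carrying `N1a1a1a1a` is maternally close to one carrying
#' `N1a1a1a1` even though the terminal labels differ.  With
#' `correction_weight = 0` the raw [shd] is recovered; the corrected value
#' never exceeds the raw one.
#'
#' Residual masses after exact matching are paired greedily along
#' parent-child edges (each unit of residual mass is credited at most
#' once), and the credited mass counts `correction_weight`-fold as shared.
#'
#' @param a,b [hg_profile] objects.
#' @param tree Optional [generate_tree] result used to resolve parenthood;
#'   without it, parenthood falls back to nomenclature-prefix stripping.
#' @param correction_weight Credit in `[0, 1]` for one-step lineage matches
#'   (default 0.5).
#' @return Distance in `[0, 1]`.
#' @export
shd_corrected <- function(a, b, tree = NULL, correction_weight = 0.5) {
  abort_if(correction_weight < 0 || correction_weight > 1,
           "correction_weight must be in [0, 1]")
  base <- shd(a, b)
  if (correction_weight == 0) return(base)
  shared <- intersect(names(a$freqs), names(b$freqs))
  res_a <- a$freqs
  res_a[shared] <- res_a[shared] - pmin(a$freqs[shared], b$freqs[shared])
  res_b <- b$freqs
  res_b[shared] <- res_b[shared] - pmin(a$freqs[shared], b$freqs[shared])
  res_a <- res_a[res_a > 1e-12]
  res_b <- res_b[res_b > 1e-12]
  credit <- 0
  for (ha in names(res_a)) {
    if (res_a[[ha]] <= 1e-12) next
    pa <- hg_parent(ha, tree)
    for (hb in names(res_b)) {
      if (res_b[[hb]] <= 1e-12) next
      related <- (!is.na(pa) && pa == hb) ||
        (!is.na(hg_parent(hb, tree)) && hg_parent(hb, tree) == ha)
      if (related) {
        m <- min(res_a[[ha]], res_b[[hb]])
        credit <- credit + m
        res_a[[ha]] <- res_a[[ha]] - m
        res_b[[hb]] <- res_b[[hb]] - m
      }
    }
  }
  max(0, base - correction_weight * credit)
}

#' Pairwise SHD matrix over a set of population profiles
#'
#' @param profiles List of [hg_profile] objects with distinct population
#'   labels.
#' @param corrected Use [shd_corrected] instead of raw [shd].
#' @param tree Optional haplogroup tree for the corrected variant.
#' @param correction_weight Credit for one-step lineage matches.
#' @return An object of class `shd_matrix`: `populations`, symmetric
#'   `values` in `[0, 1]` with zero diagonal, and the correction settings.
#' @export
shd_matrix <- function(profiles, corrected = FALSE, tree = NULL,
                       correction_weight = 0.5) {
  abort_if(length(profiles) < 2, "need at least two profiles")
  pops <- vapply(profiles, `[[`, character(1), "population")
  abort_if(anyDuplicated(pops) > 0, "duplicate population labels: ",
           paste(unique(pops[duplicated(pops)]), collapse = ", "))
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- if (corrected)
        shd_corrected(profiles[[i]], profiles[[j]], tree, correction_weight)
      else shd(profiles[[i]], profiles[[j]])
  structure(list(populations = pops, values = m, corrected = corrected,
                 correction_weight = if (corrected) correction_weight else 0),
            class = "shd_matrix")
}

#' @export
print.shd_matrix <- function(x, ...) {
  cat("shd_matrix over", length(x$populations), "populations",
      if (x$corrected) sprintf("(corrected, weight %.2f)", x$correction_weight)
      else "(raw)", "\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Write an SHD matrix as a tab-separated file
#'
#' @param x An `shd_matrix`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_shd_matrix <- function(x, path) {
  write.table(x$values, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read sample-to-population / sample-to-haplogroup tables
#'
#' Tab-separated, two or more columns; the first column is the sample id,
#' `column` picks the attribute column (by name or index).
#'
#' @param path Input file.
#' @param column Attribute column (default 2).
#' @return Named character vector keyed by sample id.
#' @export
read_assignment_table <- function(path, column = 2L) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[column]]), df[[1]])
}
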