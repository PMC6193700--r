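# Synthetic mitogenome populations: haplogroup hierarchies, frequency
# profiles, admixed profiles, and per-sample sequences carrying
# haplogroup-defining variants plus private mutations and missing data.

#' Generate a synthetic haplogroup hierarchy
#'
#' Builds a rooted tree of haplogroup labels that mimics mtDNA nomenclature:
#' each child's label extends its parent's label by one segment (letters and
#' digits alternate, as in `H` > `H1` > `H1a`).  The root is an unnamed
#' common ancestor; its children are the `n_major` major clades.
#'
#' `depth` counts label-extension levels below the root, so `depth = 1`
#' yields major clades that are themselves leaves, and each major clade has
#' `branching^(depth - 1)` leaf descendants.
#'
#' @param n_major Number of major clades (root children), >= 1.
#' @param depth Number of levels below the root, >= 1.
#' @param branching Children per internal node below the major level, >= 1.
#' @param seed Integer seed; fixes which major-clade letters are drawn.
#' @return An object of class `haplogroup_tree`: a list with `nodes`
#'   (character vector of labels, root first) and `parent` (named character
#'   vector mapping each non-root node to its parent; the root maps to `NA`).
#' @examples
#' tr <- generate_tree(2, 2, 2, seed = 1)
#' tr$nodes
#' @export
generate_tree <- function(n_major, depth, branching, seed = 0L) {
  abort_if(!is.numeric(n_major) || n_major < 1, "n_major must be >= 1")
  abort_if(!is.numeric(depth) || depth < 1, "depth must be >= 1")
  abort_if(!is.numeric(branching) || branching < 1, "branching must be >= 1")
  abort_if(n_major > 26, "n_major must be <= 26 (one letter per major clade)")
  abort_if(branching > 26, "branching must be <= 26")
  n_major <- as.integer(n_major); depth <- as.integer(depth)
  branching <- as.integer(branching)

  majors <- with_seed(seed, sort(sample(LETTERS, n_major)))
  root <- "mt-root"
  nodes <- root
  parent <- c(stats::setNames(NA_character_, root))
  level <- majors
  nodes <- c(nodes, majors)
  parent[majors] <- root
  if (depth > 1) {
    for (lev in 2:depth) {
      # mtDNA nomenclature alternates digits and lowercase letters
      seg <- if (lev %% 2 == 0) as.character(seq_len(branching))
             else letters[seq_len(branching)]
      children <- as.vector(t(outer(level, seg, paste0)))
      parent[children] <- rep(level, each = branching)
      nodes <- c(nodes, children)
      level <- children
    }
  }
  structure(list(nodes = nodes, parent = parent, root = root),
            class = "haplogroup_tree")
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("haplogroup_tree:", length(x$nodes), "nodes,",
      sum(!x$nodes %in% x$parent), "leaves\n")
  invisible(x)
}

tree_leaves <- function(tree) setdiff(tree$nodes, unname(tree$parent))

#' Construct a haplogroup frequency profile
#'
#' @param freqs Named numeric vector of sub-haplogroup frequencies; must be
#'   non-negative and sum to 1 within `1e-9`.
#' @param population Population label.
#' @param n_samples Number of samples the profile was estimated from
#'   (metadata only; SHD is frequency-based).
#' @return An object of class `hg_profile`.
#' @export
hg_profile <- function(freqs, population = "pop", n_samples = NA_integer_) {
  abort_if(is.null(names(freqs)) || any(!nzchar(names(freqs))),
           "frequencies must be named by haplogroup")
  abort_if(any(freqs < 0), "frequencies must be non-negative")
  abort_if(abs(sum(freqs) - 1) > 1e-9, "frequencies must sum to 1")
  abort_if(anyDuplicated(names(freqs)) > 0, "duplicated haplogroup labels")
  structure(list(population = population,
                 freqs = freqs[freqs > 0],
                 n_samples = n_samples),
            class = "hg_profile")
}

#' @export
print.hg_profile <- function(x, ...) {
  cat("hg_profile '", x$population, "': ", length(x$freqs),
      " sub-haplogroups\n", sep = "")
  invisible(x)
}

#' Mix haplogroup profiles as a convex combination
#'
#' Forms the profile of an admixed population from source profiles and
#' mixing proportions: per-haplogroup weighted sums.
#'
#' @param sources List of [hg_profile] objects.
#' @param weights Numeric vector of mixing proportions, same length as
#'   `sources`; non-negative, summing to 1 within `1e-6`.
#' @param population Label for the admixed profile.
#' @return An [hg_profile] for the mixture.
#' @export
admix_profiles <- function(sources, weights, population = "admixed") {
  abort_if(length(sources) == 0, "need at least one source profile")
  abort_if(length(weights) != length(sources),
           "weights and sources must have equal length")
  abort_if(any(weights < 0), "weights must be non-negative")
  abort_if(abs(sum(weights) - 1) > 1e-6, "weights must sum to 1")
  hgs <- sort(unique(unlist(lapply(sources, function(p) names(p$freqs)))))
  mix <- stats::setNames(numeric(length(hgs)), hgs)
  for (i in seq_along(sources)) {
    f <- sources[[i]]$freqs
    mix[names(f)] <- mix[names(f)] + weights[i] * f
  }
  mix <- mix / sum(mix)
  hg_profile(mix, population = population)
}

#' Build a haplotype model over a synthetic reference
#'
#' Draws a random reference sequence and assigns each haplogroup in the tree
#' a set of defining variants; a child haplogroup inherits all defining
#' variants of its parent and adds its own (mtDNA variation is strictly
#' nested along maternal lineages).  Defining variants are SNPs by default;
#' optionally some nodes receive a single-nucleotide insertion or a
#' single-position deletion so the indel-recoding path is exercised.
#'
#' @param tree A [generate_tree] result.
#' @param reference_length Reference length in nt (default the rCRS length
#'   16569; any length >= 100 is accepted so tests can run on short toys).
#' @param snps_per_node New defining SNPs introduced by each node.
#' @param indel_fraction Fraction of non-root nodes whose last defining
#'   variant is an indel instead of a SNP.
#' @param private_mutation_rate Poisson mean of extra private SNPs per
#'   sampled genome.
#' @param missing_rate Per-site probability that a base is masked to `N`.
#' @param seed Integer seed.
#' @return An object of class `haplotype_model`: reference string plus a
#'   per-haplogroup list of defining-variant data frames with columns
#'   `pos`, `kind` ("snp", "ins", "del"), `ref`, `alt`.
#' @export
generate_haplotype_model <- function(tree, reference_length = 16569L,
                                     snps_per_node = 2L,
                                     indel_fraction = 0,
                                     private_mutation_rate = 1,
                                     missing_rate = 0,
                                     seed = 0L) {
  abort_if(reference_length < 100, "reference_length must be >= 100")
  abort_if(snps_per_node < 1, "snps_per_node must be >= 1")
  bases <- c("A", "C", "G", "T")
  non_root <- setdiff(tree$nodes, tree$root)
  n_var <- length(non_root) * snps_per_node
  abort_if(n_var > reference_length - 2,
           "reference too short for the requested number of defining variants")
  with_seed(seed, {
    reference <- paste(sample(bases, reference_length, replace = TRUE),
                       collapse = "")
    ref_chars <- seq_chars(reference)[[1]]
    # distinct positions across the whole tree; keep position 1 and the last
    # position SNP-free so indel anchoring stays interior
    pool <- sample(2:(reference_length - 1), n_var)
    idx <- 0L
    own <- list()
    indel_nodes <- if (indel_fraction > 0)
      sample(non_root, max(0L, round(indel_fraction * length(non_root))))
    else character(0)
    for (node in non_root) {
      pos <- pool[idx + seq_len(snps_per_node)]
      idx <- idx + snps_per_node
      kind <- rep("snp", snps_per_node)
      if (node %in% indel_nodes)
        kind[snps_per_node] <- sample(c("ins", "del"), 1)
      ref <- ref_chars[pos]
      alt <- vapply(seq_along(pos), function(i) {
        switch(kind[i],
               snp = sample(setdiff(bases, ref[i]), 1),
               ins = sample(bases, 1),  # base inserted after pos
               del = "-")
      }, character(1))
      own[[node]] <- data.frame(pos = pos, kind = kind, ref = ref, alt = alt,
                                stringsAsFactors = FALSE)
    }
  })
  # nest: each node's defining set = parent's set + its own
  defining <- list()
  defining[[tree$root]] <- data.frame(pos = integer(), kind = character(),
                                      ref = character(), alt = character(),
                                      stringsAsFactors = FALSE)
  remaining <- non_root
  while (length(remaining) > 0) {
    ready <- remaining[unname(tree$parent[remaining]) %in% names(defining)]
    for (node in ready)
      defining[[node]] <- rbind(defining[[tree$parent[[node]]]], own[[node]])
    remaining <- setdiff(remaining, ready)
  }
  structure(list(reference = reference,
                 defining_variants = defining,
                 private_mutation_rate = private_mutation_rate,
                 missing_rate = missing_rate),
            class = "haplotype_model")
}

# Apply variant records to a reference string; indels applied last-to-first
# so earlier positions keep their coordinates.
apply_variants <- function(reference, variants) {
  chars <- seq_chars(reference)[[1]]
  if (nrow(variants) == 0) return(reference)
  snps <- variants[variants$kind == "snp", , drop = FALSE]
  chars[snps$pos] <- snps$alt
  indels <- variants[variants$kind != "snp", , drop = FALSE]
  if (nrow(indels) > 0) {
    indels <- indels[order(indels$pos, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(indels))) {
      p <- indels$pos[i]
      if (indels$kind[i] == "ins") {
        chars <- append(chars, indels$alt[i], after = p)
      } else {
        chars <- chars[-p]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Sample a synthetic population of mitogenomes
#'
#' Draws each sample's haplogroup from the population profile, builds its
#' genome from the reference by applying the haplogroup's defining variants,
#' then adds Poisson-distributed private SNPs (never at defining-variant
#' positions, so the haplogroup ground truth stays intact) and masks each
#' site to `N` independently with the model's missing rate.
#'
#' @param profile An [hg_profile]; every haplogroup must exist in the model.
#' @param n_samples Number of genomes to draw, >= 1.
#' @param model A [generate_haplotype_model] result.
#' @param seed Integer seed; output is fully deterministic given it.
#' @param prefix Sample-identifier prefix.
#' @return A list with `sequences` (named character vector),
#'   `haplogroups` (named character vector), `population` and
#'   `true_variants` (per-sample variant data frames before `N` masking).
#' @export
sample_population <- function(profile, n_samples, model, seed = 0L,
                              prefix = profile$population) {
  abort_if(!inherits(profile, "hg_profile"), "profile must be an hg_profile")
  abort_if(n_samples < 1, "n_samples must be >= 1")
  unknown <- setdiff(names(profile$freqs), names(model$defining_variants))
  abort_if(length(unknown) > 0,
           "haplogroups absent from the model: ", paste(unknown, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  ref_chars <- seq_chars(model$reference)[[1]]
  reflen <- length(ref_chars)
  ids <- sprintf("%s_%03d", prefix, seq_len(n_samples))
  with_seed(seed, {
    hgs <- sample(names(profile$freqs), n_samples, replace = TRUE,
                  prob = profile$freqs)
    seqs <- character(n_samples)
    true_variants <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      def <- model$defining_variants[[hgs[i]]]
      n_priv <- rpois(1, model$private_mutation_rate)
      if (n_priv > 0) {
        free <- setdiff(seq_len(reflen), def$pos)
        ppos <- sample(free, min(n_priv, length(free)))
        priv <- data.frame(
          pos = ppos, kind = "snp", ref = ref_chars[ppos],
          alt = vapply(ref_chars[ppos],
                       function(r) sample(setdiff(bases, r), 1), character(1)),
          stringsAsFactors = FALSE)
        vars <- rbind(def, priv)
      } else vars <- def
      vars <- vars[order(vars$pos), , drop = FALSE]
      rownames(vars) <- NULL
      g <- apply_variants(model$reference, vars)
      if (model$missing_rate > 0) {
        gc <- seq_chars(g)[[1]]
        mask <- runif(length(gc)) < model$missing_rate
        gc[mask] <- "N"
        g <- paste(gc, collapse = "")
      }
      seqs[i] <- g
      true_variants[[i]] <- vars
    }
  })
  names(seqs) <- ids
  names(hgs) <- ids
  names(true_variants) <- ids
  list(sequences = seqs, haplogroups = hgs,
       population = profile$population, true_variants = true_variants)
}

#' Write synthetic populations to the pipeline's input formats
#'
#' Writes one multi-FASTA with all samples, a tab-separated
#' sample-to-population table and a tab-separated sample-to-haplogroup
#' table; these are exactly the formats the analysis pipeline reads.
#'
#' @param pops List of [sample_population] results.
#' @param dir Output directory (created if missing).
#' @param basename File stem for the three outputs.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_population_files <- function(pops, dir, basename = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- unlist(lapply(pops, `[[`, "sequences"))
  hgs <- unlist(lapply(pops, `[[`, "haplogroups"))
  pop_of <- unlist(lapply(pops, function(p)
    stats::setNames(rep(p$population, length(p$sequences)), names(p$sequences))))
  fasta <- file.path(dir, paste0(basename, ".fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  pop_tab <- file.path(dir, paste0(basename, "_populations.tsv"))
  write.table(data.frame(sample = names(pop_of), population = unname(pop_of)),
              pop_tab, sep = "\t", quote = FALSE, row.names = FALSE)
  hg_tab <- file.path(dir, paste0(basename, "_haplogroups.tsv"))
  write.table(data.frame(sample = names(hgs), haplogroup = unname(hgs)),
              hg_tab, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, populations = pop_tab, haplogroups = hg_tab))
}
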