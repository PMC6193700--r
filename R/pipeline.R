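# End-to-end orchestration: align -> recode -> QC -> (Fst + MDS) and
# (profiles -> SHD -> MITOMIX), with a machine-readable run manifest and
# the subpopulation re-analysis pattern.

#' Pipeline configuration
#'
#' @param fasta Multi-FASTA of sample mitogenomes.
#' @param reference_fasta FASTA with the single reference sequence.
#' @param population_table Tab-separated sample-to-population table.
#' @param haplogroup_table Tab-separated sample-to-haplogroup table.
#' @param output_dir Output directory.
#' @param seed Master seed; every stochastic stage derives its own
#'   substream from it.
#' @param weights [alignment_weights] for the aligner.
#' @param tn93 [tn93_params] for the distance stage.
#' @param n_permutations Fst permutation count.
#' @param max_missing QC threshold on missing/uncertain nucleotides.
#' @param ancient_populations Populations exempt from the QC filter
#'   (the missing-data cutoff applies to modern sequences only).
#' @param exclude_hotspots Apply the hotspot exclusion list.
#' @param run_fst,run_shd,run_mitomix Stage toggles.
#' @param mitomix_test Population to decompose with MITOMIX (default: first
#'   population).
#' @param mitomix_config A [mix_search_config].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, reference_fasta, population_table,
                            haplogroup_table, output_dir, seed = 1L,
                            weights = alignment_weights(),
                            tn93 = tn93_params(),
                            n_permutations = 10000L,
                            max_missing = 500L,
                            ancient_populations = character(0),
                            exclude_hotspots = TRUE,
                            run_fst = TRUE, run_shd = TRUE,
                            run_mitomix = TRUE,
                            mitomix_test = NULL,
                            mitomix_config = mix_search_config(k_max = 3L)) {
  structure(list(fasta = fasta, reference_fasta = reference_fasta,
                 population_table = population_table,
                 haplogroup_table = haplogroup_table,
                 output_dir = output_dir, seed = seed, weights = weights,
                 tn93 = tn93, n_permutations = n_permutations,
                 max_missing = max_missing,
                 ancient_populations = ancient_populations,
                 exclude_hotspots = exclude_hotspots,
                 run_fst = run_fst, run_shd = run_shd,
                 run_mitomix = run_mitomix, mitomix_test = mitomix_test,
                 mitomix_config = mitomix_config),
            class = "pipeline_config")
}

read_fasta_named <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Run the full mitogenome population-genetic pipeline
#'
#' Stages: read inputs; align every sample to the reference and call
#' variants; QC-filter modern samples on missing data; build the recoded
#' variant table (indels as pseudo-SNPs) and apply the hotspot exclusion;
#' report identical-sequence clusters (potential maternal relatives);
#' pairwise Fst with permutation p-values, Slatkin linearization and MDS;
#' haplogroup profiles, the SHD matrix and a MITOMIX decomposition of the
#' configured test population.  All artifacts are written under
#' `config$output_dir` together with a JSON manifest recording inputs,
#' parameters, seeds, per-stage record counts and a digest of every output.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "pipeline_config"), "config must be a pipeline_config")
  for (p in c(config$fasta, config$reference_fasta, config$population_table,
              config$haplogroup_table))
    abort_if(!file.exists(p), "input file does not exist: ", p)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    expr
  }

  seqs <- stage("read inputs", read_fasta_named(config$fasta))
  reference <- read_fasta_named(config$reference_fasta)[[1]]
  groups <- read_assignment_table(config$population_table)
  hg <- read_assignment_table(config$haplogroup_table)
  counts <- list(input_samples = length(seqs))

  # QC on modern samples only
  modern <- names(seqs)[!unname(groups[names(seqs)]) %in% config$ancient_populations]
  qc <- stage("qc filter", qc_filter(seqs[modern], config$max_missing))
  kept <- c(qc$kept, seqs[setdiff(names(seqs), modern)])
  kept <- kept[names(seqs)[names(seqs) %in% names(kept)]]
  counts$qc_excluded <- length(qc$excluded)
  counts$qc_kept <- length(kept)

  variants <- stage("align + call variants",
                    align_to_reference(kept, reference, config$weights))
  tab <- stage("recode", build_variant_table(variants, reference))
  if (config$exclude_hotspots) tab <- apply_hotspot_exclusion(tab)
  counts$variable_loci <- nrow(tab$loci)
  relatives <- find_identical_sequences(tab, groups)
  counts$identical_clusters <- length(relatives)

  vcf <- file.path(config$output_dir, "variants.vcf")
  write_vcf(variants, reference, vcf)
  arp <- file.path(config$output_dir, "recoded.arp")
  write_arp(tab, groups, arp)
  mat <- file.path(config$output_dir, "variant_matrix.tsv")
  write_variant_matrix(tab, mat)

  fst <- mds <- NULL
  if (config$run_fst) {
    fst <- stage("pairwise fst", pairwise_fst(
      tab, groups, config$tn93, config$n_permutations,
      seed = derive_seed(config$seed, "fst")))
    lin <- slatkin_linearize(fst)
    mds <- if (nrow(lin) >= 3) classical_mds(lin) else NULL
    write_fst_outputs(fst, mds, config$output_dir)
  }

  profiles <- shdm <- mix <- NULL
  if (config$run_shd) {
    profiles <- stage("haplogroup profiles",
                      profile_from_assignments(hg[names(kept)],
                                               groups[names(kept)]))
    shdm <- shd_matrix(profiles)
    write_shd_matrix(shdm, file.path(config$output_dir, "shd_matrix.tsv"))
    if (config$run_mitomix && length(profiles) >= 2) {
      test_pop <- config$mitomix_test %||% names(profiles)[1]
      cfg <- config$mitomix_config
      cfg$k_max <- min(cfg$k_max, length(profiles) - 1L)
      mix <- stage("mitomix", mitomix_search(profiles[[test_pop]],
                                             profiles, cfg))
      write.table(mix[, c("rank", "shd", "K", "sources")],
                  file.path(config$output_dir, "mitomix_solutions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  outputs <- list.files(config$output_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("mitomixr")),
    inputs = list(fasta = config$fasta,
                  reference = config$reference_fasta,
                  populations = config$population_table,
                  haplogroups = config$haplogroup_table),
    parameters = list(seed = config$seed,
                      n_permutations = config$n_permutations,
                      max_missing = config$max_missing,
                      gamma_alpha = config$tn93$gamma_alpha,
                      exclude_hotspots = config$exclude_hotspots,
                      weights = unclass(config$weights)),
    counts = counts,
    identical_clusters = lapply(relatives, `[[`, "samples"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(variant_table = tab, fst = fst, mds = mds,
                 profiles = profiles, shd = shdm, mitomix = mix,
                 relatives = relatives, manifest = manifest))
}

#' Re-run the distance analyses on subsets of one population
#'
#' Splits a focal population into annotated subsets (e.g. east- and
#' west-Eurasian lineage classes, supplied as sample annotations) and
#' treats each subset as a standalone population against the full
#' comparison panel, for both Fst and SHD — useful for asking which
#' component of a mixed cohort drives its distance signal.  Subsets with fewer
#' than two samples are skipped for Fst (with a warning) but still get SHD
#' profiles.
#'
#' @param result A [run_pipeline] return value.
#' @param groups Named sample-to-population vector (full panel).
#' @param hg Named sample-to-haplogroup vector.
#' @param scheme Named list: subset label -> character vector of sample ids
#'   (disjoint subsets of one population).
#' @param config The [pipeline_config] used for the run (distance
#'   parameters and seed are reused).
#' @return A list with `fst` (or `NULL`) and `shd` over panel + subsets.
#' @export
subpopulation_reanalysis <- function(result, groups, hg, scheme, config) {
  members <- unlist(scheme)
  abort_if(anyDuplicated(members) > 0, "scheme subsets must be disjoint")
  abort_if(!all(members %in% result$variant_table$sample_ids),
           "scheme contains unknown samples")
  focal_pops <- unique(unname(groups[members]))
  # relabel: subset samples get their subset label; other samples keep
  # their population; remaining samples of the focal population(s) drop out
  groups2 <- groups
  for (s in names(scheme)) groups2[scheme[[s]]] <- s
  leftovers <- names(groups)[unname(groups) %in% focal_pops &
                               !names(groups) %in% members]
  keep <- setdiff(result$variant_table$sample_ids, leftovers)
  keep <- keep[keep %in% names(groups2)]

  tab <- result$variant_table
  idx <- match(keep, tab$sample_ids)
  tab2 <- new_variant_table(keep, tab$loci, tab$matrix[idx, , drop = FALSE])

  sizes <- table(unname(groups2[keep]))
  small <- names(sizes)[sizes < 2]
  fst <- NULL
  fst_samples <- keep[!unname(groups2[keep]) %in% small]
  if (length(small) > 0)
    warning("subsets skipped for Fst (fewer than 2 samples): ",
            paste(intersect(small, names(scheme)), collapse = ", "))
  if (length(unique(unname(groups2[fst_samples]))) >= 2) {
    idxf <- match(fst_samples, tab2$sample_ids)
    tabf <- new_variant_table(fst_samples, tab2$loci,
                              tab2$matrix[idxf, , drop = FALSE])
    fst <- pairwise_fst(tabf, groups2, config$tn93, config$n_permutations,
                        seed = derive_seed(config$seed, "fst-subpop"))
  }
  profiles <- profile_from_assignments(hg[keep], groups2[keep])
  list(fst = fst, shd = shd_matrix(profiles), groups = groups2[keep])
}
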