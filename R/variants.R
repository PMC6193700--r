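# Recoded variant matrix for Fst: QC filtering, collection of variable
# positions, indel-to-pseudo-SNP recoding, hotspot exclusion, and the
# Arlequin-dialect / tab-separated writers.

#' Quality-filter mitogenomes on missing or uncertain bases
#'
#' A sequence is excluded when its count of missing-or-uncertain letters
#' (`N` and any non-ACGT IUPAC ambiguity code; alignment gaps do not count,
#' being genuine variation) is strictly greater than `max_missing`.  The
#' study applies this to modern sequences only; callers exempt ancient
#' samples by not passing them.
#'
#' @param genomes Named character vector of sequences.
#' @param max_missing Threshold (default 500): more than this many missing
#'   or uncertain nucleotides excludes the sequence.
#' @return A list with `kept` and `excluded` (both named character vectors)
#'   and `n_missing` (per-sample counts for all inputs).
#' @export
qc_filter <- function(genomes, max_missing = 500L) {
  abort_if(is.null(names(genomes)), "genomes must be named by sample")
  n_missing <- vapply(seq_chars(genomes),
                      function(ch) sum(!ch %in% c("A", "C", "G", "T", "-")),
                      integer(1))
  names(n_missing) <- names(genomes)
  drop <- n_missing > max_missing
  list(kept = genomes[!drop], excluded = genomes[drop], n_missing = n_missing)
}

new_variant_table <- function(sample_ids, loci, mat) {
  abort_if(nrow(mat) != length(sample_ids) || ncol(mat) != nrow(loci),
           "matrix dimensions disagree with sample_ids/loci")
  rownames(mat) <- sample_ids
  colnames(mat) <- loci$id
  structure(list(sample_ids = sample_ids, loci = loci, matrix = mat),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", length(x$sample_ids), "samples x",
      nrow(x$loci), "loci (",
      paste(names(table(x$loci$kind)), table(x$loci$kind), collapse = ", "),
      ")\n")
  invisible(x)
}

locus_id <- function(pos, kind, alt) {
  ifelse(kind == "snp", as.character(pos),
         ifelse(kind == "ins", paste0(pos, ".1", alt), paste0(pos, "del")))
}

#' Recode per-sample indel events as pseudo-SNP columns
#'
#' Implements the recoding that makes indels usable in a SNP-style matrix:
#' for every distinct insertion event, carriers are coded `T` and
#' non-carriers `C`; for every distinct deletion event, carriers are coded
#' `C` and non-carriers `T`.  Distinct events at the same anchor (different
#' inserted base) become distinct loci, keeping the coding invertible.
#'
#' @param variants Data frame of indel records with columns `sample`, `pos`,
#'   `kind` ("ins"/"del"), `alt` (inserted base, `-` for deletions).
#' @param samples Ordered character vector of all sample ids.
#' @return A list with `loci` (data frame: `pos`, `kind`, `alt`, `id`) and
#'   `matrix` (samples x pseudo-SNP letter matrix); zero-column when there
#'   are no indels.
#' @export
recode_indels <- function(variants, samples) {
  v <- variants[variants$kind %in% c("ins", "del"), , drop = FALSE]
  dup <- duplicated(v[, c("sample", "pos", "kind", "alt")])
  v <- v[!dup, , drop = FALSE]
  abort_if(anyNA(v$pos) || anyNA(v$alt),
           "indel records with missing position or allele",
           if (any(is.na(v$pos))) paste0(" (sample ",
             paste(unique(v$sample[is.na(v$pos)]), collapse = ","), ")"))
  key <- paste(v$pos, v$kind, v$alt, sep = "|")
  # same sample, same anchor, same kind but different base = two distinct
  # single-nucleotide events, hence two distinct loci (keeps invertibility)
  ukey <- unique(key[order(v$pos, v$kind, v$alt)])
  loci <- do.call(rbind, lapply(ukey, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(pos = as.integer(parts[1]), kind = parts[2], alt = parts[3],
               stringsAsFactors = FALSE)
  }))
  if (is.null(loci))
    loci <- data.frame(pos = integer(), kind = character(),
                       alt = character(), stringsAsFactors = FALSE)
  loci$ref <- ifelse(loci$kind == "ins", "-", NA_character_)
  loci$id <- locus_id(loci$pos, loci$kind, loci$alt)
  mat <- matrix("", nrow = length(samples), ncol = nrow(loci))
  for (j in seq_len(nrow(loci))) {
    carriers <- v$sample[key == ukey[j]]
    bad <- setdiff(carriers, samples)
    abort_if(length(bad) > 0, "indel records for unknown samples at locus ",
             loci$id[j], ": ", paste(bad, collapse = ", "))
    carrier <- samples %in% carriers
    mat[, j] <- if (loci$kind[j] == "ins") ifelse(carrier, "T", "C")
                else ifelse(carrier, "C", "T")
  }
  list(loci = loci[, c("pos", "kind", "ref", "alt", "id")], matrix = mat)
}

#' Build the recoded samples-by-variable-positions matrix
#'
#' Collects every reference position where any sample carries a definite
#' substitution, fills each sample's literal letter there (the alternate
#' allele for carriers, the reference letter otherwise, `N`/ambiguity codes
#' preserved as observed), and appends the pseudo-SNP columns from
#' [recode_indels].  Only variable loci are kept.
#'
#' @param variant_list Output of [align_to_reference] (per-sample variant
#'   records with `ref_calls` attributes).
#' @param reference Reference sequence string.
#' @return A `variant_table`: `sample_ids`, `loci` (data frame with `pos`,
#'   `kind`, `ref`, `alt`, `id`) and the letter `matrix`.
#' @export
build_variant_table <- function(variant_list, reference) {
  samples <- names(variant_list)
  ref_chars <- seq_chars(reference)[[1]]
  allv <- do.call(rbind, lapply(samples, function(s) {
    v <- variant_list[[s]]
    if (nrow(v) == 0) return(NULL)
    v$sample <- s
    v
  }))
  if (is.null(allv))
    allv <- data.frame(pos = integer(), kind = character(), ref = character(),
                       alt = character(), sample = character())
  snp_pos <- sort(unique(allv$pos[allv$kind == "snp"]))
  mat <- matrix("", nrow = length(samples), ncol = length(snp_pos))
  for (i in seq_along(samples)) {
    calls <- attr(variant_list[[samples[i]]], "ref_calls")
    if (is.null(calls)) {
      # fall back to reference + this sample's SNP records
      calls <- ref_chars
      vs <- variant_list[[samples[i]]]
      vs <- vs[vs$kind == "snp", , drop = FALSE]
      calls[vs$pos] <- vs$alt
    }
    mat[i, ] <- calls[snp_pos]
  }
  mat[mat == "-"] <- "N"   # a deleted base gives no call at a SNP column
  snp_loci <- data.frame(pos = snp_pos, kind = "snp",
                         ref = ref_chars[snp_pos],
                         alt = NA_character_,
                         stringsAsFactors = FALSE)
  if (nrow(snp_loci) > 0)
    snp_loci$alt <- vapply(seq_along(snp_pos), function(j) {
      a <- unique(allv$alt[allv$kind == "snp" & allv$pos == snp_pos[j]])
      paste(sort(a), collapse = ",")
    }, character(1))
  snp_loci$id <- locus_id(snp_loci$pos, snp_loci$kind, snp_loci$alt)
  ind <- recode_indels(allv, samples)
  loci <- rbind(snp_loci, ind$loci)
  mat <- cbind(mat, ind$matrix)
  # keep only genuinely variable columns (>= 2 distinct non-N letters)
  variable <- vapply(seq_len(ncol(mat)), function(j) {
    letters_j <- setdiff(unique(mat[, j]), "N")
    length(letters_j) >= 2 ||
      (length(letters_j) == 1 && loci$kind[j] == "snp" &&
         letters_j != loci$ref[j])
  }, logical(1))
  ord <- order(loci$pos[variable],
               match(loci$kind[variable], c("snp", "ins", "del")))
  keep <- which(variable)[ord]
  new_variant_table(samples, loci[keep, , drop = FALSE],
                    mat[, keep, drop = FALSE])
}

#' Default mutational hotspot exclusion list
#'
#' The common indel/length-variation hotspots excluded from the recoded
#' matrix: C-insertions at 309, 315 and 16193, the 522-524 and 3106
#' deletions, and the hypervariable 16182, 16183 and 16519 positions.
#'
#' @return Data frame with columns `pos`, `kind` ("snp"/"ins"/"del") and
#'   `base` (inserted base for insertion hotspots, `NA` otherwise).
#' @export
default_hotspots <- function() {
  data.frame(
    pos  = c(309L, 315L, 522L, 523L, 524L, 3106L, 16182L, 16183L, 16193L, 16519L),
    kind = c("ins", "ins", "del", "del", "del", "del", "snp", "snp", "ins", "snp"),
    base = c("C", "C", NA, NA, NA, NA, NA, NA, "C", NA),
    stringsAsFactors = FALSE
  )
}

#' Remove hotspot loci from a variant table
#'
#' Drops every column whose locus matches a hotspot descriptor on
#' (position, kind) — and on the inserted base for insertion hotspots.
#' Column order of the survivors is preserved.
#'
#' @param table A `variant_table`.
#' @param hotspots Hotspot data frame (default [default_hotspots()]).
#' @param include_snp_hotspots Whether SNP-position hotspots (16182, 16183,
#'   16519) are excluded too (default `TRUE`).
#' @return The filtered `variant_table`.
#' @export
apply_hotspot_exclusion <- function(table, hotspots = default_hotspots(),
                                    include_snp_hotspots = TRUE) {
  abort_if(!inherits(table, "variant_table"), "table must be a variant_table")
  if (!include_snp_hotspots)
    hotspots <- hotspots[hotspots$kind != "snp", , drop = FALSE]
  hit <- vapply(seq_len(nrow(table$loci)), function(j) {
    l <- table$loci[j, ]
    any(hotspots$pos == l$pos & hotspots$kind == l$kind &
          (is.na(hotspots$base) | hotspots$base == l$alt))
  }, logical(1))
  new_variant_table(table$sample_ids,
                    table$loci[!hit, , drop = FALSE],
                    table$matrix[, !hit, drop = FALSE])
}

#' Find samples with identical recoded sequences
#'
#' Groups samples whose variant-table rows are identical under strict
#' letter equality (`N` is NOT treated as a wildcard), flagging potential
#' direct maternal relatives.  Only clusters of two or more are reported.
#'
#' @param table A `variant_table`.
#' @param groups Optional named vector mapping sample to population,
#'   reported alongside each cluster.
#' @return A list of clusters; each is a list with `samples` and
#'   `populations`.
#' @export
find_identical_sequences <- function(table, groups = NULL) {
  keys <- apply(table$matrix, 1, paste, collapse = "")
  cl <- split(table$sample_ids, keys)
  cl <- cl[vapply(cl, length, integer(1)) >= 2]
  cl <- cl[order(vapply(cl, function(s) min(match(s, table$sample_ids)),
                        integer(1)))]
  unname(lapply(cl, function(s)
    list(samples = s,
         populations = if (is.null(groups)) NULL else unname(groups[s]))))
}

#' Write a variant table in the Arlequin profile dialect
#'
#' Plain-text `.arp` writer: `[Profile]` header, `[Data]` / `[[Samples]]`
#' sections, one `SampleData` block per population with each sample's
#' recoded letter string at frequency 1.
#'
#' @param table A `variant_table`.
#' @param groups Named vector mapping sample to population.
#' @param path Output file.
#' @param title Project title line.
#' @return Invisibly, `path`.
#' @export
write_arp <- function(table, groups, path, title = "mitomixr recoded data") {
  pops <- unique(unname(groups[table$sample_ids]))
  lines <- c("[Profile]",
             paste0("  Title=\"", title, "\""),
             paste0("  NbSamples=", length(pops)),
             "  DataType=DNA",
             "  GenotypicData=0",
             "  LocusSeparator=NONE",
             "  MissingData='N'",
             "",
             "[Data]",
             "  [[Samples]]")
  for (p in pops) {
    ids <- table$sample_ids[unname(groups[table$sample_ids]) == p]
    lines <- c(lines,
               paste0("    SampleName=\"", p, "\""),
               paste0("    SampleSize=", length(ids)),
               "    SampleData={")
    for (s in ids)
      lines <- c(lines, paste0("      ", s, " 1 ",
                               paste(table$matrix[s, ], collapse = "")))
    lines <- c(lines, "    }")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant table as a tab-separated matrix
#'
#' @param table A `variant_table`.
#' @param path Output file; loci ids become column names.
#' @return Invisibly, `path`.
#' @export
write_variant_matrix <- function(table, path) {
  df <- data.frame(sample = table$sample_ids, table$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
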