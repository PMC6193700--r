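# IUPAC-ambiguity-aware global pairwise alignment with affine gap costs,
# and reference-coordinate variant calling from the resulting alignments.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"),
  W = c("A", "T"), S = c("C", "G"), K = c("G", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)
IUPAC_ALPHABET <- names(IUPAC_SETS)

#' Alignment weight scheme
#'
#' The aligner's scores by match class: exact nucleotide identity scores
#' `match`; a column whose two codes' base sets intersect scores by the
#' ambiguity class of the more ambiguous symbol (two-fold codes R, Y, M, W,
#' S, K; three-fold B, D, H, V; four-fold N); disjoint base sets score
#' `mismatch`.  A gap run of length L costs `gap_open + (L - 1) *
#' gap_extend`.  Defaults are match 6, two-fold 3, three-fold 2, four-fold
#' 1, mismatch -12, gap open -24, gap extend -6.
#'
#' @param match,iupac2_match,iupac3_match,iupac4_match,mismatch,gap_open,gap_extend
#'   Scores; must satisfy
#'   `match > iupac2 > iupac3 > iupac4 > 0 > mismatch > gap_open`.
#' @return An object of class `alignment_weights`.
#' @export
alignment_weights <- function(match = 6, iupac2_match = 3, iupac3_match = 2,
                              iupac4_match = 1, mismatch = -12,
                              gap_open = -24, gap_extend = -6) {
  w <- list(match = match, iupac2_match = iupac2_match,
            iupac3_match = iupac3_match, iupac4_match = iupac4_match,
            mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend)
  abort_if(!(match > iupac2_match && iupac2_match > iupac3_match &&
             iupac3_match > iupac4_match && iupac4_match > 0 &&
             0 > mismatch && mismatch > gap_open),
           "weights must satisfy match > iupac2 > iupac3 > iupac4 > 0 > mismatch > gap_open")
  structure(w, class = "alignment_weights")
}

#' Score one alignment column of two IUPAC codes
#'
#' If the two codes' base sets intersect the column scores by the ambiguity
#' class of the MORE ambiguous symbol (exact A/C/G/T identity scores
#' `match`); disjoint sets score `mismatch`.  Symmetric in its arguments.
#'
#' @param ref_base,query_base Single IUPAC nucleotide letters.
#' @param weights An [alignment_weights] object.
#' @return The column score.
#' @examples
#' score_column("A", "A")  # 6
#' score_column("A", "R")  # 3
#' score_column("G", "N")  # 1
#' score_column("A", "C")  # -12
#' @export
score_column <- function(ref_base, query_base, weights = alignment_weights()) {
  a <- toupper(ref_base); b <- toupper(query_base)
  abort_if(!a %in% IUPAC_ALPHABET, "not an IUPAC nucleotide code: ", ref_base)
  abort_if(!b %in% IUPAC_ALPHABET, "not an IUPAC nucleotide code: ", query_base)
  sa <- IUPAC_SETS[[a]]; sb <- IUPAC_SETS[[b]]
  if (length(intersect(sa, sb)) == 0) return(weights$mismatch)
  switch(max(length(sa), length(sb)),
         weights$match, weights$iupac2_match,
         weights$iupac3_match, weights$iupac4_match)
}

# 15 x 15 substitution matrix over the IUPAC alphabet, from score_column.
iupac_score_matrix <- function(weights) {
  m <- matrix(0, 15, 15, dimnames = list(IUPAC_ALPHABET, IUPAC_ALPHABET))
  for (a in IUPAC_ALPHABET)
    for (b in IUPAC_ALPHABET)
      m[a, b] <- score_column(a, b, weights)
  m
}

encode_iupac <- function(s) {
  chars <- seq_chars(s)[[1]]
  code <- match(chars, IUPAC_ALPHABET)
  abort_if(anyNA(code), "sequence contains non-IUPAC letters: ",
           paste(unique(chars[is.na(code)]), collapse = ", "))
  code
}

#' Global pairwise alignment of two IUPAC nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs (Gotoh's
#' three-state recursion) under the IUPAC-class weight scheme of
#' [alignment_weights].  Terminal gaps are charged like internal gaps.
#' Among co-optimal alignments the traceback deterministically prefers a
#' substitution column over a gap, and a gap in the query row over a gap in
#' the reference row.
#'
#' @param reference,query Non-empty IUPAC nucleotide strings.
#' @param weights An [alignment_weights] object.
#' @return An object of class `pairwise_alignment`: list with `aligned_ref`,
#'   `aligned_query` (equal-length gapped strings; `-` is the gap letter)
#'   and `score`.
#' @examples
#' align_global("ACGT", "ACT")
#' @export
align_global <- function(reference, query, weights = alignment_weights()) {
  abort_if(!nzchar(reference) || !nzchar(query),
           "sequences must be non-empty")
  sub <- iupac_score_matrix(weights)
  res <- gotoh_align(encode_iupac(reference), encode_iupac(query), sub,
                     weights$gap_open, weights$gap_extend)
  a_ref <- paste(c("-", IUPAC_ALPHABET)[res$ref_path + 1L], collapse = "")
  a_qry <- paste(c("-", IUPAC_ALPHABET)[res$query_path + 1L], collapse = "")
  structure(list(aligned_ref = a_ref, aligned_query = a_qry,
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment, score", x$score, "\n")
  cat("ref:  ", substr(x$aligned_ref, 1, 60),
      if (nchar(x$aligned_ref) > 60) "..." else "", "\n", sep = "")
  cat("qry:  ", substr(x$aligned_query, 1, 60),
      if (nchar(x$aligned_query) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Call reference-coordinate variants from a pairwise alignment
#'
#' Reads an alignment of a query against the reference into variant
#' records: substitutions (`snp`), insertions (bases present in the query
#' but not the reference, anchored at the preceding reference position) and
#' deletions (reference positions absent from the query).  Positions are
#' 1-based reference coordinates.  `N` in the query is missing data, not a
#' variant; ambiguity codes whose base set contains the reference base are
#' treated as uncertain reference calls, while codes excluding it are
#' reported as substitutions with the ambiguous letter as alternate.
#'
#' @param alignment A [align_global] result (reference in the `aligned_ref`
#'   row).
#' @return A data frame with columns `pos`, `kind`, `ref`, `alt`.  Runs of
#'   adjacent inserted or deleted bases are emitted per base, matching the
#'   single-nucleotide event granularity of the recoding rules.
#' @export
call_variants <- function(alignment) {
  ra <- seq_chars(alignment$aligned_ref)[[1]]
  qa <- seq_chars(alignment$aligned_query)[[1]]
  abort_if(length(ra) != length(qa), "gapped rows differ in length")
  pos <- integer(0); kind <- character(0)
  ref <- character(0); alt <- character(0)
  rpos <- 0L
  for (i in seq_along(ra)) {
    r <- ra[i]; q <- qa[i]
    if (r != "-") rpos <- rpos + 1L
    if (r == "-") {                     # insertion relative to reference
      pos <- c(pos, rpos); kind <- c(kind, "ins")
      ref <- c(ref, "-"); alt <- c(alt, q)
    } else if (q == "-") {              # deletion of this reference base
      pos <- c(pos, rpos); kind <- c(kind, "del")
      ref <- c(ref, r); alt <- c(alt, "-")
    } else if (q != r && q != "N") {
      qset <- IUPAC_SETS[[q]]
      if (!r %in% qset) {               # definite substitution
        pos <- c(pos, rpos); kind <- c(kind, "snp")
        ref <- c(ref, r); alt <- c(alt, q)
      }
    }
  }
  data.frame(pos = pos, kind = kind, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Align a set of mitogenomes to a reference and call variants
#'
#' @param sequences Named character vector of query sequences.
#' @param reference Reference sequence string (rCRS coordinates).
#' @param weights An [alignment_weights] object.
#' @return A named list (one element per sample) of variant data frames as
#'   returned by [call_variants]; each carries the sample's per-reference-
#'   position base calls in attribute `ref_calls` (used to build the variant
#'   matrix, including `N` and ambiguity letters at positions where other
#'   samples vary).
#' @export
align_to_reference <- function(sequences, reference,
                               weights = alignment_weights()) {
  abort_if(is.null(names(sequences)), "sequences must be named by sample")
  lapply(sequences, function(s) {
    aln <- align_global(reference, s, weights)
    v <- call_variants(aln)
    ra <- seq_chars(aln$aligned_ref)[[1]]
    qa <- seq_chars(aln$aligned_query)[[1]]
    calls <- qa[ra != "-"]             # query letter at each ref position
    calls[calls == "-"] <- "-"
    attr(v, "ref_calls") <- calls
    v
  })
}

#' Write variant calls as a minimal VCF body
#'
#' Writes the standard 8 fixed VCF columns (1-based positions; indels
#' left-anchored at the preceding reference base, per VCF convention) with
#' one line per variant and the carrying samples listed in INFO.
#'
#' @param variant_list Output of [align_to_reference].
#' @param reference Reference sequence string (for indel anchor bases).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variant_list, reference, path) {
  ref_chars <- seq_chars(reference)[[1]]
  recs <- list()
  for (s in names(variant_list)) {
    v <- variant_list[[s]]
    if (nrow(v) == 0) next
    v$sample <- s
    recs[[s]] <- v
  }
  lines <- c("##fileformat=VCFv4.2",
             paste0("##reference=local;length=", length(ref_chars)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (length(recs) > 0) {
    all <- do.call(rbind, recs)
    key <- paste(all$pos, all$kind, all$alt)
    for (k in unique(key[order(all$pos)])) {
      rows <- all[key == k, , drop = FALSE]
      r1 <- rows[1, ]
      if (r1$kind == "snp") {
        pos <- r1$pos; ref <- r1$ref; alt <- r1$alt
      } else if (r1$kind == "ins") {
        pos <- r1$pos
        anchor <- if (pos >= 1) ref_chars[pos] else "N"
        ref <- anchor; alt <- paste0(anchor, r1$alt)
      } else {
        pos <- r1$pos - 1L
        anchor <- if (pos >= 1) ref_chars[pos] else "N"
        ref <- paste0(anchor, r1$ref); alt <- anchor
      }
      lines <- c(lines, paste("chrM", pos, ".", ref, alt, ".", "PASS",
                              paste0("SAMPLES=", paste(rows$sample, collapse = ",")),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
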