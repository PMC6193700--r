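test_that("QC filter applies the strict more-than-500 rule", {
  mk <- function(n_N, len = 1000) {
    s <- paste(rep("A", len - n_N), collapse = "")
    paste0(s, paste(rep("N", n_N), collapse = ""))
  }
  genomes <- c(clean = mk(0), at_limit = mk(500), over = mk(501))
  res <- qc_filter(genomes, max_missing = 500)
  expect_setequal(names(res$kept), c("clean", "at_limit"))
  expect_setequal(names(res$excluded), "over")
  # ambiguity codes count as uncertain
  amb <- c(x = paste(c(rep("A", 499), rep("R", 2)), collapse = ""))
  expect_length(qc_filter(amb, 1)$excluded, 1)
  expect_length(qc_filter(amb, 2)$excluded, 0)

  # partition property: kept and excluded tile the input
  expect_setequal(c(names(res$kept), names(res$excluded)), names(genomes))
  # monotonicity: lowering the threshold never grows the kept set
  for (t in c(0, 100, 499, 500)) {
    k1 <- names(qc_filter(genomes, t)$kept)
    k2 <- names(qc_filter(genomes, t + 1)$kept)
    expect_true(all(k1 %in% k2))
  }
})

test_that("indels are recoded with the published C/T letter assignments", {
  samples <- c("s1", "s2", "s3")
  ins <- data.frame(sample = "s2", pos = 309L, kind = "ins", alt = "C")
  col <- recode_indels(ins, samples)
  expect_equal(col$matrix[, 1], c("C", "T", "C"))   # carrier gets T
  expect_equal(col$loci$id, "309.1C")

  del <- data.frame(sample = "s1", pos = 523L, kind = "del", alt = "-")
  cold <- recode_indels(del, samples)
  expect_equal(cold$matrix[, 1], c("C", "T", "T"))  # carrier gets C
  expect_equal(cold$loci$id, "523del")

  none <- recode_indels(data.frame(sample = character(), pos = integer(),
                                   kind = character(), alt = character()),
                        samples)
  expect_equal(ncol(none$matrix), 0)

  # recoding is invertible: letters map back to carrier status
  both <- rbind(ins, del,
                data.frame(sample = "s3", pos = 309L, kind = "ins", alt = "C"))
  rc <- recode_indels(both, samples)
  ins_col <- rc$matrix[, rc$loci$kind == "ins"]
  expect_setequal(samples[ins_col == "T"], c("s2", "s3"))
  del_col <- rc$matrix[, rc$loci$kind == "del"]
  expect_setequal(samples[del_col == "C"], "s1")

  # distinct inserted bases at one anchor stay distinct loci
  two <- rbind(ins, data.frame(sample = "s1", pos = 309L, kind = "ins",
                               alt = "A"))
  expect_equal(nrow(recode_indels(two, samples)$loci), 2)
})

test_that("variant tables collect variable loci with literal letters", {
  ref <- paste(rep("ACGT", 50), collapse = "")
  q1 <- ref; substr(q1, 8, 8) <- "A"     # T -> A
  q2 <- ref; substr(q2, 8, 8) <- "A"; substr(q2, 50, 50) <- "A"   # C? pos 50 = C? (50 %% 4 = 2 -> C)
  q3 <- paste0(substr(ref, 1, 100), "T", substr(ref, 101, 200))  # insertion
  vl <- align_to_reference(c(s1 = q1, s2 = q2, s3 = q3), ref)
  tab <- build_variant_table(vl, ref)
  expect_s3_class(tab, "variant_table")
  expect_true(all(c(8, 50) %in% tab$loci$pos[tab$loci$kind == "snp"]))
  expect_true(any(tab$loci$kind == "ins"))
  # letters: carriers carry alt, others the reference letter
  snp8 <- which(tab$loci$pos == 8 & tab$loci$kind == "snp")
  expect_equal(unname(tab$matrix[, snp8]), c("A", "A", "T"))
  # every kept locus is variable
  for (j in seq_len(ncol(tab$matrix)))
    expect_gte(length(unique(tab$matrix[, j])), 2)
})

test_that("hotspot exclusion removes exactly the listed descriptors", {
  loci <- data.frame(
    pos = c(100L, 16519L, 3106L, 309L, 309L, 522L),
    kind = c("snp", "snp", "del", "ins", "ins", "del"),
    ref = c("A", "T", "C", "-", "-", "A"),
    alt = c("G", "C", "-", "C", "A", "-"),
    stringsAsFactors = FALSE)
  loci$id <- c("100", "16519", "3106del", "309.1C", "309.1A", "522del")
  mat <- matrix(rep(c("A", "G"), each = 6), nrow = 2, byrow = TRUE)
  tab <- mitomixr:::new_variant_table(c("a", "b"), loci, mat)

  out <- apply_hotspot_exclusion(tab)
  # removed: 16519 SNP, 3106del, 309.1C, 522del; kept: 100 SNP and the
  # non-C insertion at 309
  expect_setequal(out$loci$id, c("100", "309.1A"))
  expect_equal(out$loci$id, c("100", "309.1A"))   # order preserved

  # switchable SNP-hotspot handling
  out2 <- apply_hotspot_exclusion(tab, include_snp_hotspots = FALSE)
  expect_true("16519" %in% out2$loci$id)

  # identity on tables without hotspot loci
  expect_equal(apply_hotspot_exclusion(out), out)
  expect_equal(nrow(default_hotspots()), 10)
})

test_that("identical variant rows cluster as potential maternal relatives", {
  loci <- data.frame(pos = 1:3, kind = "snp", ref = "A", alt = "G",
                     id = as.character(1:3), stringsAsFactors = FALSE)
  rows <- rbind(c("A", "G", "T"), c("A", "G", "T"), c("A", "G", "C"),
                c("A", "G", "C"), c("A", "G", "C"))
  tab <- mitomixr:::new_variant_table(paste0("s", 1:5), loci, rows)
  groups <- setNames(c("P1", "P1", "P1", "P2", "P2"), paste0("s", 1:5))
  cl <- find_identical_sequences(tab, groups)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$samples, c("s1", "s2"))
  expect_equal(cl[[2]]$samples, c("s3", "s4", "s5"))
  expect_equal(cl[[2]]$populations, c("P1", "P2", "P2"))

  # strict equality: N is not a wildcard
  rows2 <- rbind(c("A", "G", "T"), c("A", "G", "N"))
  tab2 <- mitomixr:::new_variant_table(c("x", "y"), loci, rows2)
  expect_length(find_identical_sequences(tab2), 0)
  # all-distinct rows give no clusters
  expect_length(find_identical_sequences(
    mitomixr:::new_variant_table(c("x", "y"), loci,
                                 rbind(c("A", "G", "T"), c("C", "G", "T")))), 0)
})

test_that("arp and matrix writers emit the documented structure", {
  loci <- data.frame(pos = c(5L, 9L), kind = "snp", ref = "A", alt = "G",
                     id = c("5", "9"), stringsAsFactors = FALSE)
  tab <- mitomixr:::new_variant_table(
    c("s1", "s2"), loci, rbind(c("A", "G"), c("G", "A")))
  groups <- setNames(c("P1", "P2"), c("s1", "s2"))
  arp <- withr::local_tempfile(fileext = ".arp")
  write_arp(tab, groups, arp)
  lines <- readLines(arp)
  expect_true("[Profile]" %in% lines)
  expect_true("[Data]" %in% lines)
  expect_true("  [[Samples]]" %in% lines)
  expect_equal(sum(grepl("SampleName=", lines)), 2)
  expect_true(any(grepl("s1 1 AG", lines)))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_matrix(tab, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(back$sample, c("s1", "s2"))
  expect_equal(back[["9"]], c("G", "A"))
})
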