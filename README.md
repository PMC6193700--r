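# mitomixr

Population-genetic analysis of complete mitochondrial genomes (mitogenomes):
who is maternally related to whom, how differentiated populations are, and
which mixtures of candidate source populations best explain a target
population. The package is aimed at human population-history studies that
compare ancient-DNA cohorts against modern mitogenome databases, and it
ships a forward simulator so the entire pipeline is testable without any
external sequence database.

## What it computes

**Alignment and recoding.** Every sample is aligned globally against the
reference (rCRS coordinates) by an IUPAC-ambiguity-aware Needleman–Wunsch /
Gotoh aligner with class-based weights — match 6, two-fold ambiguity codes
(R, Y, M, W, S, K) 3, three-fold (B, D, H, V) 2, four-fold (N) 1, mismatch
−12, gap open −24, gap extend −6 — and variants are called in reference
coordinates. Sequences with more than 500 missing-or-uncertain nucleotides
are excluded. For Fst input, indels become pseudo-SNP columns (insertion:
carriers `T`, non-carriers `C`; deletion: carriers `C`, non-carriers `T`)
and common length-variation hotspots (309.1C, 315.1C, 522–524del, 3106del,
16182C, 16183C, 16193.1C, 16519C) are excluded.

**Fst.** Distance-based AMOVA fixation index (Φst) on Tamura–Nei (1993)
distances with gamma rate heterogeneity (shape 0.325),

Φst = σ²<sub>among</sub> / (σ²<sub>among</sub> + σ²<sub>within</sub>),

with significance from permuting individuals between populations (10,000
permutations by default), Slatkin linearization Fst/(1 − Fst), and
classical MDS for visualization.

**SHD.** The Shared Haplogroup Distance between two populations' sub-
haplogroup frequency profiles *f*, *g*:

SHD(f, g) = 1 − Σ<sub>h</sub> min(f<sub>h</sub>, g<sub>h</sub>) ∈ [0, 1],

0 for identical profiles, 1 for disjoint sub-haplogroup sets, and — the
property that makes it useful — equal to 1 − w against source A when the
target is a mixture w·A + (1 − w)·B of disjoint sources. A corrected
variant grants partial credit (default 0.5) across direct
progenitor/progeny haplogroup pairs.

**MITOMIX.** Exhaustive admixture search: for each K in a configured range,
every K-subset of a candidate pool and every mixing-proportion vector on a
1% grid is scored by SHD against the test population; the best solutions
are ranked and summarized as per-source min–max proportion ranges.

## Worked example

Simulate three source populations on a 600-nt toy reference plus a fourth
population admixed 60/40 from the first two, then run the full pipeline
and decompose the admixed population:

```r
library(mitomixr)

tree  <- generate_tree(n_major = 3, depth = 3, branching = 2, seed = 7)
model <- generate_haplotype_model(tree, reference_length = 600,
                                  snps_per_node = 2, indel_fraction = 0.2,
                                  private_mutation_rate = 0.5,
                                  missing_rate = 0.002, seed = 8)
leaves <- setdiff(tree$nodes, tree$parent)
majors <- tree$nodes[!is.na(tree$parent[tree$nodes]) &
                     tree$parent[tree$nodes] == tree$root]
profiles <- lapply(seq_along(majors), function(i) {
  lv <- leaves[startsWith(leaves, majors[i])]
  hg_profile(setNames(rep(1/length(lv), length(lv)), lv), paste0("P", i))
})
mixed    <- admix_profiles(profiles[1:2], c(0.6, 0.4), population = "MIX")
all_prof <- c(profiles, list(mixed))
pops <- lapply(seq_along(all_prof), function(i)
  sample_population(all_prof[[i]], 25, model, seed = 10 + i))

files <- write_population_files(pops, "demo/in")
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(c(reference = model$reference)),
  "demo/in/reference.fasta")

cfg <- pipeline_config(
  fasta = files[["fasta"]], reference_fasta = "demo/in/reference.fasta",
  population_table = files[["populations"]],
  haplogroup_table = files[["haplogroups"]],
  output_dir = "demo/out", seed = 42, n_permutations = 1000,
  mitomix_test = "MIX",
  mitomix_config = mix_search_config(k_min = 1, k_max = 3, grid_step = 0.01))
res <- run_pipeline(cfg)

print(res$fst)
print(res$shd)
head(res$mitomix[, c("rank", "shd", "K", "sources")], 5)
mitomix_ranges(res$mitomix)
```

Output:

```
fst_result over 4 populations ( 1000 permutations )
         P1      P2      P3     MIX
P1  0.00000 0.58939 0.59790 0.20721
P2  0.58939 0.00000 0.58694 0.20003
P3  0.59790 0.58694 0.00000 0.43901
MIX 0.20721 0.20003 0.43901 0.00000
shd_matrix over 4 populations (raw)
      P1   P2 P3  MIX
P1  0.00 1.00  1 0.56
P2  1.00 0.00  1 0.48
P3  1.00 1.00  0 1.00
MIX 0.56 0.48  1 0.00
  rank    shd K                 sources
1    1 0.2496 2         P1:0.56,P2:0.44
2    2 0.2500 2         P1:0.55,P2:0.45
3    3 0.2512 2         P1:0.57,P2:0.43
4    4 0.2520 2         P1:0.54,P2:0.46
5    5 0.2528 3 P1:0.56,P2:0.43,P3:0.01
  source  min  max n_solutions
1     P1 0.51 0.60          20
2     P2 0.40 0.49          20
3     P3 0.01 0.02          10
```

Reading the numbers: the three source populations are strongly and
mutually differentiated (Fst ≈ 0.59, SHD = 1 — they share no
sub-haplogroups), while MIX sits much closer to its true sources P1 and P2
(Fst ≈ 0.21, 0.20) than to P3 (0.44). The admixture search recovers the
construction: the best solutions mix P1 and P2 at roughly 56:44 —
estimated from 25-sample empirical profiles of a population built as
60:40 — and across the 20 best solutions the P1 proportion ranges
0.51–0.60. The residual SHD ≈ 0.25 is the sampling noise between the
empirical 25-sample profiles and the generating frequencies, not lack of
fit in the model. `demo/out/` additionally receives the VCF, the recoded
matrix (`.arp` and TSV), the p-value and MDS tables, and a JSON manifest
with content digests of every artifact.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mitomixr.R` (subcommands `simulate`, `run-all`, `shd`,
`mitomix`).

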