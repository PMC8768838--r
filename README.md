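# mlstpop

Multilocus sequence typing (MLST) and population-structure analysis for
bacterial isolate collections, built around the six-locus scheme used for
*Bifidobacterium longum* (`clpC`, `fusA`, `ileS`, `purF`, `rplB`, `rpoB`;
trimmed lengths 600, 664, 487, 574, 355, 497 bp — 3,177 bp concatenated).

MLST encodes each distinct housekeeping-gene fragment as an integer allele
and each six-allele profile as a sequence type (ST). From the ST table the
package infers how a species' population is structured: which STs form
clonal complexes descended from a common founder, how diverse each locus
is, whether the loci evolve under purifying selection, how much
recombination contributes relative to mutation, and whether the
concatenated phylogeny resolves subspecies lineages.

## What it computes

* **Typing** — deterministic trimming against scheme reference alleles,
  allele/ST assignment in first-seen order, PubMLST-style profile tables
  (`mlst()`, a fitting-style entry point with `print`/`summary`/`plot`
  methods).
* **Population structure** — goeBURST clonal complexes (SLV level) and
  BURST groups (DLV level) with the canonical founder tie-break chain
  (SLV count → DLV count → frequency → ST number), and a minimum spanning
  tree over allelic profiles with the same comparison chain
  (`goeburst_groups()`, `build_mst()`).
* **Diversity and selection** — segregating sites, GC content, nucleotide
  diversity π, Tajima's D with its full 1989 constant breakdown, and
  Nei–Gojobori (1986) dN/dS with Jukes–Cantor correction
  (`stats_table()`, `tajimas_d()`, `nei_gojobori()`).
* **Recombination** — a PHI-style permutation test on
  parsimony-informative site pairs (four-gamete/forest compatibility,
  add-one p-value), a clustered-SNP scanner that reports recombinant
  segments by binomial tail probability, and a transparent SNP-partition
  r/m summary (`phi_test()`, `scan_recombinant_segments()`,
  `estimate_r_over_m()`).
* **Phylogeny** — Kimura two-parameter distances
  (d = −½ ln((1−2P−Q)√(1−2Q))), neighbor joining, column-resampling
  bootstrap supports, and lineage monophyly checks
  (`k2p_matrix()`, `neighbor_joining()`, `bootstrap_support()`,
  `check_group_monophyly()`, `st_tree()`).
* **Simulation** — a seeded multi-lineage generator with point mutation,
  subspecies-scale lineage divergence and implanted 213-bp donor
  fragments, returning ground truth for every event
  (`sim_config()`, `simulate_mlst()`).

FASTA (headers `isolateID|locus`), TSV (profiles, metadata, MST edges,
groups, statistics), Newick and JSON readers/writers are included, plus a
thin command-line front end at `inst/scripts/mlstpop`
(`simulate`, `type`, `stats`, `phi`, `scan`, `tree`, `run-all`).

## Worked example

```r
library(mlstpop)

# simulate a small three-lineage collection (30 isolates) and type it
sim <- simulate_mlst(sim_config(isolates_per_lineage = c(20, 6, 4), seed = 11))
fit <- mlst(sim$dataset)
summary(fit)
#> 30 isolates typed into 25 STs
#> Largest STs (isolate counts): ST3=6, ST1=1, ST2=1, ST4=1, ST5=1
#> Clonal complexes (SLV level): 3 multi-ST complexes, 14 singleton STs
#>  group_id founder n_STs n_isolates
#>         1       3     4          9
#>         2      20     5          5
#>         3      24     2          2
#> BURST groups (DLV level): 3 multi-ST groups, 4 singleton STs

stats_table(fit)[, c("locus", "length", "n_alleles", "polymorphic_sites",
                     "gc", "tajima_D", "pi")]
#>          locus length n_alleles polymorphic_sites     gc tajima_D      pi
#> 1         clpC    600         7                35 0.6371   1.1538 0.01938
#> 2         fusA    664        12                55 0.6080   0.5808 0.02415
#> 3         ileS    487         9                45 0.5967   0.4404 0.02609
#> 4         purF    574        10                43 0.6134   0.7924 0.02296
#> 5         rplB    355        10                34 0.5875   0.3620 0.02658
#> 6         rpoB    497        10                41 0.6211   0.4450 0.02334
#> 7 Concatenated   3177        25               253 0.6125   0.6513 0.02348

# ST-representative NJ tree; are the three lineages monophyletic?
tree <- st_tree(fit)
lin <- sim$truth$lineage_of_isolate
st_lin <- vapply(fit$st_table$isolates, function(m) lin[[m[1]]], 0L)
check_group_monophyly(tree, setNames(paste0("L", st_lin),
                                     paste0("ST", names(st_lin))))
#>   L1   L2   L3
#> TRUE TRUE TRUE
```

Reading the output: 30 isolates collapse to 25 STs because low per-isolate
mutation leaves many isolates identical across all six loci; the largest
clonal complex gathers 4 single-locus-variant STs around founder ST3
(9 isolates); each row of the statistics table describes one locus —
fragment length, distinct alleles observed, polymorphic alignment
columns, pooled GC fraction, Tajima's D and per-site nucleotide
diversity — with the final row summarizing the 3,177-bp concatenated
profile sequences; and every simulated lineage is recovered as a clade of
the neighbor-joining tree.

The methods vignette
(`vignettes/mlst-population-structure.Rmd`) documents the models, the
tie-break and sentinel policies, the simulator's design and its limits.

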