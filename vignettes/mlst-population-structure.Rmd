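---
title: "MLST population structure: models, statistics and design choices"
author: "mlstpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MLST population structure: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlstpop)
```

# Scope

`mlstpop` implements a six-locus multilocus sequence typing (MLST) pipeline
for *Bifidobacterium longum*-like isolate collections: allele and
sequence-type (ST) assignment, goeBURST clonal complexes and BURST groups,
minimum spanning trees over allelic profiles, the classic per-locus
diversity/selection statistics, a PHI-style recombination test with a
clustered-SNP segment scanner and a simple r/m summary, and
neighbor-joining phylogenies under the Kimura two-parameter (K2P) model.
A seeded simulator generates multi-lineage collections with known ground
truth so every stage can be validated without external data.

The default scheme types the housekeeping loci `clpC`, `fusA`, `ileS`,
`purF`, `rplB`, `rpoB` at trimmed lengths 600, 664, 487, 574, 355 and
497 bp (3,177 bp concatenated).

# Typing model

**Trimming.** Raw locus sequences are trimmed by an anchor-free search: the
window of the scheme length with minimum Hamming distance to the locus
reference allele is kept (leftmost on ties). A window identity below 0.80
(configurable) aborts with a locus-mismatch error rather than calling a
dubious allele. This replaces multiple alignment: for high-identity
housekeeping fragments the minimum-distance window is the aligned window,
and the rule is deterministic and dependency-free.

**Alleles and STs.** Allele numbers and ST numbers are assigned in
first-seen order, contiguously from 1. Typing software used in practice
often assigns these labels arbitrarily; making them deterministic makes
runs reproducible and diffable. All downstream statistics are invariant
under label permutation (tested by randomized relabeling). Ambiguous bases
abort allele calling — silently creating a spurious "allele" for an
uncertain base would contaminate the catalog. An existing catalog can be
preloaded so numbering stays stable across datasets.

# Clonal complexes and the MST

Profile distance between two STs is the number of loci with differing
alleles (0–6). goeBURST groups at level *g* are the connected components of
the graph joining ST pairs at distance ≤ *g*; level 1 (single-locus
variants) is reported as clonal complexes (CCs), level 2 (double-locus
variants) as BURST groups (BGs). Both levels are first-class because both
conventions are in active use; level-1 groups provably refine level-2
groups (tested). The founder of a group maximizes the canonical goeBURST
chain: SLV count, then DLV count, then isolate frequency, then the smaller
ST number — neighbor counts taken over the whole dataset.

The minimum spanning tree is built Kruskal-style: all ST pairs are sorted
by (weight, higher max-endpoint SLV count, higher max-endpoint DLV count,
higher max-endpoint isolate frequency, lexicographically smaller ST pair)
and accepted greedily under a union–find. Since the ordering is total and
deterministic, the edge set is reproducible; total weight is the global
minimum (verified against exhaustive enumeration for small ST sets). The
spanning-tree weight is invariant under ST relabeling even where
individual tie-broken edges are not.

# Diversity and selection statistics

For each locus and for the concatenated sequences the package reports the
number of alleles, segregating sites $S$, pooled GC content, nucleotide
diversity $\pi$ (mean pairwise differences per site), Tajima's $D$, a
PHI-test p-value and the Nei–Gojobori $d_N/d_S$. By default statistics are
computed over all isolate sequences; `mode = "alleles"` uses one sequence
per distinct allele (per ST for the concatenated row) instead, since
published tables do not always state which convention was used.

**Tajima's D** follows the 1989 constants exactly
($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$), with
$D = (\pi_{tot} - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$, where $\pi_{tot}$ is
the mean pairwise difference count per pair. $D$ is `NA` (a sentinel, not
an error) when $S = 0$; $n < 4$ is an error. The implementation is checked
against an independent re-derivation to $10^{-9}$. Significance stars from
legacy software use a beta approximation that is deliberately not
reproduced; the value of $D$ is the deliverable.

**Nei–Gojobori (1986) dN/dS.** Synonymous site counts per codon are the
per-position fraction of the three possible changes that preserve the
amino acid (changes to stop codons count as nonsynonymous); differences
between codon pairs average synonymous/nonsynonymous steps over all
minimal substitution pathways with equal weight, excluding pathways that
pass through a stop codon unless all are blocked. Proportions are
Jukes–Cantor corrected, $d = -\tfrac34 \ln(1 - \tfrac43 p)$. The ratio is
`NA` when $d_S = 0$ or a correction saturates ($p \ge 3/4$), except that
$d_N = 0$ with synonymous divergence present pins the ratio at 0. Codon
columns containing an internal stop are excluded with a warning
(configurable to an error). The pairwise average is computed column-wise
over codon-state counts, which is algebraically identical to the explicit
all-pairs average (tested against a recursive pathway-enumeration oracle)
but scales to hundreds of sequences. This counting estimator replaces
codon-model maximum likelihood: it is closed-form, well-oracled, and at
housekeeping-gene divergences ($\pi \le 0.02$) the two agree closely.

Frame offsets default to 0 with the trailing partial codon truncated
(several scheme lengths are not codon multiples and the correct frames are
scheme metadata the user can set per locus).

# Recombination

**PHI-style test.** Parsimony-informative sites (two or more states each
carried by two or more sequences) are scored pairwise for genealogical
compatibility: states of the two sites form a bipartite graph with an edge
per jointly observed state pair, and the sites are compatible iff the
graph is acyclic (the four-gamete test in the biallelic case). The
statistic is the mean 0/1 incompatibility over informative-site pairs
within `w` bp of each other (default `w = 100`, the conventional window);
the null distribution permutes the assignment of informative sites to
their observed positions, and the p-value uses the add-one estimator so
finite permutation runs never report 0. The binary incompatibility score is
a documented variant of the published refined score: it is exactly
checkable against brute force, and calibration is assessed by simulation
(type-I error at $\alpha = 0.05$ stays within [0.01, 0.10] over 200 clonal
replicates; power rises with the recombination rate). The window is
interpreted in alignment coordinates: a window counted in informative-site
ranks would make the permutation null degenerate whenever the number of
informative sites does not exceed the window.

**Segment scanner.** For each labeled subgroup, SNPs are the columns where
the subgroup consensus differs from the complement consensus (majority
rule, alphabetical tie-break for determinism). Sliding windows (default
200 bp, quarter-window step) whose SNP count has a binomial upper-tail
probability below `score_cutoff` (default $10^{-6}$) under the subgroup's
genome-wide SNP rate are merged and trimmed to their outermost SNPs. This
is a transparent, self-contained detector for donor-fragment imports; it
is not a reimplementation of model-based recombination inference, and its
r/m companion — the ratio of subgroup SNPs inside versus outside reported
segments — is labeled `r_over_m_simple` to prevent conflation with
model-based estimators.

# Phylogeny

K2P distances use the closed form
$d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)$ with $P$ the
transition and $Q$ the transversion difference fraction; saturated pairs
return `NA` with a warning rather than a fabricated distance. The distance
matrix is computed with one-hot cross-products so collections of several
hundred STs remain fast. Neighbor joining is the standard Saitou–Nei
agglomeration; negative branch lengths are clamped to zero with the
deficit transferred to the adjacent branch (configurable to `"keep"`).
Trees are built on one representative per ST by default, mirroring
concatenated-ST practice. Bootstrap resamples columns with replacement,
rebuilds the K2P + NJ tree, and reports the percentage of replicates
containing each internal bipartition of the point tree; degenerate
replicates are skipped but counted in the denominator. The conventional
1,000 replicates are the default; tests use far fewer for speed. Gaps and
ambiguity codes are rejected upstream rather than guessing a deletion
policy.

Lineage monophyly is decided on the unrooted tree: a label is
monophyletic iff some edge bipartitions exactly its leaves from the rest.

# The simulator

The generator emulates a worldwide multi-subspecies collection:

* one unobserved **center** sequence drawn i.i.d. with
  $P(\mathrm{G\ or\ C}) =$ `gc_target` (default 0.625);
* each lineage ancestor derived from the center by flipping each site with
  probability $\delta/2$, so two ancestors differ at $\approx\delta$ per
  site and — importantly — every lineage has a positive-length stem in the
  true genealogy. (Deriving lineages 2..k directly from lineage 1's
  ancestor is simpler but leaves lineage 1 stemless at the junction, so
  its monophyly in any reconstructed tree is a coin flip; the
  center-based model makes lineage recovery a well-posed target.)
* each isolate mutates its ancestor's copy independently at
  $\theta$ per site (uniform substitution to one of the three
  alternatives, JC-like, so downstream K2P/NG86 are not tuned to the
  generator);
* with probability `recombination_prob`, one isolate-specific fragment of
  `fragment_length` bp (default 213) is copied in from a uniformly chosen
  other lineage's ancestor at a uniform position — at most one event per
  isolate, which keeps the ground truth unambiguous.

Defaults are 437 isolates split c(380, 35, 22) across three lineages
(mirroring the dominance of subsp. *longum* over *infantis* and *suis* in
human-derived collections), $\theta = 4\times10^{-4}$,
$\delta = 0.05$, `recombination_prob = 0.02`. With these settings a run
reproduces the qualitative anatomy of a real six-locus *B. longum* survey:
roughly 300 STs among 437 isolates with ~125 singleton STs, a dominant
clonal complex carrying over half the isolates, 40–90 alleles and 60–120
polymorphic sites per locus, GC near 0.625, $\pi \approx 0.013$, and
uniformly negative Tajima's $D$.

What the simulator does **not** emulate: selection (so simulated
$d_N/d_S \approx 1$, whereas housekeeping genes under purifying selection
show ratios far below 1); coalescent genealogies (isolates radiate star-like
from their ancestor, which concentrates isolates in the ancestral ST and
makes the expected Tajima's $D$ negative rather than zero even without
demography — the package's property tests assert this star-model
expectation deliberately); indels, codon structure, or rate heterogeneity.
Passing the simulation-based tests therefore demonstrates correctness of
the algorithms under a neutral, clonal, star-genealogy model, not
biological realism of any particular statistic's value.

# Numerical and degenerate-input policy

* Undefined statistics are `NA` sentinels, never silent zeros: Tajima's
  $D$ at $S=0$, $d_N/d_S$ at $d_S=0$, saturated K2P or Jukes–Cantor
  corrections.
* Ties are always broken deterministically: leftmost trim window,
  alphabetical consensus base, smaller ST number in founder election and
  MST edge ordering.
* Permutation p-values use the add-one estimator.
* All randomness is funneled through explicit seeds; a simulation config
  with a seed is byte-reproducible, and `phi_test`/`bootstrap_support`
  accept their own seeds.

# Problem sizes used by the test suite

The shipped tests validate: Tajima's D against an independent oracle on 50
random alignments ($n \le 12$, up to 120 bp); MST optimality against
exhaustive edge-subset enumeration on 100 random instances of up to 7 STs;
goeBURST partitions against graph-component oracles on 100 random
instances of up to 20 STs; NJ consistency on 50 random additive matrices
(up to 12 leaves, exact topology, branch lengths to $10^{-9}$); PHI
calibration on 200 clonal simulations of 20 isolates with ~30 informative
sites and 1,000 permutations each, plus a 40-replicate power arm at
`recombination_prob = 0.5` with $\delta = 0.1$ donors; fragment recovery
on 50 simulations implanting one 213-bp fragment at $\delta = 0.1$
(Jaccard ≥ 0.5 against truth) with a matched specificity arm; and joint
lineage recovery (ST purity, group purity, NJ monophyly) on 20 simulations
at $\delta = 0.02$, $\theta = 0.002$. These sizes were chosen so each
check is statistically meaningful while the whole suite stays quick enough
to run routinely.

# Known limitations

* The allele catalog is built de novo or preloaded; there is no registry
  lookup, fuzzy matching, or handling of truncated alleles.
* The r/m summary is a SNP partition, not a model-based estimate; its
  value depends on the scanner's labeling scheme and cutoff.
* The PHI variant uses the binary incompatibility score; p-values are not
  comparable digit-for-digit with refined-score implementations.
* Maximum-likelihood trees, split networks and model-based recombination
  inference are out of scope by design.
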