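---
title: "Methods: a four-locus MLST toolkit for Cardinium"
author: "cardmlst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-locus MLST toolkit for Cardinium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardmlst)
```

# Scope and model of the data

*Cardinium hertigii* strains are typed by the combination of alleles at
four housekeeping loci — *gyrB*, *groEL*, *sufB* and *EF-G* — amplified
with degenerate primers and Sanger-sequenced. This package implements the
full in-silico side of that workflow: the primer scheme as data, primer
design and quality heuristics, PCR product prediction and trimming,
allele/sequence-type bookkeeping, co-infection deconvolution, and
desk-scale partitioned phylogenetics with explicit, exhaustively testable
algorithms (neighbor-joining, pruning likelihood under JC69/K80/HKY85)
in place of the heavyweight Bayesian/ML machinery a production
phylogenetics study would run. For that purpose the package exports a
partitioned supermatrix (relaxed PHYLIP plus a RAxML-style partition
file) so external MrBayes/RAxML runs remain possible; it does not wrap
them.

# The primer scheme and its arithmetic

The shipped scheme stores, per locus: the degenerate forward and reverse
primers (5'→3'), the suggested melting temperature, the gene length, the
amplified range in 1-based inclusive gene coordinates, and the published
MLST fragment size. Coordinates are 1-based inclusive everywhere in the
user-facing API; half-open conversions happen only inside
implementations.

Trimming arithmetic: an amplicon spanning `a..b` has length
`b - a + 1`, and the typed fragment is that length minus both primer
lengths. For gyrB (859–1637, primers 23 + 20 bp) this gives 736 bp and
for EF-G (1162–1689, primers 25 + 21 bp) 482 bp, matching the registered
sizes. For sufB the registered 451 bp differs from the computed 442, and
for groEL 476 differs from 454. These registered values are stored
verbatim; `validate_scheme()` reports the discrepancy and never repairs
it, because no unambiguous correction follows from the scheme file
itself (either the range or the size could be the typo). The
concatenated typing width, 736 + 476 + 451 + 482 = 2145 bp, uses the
registered sizes.

The groEL scheme carries an alternative outer forward primer
(`groel_287F`) used only when the inner primer fails to amplify; it is
excluded from fragment arithmetic and from the default `amplify()` path
because only inner-primer sequence enters typing and phylogenies.

# IUPAC machinery and the inosine policy

Sequences are normalized to uppercase with U→T. Degeneracy is the
product over positions of the allowed-set sizes; `expand_degenerate()`
materializes the matched set under a cap (default 4096) so a
pathologically degenerate pattern fails loudly. Inosine (`I`), present
in two scheme primers, pairs promiscuously; the default policy treats it
as a universal base (allowed set A/C/G/T, self-complementary, degeneracy
contribution 4). A strict mode treats it as never matching, for users
who want worst-case mismatch counts. Gaps are permitted only in
alignment contexts and rejected at every primer boundary.

# Primer design

Candidates are consensus windows of a multi-strain alignment: each
column's minimal covering IUPAC code, scanned over every window in the
requested length range and both orientations. Ranking is lexicographic:
fewer ambiguities first, then a longer degeneracy-free 3' suffix (3'
fidelity governs polymerase extension), then lower hairpin plus
self-dimer score, then the leftmost window and forward orientation — a
fully deterministic order that is invariant to the input row order.

The structure checks are deliberately simple complementarity-run
heuristics rather than nearest-neighbor thermodynamics: the hairpin
score is the longest antiparallel self-foldback stem with a loop of at
least 3 bases; the dimer score is the longest contiguous complementary
run between two primers over all offsets, with runs touching either 3'
terminus flagged separately. Degenerate positions count as pairable if
any allowed base pairing complements — a conservative (worst-case)
convention for degenerate primers. Default rejection thresholds are a
stem/run of 5, or 3 when 3'-anchored. Melting temperatures use the
Wallace rule `2(A+T) + 4(G+C)` up to 14-mers and
`64.9 + 41 (GC − 16.4) / L` above; degenerate positions contribute their
expected GC content, which equals the mean over the full expansion and
keeps the estimate deterministic. M13 sequencing tags (the standard −21
M13F and M13R sequences, configurable) can be prepended for
sequencing-facility workflows and are excluded from all matching and
trimming arithmetic.

# In-silico PCR

`find_binding_sites()` scans both strands of a concrete template for
windows matching the degenerate primer with at most `max_mismatches`
mismatches (default 0 — the degenerate codes already encode the
tolerated variation) and zero mismatches in the 3'-terminal
`three_prime_exact` bases (default 3). `amplify()` pairs every
forward-primer site on the plus strand with every reverse-primer site on
the minus strand that lies fully to its right and whose product length
falls in the size window; the default window is the registered fragment
size plus both primer lengths ± 20%, since the scheme's product sizes
are essentially fixed per locus. No product is an empty tibble, not an
error — failed amplification is an ordinary outcome. `trim_primers()`
removes both primer footprints; an amplicon exactly equal to the primers
yields the empty-fragment sentinel.

# Typing, alleles and co-infections

Allele identity is exact sequence equality, the MLST convention; a new
fragment joins the database under the next id for its locus (append-only)
and carries a nearest-allele Hamming note so near-matches are visible
without any clustering threshold. Sequence types map one-to-one onto
distinct complete profiles. Fragments whose length disagrees with the
locus registry, or with more than 2% ambiguous bases, are rejected.

Hosts carrying two strains yield allele unions per locus. Two resolvers
are provided:

* **Allelic intersection analysis.** Singly-infected individuals anchor
  profiles (kept partial when loci are missing; completion is never
  guessed). For each multiply-infected individual, anchored profiles
  consistent with its allele sets are subtracted; a locus with exactly
  one unexplained allele for a single residual strain is assigned. When
  subtraction does not settle the observation, the resolver enumerates
  every strain-set decomposition consistent with it: a unique
  decomposition counts as a resolution, several go to the ambiguity
  report in full, and none flags the observation as conflicting. The
  enumeration is capped (200k candidate combinations) and reports a
  refusal rather than an incomplete answer beyond that. Records with
  multiple alleles at a single locus but one everywhere else (the
  two-copy *sufB*-like paralog signature) flow through the same path and
  surface in the ambiguity report rather than being forced into one
  profile.
* **Titer rank consistency.** Where co-infecting strains sit at stably
  different densities, per-allele qPCR titers rank alleles within each
  individual and locus; same-rank alleles across loci form a candidate
  strain. Adjacent titers within a 1.5× ratio (configurable) are ties;
  tied cells are excluded from the consistency score's denominator. The
  score is the fraction of resolvable cells agreeing with the per-locus
  majority rank map, and an assignment is returned only at or above the
  threshold (default 0.8).

# Phylogenetics

`concatenate_loci()` builds a supermatrix with a per-column (locus,
codon position) partition map. Codon positions derive from the
fragment's start coordinate within the gene's reading frame (gene
coordinate 1 = codon position 1) and are overridable per locus; for
partial-gene fragments this frame-from-coordinate rule is a documented
package choice, not an inference about how any particular study
assigned them.

Distances are p or JC69 (`d = −¾ ln(1 − 4p/3)`) with pairwise deletion
of gapped/ambiguous sites. At p ≥ 0.75 the JC correction has no finite
value; such pairs are flagged in a `saturated` attribute and filled with
twice the largest finite distance (5.0 if none) under a warning — NaN is
forbidden downstream, and this fill keeps saturated pairs maximally far
without inventing precision.

Neighbor-joining is the standard Saitou–Nei agglomeration with the Q
criterion. Two numerical contracts are pinned down for determinism: ties
in Q break to the lowest (row, column) index pair in the current node
ordering, and negative branch lengths are clamped to zero with a
warning. Bootstrap resampling draws columns with replacement within each
partition, so every replicate preserves per-gene and per-codon column
counts; support is the fraction of replicate trees containing each
internal bipartition of the reference tree.

The pruning likelihood treats gaps and ambiguity codes as missing data
(partial-likelihood indicators over the allowed set). Transition
probabilities come from the spectral decomposition of the
frequency-symmetrized HKY85 rate matrix, scaled to one expected
substitution per unit branch length, with JC69 and K80 as special
cases; the JC69 closed form is exported separately as an independent
check. AIC model selection fits on a fixed tree (topology and branch
lengths shared across models, so only substitution parameters — 0, 1
and 4 — enter `k`): K80's κ by bounded one-dimensional search on the
log scale over [0.05, 50], with κ = 1 always evaluated so K80's
likelihood can never drop below JC69's despite optimizer tolerance;
HKY85 with empirical (add-one smoothed) base frequencies. Monophyly is
the unrooted notion: a clade is monophyletic iff some internal edge's
bipartition separates exactly that clade.

# Synthetic data: what it emulates and what it does not

The generators produce every fixture the other modules consume, seeded
and bit-reproducible. `simulate_tree()` plants named clades (the A/C/E
grouping of *Cardinium* strains motivates the default three-clade
shape) as monophyletic subtrees attached by long stems to a random
backbone; defaults put backbone and within-clade branches at a mean of
0.03 substitutions/site and stems at 0.3 — a moderate-divergence regime
in which clade recovery is expected but not trivial.
`evolve_sequences()` runs the substitution model down the tree with no
indels, no rate heterogeneity among sites and no recombination.
`plant_primer_sites()` embeds one concrete realization of each primer
at the scheme coordinates in a random background and rejects backgrounds
with spurious binding sites. `simulate_coinfection()` defaults to two
strains at a 10:1 titer ratio with log-normal noise (sd 0.2 on the log
scale) across 20 individuals — the high/low-density two-strain situation
reported in co-infected *Encarsia inaron*.

Passing tests on these fixtures therefore demonstrate algorithmic
correctness under the stated generative assumptions; they do not
demonstrate robustness to alignment error, indels, heterotachy,
sequencing chimeras or chromatogram mixtures, none of which the
generators produce. The published field trees for the real 41-strain
panel are not reproducible here without the deposited sequences
(GenBank MK264778–MK264911) and full Bayesian machinery; users with
those sequences can align them per locus, concatenate, and run the NJ +
bootstrap + monophyly path, or export the partitioned supermatrix for
MrBayes/RAxML.

# Problem sizes and numerical choices

The test suite and the acceptance script use fixed, documented sizes
chosen to make the exhaustive oracles practical: 100 planted PCR
templates; 500 random IUPAC patterns of degeneracy ≤ 1024; 50
five-taxon additive matrices against all 15 topologies; 50 likelihood
instances of at most 4 taxa and 6 sites against full state-space
summation (relative tolerance 1e-10); 50 model-selection and 100
clade-recovery replicates at 500–600 sites; co-infection panels of 8–20
individuals. Other defaults worth knowing: the expansion cap (4096),
the enumeration cap in intersection analysis (2e5), the κ search range
([0.05, 50]), the titer tie ratio (1.5), the titer score threshold
(0.8), and the amplicon size window (±20%).

# Known limitations

Exact-match allele calling deliberately ignores sequencing error;
chromatogram handling and heterozygous base calling are out of scope.
The Tm formulas are ranking heuristics, not thermodynamic predictions.
NJ with JC distances degrades at saturation, and the likelihood engine
fits no rate heterogeneity (no Γ, no invariant sites) and searches no
topologies. The intersection resolver assumes every anchored profile
consistent with an observation is actually present in it; when that
assumption fails the enumeration fallback still reports all consistent
decompositions, but anchors coincidentally consistent with an unrelated
co-infection can make a resolution look unique when biology was
messier.
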