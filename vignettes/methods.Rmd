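---
title: "Methods: population-specific missense variants, network propagation, and interaction evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-specific missense variants, network propagation, and interaction evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`snpnetevo` chains four analyses that are usually run separately: a
population-genetic uniqueness screen on non-synonymous SNPs, a partition of
the resulting genes by subpopulation phenotype, a network-propagation
extension of the corresponding protein sets, and a phylogenetic
reconstruction of when the proteins' interactions appeared or disappeared.
This vignette records the models, the tunable parameters, the numerical
conventions, and the design decisions taken where the method was genuinely
underdetermined, so that a maintainer can tell deliberate choices from
accidents.

## The uniqueness screen

The screen asks: which genes carry a protein-changing variant that exists in
the focal population and nowhere else? Concretely, a variant is
*focal-unique* when all four conditions hold:

(a) it is non-synonymous with HIGH or MODERATE impact (the SnpEff-style
    severity annotation carried in the input; the package classifies codon
    effects itself but takes impact as given, since impact is an annotation
    of gene-structure disruption, not a codon computation);
(b) at least one focal individual carries the alternative allele;
(c) no comparison breed's call list contains the same alternative allele at
    the same chromosome and position;
(d) no related species shows the focal alternative residue at the aligned
    protein column, either as its aligned residue or among its own
    segregating alternatives.

Two of these required interpretation. "Present only in the focal
population" is implemented as *carrier-based*: one focal carrier suffices
and any non-focal carrier of the same allele disqualifies, with no
allele-frequency threshold — the weakest condition consistent with the
phrase, and the one that makes no assumption about dosage. And condition
(c) is checked against the comparison populations' *call lists*, not their
genotypes: a breed VCF containing the allele at all disqualifies the
variant. The comparison panel is an argument, so wolves or other outgroups
can be included or excluded freely.

Condition (d) works at the protein-alignment level rather than through a
genomic lift-over: each gene has one aligned FASTA with a row per species,
the focal protein position maps to an alignment column through the focal
row's gaps, and a gap in a species at that column makes the species
non-informative (the condition is vacuously true for it). This matches how
cross-species residue evidence is actually presented in this kind of study
and avoids inventing coordinate maps the data do not contain.

Upstream of the screen, variants pass the GATK-style hard filter: a record
is removed when QD < 5.0, MQ < 40.0, FS > 200.0 or QUAL < 30.0. All four
inequalities are strict (a value exactly at a threshold is retained), a
missing statistic never fires its clause, and the per-clause removal tally
is reported. Effect categories are tabulated with the fixed severity
precedence exonic > splice site > UTR > intron > intergenic when a variant
overlaps several annotations; splice sites are intronic positions within
2 bp of an exon boundary (the common annotation convention). Ti/Tv counts
A↔G and C↔T ref→alt pairs as transitions without strand folding.

Genes then partition by who carries their focal-unique variants:
*tail-specific* when only long-tail or short-tail individuals do,
*non-tail-specific* when only non-tail individuals do, *common* when both
sides carry them. The three sets are asserted on every run to be disjoint
and to cover exactly the carrier-bearing focal-specific genes. Term
enrichment is a one-sided hypergeometric upper tail per term with
Bonferroni correction over the number of tested terms (flat term map; no
ontology-graph propagation).

## Network propagation

Protein sets are extended by random walk with restart: the fixed point of
`r = c·e + (1 − c)·W·r` with restart probability `c = 0.95` (close to the
seeds by design), seed distribution `e` uniform over the seed proteins, and
`W` the column-normalised adjacency. Defaults and conventions:

* **Weights.** `W` uses edge scores as weights. Whether the original
  propagation used weighted or binary adjacency is not recoverable, so a
  `weighted = FALSE` flag provides the binary alternative.
* **Thresholding.** The network is *not* pre-thresholded at 0.7 for
  propagation; the 0.7 cutoff belongs to the interaction-evolution stage,
  where interaction credibility matters. `run_config(threshold_before_rwr
  = TRUE)` applies it earlier for sensitivity analyses.
* **Dangling columns.** Columns of isolated nodes redirect their mass to
  the seed distribution, keeping `W` stochastic; the score vector sums to 1
  at every iteration and unreachable nodes stay at exactly 0.
* **Convergence.** Power iteration stops when the L1 change drops below
  `1e-10`; with `c = 1` the first iterate is already the exact fixed point
  (the seed vector).
* **Top 5%.** The extended set is the first `ceiling(0.05 × n)` nodes among
  the `n` nodes with nonzero score, ranked by score with lexicographic id
  as tie-break. Published extended-set sizes from a single network differ
  per seed set, which implies a set-dependent denominator; nonzero-score
  nodes is the natural such denominator, and seeds rank like any other
  node. This is the one place where a different reading (seeds excluded,
  or a whole-network denominator) would change set sizes, so the fraction
  is a parameter.

Within- versus between-set enrichment is the hypergeometric upper tail for
the number of interacting within-set pairs among all interacting pairs,
i.e. a one-sided Fisher test in the direction of within-set clustering —
one-sided because the scientific claim being tested is directional.

## Interaction transfer and ancestral reconstruction

An interaction between two focal proteins transfers to another species
through their ortholog groups: with `m` and `k` members there, the
interaction is *present* iff strictly more than half of the `m × k`
cross-group pairs interact at score ≥ 0.7 (self-pairs from overlapping
groups are excluded from the count), *unknown* when either group is empty
in that species, and *absent* otherwise. The rule is symmetric in the two
proteins; exactly half is absent.

Ancestral states come from unit-cost maximum parsimony on the rooted
binary species tree (((dog,cat),(horse,(pig,cow))),mouse). The
implementation is a Sankoff dynamic program vectorised across pairs, which
for binary characters on binary trees coincides with Fitch's algorithm;
the score is the minimum number of changes over all ancestral labelings
*and* all assignments of unknown tips. The conventions:

* **Unknown tips are unconstrained**, not absent. Turning absence of
  evidence into evidence of absence would manufacture gains on the focal
  branch — the very direction under test — so the conservative choice is
  the only defensible one.
* **Ambiguity resolution.** Minimising total changes does not pick among
  equally parsimonious reconstructions. The default top-down pass prefers
  the parent's resolved state on ties (a DELTRAN-like rule pushing changes
  tipward); `resolve = "acctran"` breaks ties toward a change on the
  earlier branch. Both realise exactly the parsimony score, which the
  tests assert.
* **Root ambiguity** resolves to the outgroup tip's state, and to absent
  when the outgroup is unknown.
* Trees with polytomies are rejected rather than silently mishandled.

Branch accounting then counts, per branch, pairs gaining (parent 0, child
1) and losing (parent 1, child 0) the interaction, with the denominators
(pairs without/with interaction at the parent) reported alongside; a zero
denominator yields `NA`, not 0. Gains plus losses across branches equal
the summed parsimony score — an identity asserted on every call.

The randomization test draws, 10,000 times, as many pairs as the observed
set uniformly without replacement from the universe of profiled pairs,
recomputes each branch's gain fraction, and reports the one-sided add-one
p-value `(1 + #{replicates ≥ observed}) / (n + 1)`. The universe is the
set of focal pairs with computable profiles (both proteins mapped to
ortholog groups), not all conceivable pairs: resampling from pairs the
method could never have profiled would deflate the null. Because
reconstruction is independent across pairs, replicates reuse the
universe-wide reconstruction, which makes 10,000 replicates effectively
free.

## What the generator emulates — and what it does not

`simulate_cohort()` produces gene models with coding frames on simulated
chromosomes, per-population VCF call sets, per-gene protein alignments,
species alternative-residue tables, and a planted truth record. Its
defaults are the study conditions of the motivating design: focal
subpopulations of 7 (long-tail), 5 (short-tail) and 10 (non-tail)
individuals, a 12-breed comparison panel with the published sample sizes,
six related species, and a Ti/Tv target of 2.04. Desk-scale parameters
were fixed once: 100 genes of 50–120 codons, 30 sites per gene, 10 planted
genes (10% of genes) and 50 decoys — enough sites for stable category
fractions and enough planted/decoy structure to measure precision and
recall exactly, while keeping a full cohort under ten seconds.

Planting is constructive: planted missense SNPs are generated in coding
space (codon and position chosen, then mapped through the gene model to
genomic coordinates), are guaranteed HIGH/MODERATE, absent from every
breed call list, and absent from every species' aligned column and
alternative-residue set. Each decoy violates exactly one condition: LOW
impact, one breed sharing the allele, or one species showing the
alternative residue. Background missense variants with focal carriers are
forced to recur in a breed, so they can never masquerade as planted.
Effects are annotated by the generator's own coding-space computation and
re-derived independently by the genomic-coordinate classifier; the tests
require 100% agreement, which exercises the exon/strand/frame plumbing in
both directions.

`simulate_interaction_history()` evolves each pair root-to-tips as a
two-state Markov process (per-branch gain rate 0.05, loss rate 0.02, root
presence 0.15 by default) and realises tip states through the observable
layer the pipeline actually consumes: ortholog groups of 1–3 members
(empty with probability 0.1, producing unknowns), species networks in
which present pairs have strictly more than half of their cross-group
pairs interacting at score ≥ 0.7, absent pairs at most half (sometimes
exactly half, to exercise the boundary), plus sub-threshold noise edges
the cutoff must ignore. The branch-rate excess applies to a designated
*subset* of pairs (10% by default, recorded in the truth): this is what
makes the randomization test meaningful, since an excess applied to every
pair would leave any equal-sized random subset with the same expected gain
fraction and the test could never detect anything. With
`excess_factor = 1` the planted subset is exchangeable with the rest, and
its p-values are uniform — the null-calibration property the tests check
across 50 seeds.

What the generators deliberately do *not* emulate: linkage disequilibrium,
demography, or shared ancestry between breeds (carriers are independent
draws); sequencing-read noise (call statistics are drawn directly);
realistic ortholog-family structure (groups are per-protein, 1–3 members);
and STRING's evidence-channel score combination. Passing tests therefore
show that the pipeline's logic is correct under its stated definitions —
not that those definitions are robust to the correlation structure of real
cohorts, where a rare allele shared identical-by-descent with an unsampled
breed would still pass condition (c).

## Numerical choices and degenerate inputs

Propagation tolerance 1e-10 (L1), score-sum invariant 1e-9, solver
equivalence checked to 1e-8 (L-infinity) on graphs up to 50 nodes.
Category fractions must sum to 1 within 1e-12, and are reported as 0 for
empty input rather than NaN. Zero transversions make Ti/Tv an explicit
error, not Inf. An empty protein set extracts an empty subnetwork; an
empty enrichment background is an error. Readers reject rather than
coerce: non-SNP and multiallelic VCF records are skipped with counts,
out-of-range edge scores and unbalanced newick parentheses are errors
naming the line or character, unlabelled VCF samples are errors naming the
sample, and duplicate edge orientations merge to the maximum score with a
message. Unnamed internal nodes get deterministic preorder names
(`A1, A2, ...`) so per-branch reports are stable across runs.

Test problem sizes — 500 brute-force parsimony characters on trees of 4–8
tips, 100 propagation graphs up to 50 nodes, a 100-gene cohort with 10
planted and 50 decoy genes, 2,000-pair histories with 10,000-replicate
randomization, and a 100,000-site cohort for the Ti/Tv calibration — were
chosen so the full suite completes in about a minute while every
enumeration-backed check stays exact.

## Known limitations

* Impact (HIGH/MODERATE/LOW/MODIFIER) is consumed, not computed; the
  codon classifier covers effect classes only, without the full effect
  ontology of a dedicated annotator (no start-loss/stop-gain distinction —
  a premature stop classifies as non-synonymous).
* The parsimony machinery is binary-state, unit-cost and binary-tree only;
  there is no likelihood-based reconstruction and branch lengths never
  enter the computation.
* Under convergent independent gains, maximum parsimony can reconstruct an
  ancestral gain plus losses even when the generating process never loses
  an interaction; reconstructed per-branch counts are estimates of the
  parsimony-optimal history, not of the generating one.
* Headline counts from database-backed studies (numbers of
  population-specific genes, extended-set sizes, profiled-pair totals)
  depend on database versions and raw data volumes and are not
  reproducible at desk scale; the package's guarantees are the exact
  property checks above, not those counts.

## Interfaces

All I/O is plain text: VCF 4.x (via `vcfR`), newick (via `ape`), aligned
FASTA (via `Biostrings`), TSV edge lists, ortholog tables, gene models and
species-residue tables, YAML configuration, and Cytoscape-compatible SIF
export for subnetworks. The exported functions compose the pipeline in R;
`scripts/acceptance.R` is the shell entry point that reruns the whole
chain and emits its quantities as JSON.
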