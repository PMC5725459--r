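# snpnetevo

Identifying what makes a population genetically distinctive — and how that
distinctiveness propagates through protein-interaction networks and deep
evolutionary time — is a recurring task in population and comparative
genomics of non-model animals. `snpnetevo` implements that analysis chain as
a tested R pipeline, modelled on studies of breed-specific traits in dogs
(the motivating case is a bob-tailed native breed whose 22 sequenced
individuals split into long-tail, short-tail and non-tail subpopulations):

1. **Variant screening.** Multi-sample SNP calls are hard-filtered
   (removal when QD < 5.0, MQ < 40.0, FS > 200.0 or QUAL < 30.0, all
   strict), classified by codon-level effect (standard genetic code,
   strand-aware), and summarised by Ti/Tv ratio and effect-category tables.
2. **Population-specific genes.** A gene is focal-specific when it carries a
   non-synonymous SNP of HIGH/MODERATE impact whose alternative allele is
   carried by at least one focal individual, occurs in no comparison breed
   at the same position, and whose alternative residue appears in no related
   species at the aligned protein column. Genes partition into
   tail-specific, non-tail-specific and common sets by subpopulation
   carriers; over-representation of annotation terms is tested with a
   one-sided hypergeometric p and Bonferroni correction.
3. **Network propagation.** Each protein set is extended over a scored
   (STRING-like) interaction network by random walk with restart,

   r = c·e + (1 − c)·W·r,

   with restart probability c = 0.95, W the column-normalised score-weighted
   adjacency, and e uniform over the seeds; the top 5% of nonzero-score
   proteins form the extended set. Within- versus between-set interaction
   enrichment is a one-sided Fisher/hypergeometric test.
4. **Interaction evolution.** Dog protein pairs transfer to related species
   through ortholog groups (present iff strictly more than half of all
   cross-group ortholog pairs interact at score ≥ 0.7). Ancestral states on
   the species tree (((dog,cat),(horse,(pig,cow))),mouse) are reconstructed
   by maximum parsimony (Fitch on binary characters; unknown tips
   unconstrained), gains (+) and losses (−) are accounted per branch with
   their denominators, and per-branch gain fractions get empirical p-values
   from 10,000 resamples of equal-sized pair sets.

A synthetic-data module generates every input with planted ground truth —
focal-unique missense SNPs, decoys violating exactly one uniqueness
condition each, and an interaction history with an excess of gains on one
branch — so the whole pipeline is testable end to end without downloads.

## Worked example

```r
library(snpnetevo)

spec <- cohort_spec(n_genes = 60, n_sites_per_gene = 20,
                    fraction_focal_unique_missense = 0.1, n_decoy_genes = 15,
                    comparison_breeds = c(Kunming = 10, YingjiangVillage = 10),
                    related_species = c("cat", "cow", "horse", "mouse", "pig"),
                    rng_seed = 101)
cohort <- simulate_cohort(spec)
focal <- snpnetevo:::hard_filter_callset(cohort$focal)
focal
#> population_callset: 932 SNP sites x 22 samples (LT=7, NT=10, ST=5)
ti_tv_ratio(focal$variants)
#> [1] 2.06

screen <- find_focal_specific_genes(focal, cohort$breeds,
                                    cohort$alignments, cohort$species_residues)
classify_by_subpopulation(screen)
#> gene_classification: 6 focal-specific genes (2 tail, 2 non-tail, 2 common)
setequal(screen$genes, cohort$truth$planted_genes)
#> [1] TRUE
```

All six planted genes are recovered (the 15 decoys — LOW impact,
breed-shared, or species-shared — are rejected), and the subpopulation
partition matches the planted classes. The evolutionary stage, on a history
with a 10-fold gain excess planted on the dog terminal branch:

```r
tree <- read_newick("(((dog,cat),(horse,(pig,cow))),mouse);")
h <- simulate_interaction_history(tree, n_pairs = 1000, excess_factor = 10,
                                  rng_seed = 101)
profiles <- build_interaction_profiles(h$pairs, h$ortholog_map, h$networks,
                                       species = tree$tip.label)
rec <- fitch_reconstruct_many(tree, snpnetevo:::profiles_to_states(profiles))
head(branch_change_summary(rec)[order(-branch_change_summary(rec)$gain_fraction),
     c("branch_id", "gains", "n_without_at_parent", "gain_fraction")], 3)
#>   branch_id gains n_without_at_parent gain_fraction
#> 3       dog    87                 789    0.11026616
#> 1        A2    43                 809    0.05315204
#> 7        A5    35                 778    0.04498715

rt <- randomization_test(rec, h$truth$planted_pairs, n = 10000, rng_seed = 102)
rt[rt$branch_id == "dog", ]
#>   branch_id observed_gain_fraction   p_value
#> 3       dog              0.4166667 9.999e-05
```

The dog branch ranks first by gain fraction (87 gains among 789 pairs
without interaction at its ancestor), and the planted pair set's
gain fraction on that branch (41.7%) exceeds all 10,000 random same-size
pair sets, giving the add-one floor p = 1/10001.

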