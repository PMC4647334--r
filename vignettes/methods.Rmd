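---
title: "From chemically defined inducers to enzyme regulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chemically defined inducers to enzyme regulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazyreg)
```

## The scientific problem

Filamentous fungi such as *Aspergillus oryzae* degrade plant cell walls with
a cocktail of carbohydrate-active enzymes (CAZymes) whose expression is
triggered by small, chemically defined oligosaccharide inducers —
cellohexaose, sophorose, xylopentaose and the like — and repressed by
glucose. `cazyreg` implements the integrative analysis that connects such
inducers to enzyme regulation: per-inducer differential expression against a
glucose reference, GO-term and metabolic-pathway regulation summaries,
chemical-space and expression-space clustering, secretome and CAZy
regulation tables, a guilt-by-association network for candidate secreted
enzymes, and an association table linking candidate
transcription-factor-binding metabolites through reactions and enzymes to
the regulation of their genes.

Because the microarray data behind this experimental design are not
publicly deposited, the package treats the study design itself as the
object of analysis: a synthetic-data module plants known structure (ten
inducers plus glucose, three biological replicates, signed log
fold-changes, annotated gene sets, a toy genome-scale metabolic network)
and every downstream stage is validated against that planted ground truth.
The one directly reproducible data object — a reference association table
linking six strong-binder metabolites to the log fold-changes of their
reaction genes — ships as a packaged fixture.

## Differential expression

For each inducer the log2 expression of every gene is compared with the
glucose reference by a two-sample t-test on replicate values
(`pairwise_de`). The log fold-change is `mean(inducer) − mean(glucose)`,
so positive values mean up-regulation by the inducer.

The default pools the within-group variances (Student's test). The choice
matters at this sample size: with three replicates per group the Welch
unequal-variance statistic is markedly conservative — its measured size at
the nominal 0.05 level is about 0.032 — whereas the pooled statistic is
exactly t-distributed under the equal-variance Gaussian noise model that
both the synthetic generator and conventional microarray practice assume.
An analysis stage whose stated operating point is "significant at
p < 0.05" should actually reject 5% of null genes, so the pooled test is
the default and the Welch variant remains available via
`var_equal = FALSE`. Multiple-testing correction defaults to none (the
operating point of the original design is a raw p < 0.05 cutoff);
Benjamini–Hochberg is available with `adjust = "BH"`.

Degenerate inputs are resolved rather than erroring: two groups with zero
variance and equal means give p = 1 (no evidence), and p-values are floored
at the smallest positive double so they stay in (0, 1]. Genes with missing
values in any used sample are dropped with a warning; the method has no
principled imputation at n = 3 and silently filling values would bias the
variance estimate.

## Functional matrices and descriptor ranking

`build_go_matrix` counts, per GO term and inducer, the significant genes
annotated to that term. A gene with several terms contributes once to each
of them — annotation multiplicity is information about functional breadth,
not double counting — and the per-inducer fraction of significant genes
with any annotation is reported as a coverage attribute. No enrichment
p-values are computed: the downstream consumers (clustering, descriptor
ranking) want the count matrix itself.

Because count scales differ wildly across terms, `standardize_matrix`
z-scores each row with the population standard deviation; constant rows
map to zero and are flagged. `rank_descriptors` scores each descriptor row
by a correlation-based feature-selection merit against item cluster
labels, averaged over cross-validation folds (10 by default, degenerating
to leave-one-out when items are scarce, as with ten inducers). For a
single descriptor the merit is its correlation with the label; for label
vectors with more than two classes the correlation ratio (the square root
of the one-way ANOVA R²) is used, which reduces to |Pearson r| for a
binary indicator. The subset-level merit
`k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` (`cfs_merit`) exposes the redundancy
penalty for callers who want to grow subsets. Fold membership is keyed to
sorted item names so the ranking is invariant to column permutation, and
ties break lexicographically by descriptor name so output order is
deterministic.

## Clustering

`train_som` implements the classical sequential self-organizing map: at
each of 4000 iterations (the default) one item is drawn, its best-matching
unit is located by Euclidean distance, and every codebook vector moves
toward the item under a Gaussian neighborhood. The learning rate decays
linearly 0.05 → 0.01 and the neighborhood width from half the grid
diagonal to 0.5; both schedules are exposed because no universal values
exist, and these are the standard textbook ranges. The codebook is
initialized from randomly drawn items with a small jitter, which converges
faster than uniform-random initialization and keeps the single-item edge
case exact. Equidistant ties go to the lowest neuron index so training is
reproducible bit-for-bit under a seed. Grid defaults follow the two use
cases: 5×5 for small chemical-descriptor matrices, 4×6 (24 neurons) for GO
count matrices.

`som_kmeans` then runs Lloyd k-means on the *original* items,
initialized from k codebook vectors chosen by k-means++, with Lloyd capped
at 4000 iterations. A single Lloyd run from any fixed initialization is
well known to stick in local optima, so the k-means++ draw is restarted
(10 times by default) and the lowest-inertia solution kept; this is the
same remedy `stats::kmeans(nstart = …)` applies, restricted here to
codebook-seeded starts. The number of clusters k is an explicit parameter
(default 3): no parameter-free rule can be guaranteed to derive a specific
cluster count from a SOM codebook, so the package does not pretend to —
`silhouette_sweep` is provided for callers who want a data-driven sweep.

`hierarchical_cluster` wraps average-linkage agglomerative clustering over
Euclidean distances (the conventional heatmap default when no linkage is
stated), and emits the leaf order for heatmap rendering plus a Newick
export of the tree.

## Pathway regulation

`pathway_fractions` computes, per pathway and inducer, the fraction of the
pathway's genes significantly up- and down-regulated. Genes appearing in
several pathways count toward each — the only reading consistent with
per-pathway fractions over a genome-scale metabolic model, where enzymes
are shared freely. A pathway–inducer pair is "highly affected"
(`highly_affected`) when at least half the pathway changed significantly,
counting both directions, with the boundary included. `build_two_block_matrix`
turns the fraction matrix into an inducer × (2 × pathways) descriptor
matrix (up- and down-fraction per pathway) that feeds the clustering
module. No significance floor is applied to the fractions beyond the DE
call itself, and reaction stoichiometry is never used beyond
reactant/product identity.

## Secretome, CAZy tables and guilt by association

`extracellular_table` retains genes flagged extracellular that are
significant in at least one inducer and emits their full logFC row for
heatmap clustering. `cazy_regulation_summary` counts distinct genes per
CAZy class (GH, GT, PL, CE, AA) that are up- (or down-) regulated in at
least one inducer; a gene can be both, in which case both tallies and an
overlap column record it. `induction_table` renders per-gene, per-inducer
regulation arrows (↑/↓/—) that are cross-checked against the DE table.

The guilt-by-association stage encodes each gene's regulation as a ternary
profile (−1/0/+1 per inducer). A candidate (an extracellular non-CAZy
gene) is associated with a CAZy gene when the two profiles agree exactly
on the CAZy gene's significant-support set, the support holds at least
`min_support = 2` inducers (a single shared inducer is too weak a pattern
to call an association), and the candidate is significant across the whole
support. Exact ternary matching — direction and significance — is the
strictest reading of "follows the same expression profile"; a Pearson
alternative over shared significant inducers (`associate_correlation`) is
provided but is not the default. The typed gene–inducer network
(`build_association_network`) exports to GraphML and SIF.

## Metabolite–gene association tables

`reactions_of` returns every reaction containing a metabolite as reactant
or product (reversible reactions match on either side).
`build_metabolite_table` traces metabolite → reaction → enzyme → gene and
attaches the gene's per-inducer logFC, leaving cells missing ("-") where
the gene is not significant against glucose; missing cells are excluded
from, never zero-filled into, statistics and consistency calls.
`classify_consistency` labels each metabolite down-consistent (every
observed cell negative), up-consistent, mixed, or no-data. Gene
association strings with several genes (`A;B`) produce one row per gene;
boolean gene–protein–reaction logic is deliberately not interpreted.

The packaged table (`load_strong_binder_table`, checksum-verified on load)
records six candidate transcription-factor-binding metabolites — sulfite,
sulfate, uroporphyrinogen III, ethanolamine phosphate, D-glyceraldehyde
3-phosphate and taurine — with their reactions, enzymes, gene ids and
reference logFC values across ten inducers. The transketolase entry lists
three reactions but a single gene and eight observed cells; the source
layout does not say which two inducer columns are missing, so the fixture
assigns the gaps to the galactosyl-mannotriose and glucohexaose columns by
column-count alignment and keeps the two extra reactions as all-missing
rows so no value is duplicated. This transcription assumption affects no
statistic (min, max, mean and count are over observed cells).

## The synthetic-data module

`synth_config` defaults encode the emulated design: ten named
oligosaccharide inducers plus glucose, three biological replicates,
independent Gaussian noise on the log2 scale (sd 0.25), planted effects
with mean |logFC| 2, 58 GO terms across the three ontology classes, 66
metabolic pathways at full scale (scaled down for small gene universes so
pathways stay nonempty), CAZy families over 5% of genes and a 10%
extracellular fraction. Planted magnitudes are exactly ± the configured
effect size: under that convention the pooled t-test's power at effect =
5× noise and n = 3 is 0.9928, so the planted-sign recovery guarantee
(≥ 99%) holds by design rather than by luck. Everything is deterministic
under the configured seed, with sub-generators offset so the same seed can
drive a coherent multi-part study.

`generate_study` builds an end-to-end scenario in which recovery is
certain by construction, not by chance: randomly planted DE genes are
sampled outside pathway membership and outside the association genes; one
designated pathway has all its genes planted down-regulated in one
designated inducer (making it the unique highly-affected pair at the 0.5
threshold); and each planted CAZy gene shares an identical planted
significance profile (2–4 inducers) with one extracellular non-CAZy
partner.

What the generator does *not* emulate: probe-level microarray signal,
normalization artifacts, dye bias, variance heterogeneity across genes,
or correlated expression programs. Passing tests therefore demonstrate
the correctness of the pipeline's logic and its statistical calibration
under the stated noise model — not robustness to the pathologies of real
microarray data.

## Validation scenarios and problem sizes

The packaged checks run at sizes chosen to make their conclusions exact:

* **Type-I calibration** — 10,000 null genes, one inducer, three
  replicates: the significant-call rate at α = 0.05 must sit inside the
  99% binomial band around 0.05. This is the scale at which the band
  (±0.0056) cleanly separates a calibrated test from the Welch variant's
  0.032.
* **Cluster recovery** — 100 planted descriptor matrices (10 items × 186
  descriptors, 3 clusters, separation 10× noise), SOM 4×6 with 4000
  iterations, k-means k = 3: adjusted Rand index 1.0 expected in ≥ 95
  runs. Tiny instances (n ≤ 8) are checked against the exhaustive
  optimum over all 2-partitions.
* **Oracle equivalence** — 100 randomized 60-gene studies: pathway
  fractions, CAZy summaries, signed profiles, association edges and
  reaction membership must equal independent brute-force recounts.
* **End-to-end study** — 400 genes, 10 inducers, 3 replicates, planted
  effects at 75× noise, significance at α = 1e-4. At three replicates a
  t-test's p-values cannot distinguish planted from null genes reliably
  below ~1e-3 when effects are modest, and any α leaves α × (null tests)
  expected false positives; exact set equality between planted and
  recovered calls is therefore not a meaningful target at realistic
  noise. The scenario instead uses strong effects (detection certain)
  and asserts that every planted call is recovered with its planted
  sign, that extra calls stay within the binomial false-positive budget
  of α, and that the planted pathway and association partners are
  recovered exactly.

## Known limitations

* Headline counts at the scale of a real experiment (thousands of
  significant genes per inducer, dozens of regulated CAZy genes and
  secreted proteins) depend on microarray data and annotation services
  that are not packaged here; the analyses are reproduced structurally,
  on synthetic data, not numerically.
* The SOM is the classical sequential variant only; no batch SOM, no
  U-matrix visualization.
* GO annotation is consumed as given — no graph propagation to ancestor
  terms.
* SBML input is not supported; metabolic networks are read from the TSV
  reaction-table format documented in `read_reaction_table`.
* Docking, pocket detection, homology modeling and signal-peptide
  prediction are outside the package's scope; their outputs (the
  strong-binder list, extracellular flags, CAZy families) are inputs.

## A worked miniature

```{r worked, eval = FALSE}
cfg <- synth_config(n_genes = 400, de_fraction_per_inducer = 0.03,
                    effect_size_logfc = 1.5, noise_sd = 0.02,
                    n_pathways = 8, n_pathway_genes = 64, seed = 77)
st  <- generate_study(cfg)
de  <- de_table(st$expression, alpha = 1e-4)
ss  <- significant_sets(de)
reg <- pathway_fractions(ss, st$network)
highly_affected(reg)

tab <- load_strong_binder_table()
classify_consistency(tab)
row_stats(tab, "AO090001000571")
```
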