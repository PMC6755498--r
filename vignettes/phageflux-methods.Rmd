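---
title: "Models and methods in phageflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phageflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageflux)
```

phageflux quantifies homologous recombination in a collection of aligned
phage (prophage) genomes at two levels: the whole genome, through a
haplotype-copying model that decomposes each genome into donor-derived
chunks; and the gene, through pan-genome classification, the four-gamete
bound on recombination events, and a diversity-controlled regression.
This vignette explains each model, its assumptions, the tunable parameters
and the numerical choices, and what the synthetic-data generators do and do
not emulate.

## Input model and filtering

The unit of input is a gap-aware multiple alignment (`haplotype_alignment`)
with one record per genome and an optional population label per record.
Before painting, `apply_exclusions()` removes genomes named explicitly
(e.g. a genome whose large inversion does not align) and genomes
byte-identical to an earlier record: duplicated haplotypes would act as
perfect donors for each other and distort every downstream chunk count.
`extract_core_snps()` then retains alignment columns that are polymorphic,
strictly biallelic, and free of gaps and ambiguity codes in every sample.
The biallelic restriction is a modelling choice rather than a data-format
one: the copying model emits match/mismatch probabilities per site, and
two-allele sites make the mismatch probability interpretable as a single
miscopy rate. Multiallelic sites are rare in closely related collections
and are dropped rather than recoded. Alleles are coded 0/1 with 0 the
major allele; an exact 50/50 tie goes to the alphabetically first allele
so the coding is deterministic.

For per-gene statistics (`nucleotide_diversity()`), columns containing a
gap are removed entirely (complete deletion) before computing the mean
pairwise per-site difference; the gap-filtered length L is also the
denominator for the per-nucleotide recombination intensity below, so both
statistics refer to the same set of sites.

## The copying model (chromosome painting)

Each genome in turn is treated as a *recipient* and all other genomes as a
leave-one-out *donor panel*. Conditional on the recipient, a hidden donor
identity evolves along the SNP sequence as a Markov chain: between
adjacent SNPs separated by d alignment columns the donor switches with
probability 1 − exp(−λ d), and conditional on a switch the new donor is
uniform over the k panel members (so a "switch" may land on the same
donor; this closed-form kernel is the standard simplification of the
Li–Stephens model). At each SNP the recipient allele matches the current
donor's allele with probability 1 − θ and mismatches with probability θ.

Two parameters matter:

* `switch_scale` (λ, per bp): the expected switch intensity. The default
  sets λ = 10 / (total inter-SNP distance), i.e. roughly ten expected
  switch opportunities across the painted region — weakly informative for
  mosaic genomes whose true segment counts are of that order. When the
  generating segment length is known (as in simulations) λ = 1/mean
  segment length is the natural choice.
* `miscopy` (θ, per site, in (0, 0.5)): the emission mismatch rate,
  defaulting to the Watterson-style convention θ_w/(θ_w + 2k) with
  θ_w = 1/Σ_{i<k} 1/i, clipped to (1e-4, 0.49).

No expectation–maximisation refinement is run by default: a single
fixed-parameter forward–backward pass is deterministic, fast, and
sufficient for chunk-count contrasts; both parameters are overridable.

The forward–backward recursions are scaled per site, so likelihoods stay
finite for alignments up to at least 1e5 SNPs. The per-site copy
posterior rows sum to one by construction. Expected chunk counts per
donor are posterior expectations of *maximal copied segments*: the
initial assignment contributes P(z₁ = d), and each transition contributes
P(z_l ≠ d, z_{l+1} = d) — a switch that lands on the incumbent donor does
not open a new chunk. Running every sample as recipient fills the
co-ancestry matrix X, with X[r, d] the expected number of chunks r copied
from d and a structural zero diagonal. A companion matrix of expected
copied *sites* per donor is kept alongside (see Flux below for why).

## Partition model and MCMC

Clusters of individuals are inferred from X alone. Each recipient row,
aggregated over donor clusters, is modelled as draws over donors in which
a donor from cluster b is chosen with probability q_b/n_b — cluster
proportions q under a symmetric Dirichlet(β) prior, chunks spread
uniformly within a cluster, and the recipient excluded from its own
cluster's donor count. Marginalising q gives a Dirichlet–multinomial term
over the aggregated counts plus a −Σ_b x_rb log n_b uniform-spread term.
The spread term is essential: without it the single-cluster partition is
always a global optimum (a one-category multinomial has probability one),
and partitions of different sizes are not comparable. Expected (real-
valued) chunk counts enter through the Γ continuous extension of the
factorials. β defaults to 1 (flat); no additional effective-independence
divisor is applied to X by default, though a scalar divisor can be passed
by rescaling X.

The posterior over partitions (flat prior) is explored by
Metropolis–Hastings with two move families: reassigning one individual to
another cluster or a new singleton, and merging a random cluster pair or
splitting a random cluster by a uniform non-trivial bipartition. Both
moves carry explicit Hastings corrections. The default chain lengths
follow the 1e5 + 1e5 convention of the reference workflow; the package's
own tests use 5e3 + 5e3, which on block-structured matrices of a few
dozen samples recovers planted partitions reliably while keeping the full
suite inside a few minutes. The MAP partition is the highest-likelihood
state visited anywhere in the run. A greedy agglomeration
(`merge_tree()`) then merges the pair losing the least log marginal
likelihood until one cluster remains, recording the order as a rooted
Newick tree; ties break on the lexicographically smallest label pair so
the tree is deterministic.

No claim is made of numerical agreement with any particular external
implementation of this class of model: the likelihood above is the
standard conjugate choice, stated in full so that every number is
reproducible from this document.

## Genetic flux

`import_fractions()` converts X into per-recipient fractions received
from each donor population; the denominator includes own-population
donors by default (each painted genome is a complete mosaic, so fractions
over all donor populations sum to one), with a cross-population-only
denominator available. Medians are taken over recipient × donor-population
pairs, matching a per-individual-recipient reading, and import and export
views are two slices of the same table. Group contrasts use a two-sided
Wilcoxon rank-sum test: the exact null distribution (by a subset-count
dynamic programme equivalent to full enumeration) whenever the combined
sample is ≤ 20 and untied, otherwise the normal approximation with tie
and continuity corrections.

Two measures are exposed. Chunk *counts* (`measure = "chunks"`, the
default and the heatmap currency) weight each copied segment equally;
they emphasise boundary events and are the natural visual summary.
Copied-site *lengths* (`measure = "lengths"`) estimate the genome
fraction copied from each population. For parameter recovery of a planted
migration fraction the lengths measure is the estimand-matched one: when
a population offers many equally good donors, the posterior churns among
them and the count measure inflates that population's share, whereas the
site measure is invariant to the churn. The package's recovery checks
therefore use lengths, while the co-ancestry heatmap and flux tables
default to counts.

One further subtlety affects what "perfect recovery" means. When several
panel members share the recipient's founder at a site, any copying model
must split the attribution among them; the recovered fraction from a
donor population is therefore slightly below the raw planted fraction
whenever the recipient's own population also carries migrant segments.
The generator returns this realized attribution expectation
(`expected_import`) computed directly from the true founder mosaics, and
recovery is judged against both it and the planted value.

## Pan-genome classification

Genes are clustered by best local alignment percent identity (BLOSUM62,
affine gaps 10/4, identities normalised by the shorter sequence — the
blastp shorter-length convention) with an edge at or above the threshold
and connected components as clusters. Component clustering preserves the
property that matters for the parameter sweep — the pan-genome size is
monotone non-decreasing in the threshold — without a heavier
cluster-refinement stack; exact reproduction of any particular external
pipeline's cluster inventory is not a goal. Categories follow presence:
core = 100 % of genomes, soft-core ≥ 90 % (Methods-style "at least"),
singleton = exactly one genome, shell otherwise.

Paralogue splitting has no synteny information to lean on here, so the
`split_paralogs` option re-clusters any cluster containing two or more
genes of one genome by single linkage at a stricter threshold
(threshold + 10, capped at 95). The rationale is empirical: apparent
paralogues in prophage annotation are typically one gene interrupted by
an internal stop plus a restart, annotated as two fragments, and
fragments separate at a stricter threshold while true family members do
not. `detect_interrupted()` makes the artifact explicit: a same-genome
pair whose concatenation aligns end-to-end to a full-length member of the
same cluster (identity ≥ 80 over ≥ 80 % coverage, both configurable) is
flagged as interrupted rather than duplicated, and the rejoined CDS is
checked for the mid-gene stop codon.

## Gene-level recombination

Two biallelic sites showing all four gametes imply at least one
recombination event between them under infinite sites. `rmin()` removes
gap columns, collects all incompatible site pairs as open intervals in
alignment coordinates, and selects a maximal set of pairwise disjoint
intervals by the classic right-endpoint greedy scan. For interval
scheduling this greedy is provably optimal, so the reported minimum is
exact for the given incompatibility set; the test suite nevertheless
asserts equality with an exhaustive minimum-breakpoint search on hundreds
of random instances. Breakpoint intervals are reported half-open,
0-based.

Per gene, the regression y = β₀ + β₁·π + β₂·n + ε relates rmin per
nucleotide to nucleotide diversity π with the number of aligned sequences
n as a covariate; the fitted line is displayed holding n at its mean.
Residuals are the recombination-intensity score after accounting for
diversity and sample size; genes with |standardized residual| > 2 are
flagged as deviating, with the caveat that an essentially perfect fit
(residuals at floating-point noise) flags nothing. A constant n makes the
design rank-deficient; x₂ is then dropped with a warning.

## What the generators emulate — and what they do not

`simulate_populations()` draws K founder sequences from a common random
ancestor at a set divergence, then builds each individual as a mosaic of
geometric-length segments copied from founders chosen by its population's
row of the migration matrix, plus per-site noise mutations. Defaults
(two to three populations of 6–8 genomes, 15–50 kb, divergence 0.02,
mutation 5e-4, mean segment 2 kb) mirror the scale of a small prophage
collection: a few dozen genomes, a few thousand core SNPs. The mosaic
model deliberately matches the copying HMM's assumptions — that is what
makes flux recovery a clean parameter-recovery exercise rather than a
model-robustness study. It does *not* emulate coalescent genealogies,
gene gain/loss along the genome, insertion sequences, inversions or
alignment error; passing tests demonstrate correctness of the inference
machinery, not robustness to real-data violations of the copying model.

`simulate_recombining_gene()` builds recombinants of two divergent
parents switching only at planted breakpoints, with private mutations at
globally unique, parent-monomorphic sites (true infinite sites — a
singleton can never complete a four-gamete pattern, so the planted
crossover count is a hard upper bound for rmin).
`simulate_gene_families()` controls the *pairwise* identity within a
family (per-copy mutation fraction 1 − sqrt(target)), its presence
fraction, and optionally emits one copy as an interrupted 5'/3' fragment
pair with an internal stop in the CDS.

All generators are byte-reproducible from their seed and return their
ground truth alongside the data.

## Numerical and scale choices

* Scaled (not log-space) forward–backward; posteriors renormalised per
  site; contract tested to 1e-9, enumeration-checked to 1e-10.
* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at I/O boundaries.
* Greedy merge ties and major-allele ties have deterministic
  lexicographic rules.
* Test problem sizes — 20-sample paintings of a few thousand SNPs,
  5 000 + 5 000 MCMC iterations, 200 oracle instances of ≤ 12 sites —
  were chosen so each stage's check runs in seconds to a couple of
  minutes on one CPU while leaving the planted signals far above their
  detection thresholds.

## Known limitations

* Expected chunk counts depend on panel composition (the donor-churn
  effect above); comparisons of count-based fractions across populations
  of very different sizes should be read with that in mind, or made with
  the lengths measure.
* The partition sampler implements the two basic move families only — no
  hyperparameter resampling, no super-individual moves — so very large
  collections may mix slowly.
* Component clustering cannot split a family bridged by one intermediate
  gene (chaining); the threshold sweep makes such cases visible as
  non-robust clusters across thresholds.
* The four-gamete bound is conservative by construction: recurrent or
  back mutation in real data can violate infinite sites and inflate
  incompatibilities, which the gap and biallelic filters only partly
  mitigate.
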