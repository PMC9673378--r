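---
title: "Methods: duplication profiling, co-duplication statistics and expression specialization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication profiling, co-duplication statistics and expression specialization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodup)
```

## The model

The unit of analysis is the **orthogroup**: the set of genes descended
from a single gene in the last common ancestor of the species panel.
Because the orthogroup inference step (upstream of this package) splits
families at duplications older than that ancestor, any orthogroup with
more than one gene in some species testifies to a duplication *within*
one of the two focal lineages. This reduces a complicated phylogenetic
question to counting:

* a lineage is **duplicated** in an orthogroup when at least one of its
  species has two or more members;
* in the WGD-bearing lineage (vertebrates), duplicated orthogroups
  containing at least one gene from a curated 2R ohnolog list are
  classified **ohnolog**, the rest **small-scale**;
* orthogroups whose vertebrate duplication is confined to the
  3R-bearing teleost (zebrafish) *and* supported by at least one 3R
  label are treated as **non-duplicated**, so that a teleost-specific
  WGD does not masquerade as a small-scale event shared by vertebrates.

Two classification subtleties are deliberate. The ohnolog reassignment
applies only to orthogroups already duplicated in the lineage: a 2R
label on a single-copy orthogroup means the ohnolog partner was lost (or
split into another orthogroup) and there is no duplication to classify.
And 2R evidence takes precedence over the 3R demotion — one labelled
pair suffices in either direction, because the curated lists are
evidence of retention, not quantitative annotations.

The joint class per orthogroup (`both_single`, lineage-specific
duplication, `parallel_dup`, or presence in only one lineage) partitions
the orthogroup set; `mean_copies` per lineage averages copy numbers over
species that retain the orthogroup at all, so that loss is not conflated
with low copy number.

## Co-duplication statistics

On the universe of shared orthogroups (≥1 gene in each lineage;
optionally anchored to one reference species on the A side, the default
comparison), the observed count of each (A category × B category) cell
is compared with `N · P(A) · P(B)` computed from the margins. The test
is hypergeometric: conditional on both margins, the cell count under
independence is exactly hypergeometric, and `phyper` gives the upper
tail for cells at or above expectation, the lower tail otherwise, with
the direction reported. Bonferroni multiplies by the number of cells in
the design (6 in the 2×3 default) — the divisor is the number of tests
actually run in the call.

The fold change is reported both as the plain ratio
`observed/expected` and as its binary logarithm. The headline number is
the plain ratio; a worked example with expected 4.3% and observed 7.3%
of the universe gives 7.3/4.3 ≈ 1.7 while log2(7.3/4.3) ≈ 0.76, and
emitting both keeps either convention reproducible.

Copy-number association between jointly duplicated orthogroups uses
Spearman's ρ on the two lineages' mean copy numbers and a 2×2
chi-squared test after dichotomizing each side at **2.5 mean copies** —
the threshold separating "kept one extra copy" families from expanded
families. The dichotomization point is a tunable argument.

## Gene-tree validation

Duplication calls are corroborated by testing whether each lineage's
genes form a clade. Gene trees from standard inference are unrooted, so
monophyly is defined on bipartitions: lineage L is monophyletic iff some
edge splits exactly the L tips from the rest. The implementation
enumerates the clades of the stored representation (`ape::prop.part`)
together with their complements, plus the pendant-edge case (L = all
tips but one, always a valid split). Lineages with ≤1 tip are trivially
monophyletic; trees with <3 mapped tips are flagged untestable and
excluded from the validation rate, with their count reported — how such
trees were scored upstream is not recoverable, so they are surfaced
rather than silently absorbed. Multifurcations are used as-is.

## GO parallelism

Annotations are propagated to ancestors along `is_a` and `part_of`
edges only (the standard propagation set; other relationship types do
not support the subsumption reading). Transfer between species goes
through orthogroups: every gene in an orthogroup inherits the union of
the source species' term sets, *including* the source genes themselves,
so the source side is never annotated more restrictively than the
target side; orthogroups lacking either species are excluded. The
≥50-genes-per-side filter is applied after transfer and propagation.
Per term, the percentage of annotated genes in duplicated orthogroups
is computed under three definitions on the WGD side (SSD only, ohnolog
only, either). No correlation test is attached to the paired series:
GO terms are nested, hence not independent, and a p-value would
overstate the evidence.

## Expression specialization

Expression enters as TPM. Condition-level values are arithmetic means
over replicate samples. Tissue specificity uses
τ = Σᵢ(1 − xᵢ/x_max)/(n−1): 0 for uniform expression, 1 for
single-condition expression, invariant to rescaling, undefined for
all-zero genes (flagged NA). τ is computed on untransformed means by
default with an optional `log2(x+1)` switch — the transform choice is
surfaced because it changes τ for broadly expressed genes.

Presence/absence per condition uses a fixed threshold, default
**TPM ≥ 1** on condition means. The underlying study called genes
expressed "above background" with a database-specific procedure that is
not reproducible from thresholds alone; a fixed conventional cutoff is
an explicit approximation, configurable, and the presence counts are
monotone in it (tested). The seven-condition map between amphioxus and
zebrafish tissues ships as data (`inst/extdata`), not code.

For each orthogroup in a 1:1, 1:many or many:1 configuration between
two species, the difference in expressed-condition counts is computed
with the A-minus-B sign convention, either per gene pair (`one_to_one`,
the red-line comparison) or with the duplicated side collapsed to the
**union of duplicates** — the number of conditions where at least one
duplicate is expressed. Under subfunctionalization duplicates partition
an ancestral expression domain, so per-gene deltas skew toward the
single-copy species while union deltas re-center at zero; this
skew-and-reversion signature is what the sign tests in the test suite
assert on generator output. Distribution summaries report the
Fisher–Pearson adjusted sample skewness. Boxplot statistics use
linear-interpolation quartiles (`quantile` type 7) with whiskers at the
last observations within 1.5 IQR; the quartile rule is documented
because hinge-based conventions give slightly different boxes.

## Synteny

Dotplots place each one-to-one ortholog at its gene midpoints. Tandem
duplication means strictly consecutive gene ranks on a chromosome
(rank = 0-based position by ascending start); a `max_intervening`
parameter (default 0) is exposed for sensitivity analysis. Orthogroup
aggregation calls a family tandem if any pair is tandem, else
intra-chromosomal if all members share a chromosome, else
inter-chromosomal; both pair-level and family-level tallies are emitted
because "percent of duplications" is ambiguous between the two units.
Chromosome homology assigns as partners all chromosomes receiving at
least `min_fraction` (default 0.2) of a chromosome's one-to-one
orthologs: one partner is a one-to-one correspondence, two or more is a
fusion/fission call. The 0.2 default separates a ~50/50 fusion split
from background scatter; chromosomes with fewer than `min_orthologs`
mapped genes are left uncalled. Formal synteny-block detection and
breakpoint statistics are out of scope.

## Gene-model evidence

Sequence-similarity evidence is **strong** when a hit covers >75% of
both query and subject with e-value < 1e-8, **weak** when any hit has
e-value < 1e-4. The published thresholds are printed as
"length/alignment length > 0.75", which read literally is ≥1 for
ungapped alignments and vacuous; they are implemented as alignment
coverage of query and subject. Expression evidence is strong when a
gene is expressed in more than 3 libraries, none at 0, weak otherwise —
expression in exactly 3 libraries is unassigned by the published rule
and resolved conservatively as weak. A gene is retained when at least
one strategy is strong. CDS/protein correspondence translates the CDS
(standard code, trailing stop trimmed), counts positional mismatches
plus the length difference over the longer length, and passes at ≤10%
(inclusive).

## The synthetic generator

The generator encodes the study conditions the pipeline assumes: a
3-amphioxus + 4-vertebrate panel; marginal duplication probabilities
0.20 (amphioxus) and 0.25 (vertebrates), matching the just-under-20% vs
over-20% duplicated-orthogroup regime; half of vertebrate duplicated
orthogroups 2R-labelled; a 5% teleost-only 3R fraction; 20%
lineage-specific orthogroups; a 25% tandem placement fraction (tandem
duplication is common but not dominant); 7 matched conditions with an
80%-dense ancestral presence profile; subfunctionalization probability
0.7 (the partition regime); lognormal TPM (meanlog 3, sdlog 1) with 2%
dropout so that presence calls at TPM ≥ 1 are nearly noise-free; 10%
scrambled gene trees.

Joint duplication is drawn directly from the four-cell distribution
with `P(dup A ∧ dup B) = f · pA · pB` capped at the smaller marginal
(`f = 1` is independence; the feasibility bound
`f ≤ min(pA,pB)/(pA·pB)` is enforced with an informative error). This
realizes the enrichment-factor definition exactly, without the shared
latent-cause construction that would achieve the same law indirectly.

Each component (orthogroups, placement, expression, trees, GO) draws
from its own stream derived from the master seed, so regenerating one
component cannot shift the others; the same seed reproduces the bundle
byte-for-byte. Scrambled trees are made by exchanging one tip label
across lineages rather than re-randomizing the topology: full
randomization of a small family is monophyletic by chance (probability
1/3 for a 2+2 family), which would bias scramble-rate recovery, while
the label swap guarantees broken monophyly whenever both lineages have
≥2 tips — and trees are only emitted for such families, since anything
smaller is trivially monophyletic.

What the generator does **not** emulate: sequence evolution (orthology
is assigned, not inferred from similarity, so homology detection
failure exists only as the lineage-specific class), correlated gene
order between species (dotplot tests construct synteny explicitly),
expression correlation between tissues, assembly or annotation error.
Passing tests therefore show that the statistics recover the parameters
of data that satisfy the model's assumptions — not that real data do.

## Problem sizes and numerical choices

Parameter-recovery checks run at the sizes where the binomial
confidence intervals are informative: 5000 orthogroups for
enrichment-factor recovery (f ∈ {1, 2, 4}), 1200 for scramble-rate
recovery, 2500 with elevated duplication rates for tandem-fraction
recovery (two-copy families identify the parameter exactly; larger
families dilute the pair-level frequency by construction), 200 random
≤8-tip trees against the edge-removal oracle. Hypergeometric p-values
are validated by exhaustive enumeration over every universe of size
≤12. Ties in gene ranking break by end coordinate then gene id;
division by zero duplicated orthogroups yields NA rather than an error
in summaries; the Bonferroni product is capped at 1.

## Known limitations

Orthogroup inference quality bounds everything downstream: the
classifier trusts the table it is given. The ohnolog rule inherits the
curation of the 2R/3R lists. The presence threshold is a stand-in for a
background model. The fusion/fission caller detects partner
multiplicity, not rearrangement breakpoints. And the GO transfer
assumes functional equivalence within orthogroups, which overstates
annotation confidence for fast-evolving duplicates.
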