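---
title: "Paralog buffering and variable gene essentiality: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog buffering and variable gene essentiality: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralethal)
```

## The scientific question

Pooled CRISPR-Cas9 fitness screens across panels of cell lines measure, for
every gene and every line, how much knocking the gene out impairs growth.
A long-standing observation from model organisms is that duplicate genes
(paralogs) are less often essential than singletons, presumably because a
surviving paralog can buffer the loss. Screens across many genetically
heterogeneous lines let us ask a sharper question: when a gene is essential
in only *some* lines, is that variability explained by the expression state
of a paralog? If gene A1 is dispensable wherever its paralog A2 is well
expressed, but essential wherever A2 is lost or silenced, the pair behaves
as synthetic lethal.

`paralethal` implements that analysis end to end: guide-level quality
control, score binarization, essentiality categories, paralogy and
duplication-mode annotation, the expression-stratified synthetic-lethality
test with copy-number and nonsense-mutation follow-ups, and the enrichment
battery relating synthetic lethality to whole-genome duplication (WGD) and
protein complex membership. A first-class synthetic-data generator emits a
complete cohort (toy genome, guide library, screen log-fold changes,
expression, copy number, mutations, paralog/WGD/complex annotations) with
planted ground truth, so every stage is testable without any external
download.

## Guide processing

sgRNAs that match several genomic loci confound single-gene fitness
attribution, and they disproportionately target paralogs — exactly the
genes under study — so they are removed before scoring. Alignment is an
exhaustive scan: every offset of every chromosome, both strands, up to two
mismatches over the 20-nt protospacer, keeping only hits with a canonical
NGG PAM immediately 3' of the protospacer on the hit strand ("N" matches
any base). Exhaustiveness is the point: on toy genomes it is tractable, and
the implementation *is* its own specification, checked in the tests against
an independently written sliding-window oracle.

Mismatch positions are indexed 1..20 from the PAM-distal (5') end, so "the
two most PAM-distal nucleotides" are positions 1 and 2. A guide is
multi-targeting iff it has (a) two or more perfect hits, (b) a perfect hit
plus any single-mismatch hit, or (c) a perfect hit plus a double-mismatch
hit with both mismatches at positions 1–2. Guides with no perfect hit at
all are dropped with their own reason: the screens were designed against
the reference sequence, so a guide that no longer matches it perfectly
cannot be attributed with confidence. Retained guides must overlap exactly
one annotated gene; loci covered by two genes (read-through-like
configurations) are dropped.

Genes keep a score only if at least three retained guides target them — one
or two guides are considered insufficient for a reliable score. The gene
score in a line is the arithmetic mean of its retained guides' log-fold
changes. This is a deliberately simple aggregation scorer; it does not
correct copy-number artefacts. Cohorts scored by a dedicated
copy-number-aware pipeline can be supplied directly to
`run_pipeline_tables()`, which skips guide processing. Screen quality is
summarized as the mean area under the precision-recall curve (average
precision) for recovering a reference essential set against a reference
nonessential set, ranking genes by ascending score.

## Binarizing fitness scores

The pooled distribution of gene scores across all lines is modelled as a
1-D Gaussian mixture with 1–5 components, fit by EM; the component count is
chosen by AIC with 3k − 1 free parameters (k means, k variances, k − 1
weights). Three components are the expected structure: severe fitness
defect, moderate defect, no defect. The binarization threshold is the
boundary point between the two lowest-mean components — the point where
their *weighted* densities are equal, equivalently where the posterior
responsibility switches. The boundary is located by bisection on a sign
change to an interval below 1e-8. When several crossings exist the one
nearest the moderate component's mean is used. A score at or below the
threshold is an essential call; the inclusive boundary matters and is
tested. Whether such a boundary should be an equal-density or
equal-posterior point is a convention; under weighted densities the two
coincide, and the choice is recorded in the threshold's metadata.

Two numerical choices deserve note. First, EM restarts: each component
count is fit from `n_restarts` (default 10) initializations, seeded
`seed + 0..9`. Random initial means are drawn as data quantiles, which
makes the fit invariant to the order of the input scores. Second, random
restarts alone reliably miss a low-weight component sitting as a *shoulder*
between two dominant components (it is not a density mode, so no
mode-seeking init finds it either). The first initialization is therefore
incremental: the best (k−1)-component fit plus one narrow component placed
at the peak of the positive residual between a kernel density estimate and
the (k−1)-model density. On mixtures with a 5% shoulder component this
recovers the global optimum where every random restart converges to a
local one, and it is what makes AIC select the true component count.

Unequal-variance 1-D mixtures also have an unbounded likelihood: a
component can collapse onto a handful of near-identical points, and such a
spike gains just enough log-likelihood on large samples to fool AIC into
an extra component. Converged solutions containing a component narrower
than 10% of the pooled standard deviation or lighter than 2% weight are
therefore rejected as degenerate, as are EM paths with vanishing weight or
variance. Both guards are far below any component the score model
produces, and they are exposed as arguments.

Because the threshold could influence everything downstream, the pipeline
accepts a threshold override (`tau_override`), and sensitivity reruns at
fixed thresholds of −0.4 and −0.6 around a data-derived boundary are part
of the test suite: essential-call counts and never-essential counts must
move monotonically with the threshold.

## Essentiality categories

Per gene, the fraction of scored lines with an essential call determines
the category: **never** (zero essential lines), **broadly** (essential in
at least 90% of scored lines), **sometimes** (everything in between).
Genes with any essential line are also binned into deciles of
percent-essential. These categories, not the raw fractions, drive the
comparative analyses because percent essentiality is strongly bimodal and
poorly summarized by means.

## Paralogy, duplication mode, complexes

The paralog-pair table is directional: each unordered pair appears once per
direction with the two asymmetric protein-sequence identities (percent of
the focal gene's sequence matched in the partner — asymmetric because the
proteins differ in length). Pairs are kept when both identities are at
least 20% (inclusive) and both genes are protein-coding. A gene's *closest*
paralog is the partner in which the largest share of the gene's own
sequence is matched, with ties broken alphabetically; the direction used
for "closest" is a genuine ambiguity, so the convention is fixed here and
recorded, and the other convention is a one-line change. Genes absent from
the filtered table are singletons.

A pair is a whole-genome duplicate if it appears on either of two curated
WGD pair lists (their union); all other pairs are small-scale duplicates.
A gene is WGD if it participates in at least one WGD pair, regardless of
additional SSD pairs. Complex annotation flags whether either gene of a
pair is a member of any protein complex and whether one complex contains
both. Complex enrichment of a gene set (e.g. the broadly essential genes)
uses a one-sided hypergeometric test per complex against a user-supplied
background universe, with Benjamini–Hochberg correction across complexes.

## The synthetic-lethality test

For every *sometimes* essential gene A1 that is essential in at least 1%
(inclusive) of its scored lines and has at least one paralog with
expression data, the test asks whether A2's expression is lower in the
lines where A1 is essential. Two modes define the tested family: `closest`
(each A1 contributes its most similar expressed paralog) and `all` (every
expressed paralog). The test itself is a pooled-variance two-sample t-test
of A2 expression between the A1-essential and A1-non-essential strata
(lines are intersected pairwise with expression availability; strata with
fewer than two lines skip the pair). Benjamini–Hochberg FDR is applied per
mode — the two modes are separately reported families, never pooled — and
a pair is a putative synthetic lethal iff q < 10% *and* the essential
stratum has the lower mean. The direction filter is applied post hoc to a
two-sided p rather than folded into a one-sided test; this mirrors the
common reading of "significantly lower at FDR 10%", and a one-sided option
remains available through the underlying test.

Follow-ups run on the flagged pairs only, each with BH across its own
evaluable set: a t-test of A2 *copy number* between the same strata
(flagged when p < 0.05, q < 0.10, copy number lower in the essential
stratum), and a one-sided Fisher enrichment test of A2 *nonsense
mutations* in the essential stratum, restricted to pairs whose A2 is
nonsense-mutated in at least one line. The report emits the CN count, the
nonsense count, and their union, since "fraction of SL pairs with a
genetic driver" can reasonably mean either.

The enrichment battery computes Fisher sample odds ratios (cross-product
ad/bc, exact p) of the SL flag against duplication mode and complex
membership, overall and within subsets (WGD-only, complex-member-only),
plus t-tests of pair identity between SL and non-SL pairs overall and
within WGD / SSD / complex subsets.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions at desk scale: 60 cell
lines and 600 genes (vs hundreds of lines and ~16,500 genes at full
scale), 61% paralogs, 64% WGD pairs, categories 48% never / 46% sometimes
/ 6% broadly, ~4 guides per gene, and three score components at
(−1.0, 0.2), (−0.5, 0.15), (0.0, 0.15) for the essential / moderate /
tolerated phenotypes. Family sizes 2–5 are drawn with weights
(0.45, 0.25, 0.17, 0.13), putting roughly 30% of paralog genes in
two-gene families, in line with the observation that about a third of
paralogs have exactly one partner. Identities are uniform on [20, 100]
except planted SL pairs, drawn from [60, 100] so that the
identity-vs-synthetic-lethality direction is a recoverable property.

Scores are generated per gene and line from the category-matched
components: never-essential genes draw every line from the tolerated
component; broadly essential genes from the essential component;
sometimes-essential genes draw the essential component at a per-gene
frequency uniform on [0.05, 0.80] and otherwise the moderate component
with probability 0.25, else the tolerated one. Planted SL genes (A1) draw
the essential component exactly in the lines where their partner A2 is in
its low-expression state (30% of lines by default) and the tolerated
component elsewhere. The moderate share and the per-gene frequency range
were fixed once, by a design constraint rather than tuning: with the three
component defaults above and the equal-weighted-density threshold rule,
the pooled mixture must place the boundary in a region that (i) calls
essential-component draws essential with high probability (so broadly
genes clear the 90% cutoff), (ii) rarely touches tolerated draws (so never
genes stay never), and (iii) leaves sometimes genes a detectable essential
fraction. A design in which every sometimes gene draws *all* its lines
from the moderate component fails (i)–(iii) jointly: it drags the
boundary to about −0.85, under which most sometimes genes binarize as
never essential. The per-line composition used here keeps the implied
boundary near −0.64 and category recovery above 95%. `implied_mixture()`
and `implied_threshold()` expose the model-implied pooled weights and
analytic boundary, and the generator's component draws are checked against
them (with a standard error that includes the between-gene spread of the
per-gene frequencies).

Planted structure beyond expression: a configured fraction (36%) of
planted pairs also reduce A2 copy number in the low-expression lines; one
planted pair concentrates A2 nonsense mutations in those lines; planted SL
pairs are placed among WGD vs SSD pairs so the planted odds ratio is 2.3;
WGD pairs are planted into shared complexes at odds 2.3 over SSD pairs;
and one complex is filled with broadly essential genes so complex
enrichment has a planted positive control. The toy genome plants gene
duplications (copy of one gene's sequence over another's interval, with a
configurable per-base mutation rate) as the source of genuine
multi-targeting guides; at mutation rate 0 every guide of a duplicated
gene is multi-targeting by construction, which anchors the classifier's
sensitivity test.

What the generator does *not* emulate: sequencing reads, guide-efficacy
variation, copy-number artefacts in guide LFCs (the generator adds i.i.d.
Gaussian guide noise, sd 0.1, precisely because copy-number correction is
out of scope for the scorer), chromosome-arm CN segments, tissue lineages,
and any association between essentiality category and paralogy features.
That last point matters for interpretation: passing tests show the
*machinery* recovers planted structure under known conditions; they do not
show that real screens have these effect sizes, and analyses such as the
category-vs-paralogy odds ratios are expected to be null on synthetic
cohorts.

Desk-scale choices throughout the test-suite and acceptance runs: cohorts
of 150–900 genes and 30–60 lines, 20,000-point mixtures for threshold
recovery, 50 null cohorts for FDR control, and 5 cohorts of ~650 pairs for
odds-ratio recovery (the median over cohorts is reported because a single
cohort's log-OR standard error is ~0.3).

## Degenerate inputs and tie-breaks

Zero-variance strata in the t-test return t = 0, p = 1 when means are
equal and a flagged p = 0 otherwise. The Mann–Whitney test is exact (by
enumeration) only for small untied samples and otherwise uses a
tie-corrected normal approximation; fully tied inputs return p = 1. Genes
scored in zero lines are excluded from summaries with a warning; guides
with missing LFCs are omitted per line, and a gene's score in a line is
missing when fewer than three informative guides remain. Ranking
tie-breaks (precision-recall, closest-paralog selection) are resolved by
gene symbol so results are reproducible. All randomness flows from a
single integer seed; generators restore the caller's RNG state.

## Known limitations

The aggregation scorer is not a copy-number-corrected estimator, so real
cohorts should come in through pre-computed gene scores when such
correction matters. The exhaustive aligner targets toy genomes; it is
quadratic in genome size times library size and is not meant for
mammalian-scale references. AIC on very large pooled samples can prefer an
extra mixture component when per-gene score variances are genuinely
heterogeneous; the incremental initialization mitigates the local-optimum
half of this problem but not the model-misfit half. The multinomial-logit
comparison treats categories nominally, not ordinally.
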