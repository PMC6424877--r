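---
title: "Profiling water-kefir metagenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling water-kefir metagenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kefirmg)
```

Water kefir is a sucrose–fig fermentation carried by a small community of
lactic acid bacteria, bifidobacteria and yeasts attached to polysaccharide
grains. Shotgun metagenomics of such a community yields millions of short
reads whose taxonomic and functional interpretation requires a chain of
decisions — how to turn alignments into per-read taxa, how to merge
disagreeing classifiers, how to decide whether a *species* (not just its
genus) is really present, and how to summarise what a reconstructed genome
can biosynthesise. `kefirmg` implements that chain as small, testable
functions, together with a synthetic-community simulator that plants ground
truth for every stage.

This vignette explains the models and the choices behind them. It states no
empirical result that the package's test suite and `scripts/acceptance.R`
do not themselves compute.

## Naive LCA read classification

A read's tabular alignment hits (bitscore $S$, E-value $E$) are filtered in
two passes: hits with $S < \mathrm{MinScore}$ or $E > \mathrm{MaxExpected}$
are dropped, then only hits with

$$S \ge \left(1 - \frac{\mathrm{TopPercent}}{100}\right) \cdot S_{\max}$$

survive, where $S_{\max}$ is the best bitscore *after* the floors. Ties at
the cutoff are retained (a `>=` comparison). The read is assigned the lowest
common ancestor (LCA) of the surviving hits' taxa — the deepest node
ancestral to all of them — or left unassigned when nothing survives. Two
presets bundle the usual parameterisations: `megan-main`
(MinScore 100, MaxExpected 0.01, TopPercent 10, MinSupport 150) for
whole-metagenome read sets and `megan-marker` (80, 0.01, 100, 10) for
marker-gene subsets. Only `lca_percent = 100` (plain naive LCA) is
implemented; weighted variants are rejected explicitly rather than silently
approximated.

Whether TopPercent should be computed before or after the MinScore floor is
ambiguous in common usage; `kefirmg` freezes *floors first*, which makes
`filter_hits()` idempotent and monotone in both thresholds (both properties
are tested).

### Minimum support

The min-support rule removes weakly supported taxa from the profile. Its
destination is genuinely underdetermined in the field (different MEGAN
versions moved unsupported reads to the parent or to "not assigned"), so the
semantics here are explicit: a taxon whose *direct* read count is below
`min_support` passes its reads to the nearest ancestor-or-self whose
*cumulative clade count* (computed on the input assignment) reaches
`min_support`; the root is never a push-up target, and reads with no
qualifying ancestor become unassigned. With this rule every retained
non-root clade holds at least `min_support` reads and the total read count
is conserved — the invariants the test suite scans on random tables. The
alternative (`unsupported_to = "unassigned"`) is available for users who
prefer discarding to up-ranking; push-up is the default because it preserves
the higher-rank signal that community profiles report as "above genus".

## Consensus across classifiers

Different classifiers disagree systematically: database gaps can hide an
entire genus from one tool while another sees it clearly. The consensus is
deliberately simple — a fixed priority order; the first tool that assigns a
read wins. The strict first-wins rule is kept even when a lower-priority
tool offers a more specific rank, because any "most specific wins"
refinement would change results in ways the simple rule's users could not
predict. Reads missing from a tool's output file are counted as unassigned
for that tool (classifiers routinely omit unclassified reads); a strict mode
turns this into an error.

The genus table then applies the roll-up: assignments at subspecies,
species or species-group rank (and at unranked nodes that have a genus
ancestor) roll up to their genus; genus-rank calls stay; anything above
genus becomes "above genus"; root-level calls are uninformative and count as
unassigned. Genus categories holding strictly less than 0.5% of all reads
merge into "minorities" — the threshold applies to genus categories only,
never to the special categories. All percentages use the *total* read count
of the data set as denominator, so the table always partitions the reads
and sums to 100. Temporal shifts are plain per-category differences in
percentage points between two such tables.

## Fragment recruitment and presence calling

Recruitment asks a sharper question than classification: does this
*particular* reference genome attract reads along its whole length, and at
what identity? The engine retains, per read, hits with identity ≥ 60%,
picks the single best survivor by bitscore (ties: lower E-value, then
lexicographic subject id), and then drops the read if that chosen hit
covers less than 60% of the read. The order — identity filter, then top-hit
choice, then coverage check *on that one hit* — is frozen because
reordering changes results; it is recorded in the output metadata. The
recruited position is the subject-alignment midpoint (symmetric under
strand; reverse hits are normalised by swapping coordinates), in
concatenated coordinates when several genomes share an axis.

The classic recruitment plot is a 2-D histogram of (position, identity),
normalised by the largest bin; defaults of 5 kbp × 1% identity are purely
presentational and configurable. Presence calling replaces the visual
judgment of such plots with three explicit, reported metrics over position
windows (one window per 5 kbp by default):

* **present** — windows holding a read with identity ≥ 95% cover ≥ 0.6 of
  the genome (near-identical reads throughout the length);
* **novel relative** — not present, but windows holding reads in the
  70–90% identity band cover ≥ 0.6 of the genome *and* the median
  recruited identity falls inside that band — the uniform lower-identity
  blanket that signals a related species absent from the database;
* **absent** — anything else, including the deceptive case of
  perfect-identity reads confined to a few conserved regions.

The 95% floor, 0.6 breadth and [70, 90] band are package definitions, not
community standards; every call reports its thresholds alongside the
metrics so downstream readers can re-derive the verdict.

## Assembly statistics and MAG curation

`compute_stats()` uses the dominant N50 convention: sort lengths
descending; N50 is the length at which the cumulative sum first reaches
*at least* half the total, L50 its 1-based index. The median of an even
count averages the two central lengths; means and medians are stored in bp
at full precision, with `format_assembly_stats()` as a one-decimal
kbp/Mbp formatting layer — rounded values are never stored. The contig
length filter is *strictly* greater than 1000 bp, reading "longer than"
literally.

Bin curation implements two rules taken as given (their evidence —
mapping hits and similarity searches — is produced upstream and supplied
as table columns): a member contig mapped to a species outside the target
genus is discarded unless it carries the target-genus-similarity flag; and
contigs anywhere in the assembly whose rRNA annotation matches the target
genus are appended, once, to the curated bin. rRNA genes assemble apart
from their genomes often enough that this rescue step is what restores a
MAG's ribosomal operons. Purification never adds contigs, rescue never
removes them, and rescue is idempotent — all three properties are tested.

## Pathway scoring

Biosynthetic potential is summarised per (organism, pathway) from per-gene
evidence statuses into four calls — very likely, likely, unlikely, very
unlikely (the green/yellow/gray/black of the usual matrix figures). The
caption-level conditions can co-occur, so a precedence was fixed by
evidential strength: any loss-of-function mutation ⇒ very unlikely (a
broken gene is conclusive regardless of the rest); else any missing gene ⇒
unlikely; else any partially assembled gene ⇒ likely; else very likely.
A gene defined for a pathway but absent from the status table defaults to
"not found" with a warning — absence of evidence, scored as such. The
scoring is permutation-invariant and monotone under single-gene
degradation; both properties and the exhaustive 256-combination
enumeration are tested.

## The synthetic community

The simulator emulates the features of a real fermented-beverage
metagenome that the downstream decisions depend on, and nothing more:

* **Composition** — five members (two lactobacilli-scale abundances at
  0.25, a yeast at 0.20, a second yeast at 0.18, and a planted novel
  relative at 0.12) with multinomial read counts.
* **Read lengths** — normal(205, 30) truncated to [20, 260] bp, matching
  the median (~205 bp) and range of quality-trimmed short-read data sets;
  only those two facts are modelled.
* **Identity** — each member has a per-read identity model; near-100%
  (e.g. N(99, 0.5)) for species whose genome is the reference, N(77, 3)
  for the novel relative so its reads blanket a related reference in the
  70–85% band.
* **Alignments** — each read gets a top hit to its source genome at its
  planted identity, plus 0–3 same-genus decoy hits 5–20 identity points
  lower, a drop chosen so TopPercent = 10 filtering keeps some decoys and
  rejects others. Bitscore (`align_len · (2·id/100 − 1)`) and E-value
  (`10^(−bitscore/10)`) are monotone surrogates: ordering and thresholds
  behave correctly, absolute calibration is meaningless and must not be
  relied on.
* **Classifier quirks** — per-tool assignment probabilities, a genus-level
  blind spot (a tool whose database lacks *Dekkera*), low-identity reads
  assigned at genus rather than species, and a small misassignment rate.
* **Curation fixtures** — bins with planted contaminants (flagged and
  unflagged) and off-bin rRNA contigs; gene-status tables with expected
  calls computed by an independent worst-status lookup.

Genome lengths default to 200–300 kbp rather than the 1.5–12 Mbp of real
genomes: breadth metrics depend only on the number of position windows per
genome, and the smaller size keeps a 50,000-read simulation under a
second. What the simulator does *not* model: sequence content (FASTA
output is placeholder bases), sequencing error profiles beyond the scalar
identity, quality scores, chimeras, strain mixtures, GC or coverage biases
— so green tests demonstrate the correctness of the decision logic on
idealised inputs, not robustness to every artefact of real data.

Every generator is a pure function of its parameters and a seed (RNG use
is scoped, never leaking into the caller's session), which is what makes
byte-identical pipeline re-runs testable.

## Problem sizes and numerical notes

The test suite and acceptance script use: 1000 random taxonomies (≤ 200
nodes) for the LCA oracle, 200 random tables for the min-support
invariant, 10,000 reads for consensus conservation, 50,000 reads for
recruitment recovery, 30 seeded presence scenarios, 500 random contig sets
for the statistics oracle, the full 256-combination pathway enumeration
and 50 bin fixtures — sizes at which binomial noise is far smaller than
the tolerances being checked while the whole suite stays fast. Identity
values are truncated to (50, 100]; percentages are computed at full
precision and rounded only in report files (two decimals); E-value/bitscore
comparisons use exact arithmetic on the synthetic surrogates.

## Known limitations

* The LCA engine consumes tabular alignments; it does not parse RMA files
  or run any aligner or classifier.
* Weighted LCA (`lca_percent` < 100) is not implemented.
* Presence thresholds are package definitions; on real data they should be
  tuned against positive and negative control genomes.
* `score_matrix()` loops over (taxon, pathway) cells in R; it is meant for
  tens of organisms × dozens of pathways, not genome-scale models.
* The consensus keeps the strict first-wins rule even when a
  lower-priority tool is more specific; users wanting rank-aware merging
  must post-process.
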