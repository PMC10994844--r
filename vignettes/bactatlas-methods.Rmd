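---
title: "bactatlas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bactatlas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactatlas)
```

# Scope

`bactatlas` re-implements, as a self-contained and fully tested toolkit,
the computational spine of a bacterial transcriptome-atlas analysis:
dRNA-seq-based annotation of transcript features (transcription start
sites, intrinsic terminators, operons and sub-operons, small regulatory
RNAs), genome-wide discovery of invertible repeats (invertons),
conditional-expression analysis (CPM filtering, differential testing,
preranked gene-set enrichment, co-expression) and the integration of the
sRNA annotation with pooled transposon-mutant fitness data. A synthetic
data generator plants every feature class with known truth, so the entire
pipeline can be exercised and validated without sequencing data.

This vignette records the models, the tunable parameters and their
defaults, and the design decisions taken where the underlying methods
leave genuine freedom. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

# dRNA-seq model and TSS calling

In dRNA-seq, a Terminator-Exonuclease-treated library (TEX+) degrades
processed RNAs carrying 5'-monophosphates, so genuine transcription start
sites appear as 5'-end read-start pileups *enriched* in TEX+ relative to
the untreated library (TEX−), while processing sites show the opposite
pattern. `detect_tss()` calls a position a TSS candidate when

* the TEX+ 5'-start count reaches `min_height` (default 10 reads), and
* the enrichment `TEX+ / max(TEX−, pseudocount)` reaches `min_enrichment`
  (default 2.0; pseudocount 1).

Candidates within `cluster_window` (3 bp) on a strand are merged, keeping
the highest TEX+ height and breaking ties toward the most upstream
position in transcription orientation. These thresholds are conventional
dRNA-seq practice; the original tool chain delegates them to its TSS
caller without printing them, so here they are explicit, documented
arguments rather than hidden defaults.

`classify_tss()` assigns positional classes against the gene annotation:
per gene, the highest-enrichment same-strand candidate within the 300-bp
window upstream of the gene start is *primary* and all other candidates in
that window are *secondary*; sense candidates inside a gene body are
*internal*; antisense candidates overlapping a gene extended by 100-bp
flanks are *antisense*; candidates with no class are *orphan*. Two
conventions had to be fixed:

* **Window bounds.** The "300-bp region upstream" is taken as the 300
  positions immediately upstream of the annotated start coordinate
  (`[start-300, start-1]` on the plus strand), so a candidate exactly
  300 bp upstream is inside the window and one at 301 bp is not.
* **Ties.** Equal enrichment within a window resolves to the candidate
  closest to the gene start, making the output deterministic.
* **Multi-class records.** One physical TSS may hold classes with respect
  to several genes; it is emitted once, with a class list, so downstream
  joins have a stable record identity. A TSS that ends up primary for two
  divergently transcribed genes is allowed and flagged
  (`divergent_primary`) rather than silently resolved.

# Terminators and operons

Two independent heuristics predict rho-independent terminators and are
reported side by side, never merged (`method` column):

* `find_hairpin_terminators()` scans for a stem of 5–12 pairs (allowing
  one non-complementary position; G·U wobble counts as a match, since
  termination happens on the RNA), a loop of 3–8 nt, and a run of at
  least 4 U within 8 nt of the stem. The score is
  `(matched pairs − mismatches) + U-tail length`, and overlapping hits
  are reduced to the best-scoring one.
* `find_coverage_drop_terminators()` scans the intergenic spans between
  same-strand adjacent genes (and the boundary spans flanking the first
  and last gene of each strand) for the drop
  `1 − mean(cov downstream 50 bp) / mean(cov upstream 50 bp)`, reporting
  positions with drop ≥ 0.5 and upstream support ≥ 10 reads. The
  *position* reported is the one maximizing the absolute coverage loss
  (`up − down`), while the drop ratio remains the score and threshold:
  a purely relative criterion would systematically relocate calls onto
  the low-coverage read-through tail downstream of the true terminator,
  where a 10-to-0 transition looks like a 100% drop.

`assemble_operons()` joins consecutive same-strand genes when the
intergenic gap is ≤ 300 bp (mirroring the TSS window), the minimum
intergenic untreated coverage is ≥ 5 reads, and no terminator lies
between them. The lead TSS is the first member's primary TSS; each
primary or secondary TSS at a non-first member opens one sub-operon
from that member to the operon end (at most one per member, primary
preferred). In the bundled pipeline only coverage-corroborated
(coverage-drop) terminators gate the joining; hairpin-only predictions
are emitted as annotation but, being sequence-only evidence, are not
allowed to split a transcriptionally continuous unit.

# Small RNA discovery

Transcript intervals come from maximal runs of untreated coverage
(`call_transcripts()`: ≥ 5 reads, runs ≤ 10 bp apart merged, < 30 nt
dropped). Because sRNAs embedded in longer transcription units (UTR-derived,
intra-operonic) are invisible to plain run-calling,
`derive_srna_candidates()` additionally walks downstream from every 5'
anchor — a detected TSS or processing site — while coverage stays above
half the anchor level, producing candidates nested inside larger units.

Processing sites are not defined operationally by the original tool
chain; here they are positions where untreated coverage steps up at least
3-fold over the mean of the 5 upstream positions, with ≥ 10 reads, that
are *not* TEX-enriched (and not within 3 bp of a TEX-enriched start) —
i.e. 5' ends that exist but fail the TSS test.

`classify_srnas()` assigns exactly one class per candidate in the fixed
precedence *intergenic → antisense → 5' UTR-derived → 3' UTR-derived →
intra-operonic* (first satisfied wins; the rest are rejected as
unclassifiable):

* **intergenic** — a TSS at the 5' end that is not an mRNA TSS, and no
  overlap with any genetic feature on either strand. "Genetic feature"
  includes gene bodies and operon spans widened into transcript extents
  (150 bp upstream, 300 bp downstream), otherwise a 3' UTR fragment
  outside any gene body would masquerade as intergenic.
* **antisense** — TSS-supported, overlapping a gene on the opposite
  strand only.
* **5' UTR-derived** — shares a primary/secondary mRNA TSS and ends
  before that gene's coding start.
* **3' UTR-derived** — 5' end (TSS or processing site) within 300 bp
  downstream of a gene on the same strand, 3' end at a terminator or
  processing site shared with the mRNA.
* **intra-operonic** — inside an operon span with a TSS or processing
  site at the 5' end; the candidate's own 3' boundary (it was called
  where coverage fell) is taken as the required coverage-drop evidence.

The intergenic-first precedence keeps the class that feeds the fitness
reanalysis maximally conservative. `curate_srnas()` then applies the
five exclusion rules used for manual curation: (1) no promoter or
processing site up to 50 bp upstream of the 5' end; (2) complete
same-strand overlap with an annotated mRNA; (3) complete overlap with an
annotated terminator; (4) overlap with supplied cis-regulatory elements
(riboswitches/thermometers), applied only when such an interval file is
given; (5) no evident coverage change versus the 50-bp flanks, exposed
as a fold-change parameter with default 2 because the source describes
the criterion without a threshold. Accepted records must additionally be
30–500 nt long with a normalized folding energy below −0.05.

## Folding-stability proxy

The stability filter uses a weighted Nussinov-style dynamic program over
nested structures (GC = −3, AU = −2, GU = −1 per pair, hairpin loops
≥ 3 nt) instead of a full nearest-neighbour thermodynamic model. The
threshold −0.05 per nucleotide therefore applies to this proxy scale and
is configurable (`energy_threshold`). The proxy is deterministic, never
positive, zero for unpairable sequences, and is validated in the test
suite against an exhaustive enumeration of all nested structures on
short sequences. "Normalized" is taken as energy divided by sequence
length; that reading is an assumption and is stated here rather than
hidden. Two caveats follow from the simplification: absolute values are
not comparable to thermodynamic free energies, and because G·U pairs are
allowed the proxy is not exactly invariant under reverse complementation
(a G·U pair maps to an unpairable A·C); the test suite asserts the
symmetry on Watson–Crick-only alphabets where it holds exactly.

# Inverton discovery

`find_inverted_repeats()` reports all maximal inverted arm pairs with
arm length 12–25 bp (configurable), spacer 30–1000 bp, and a mismatch
count within the length-dependent budget: 0 mismatches for arms up to
11 bp, 1 for 12–19 bp, 2 above 19 bp. The budget rule is stated for
arms ≤ 11, ≤ 13 and > 19; for the unstated 14–19 range the package uses
budget 1, the monotone interpolation between the stated anchors. A hit
whose arms are both contained in another hit's arms with at most as many
mismatches is suppressed as non-maximal; a contained hit with *fewer*
mismatches than its container survives, since it makes a strictly
stronger claim. The scanner is an anchor-walk over (inner arm end,
spacer) pairs implemented in C++; `ir_brute_force()` is a deliberately
naive enumeration of every (start, arm, spacer) triple kept in the
package as an independent reference, and the acceptance suite asserts
exact agreement between the two on random sequences.

Composition filters remove homopolymeric repeats and repeats with GC
fraction outside [0.15, 0.85]. `flag_promoter_invertons()` marks repeats
whose arms or spacer intersect the 50-bp window immediately upstream of
any mapped TSS; the window is strand-aware by default with a switch to
ignore strand, since the source does not state which was used.

At the default arm minimum the mismatch budgets make random hits common
(tens of hits per 50 kb of i.i.d. sequence); at `arm_min = 15` the
empirical false-positive rate on random 5-kb sequence is on the order of
0.1 hits per sequence. Containment suppression keeps the output free of
combinatorial duplicates but deliberately does not merge near-identical
hits at different spacers.

# Expression analysis

`cpm()` is plain counts-per-million with library sizes defaulting to
column sums; no between-sample normalization (such as trimmed-mean
scaling) is applied by default, but library sizes can be supplied to act
as normalization factors. `filter_expressed()` retains a gene when there
is at least one condition in which *every* replicate exceeds 0.6635 CPM —
about ten reads at a ~15-million-read median library — with an
`all_samples` variant.

## The differential-expression stand-in

The reference analysis fits per-gene negative-binomial generalized
linear models with tagwise dispersion; re-implementing that machinery is
out of scope here. `nb_de_test()` is a deliberately simple, clearly
labelled stand-in: a per-gene likelihood-ratio test between a two-mean
and a common-mean NB model with a *single common dispersion*, estimated
by the pooled method of moments `sum(var − mean) / sum(mean²)` across
genes (the ratio-of-sums form is far less noisy than averaging per-gene
ratios at 2–3 replicates). P-values use the χ²(1) approximation, fold
changes come from mean CPM with a 0.5 pseudocount, and FDR is
Benjamini–Hochberg. The acceptance suite verifies the two properties
that matter for the downstream thresholds: null type-I error within
[0.03, 0.07] at nominal 0.05, and power above 90% for planted 16-fold
changes at dispersion 0.05 with 3 vs 3 replicates. Externally computed
DE tables (e.g. from a GLM fit) can be read with `read_de_tsv()` and fed
to `significant_de()` (|log2FC| > 2 and FDR < 0.05), `rank_metric()`
(−log10 p × sign FC, ties broken by gene id, zero p floored and flagged)
and `preranked_gsea()` unchanged.

## Preranked enrichment

`preranked_gsea()` computes the weighted Kolmogorov–Smirnov-style
running-sum enrichment score with hit increments proportional to
|score|. The null is gene-label permutation — member positions resampled
uniformly from the ranking — because a preranked list has no sample
labels to permute; the p-value is two-sided on |ES| with the standard
+1 correction, and FDR is Benjamini–Hochberg across sets. Sets with
fewer than 10 members present in the ranking are dropped unless named in
`exempt_sets` (the mechanism used to retain polysaccharide-utilization
loci regardless of size). The ES computation is asserted in the test
suite to agree to machine precision with the independent `fgsea`
implementation; the permutation scheme is this package's own.

# Fitness integration and binding

`categorize_fitness()` applies the three phenotype categories per
(sRNA, experiment) entry: *significant* when |t| > 4, *strong* when
|fit| > 2 and |t| > 5, *combined* when both — implemented as independent
predicates (an entry with |t| between 4 and 5 and |fit| > 2 is
significant but not strong). Entries from unsuccessful experiments get
no category at all. `prioritize_srnas()` orders mutants by the count of
significant experiments, then maximum |fit|, then id, attaching maximum
CPM and peak condition from the expression matrix.

`gene_set_correlation()` computes, per gene set, the median Pearson
correlation between a query gene's z-scored CPM profile and each
member's profile, excluding the query from its own sets and dropping
sets with fewer than 10 usable members; |median r| > 0.5 marks a set as
labelled. Correlations use condition-mean profiles by default (replicates
averaged) with a per-sample switch, since the reference analysis
correlates across profiled conditions without stating the replicate
handling; the set-size rule counts members after operon collapsing when
an operon map is supplied upstream, else gene members.

`fit_binding_curve()` least-squares fits the one-site specific binding
hyperbola `Y = Bmax·X / (Kd + X)` via Levenberg–Marquardt, with starts
`Bmax = max(y)` and `Kd` at half-maximal binding by linear
interpolation; positivity is enforced by box constraints.

# The synthetic-data generator

The generator defines the study conditions under which all recovery
guarantees are stated; its defaults are fixed and are not tuned per run.

* **Genomes** are uniform i.i.d. nucleotide sequence with genes laid out
  in operon-like blocks (1–3 genes, within-block gaps 60–150 bp,
  between-block gaps 450–900 bp, random strand per block), mean gene
  length 900 bp. Sequential placement guarantees non-overlap; placement
  is retried a bounded number of times and fails loudly rather than
  truncating.
* **Coverage** renders each planted transcription unit as a per-position
  Poisson rate: TEX+ 5'-starts at a planted TSS average `tss_height`
  (100 reads) against `tss_height / enrichment_factor` (factor 10) in
  the untreated track; processing sites show the mirrored pattern;
  internal starts occur at 1% of local coverage in the untreated library
  and are TEX-depleted in the treated one; background is Poisson(0.1)
  per position. Downstream of a planted terminator, coverage falls to
  `1 − terminator_drop` (drop 0.9) of the unit level and decays linearly
  to background over 100 bp, emulating polymerase read-through.
* **Embedded sRNAs** (5'/3' UTR-derived, intra-operonic) are planted as
  4-fold-elevated segments inside their host units so that
  anchor-walking recovers their boundaries; intergenic and antisense
  sRNAs get their own units and TSSs. Intra-operonic sRNAs end well
  inside their host gene so that their boundary drop cannot be mistaken
  for an intergenic terminator.
* **Counts** are negative-binomial around condition means (Poisson at
  dispersion 0) with log-normal baseline abundances; planted fold
  changes multiply one condition's mean; regulon members share a latent
  per-condition profile mixed as `amp·(√ρ·z + √(1−ρ)·e)` to reach a
  target inter-gene correlation ρ. The expression container carries the
  generator's nominal library sizes, so planted fold changes are
  measured free of the composition bias that column-sum normalization
  would introduce when many genes change in one direction.
* **Fitness tables** draw background |t| uniformly inside the null band
  (< 3) and background fit from N(0, 0.5); planted hits carry their
  specified fit and t; 5% of background entries are flagged
  unsuccessful, and planted hits honour their own success flag.

The bundled demonstration dataset (`make_demo()`) is one 50-kb replicon
with 20 genes in 10 blocks, 40 planted TSSs (10 primary, 6 secondary,
9 sRNA-borne, 15 orphan), 10 terminators, 12 sRNAs across the five
classes, and 8 inverted repeats including mismatched arms and a
homopolymeric decoy, plus a 500-gene count matrix (4 conditions × 2
replicates, 80 planted 16-fold changes, one 30-gene regulon at target
correlation 0.9), gene sets, and an 80 × 100 fitness table with 5
planted hits. These sizes keep the full validation suite within a few
minutes on one CPU while leaving every recovery margin meaningful.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level artefacts and mapping ambiguity,
rRNA contamination, batch effects, overlapping transcription on the same
strand, condition-dependent TSS usage, and sequence-dependent coverage
bias. Recovery rates on the demo are upper bounds attainable under clean
signal, not field performance estimates.

# Numerical and convention notes

* All in-memory coordinates are 1-based inclusive (GFF3 convention);
  BED and bedGraph are converted at the I/O boundary, the only place an
  off-by-one can enter.
* Strand-specific tracks follow the strand of transcription.
* Seeds are mandatory function arguments; the caller's RNG state is
  saved and restored, and internal stages derive child seeds from one
  master seed so stages remain independently reproducible.
* Every reader rejects, with a located error, duplicate FASTA headers,
  non-IUPAC characters, missing GFF3 pragmas, negative-width features,
  features on undeclared replicons, overlapping bedGraph intervals,
  duplicate gene-set definitions and empty set names; duplicate set
  members are de-duplicated with a warning.
* Zero-variance expression profiles are flagged and excluded from
  correlations; constant asRNA/operon pairs are reported as neutral
  with a zero-variance note rather than NA-propagated.
* Run manifests record package version, seed, parameters and MD5
  checksums of all inputs and outputs; reruns with the same seed and
  configuration are bit-identical for the deterministic stages.

# Known limitations

* The DE stand-in shares one dispersion across genes; genes with
  atypical dispersion will be mis-calibrated relative to a tagwise fit.
  Use an external GLM-based table for publication-grade contrasts.
* Coverage-drop terminator calling reports one position per intergenic
  span, so multiple termination events between two widely separated
  genes collapse to the strongest.
* The folding proxy ranks stability sensibly on clear positives and
  negatives but is not a substitute for a thermodynamic model near the
  threshold.
* Inverton scanning does not quantify inversion from read orientation;
  it locates invertible repeats only.
* sRNA classification assumes single-TSS transcripts; alternative 5'
  ends within one unit are classified independently.
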