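---
title: "Methods: piRNA identification, characterization and differential expression"
author: "pirnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA identification, characterization and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

# Overview

`pirnakit` implements a testis small RNA-seq piRNA profiling workflow as a
set of composable, tested stages:

1. **preprocess** — raw-read QC, adapter trimming and exact accounting;
2. **identify** — tag collapsing, known-sRNA removal, 1U/10A candidate call;
3. **characterize** — length/base-composition statistics and the ping-pong
   5'-overlap signature;
4. **origin** — genome alignment, feature-category and transposon
   assignment;
5. **clusters** — sliding-window piRNA cluster detection with strand and
   5'U statistics;
6. **diffexp** — TPM normalization and a negative-binomial Wald screen.

Every stage is exercised against a bundled synthetic-data generator
(`sim_config()`, `make_genome()`, `simulate_libraries()`) that plants known
piRNA biology into a toy genome, so the whole pipeline is testable with no
external downloads. This vignette records the model assumptions, the
tunable parameters, and the design decisions taken where the underlying
methodology left choices open.

# Read filtering and accounting

Reads pass a fixed cascade; each read is counted once, in the first
category it fails:

| order | filter | rule | default |
|---|---|---|---|
| 1 | N content | N fraction > `max_n_fraction` | 0.10 (strict >) |
| 2 | low quality | fraction of bases with Phred ≤ `q_threshold` > `max_low_fraction` | Q ≤ 5, > 0.5 |
| 3 | 5' contamination | full 5' adapter occurs anywhere in the read | exact match |
| 4 | 3' adapter / insert | no adapter-prefix match of ≥ `min_overlap` nt, or empty insert | 8 nt, 0 mismatches |
| 5 | homopolymer | one base ≥ `poly_frac` of the insert, or a run ≥ `poly_run` nt | 0.8 / 15 nt |
| 6 | length gate | insert outside `length_range` | 24–33 nt |

Because the cascade partitions the input, the accounting identity

```
total_reads = clean_reads + n_gt10pct + low_quality +
              adapter5p_contamination + adapter3p_null_or_insert_null +
              polyATGC
```

holds exactly on every run, where `clean_reads` is the *pre-length-gate*
survivor count. Published accounting tables for this kind of experiment
balance without a length-gate category, while the textual definition of
clean reads is length-gated — so both views are emitted: `clean_reads`
satisfies the identity and `length_pass` counts the 24–33 nt survivors the
rest of the pipeline uses. The homopolymer rule ("poly A/T/C/G") has no
standard quantitative definition; the two-part rule above (dominant-base
fraction or a long run) is common read-cleaning practice and both knobs are
exposed.

Adapter matching is deliberately exact-match (configurable to 1 mismatch):
at small-RNA read lengths with modern base quality this loses almost
nothing, and it makes trimming byte-reproducible and directly testable.
The 3' adapter is located by its first qualifying prefix occurrence, with
truncated matches at the read end accepted down to the minimum overlap.

# Tags and the candidate rule

Reads with identical insert sequence collapse to one **tag** carrying
per-sample counts. Tags matching user-supplied reference sets (rRNA, tRNA,
snRNA, snoRNA, miRNA) are removed first — a tag is removed when it is an
exact substring of a reference sequence or its reverse complement, classes
scanned in the fixed order above with first-match-wins. Live
covariance-model scanning (Rfam) and hairpin prediction for novel miRNAs
are out of scope; the reference-set slots play their role.

A remaining tag is a **candidate piRNA** when its first base is U or its
10th base is A (1-based positions, U ≡ T in the DNA alphabet). These are
the classical marks of primary and ping-pong-amplified secondary piRNAs.
The rule is a pure per-sequence predicate; mapping status plays no role in
the call (alignment is a separate stage).

# Ping-pong signature

For two alignments on the same chromosome and opposite strands, with
0-based half-open coordinates, the 5'–5' overlap is
`(minus-strand end − 1) − (plus-strand start) + 1`. The profile tallies
every unordered opposite-strand pair at overlaps 1–20, weighted by the
product of the two hits' weights (read-count abundance); `weighted = FALSE`
switches to unique-pair counting. The signature statistic is

```
z10 = (c10 − mean(c_k, k ≠ 10)) / sd_pop(c_k, k ≠ 10)
```

with the population standard deviation over the bounded 1–20 window, which
keeps the background independent of read length.

A practical caveat found during testing: with abundance weighting the
background bins are sums of *products* of heavy-tailed counts, so a single
antisense coincidence between two very abundant tags can dominate the
background standard deviation and deflate `z10` even when the overlap-10
excess is overwhelming. The unique-pair mode is robust to this and is the
better diagnostic when tag abundances span orders of magnitude; both are
reported by the reproduction script.

# Genome alignment and origin assignment

Tags are aligned by exhaustive exact search (optionally one mismatch) on
both strands — at toy-genome scale this is fast, deterministic and
verifiable against a naive sliding-window oracle, which the test suite does
exactly. A tag's total read count is split equally across its hits
(fractional multi-mapper weighting, the least biased default; best-hit-only
counting would need an arbitrary tie-break).

Each hit is assigned one genomic category by fixed priority

```
CDS > 5'UTR > 3'UTR > repeat > intron > lncRNA > unannotated
```

requiring the feature to cover at least 50% of the hit (both configurable).
Exon categories take precedence over repeats, mirroring common annotators;
introns are derived as gene bodies minus exons, since GFF3 files rarely
list introns explicitly. Repeat-derived hits carry the TE class/family
parsed from the repeat track's `class/family` name field; malformed labels
are binned as `unparsed` rather than dropped. Per-TE-class ping-pong
profiles reuse the same signature code on the class partition.

# Cluster detection

piRNA clusters are detected with a transparent sliding-window density
detector (the probabilistic model of dedicated cluster tools belongs to
those tools' own publications):

* windows of `window = 5000` nt advanced by `step = 1000` nt, anchored at
  the first hit 5' end per chromosome (anchoring at the data makes the
  detector exactly translation invariant);
* a window qualifies with ≥ `min_loci = 10` distinct hit 5' positions and
  total hit weight ≥ `min_weight = 30`;
* runs of overlapping qualifying windows are trimmed to their member-hit
  extent *before* merging; trimmed extents within `merge_gap = 10000` nt
  merge; merged intervals shorter than `min_length = 1000` nt are dropped.

Trimming before merging matters: window intervals overhang the underlying
loci by up to one window length on each side, and merging on raw window
coordinates would chain neighbouring loci groups across gaps that are in
fact larger than `merge_gap`.

Per cluster we report the weighted strand split, a directionality call
(mono-directional at ≥ 0.75 strand fraction, a conventional threshold), and
the read-weighted first-base U fraction of member tags. The aggregate
sense/antisense balance over all clusters is reported alongside, because
individually strand-specific clusters typically average out near an even
split — reproducing that contrast is one of the package's property tests.

# Differential expression

Counts are normalized to tags-per-million (`count / library total × 1e6`;
no length normalization — small RNA tags are effectively fixed-length).
Group means of TPM are floored at 0.01 only when exactly zero, so log2 fold
changes stay finite; the reported fold change is `log2(mean_B / mean_A)`
computed from these floored TPM means, which reproduces published worked
examples digit-for-digit, including the all-zero-group case
(`log2(0.01 / 565.937) = −15.7884`).

The test statistic, by contrast, is computed on raw counts: median-of-ratios
size factors, a per-tag method-of-moments common-scale dispersion from the
pooled within-group variance of normalized counts (floored at `1e-8`), and
a Wald contrast of log2 group means with a delta-method standard error.
The statistic is referred to a t distribution with `nA + nB − 2` degrees of
freedom rather than the normal: at three replicates per group the
plugged-in dispersion is noisy, a normal reference empirically inflates the
type-I error to ~0.12, and the t(4) reference brings it to ~0.05. The
package's calibration tests pin this: empirical type-I error within
[0.03, 0.08] at α = 0.05 on null negative-binomial data (n = 3 per group,
dispersion 0.1), and ≥ 80% power at |log2FC| = 2.

Screening uses the raw-p rule `p < 0.05` and `|FC| > 1.5` (no multiple
testing correction, matching the screening convention this workflow
follows); a BH-adjusted column is available via `fdr = TRUE`. Positive
log2FC means higher expression in group B, the second group level.

# The synthetic-data generator

`make_genome()` builds random chromosomes (default 3 × 150 kb, A/C/G/T
only) and plants, without overlap: piRNA clusters, gene models
(5'UTR/CDS/intron/CDS/3'UTR), lncRNA genes, repeat intervals labelled with
a retrotransposon-dominated TE composition, and piRNA loci inside each
annotation type plus unannotated space. Key emulated structures:

* **Length distribution**: locus lengths drawn from a discretized normal
  over 24–33 nt centred at the 29 nt mode (sd 1.5 nt, matching a sharply
  peaked unimodal distribution).
* **1U bias**: each locus's own 5' genomic base is set to U with
  probability `frac_1U = 0.9`, otherwise to an explicit non-U base, so the
  planted rate is exactly the configured parameter.
* **Ping-pong pairs**: a fraction (`frac_pingpong_pairs = 0.25`) of cluster
  and repeat loci get an opposite-strand partner whose 5' end overlaps the
  primary's by exactly 10 nt. The 10A mark on secondaries is then automatic:
  the partner's 10th base is the complement of the primary's 5' U. A
  smaller fraction (`frac_antisense_bg = 0.10`) of loci get a partner at a
  random overlap *other than* 10 nt, emulating the incidental antisense
  overlaps real libraries always contain — without them the Z-score
  background would be degenerately zero on clean synthetic data.
* **Clusters**: mono-strand, 3–8 kb, ≥ 40 distinct loci, isolated by
  ≥ 12 kb from other planted features on both sides so that a
  window-based detector can neither bridge two clusters nor chain a cluster
  with neighbouring feature loci.
* **Counts**: per-tag lognormal baseline means with gamma-mixed multinomial
  read allocation per library, giving negative-binomial-like marginal
  counts at fixed library size (dispersion 0.1) — the noise model the DE
  test assumes, which is what makes its calibration properties testable.
* **DE tags**: 30 tags (planted among well-expressed 5'U primaries so the
  candidate gate cannot hide them), half up- and half down-regulated in
  group B at |log2FC| = 2.
* **QC classes**: one planted read class per filter (low quality, high-N,
  5' contamination, missing 3' adapter, homopolymer, out-of-range length)
  at per-library fractions emulating typical accounting tables; quality
  strings are constant Q38 except for the planted low-quality reads, so QC
  outcomes are fully controlled and the manifest is an exact oracle.
* **Known sRNAs**: rRNA/tRNA/snRNA/snoRNA/miRNA reads are 24–28 nt
  fragments cut from generated reference sets, so the removal stage has
  exact planted truth.

Reads are `insert + 3' adapter + random pad` truncated to 50 nt (Phred+33),
with the TruSeq small-RNA adapters as defaults (the RNA-alphabet 5' adapter
stored DNA-converted so trimming tests are byte-exact). Tag sequences are
re-placed if they would collide with an adapter seed or another tag, so
every planted tag is unique and alignment truth is unambiguous. All outputs
are deterministic functions of the seed, byte-identically.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: sequencing errors and isomiR-like
heterogeneity (tags are exact genome substrings), realistic chromosome
sizes and repeat landscapes, multi-mapping tags, cross-contamination
between annotation categories, non-uniform positional quality profiles,
and any relationship between fertility phenotypes and expression. The
pipeline's statistical behaviour on real sheep-scale data (hundreds of
clusters, thousands of DE tags) is outside what a toy genome can certify;
the tests certify the algorithms, not the biology.

# Problem sizes and numerical choices

The bundled studies run at 3 chromosomes × 150 kb with two groups of three
replicate libraries. Module tests use 20,000 reads per library; the
acceptance suite and the reproduction script use the default 100,000 reads
per library — the depth at which the planted-parameter recovery properties
(length mode, 3σ recovery of the 1U fraction, ≥ 90% reciprocal cluster
overlap, ≥ 80% end-to-end DE power) are stated and verified.

Degenerate inputs are handled explicitly rather than by exception where a
flag is more useful: empty libraries give all-zero accounting rows, empty
hit sets give empty cluster tables, profiles with no opposite-strand pairs
or zero background spread carry `z10 = NA`, all-zero tags are excluded from
testing but reported with p = 1, and an all-zero sample (TPM undefined) is
an error. Ties in the length histogram resolve to the smallest length;
feature-priority ties resolve by the fixed category order. Seeds below
2^31 fully determine every random draw.

# Known limitations

* Exact-match alignment and trimming ignore sequencing errors; on error-free
  synthetic data this is lossless, on real data a dedicated aligner/trimmer
  tolerant of mismatches would recover more reads.
* The window detector reports cluster extents trimmed to observed hits; a
  probabilistic model could call boundaries in low-coverage flanks.
* The NB Wald test uses a per-tag moment dispersion without shrinkage;
  with more replicates or very low counts a shared-dispersion model would
  be more efficient.
* The abundance-weighted ping-pong Z-score is sensitive to single
  high-abundance antisense coincidences (see above); use the unique-pair
  mode when in doubt.
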