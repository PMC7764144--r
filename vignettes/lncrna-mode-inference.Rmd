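---
title: "Inferring how a lncRNA meets its targets: co- vs post-transcriptional antisense interactions"
author: "lncmode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring how a lncRNA meets its targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmode)
```

## The question

A standard way to probe the function of a long non-coding RNA (lncRNA) is to
knock it down with an antisense oligonucleotide (ASO) and record which
promoters change expression (CAGE-style, promoter-level DEG tables). That
tells you *which* genes respond, but not *how* the lncRNA reaches them. One
candidate mechanism is direct RNA:RNA base-pairing, and it comes in two
flavors with different cellular geographies:

* **co-transcriptional**: the lncRNA hybridizes with the 5' end of the
  *nascent* transcript at the target locus, introns included. This puts the
  lncRNA at chromatin near the target promoter and implies
  transcription-level regulation.
* **post-transcriptional**: the lncRNA hybridizes with the *mature* spliced
  transcript, in the nucleoplasm or cytoplasm.

`lncmode` implements a decision pipeline for one knockdown experiment: build
both candidate target sequence sets, search for statistically significant
antisense duplexes in each, test whether strong duplex hits are enriched
among the knockdown's DEGs in each mode, and — when both modes look
significant — break the tie with independent RNA–chromatin contact peaks
(iMARGI-style): genuine co-transcriptional regulators should have their
candidate promoters co-localized with the lncRNA's chromatin contacts.

## Target construction

For every promoter in the tested background:

* the **co** target is the genomic window `[TSS, TSS + 1000)` on the sense
  strand of transcription (reverse-complemented for minus-strand genes),
  truncated at the chromosome edge and at the gene's 3' end. Introns inside
  the window are kept: this is the 5' kilobase of the pre-mRNA as it emerges
  from the polymerase. We anchor the window at the TSS and take only
  downstream sequence, because the interacting molecule is the nascent RNA —
  upstream promoter DNA is never part of it. Window placement is exposed as
  `window_len` for users who want a different compromise.
* the **post** target is the mature (spliced, strand-aware) sequence of the
  *longest* isoform expressed from that promoter; "longest" means mature
  length, not genomic span, because the molecule available for
  post-transcriptional pairing is the processed RNA. Ties break on the
  lexicographically smallest transcript id so results are reproducible.

Promoter identity is the exact strand-aware TSS coordinate: transcripts
sharing a TSS share a promoter. Callers whose annotation encodes a
promoter-to-transcript assignment (e.g. CAGE cluster mappings) should encode
it in the GTF they provide.

## The duplex engine

The antisense search is a classical seed-and-extend scheme over ungapped,
antiparallel duplexes:

1. **Seeds**: exact reverse-complement words of `word_len = 8` nt.
2. **Extension**: ungapped x-drop extension along the duplex diagonal with
   scores +2 (Watson–Crick), +1 (G:U wobble; G:T in the internal DNA
   alphabet), −3 (mismatch) and `xdrop = 12`.
3. **Energy**: each candidate duplex is scored with a nearest-neighbor
   model: a duplex initiation penalty (+4.09 kcal/mol) plus one stacking
   term per adjacent pair of non-mismatched positions, from a bundled
   RNA/RNA Watson–Crick dG37 stack table. Stacks containing wobble pairs
   are penalized by +0.9 kcal/mol per wobble pair and clamped at ≤ 0, so
   stacking never stabilizes through a wobble more than through Watson–
   Crick pairing and perfect-duplex energy is monotone in length. A
   mismatch breaks stacking and adds +2.0 kcal/mol. The hit score is
   −energy.
4. **Significance**: scores are calibrated on dinucleotide-preserving
   (Altschul–Erickson) shuffles of (query, target) pairs. Null maxima
   follow the Karlin–Altschul extreme-value form
   `P(S >= s) = 1 − exp(−K·m·n·e^(−λs))` with `m`, `n` the molecule
   lengths. Pairs are binned by the GC content of both molecules (edges
   0.4/0.6) and, inside a bin, `K` is modulated continuously with the
   target's GC: `K_pair = K·exp(λ·b_t·(gc_t − gc_ref))`, with
   `(λ, K, b_t)` fitted by maximum likelihood (moment-initialized). The
   continuous term matters: without it, residual within-bin GC spread
   leaves pooled null p-values visibly non-uniform. Per target, the best
   hit is the pair's summary p-value, and Benjamini–Hochberg adjustment is
   applied across all targets of a run.

Two deliberate simplifications, both visible in the API: duplexes are
gapless (no bulges or internal loops), and no intramolecular structure or
accessibility term is used. Gapless duplexes keep an exact brute-force
oracle feasible, which the test suite exploits: for pairs where both
molecules are at most `exact_limit = 100` nt the engine skips seeding
entirely and scans every antiparallel diagonal exactly (Kadane's maximal
segment per diagonal). This makes "the best hit equals the brute-force
optimum" a hard contract for short sequences rather than a high-probability
heuristic claim; a seed-only path can miss a maximal segment that happens to
contain no exact 8-mer. Long sequences use the seeded path, whose agreement
with single-seed extension is tested separately.

All engine constants live in one place, `duplex_params()`.

## Enrichment of hits among DEGs

Per knockdown and per mode, "strong hits" are targets with adjusted duplex
p-value below 0.01. Two tests ask whether strong hits concentrate among the
DEGs over the tested background (all promoters of the knockdown table):

* an exact **hypergeometric** upper tail `P(X >= k)`;
* a preranked **GSEA**: promoters ranked by `−log10(p_adj)` (0 for
  hit-less promoters), enrichment score = maximal positive deviation of the
  weighted Kolmogorov–Smirnov running sum (hit increments ∝ |score|^w with
  w = 1, uniform miss decrements), and a label-permutation p-value
  `(1 + #{ES_perm >= ES_obs}) / (1 + n_perm)` with `n_perm = 1000`.

A knockdown/mode is *significant* when either test clears `alpha = 0.01`.
A knockdown with zero DEGs has nothing to test and is reported
non-significant with a warning. Note that a permutation p-value with a DEG
set of one or two promoters is too discrete to ever clear 0.01; calibration
statements about these tests presuppose a handful of DEGs at least.

## Co-localization with RNA-chromatin contacts

When both modes are significant, the tie-breaker asks whether the promoters
of DEGs-with-strong-co-hits sit near the lncRNA's chromatin contact peaks.
Promoters become intervals `[TSS − 500, TSS + 500)` (the flank is
configurable and recorded in every result file; no canonical width exists
for CAGE promoters vs. contact peaks). Two statistics are computed:

* **relative distance**: each query midpoint's distance to the nearest
  reference midpoint, divided by the gap between its two flanking reference
  midpoints, folded into [0, 0.5]; uniform under independence. The
  statistic is the mean absolute deviation of the ECDF of these values from
  the uniform CDF, `mean |ECDF(r) − 2r|`, which lies in [0, 1] — near 0
  under independence, 1 for coincident sets. Query midpoints outside the
  span of reference midpoints have no flanking pair and are dropped.
* **proximity count**: query intervals within distance `d = 0` of a peak.

The null re-places each query interval uniformly within its own chromosome
(lengths preserved, reference fixed), with `n_perm = 100` and a one-sided
(attraction) p-value for each statistic; the relative-distance p is the
headline value the decision rule thresholds. We permute the query set
rather than reproducing an ECDF-permutation scheme because it is simple,
valid under the stated null, and preserves per-chromosome interval counts
and lengths.

## The decision rule

With co- and post-mode enrichment results and (if needed) the
co-localization p:

| co significant | post significant | co-localization p < 0.01 | call |
|---|---|---|---|
| yes | no | — | `co` |
| no | yes | — | `post` |
| yes | yes | yes | `co_via_coloc` |
| yes | yes | no / unavailable | `ambiguous` |
| no | no | — | `none` |

The same `alpha = 0.01` is shared by all three stages.

## Cross-experiment statistics

For comparing DEG sets across knockdowns and species, `overlap_pvalue()`
computes the exact hypergeometric tail over a gene universe of 45,480 —
the sum of GENCODE v35 protein-coding (19,954), long non-coding (17,957)
and small non-coding (7,569) gene counts, exposed as
`gencode_v35_gene_counts`. The default tail is the strictly-greater
`P(X > k)` of the upper-tail `phyper` call pattern, with the conventional
`P(X >= k)` available via `tail = "ge"`. `concordance_summary()` counts
shared genes with strictly negative log2 fold-change in every experiment —
the signature of a knocked-down activator — and reports the percentage to
one decimal.

## The synthetic study

Real ASO-knockdown compendia and contact-peak data are large external
resources; the package instead ships a generator whose defaults define the
study conditions used by the test suite. `sim_config()` builds:

* a two-chromosome genome of 50 non-overlapping genes (i.i.d. bases,
  GC 0.5), each with 3–4 exons (exons ~U(200, 400) bp, introns
  ~U(800, 1200) bp) on a random strand; 30% of multi-exon genes carry a
  second isoform skipping one internal exon, to exercise the
  longest-isoform rule;
* a 2 kb lncRNA carrying, for each of 10 true targets, a 40 nt planted
  segment: the reverse complement (with 5% per-base mutations) of either a
  fully intronic window inside the first kilobase of the nascent transcript
  (**co** mode — sequence absent from the mature mRNA) or a window of the
  mature transcript centered on its 3'-most exon–exon junction (**post**
  mode — sequence not contiguous in the genomic 5' window). The gene
  structure guarantees both: intron 1 always intersects the first kilobase,
  and the last junction's upstream exon ends beyond it;
* a knockdown table where true targets draw log2FC ~ N(−1.5, 0.5), null
  promoters ~ N(0, 0.3), and every row is flagged DEG by the same rule
  (|log2FC| above the two-sided 95% null quantile), so true targets are
  almost always flagged while null promoters contaminate the DEG list at
  ~5% — enrichment tests face realistic false positives;
* contact peaks of 400 bp centered within ±500 bp of 80% of true-target
  TSSs, over 50 uniformly placed background peaks.

Each generator consumes its own RNG stream (master seed + fixed offset), so
regenerating one artifact leaves the others untouched. Everything is
byte-reproducible under a fixed seed.

What the simulation does *not* emulate: real genome composition (repeats,
isochores, GC heterogeneity), CAGE count-level noise, ASO off-target
effects, expression-dependent detection, or cell-type-specific contact
maps. Passing the planted-mode recovery tests therefore shows the pipeline
correctly separates the two mechanisms when the structural signal exists at
the stated effect sizes; it does not certify performance on real compendia.

## Problem sizes and numerical choices

The test suite and the acceptance script size their experiments to run on a
single CPU in minutes: mode recovery uses 50 co-planted + 50 post-planted
simulated knockdowns at the default effect sizes; the type-I calibration
uses one unplanted 200-promoter simulation with 500 DEG-label permutations
(a 200-promoter background keeps the permutation grid fine enough for a
meaningful 1% threshold); null-uniformity checks use 500 fresh shuffled
pairs against a calibration built from 800 null pairs (a three-parameter
fit must be estimated more precisely than the distribution it is checked
against); the brute-force oracle is compared on 200 random pairs of up to
60 nt.

Other numerical choices: p-values are floored at 1e-300 before log10;
degenerate Gumbel fits (zero-variance null maxima) raise an error rather
than producing fake significance; all-equal GSEA scores fall back to
uniform increments with a warning; BH adjustment includes hit-less targets
at p = 1 so the correction denominator is the full target set; result
tables are written with headers in sorted row order so outputs are
byte-stable.

## Known limitations

* The duplex model is gapless and structure-blind; strongly structured
  lncRNAs will be over-called.
* Significance is calibrated per (query, target-bin); a pair falling in an
  untrained GC bin borrows the nearest trained bin with a warning.
* The co-localization test conditions on the observed per-chromosome
  interval counts and lengths; chromosomes absent from the reference peaks
  contribute nothing.
* The decision rule is per-knockdown; no multiplicity control is applied
  across a screen of many knockdowns.
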