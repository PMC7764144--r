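# lncmode

Deciding *how* a long non-coding RNA (lncRNA) reaches the genes it
regulates. Given an ASO-knockdown experiment — a promoter-level table of
log2 fold-changes with differentially-expressed-gene (DEG) flags — `lncmode`
asks whether the knocked-down lncRNA plausibly regulates its DEGs through
direct antisense RNA:RNA base-pairing, and if so in which of two modes:

* **co-transcriptional** — pairing with the 5' kilobase of the *nascent*
  transcript (introns included), which places the lncRNA at chromatin near
  the target promoter;
* **post-transcriptional** — pairing with the *mature* spliced isoform.

It is aimed at computational biologists analyzing lncRNA knockdown screens
(FANTOM-style CAGE perturbation data) together with RNA–chromatin contact
maps (iMARGI/GRID-seq-style peak sets).

## The method

For every promoter in the tested background two candidate targets are
built: the genomic window `[TSS, TSS + 1000)` on the sense strand (co), and
the longest mature isoform of that promoter (post). A seed-and-extend
antisense search (exact reverse-complement 8-mer seeds, ungapped x-drop
extension) scores candidate duplexes with a nearest-neighbor hybridization
model (Watson–Crick stacks, penalized G:U wobble, mismatch breaks), and
converts the best score per pair into a p-value via an extreme-value null

    P(S >= s) = 1 - exp(-K_pair * m * n * e^(-lambda * s)),

fitted on dinucleotide-preserving shuffles, with `m`, `n` the molecule
lengths and `K_pair` modulated by the GC contents of both molecules —
so long or GC-rich targets are not spuriously significant. Per knockdown
and mode, enrichment of strong hits (BH-adjusted p < 0.01) among the DEGs
is tested with an exact hypergeometric tail and a preranked GSEA
permutation test; a mode is significant when either test clears alpha =
0.01. If both modes fire, RNA–chromatin contact peaks break the tie: a
permutation test of co-localization between candidate promoters and peaks
(relative-distance ECDF statistic, 100 uniform re-placements) decides
`co_via_coloc` versus `ambiguous`. Cross-experiment overlap statistics use
the exact hypergeometric tail over the 45,480-gene GENCODE v35 universe.

A fully seeded synthetic-data generator plants mode-specific antisense
signal (intron-resident for co, junction-spanning for post) so the whole
pipeline is testable end to end with known ground truth. See the vignette
(`vignettes/lncrna-mode-inference.Rmd`) for the model details and design
choices.

## Worked example

```r
library(lncmode)

sim <- simulate_dataset(sim_config(planted_mode = "co", seed = 1))
res <- run_pipeline(sim$genome, sim$genes, sim$lncrna, sim$kd, sim$peaks,
                    seed = 1)
res$mode_call
#> <mode_call> ASO_sim_1: co (co: hgd=1.07e-09 gsea=0.000999 | post: hgd=1 gsea=0.939)
res$co
#> <enrichment_result> ASO_sim_1 [co]: 10/10 hits in 11 DEGs of 50; HGD p=1.07e-09, GSEA p=0.000999 -> significant
res$post
#> <enrichment_result> ASO_sim_1 [post]: 0/0 hits in 11 DEGs of 50; HGD p=1, GSEA p=0.939 -> not significant
head(as.data.frame(res$hits_co)[, c("target_id", "energy", "score", "p_adj")], 3)
#>   target_id energy score        p_adj
#> 1   g024_p1 -81.76 81.76 2.200285e-10
#> 2   g020_p1 -78.16 78.16 2.706453e-10
#> 3   g049_p1 -77.61 77.61 2.706453e-10
```

The simulation planted 10 antisense segments into intronic 5' windows; all
10 true targets surface as the strongest co-mode hits (duplex free energies
around −80 kcal/mol, adjusted p ~ 1e-10), the co-mode enrichment is
overwhelming (10 of 10 strong hits fall in the 11 DEGs of a 50-promoter
background), the post mode shows nothing, and the verdict is `co`.

File-based inputs work the same way through `read_fasta()`, `read_gtf()`,
`read_knockdown_tsv()` and `read_bed()`; a thin CLI wrapper with
`simulate` / `targets` / `predict` / `coloc` / `run-all` subcommands lives
at `inst/scripts/lncmode.R`.

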