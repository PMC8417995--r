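# lncscape

Genome-wide identification and functional annotation of long non-coding RNAs
(lncRNAs) from assembled transcript models, as a tested, reusable R pipeline.

## The problem

Transcriptome assemblies of non-model organisms contain tens of thousands of
transcripts that are not in the reference annotation. Deciding which of them
are genuine lncRNAs — and then saying anything about what those lncRNAs *do* —
takes a long chain of filters and evidence channels that is usually run as
one-off scripts. lncscape packages that chain for people who work with
assembled transcripts (GTF), expression matrices (TPM), and the usual tabular
alignment and motif formats:

1. **Identification.** Assembled transcripts are cleaned of organelle
   contamination (exonic overlap ratio with chloroplast/mitochondrial
   intervals strictly > 0.75) and known ncRNAs (> 0.3), merged across samples,
   and classified against the reference with cuffcompare-style class codes
   under the fixed precedence `= > j > i > x > o > u`. Transcripts coded
   `j/u/x/o` are kept; intronic (`i`) transcripts are treated as assembly
   contamination, and a two-classifier machine-learning filter (bagged
   decision trees + a regularized logistic separator, combined by a
   configurable consensus rule) trained on the `=` vs `i` assembly features —
   recurrence ratio, max TPM, mean TPM, length, exon count — removes
   intronic-looking candidates. A coding-ability cascade then removes
   transcripts with protein similarity (e < 1e-4 AND alignment ≥ 40 aa AND
   identity ≥ 35%), length < 150 bp, a coding verdict (longest ORF ≥ 100 aa,
   or Fickett TESTCODE ≥ 0.95 with ORF ≥ 50 aa), or a protein-domain hit
   (e < 1e-4).
2. **Annotation** through three evidence channels: tissue specificity
   (τ = Σ(1 − xᵢ/max x)/(N − 1), called at τ > 0.95 with the top-TSI sample's
   tissue description), adjacent coding genes (< 100 kb), and co-expression —
   unsigned adjacency aᵢⱼ = |cor|⁶ with the topological overlap measure
   TOMᵢⱼ = (Lᵢⱼ + aᵢⱼ)/(min(kᵢ,kⱼ) + 1 − aᵢⱼ), edges at TOM > 0.1, plus
   per-lncRNA GSEA (weighted KS running sum, permutation p, BH, padj < 0.005)
   over the lncRNA's co-expression ranking of coding genes.
3. **Mining**: keyword/GO selection of pathway-related lncRNAs, bipartite
   lncRNA–gene networks, k-means expression-pattern clusters on z-scored
   profiles, a negative-regulation scan (Pearson r ≤ −0.8 on scaled
   profiles), and differentially expressed lncRNAs by a moderated t with
   moment-matched empirical-Bayes variance shrinkage (called at logFC > 2 and
   adjusted p < 0.001 on log2(TPM+1)).
4. **Regulatory context**: exact-p-value PWM scanning of 3-kb lncRNA
   promoters (dynamic-programming null distribution, hits at p < 1e-6) and
   two-tier reciprocal-best-hit orthologs (mutual best hits; rank-2/3 hits
   below the peak of the best-hit e-value distribution).
5. **Pathway preference**: genes classified flavonoid-preferred,
   lignin-preferred, dual or none from the GO annotations of their
   co-expression partners.

A synthetic-data module (`simulatePipelineData()` and the `make*()`
generators) produces every input with planted ground truth — class codes
realized by construction, contaminants straddling the filter thresholds,
planted tissue-specific / co-expressed / anti-correlated rows, motif
occurrences, orthologs — so the whole pipeline is testable without any
downloads. See the methods vignette (`vignettes/lncscape-methods.Rmd`) for
models, parameter defaults and design rationale.

## Worked example

```r
library(lncscape)

sim <- simulatePipelineData(seed = 1)        # genome, assembly, expression, truth
res <- runIdentification(sim$assembly, sim$annotation, sim$genome, sim$expr,
                         sim$organelleBed, sim$ncrnaBed,
                         sim$simHits, sim$domainHits, seed = 1)
res$lncrna
#> TranscriptSet with 123 transcripts on 4 contig(s)
#>   genes: 123
#>   txData extras: recurrence, n_members, locus
res$logs$cascade
#>              stage n_in n_removed n_out
#> 1       similarity  138         5   133
#> 2           length  133         0   133
#> 3 coding_potential  133         5   128
#> 4           domain  128         5   123
res$model
#> ContaminationModel (rule: both_agree )
#>   trained on 50 '=' and 30 'i' examples; held-out accuracy 1.000
```

From 2,944 per-sample transcript records the pipeline keeps 123 lncRNAs: the
overlap filters drop the planted organelle/ncRNA contaminants above their
thresholds, the ML filter removes the 15 intronic-artifact plants, and the
cascade removes the similarity/domain-tagged coding transcripts plus a
handful of random-sequence Fickett false positives (the quantified cost of
the transparent coding scorer).

```r
geneIds <- sort(unique(txData(sim$annotation)$gene_id))
ann <- runAnnotation(res$lncrna, sim$annotation, sim$expr, geneIds,
                     goTable = sim$goTable, nPerm = 1000, seed = 1)
ann$annotations$summary[c("n_tissue", "n_adjacent", "n_coexpression",
                          "n_annotated", "percent_annotated")]
#> $n_tissue       [1] 20
#> $n_adjacent     [1] 119
#> $n_coexpression [1] 5
#> $n_annotated    [1] 119
#> $percent_annotated [1] 96.75

head(ann$tissue[ann$tissue$specific,
                c("lncrna_id", "tau", "top_tsi", "tissue")], 3)
#>   lncrna_id       tau   top_tsi   tissue
#> 1 T0051_s09 0.9687105 0.4503914 tissue01
#> 2 T0052_s10 0.9658969 0.4291809 tissue02
#> 3 T0053_s01 0.9644727 0.4191883 tissue03
```

All 20 planted tissue-specific lncRNAs are recovered (τ > 0.95) with the
right tissue label; τ ≈ 0.965 is exactly what a fold-100 boost in 2 of 40
described samples should give. Keyword mining then finds the lncRNA planted
in the module whose genes share a secondary-cell-wall GO term, and its five
partner genes at TOM > 0.1:

```r
scw <- selectRelated(ann$annotations, "secondary cell wall",
                     goTable = sim$goTable, termNames = sim$termNames)
buildBipartiteNetwork(scw, ann$tom, geneIds)$edges
#>   lncrna_id gene_id    weight
#> 1 T0072_s06   G0005 0.8068267
#> 2 T0072_s06   G0001 0.8051046
#> 3 T0072_s06   G0004 0.8007593
#> 4 T0072_s06   G0003 0.7958009
#> 5 T0072_s06   G0002 0.7956092
```

## Acceptance script

`scripts/acceptance.R` re-runs the entire pipeline from scratch against the
installed package — simulation, identification, three-channel annotation,
network mining (selection, bipartite network, 12 pattern clusters,
negative-pair scan, differential expression), promoter motif scanning, RBH
orthology and pathway-preference classification — logging the stage
summaries, and writes the JSON target report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
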