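# genepip

Functional fine-mapping and gene-level posterior inclusion probabilities
(PIPs) for GWAS loci.

Most trait-associated variants are non-coding, sit in long stretches of
linkage disequilibrium (LD), and act through regulatory elements that are
active only in particular cell types. `genepip` is an R toolkit for the
post-GWAS analysis chain that deals with this, aimed at statistical
geneticists integrating GWAS summary statistics with cell-type-resolved
open chromatin (e.g. scATAC-seq peaks):

1. **Enrichment** — how strongly causal variants concentrate in functional
   annotations, via an EM fit of the logistic prior model
   π<sub>j</sub> = logistic(α₀ + α·A<sub>j</sub>) over LD blocks, reported
   as log₂ fold enrichment with Wald CIs and BH adjustment.
2. **Fine-mapping** — single-effect Bayesian fine-mapping per LD block from
   z-scores, with Wakefield approximate Bayes factors
   logBF = ½·log(1/(1+σ₀²)) + (z²/2)·σ₀²/(1+σ₀²), informative priors from
   the enrichment model, PIPs, and purity-filtered credible sets.
3. **Gene mapping** — gene PIP = Σᵢ PIPᵢ·w̃<sub>ig</sub>, the weighted sum
   of the PIPs of all SNPs linked to a gene through exons, active
   promoters, enhancer loops (ABC ≥ 0.015, PC-HiC, open chromatin within
   20 kb of an active promoter), UTRs, or an exponential distance decay
   e^(−d/5·10⁴) as a fallback; per-SNP weights are normalized so every SNP
   contributes one unit of evidence. Credible gene sets cover 80% of each
   locus's mapped PIP mass.
4. **Partitioning** — summed PIPs by disjoint functional annotation
   category (expected causal variants per category; per-locus category
   probabilities) and locus-level cell-type assignment.
5. **eQTL sharing** — the exact decomposition p = Σ_c p_c·w_c of tissue
   sharing over functional categories, enrichment versus matched controls,
   and a power study of cell-fraction dilution in bulk eQTL detection.
6. **Simulation** — generators for all of the above with ground truth:
   AR(1)-LD z-scores with annotation-enriched causal placement, gene
   landscapes with enhancer loops, and cell-type-mixture eQTL effects.

## Worked example

Simulate a small annotated genome, estimate enrichment, fine-map with the
fitted priors, and partition the PIP mass:

```r
library(genepip)

sim   <- simulate_annotated_genome(sim_config(n_blocks = 200, seed = 1))
A     <- as_annotation_matrix(sim$annotations)
model <- fit_enrichment_em(sim$variants, A)
model
#> Enrichment model (logistic prior):
#>   alpha0 = -5.278  sigma0_sq = 31.62
#>    in_ocr : alpha = 2.28  (log2FE = 3.29 )
#>   converged: TRUE after 10 iterations

priors <- priors_from_model(model, A, block_id = sim$variants$block_id)
fm     <- finemap_blocks(sim$variants, priors = priors)
sum(fm$pip >= 0.5)
#> [1] 159

partition_pips(fm, sim$annotations, scope = "genomewide")
#>        scope category summed_pip proportion
#> 1 genomewide   in_ocr  103.55875  0.5177937
#> 2 genomewide    other   96.44125  0.4822063
```

The recovered log₂ fold enrichment (3.3) is close to the generating value
(3; a 200-block genome leaves visible sampling noise): causal variants were
placed in the 10% `in_ocr` annotation with 8-fold relative odds. Out of 200
simulated loci, 159 variants reach PIP ≥ 0.5 under the informative prior,
and the summed PIP partition attributes ~52% of the causal signal to the
annotation, near the generator's placement fraction 8·0.1/(8·0.1+0.9) ≈ 0.47.

A two-SNP locus shows the gene-PIP arithmetic end to end: SNP `s1`
(PIP 0.6) exonic in `g1`, SNP `s2` (PIP 0.4) looped to both `g1` and `g2`:

```r
fm <- data.frame(block_id = "L1", variant_id = c("s1", "s2"), pip = c(0.6, 0.4))
w  <- normalize_weights(data.frame(
  variant_id = c("s1", "s2", "s2"), gene_id = c("g1", "g1", "g2"),
  weight = 1, method = c("Exon", "PCHiC", "PCHiC"), distance = NA_real_))
compute_gene_pips(fm, w)$genes
#>   gene_id gene_pip n_blocks multi_block
#> 1      g1      0.8        1       FALSE
#> 2      g2      0.2        1       FALSE
```

`s2`'s evidence splits 0.5/0.5 over its two loop targets, so
`g1` gets 0.6 + 0.4·0.5 = 0.8 and the 80% credible gene set is `{g1}`.

## Command line

A thin CLI wraps the same functions
(`inst/cli/genepip <command> --options`): `simulate`, `finemap`, `enrich`,
`genemap`, `partition`, `eqtl-share`. Each run echoes its effective
configuration to `config_used.yaml` in the output directory.

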