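---
title: "Functional fine-mapping and gene-level PIPs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional fine-mapping and gene-level PIPs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genepip)
```

# The problem

Genome-wide association studies of complex traits such as atrial
fibrillation identify many associated loci, but linkage disequilibrium (LD)
obscures which variant in a locus is causal, and long-range gene regulation
obscures which gene it targets. Most risk variants are non-coding and act
through regulatory elements that are active in specific cell types —
cardiomyocyte open chromatin in the case of cardiac arrhythmia. `genepip`
implements a complete post-GWAS workflow for this setting: enrichment-aware
Bayesian fine-mapping of individual variants, aggregation of variant-level
evidence into gene-level posterior inclusion probabilities (PIPs), PIP
partitioning by functional annotation, and an eQTL tissue-sharing
decomposition that explains why bulk eQTL data often miss cell-type-specific
regulatory variants.

# Single-effect fine-mapping from z-scores

Within an approximately independent LD block we assume at most one causal
variant (the `L = 1` single-effect regression regime, which is robust to
mismatched LD because the posterior then depends on the z-scores only). The
effect of the causal variant has a spike-and-slab prior: zero with high
probability, otherwise normal with variance $\sigma_0^2$ on the z-score
scale. For SNP $j$ with z-score $z_j$, the evidence against the null is the
Wakefield-style approximate Bayes factor

$$\log \mathrm{BF}_j = \tfrac12 \log\frac{1}{1+\sigma_0^2}
  + \frac{z_j^2}{2}\,\frac{\sigma_0^2}{1+\sigma_0^2},$$

and with per-SNP prior probabilities $\pi_j$ (summing to one within the
block) the PIP is

$$\mathrm{PIP}_j = \frac{\pi_j \mathrm{BF}_j}{\sum_k \pi_k \mathrm{BF}_k},$$

computed with a log-sum-exp guard. When $\sigma_0^2$ is not supplied it is
profiled over 21 log-spaced grid points in $[10^{-3}, 10^{3}]$ by maximizing
the single-effect marginal likelihood; a fit at a grid boundary is flagged.
This grid profiling approximates, but does not reproduce exactly, the
internal prior-variance estimation of variational fine-mapping software;
the approximation is deliberate and documented here.

Credible sets collect SNPs in decreasing PIP order (ties broken by
ascending position) until the requested coverage (default 95%) is reached.
When an LD matrix is available, a set whose minimum absolute pairwise
correlation falls below 0.5 is discarded, following the usual purity
convention; without an LD matrix the purity filter is skipped and the
result says so (`purity = NA`). This is why LD matrices are an optional
input throughout: with a single effect they matter only for purity.

The fine-mapping mode used for GWAS loci conditions on exactly one causal
variant per analyzed block, because analyzed loci are preselected to contain
a genome-wide-significant signal ($P < 5\times10^{-8}$). The explicit
"no causal variant" configuration appears only inside the enrichment model
below, which scans all blocks genome-wide.

```{r finemap-example}
fit <- finemap_block(c(4, 1, 0), sigma0_sq = 1)
round(fit$variants$pip, 3)
```

# Enrichment of causal variants in functional annotations

Cell-type-resolved open chromatin lets us ask where causal variants
concentrate. The prior probability that SNP $j$ is causal follows a
logistic model on its binary annotations $A_j$:
$\pi_j = \mathrm{logistic}(\alpha_0 + \alpha \cdot A_j)$. The per-block
likelihood sums over the no-causal configuration and each single-causal
configuration,

$$L_b = \prod_k (1-\pi_k) \Big(1 + \sum_j \mathrm{BF}_j
  \frac{\pi_j}{1-\pi_j}\Big),$$

and the EM algorithm alternates between per-block posterior causal
probabilities (soft labels, including the no-causal mass) and a logistic
regression of those labels on the annotations. This makes the marginal
log-likelihood non-decreasing, which the test suite asserts. Coefficients
are capped at $|\alpha| \le 10$ to prevent separation blow-up on sparse
annotations, and $\sigma_0^2$ is profiled once, on the same grid as the
fine-mapping module, before the EM starts.

Wald standard errors are computed from the numerically differentiated
observed information of the *marginal* log-likelihood rather than from the
complete-data logistic fit, so they propagate E-step uncertainty.
Enrichment is reported as $\log_2$ fold enrichment ($\alpha_k / \ln 2$)
with Benjamini–Hochberg adjustment across the declared family. Marginal
(one-annotation-at-a-time) fits produce the report; a joint fit over all
annotations produces the fine-mapping priors, which are renormalized to sum
to one within each block as the single-effect semantics require. Whether
such renormalization happened upstream in the original tooling is not
documented anywhere we could verify, so we state our choice here: it is
required for `L = 1` posterior algebra to be coherent.

Two estimation properties deserve a note, because they shape what "recovery
of the truth" means on synthetic data:

* the logistic model estimates a *log-odds* enrichment, while the natural
  generative quantity (causal placement proportional to $e^{\alpha A}$
  within a block) is a *relative risk*; at realistic causal rates
  (~1 causal per 100 SNPs) the two differ by a few hundredths;
* when causal signals are moderate ($\lambda \approx 5$ on the z scale),
  posterior mass leaks from unannotated causal SNPs toward annotated null
  SNPs, biasing the marginal-model EM slightly upward. The effect
  disappears for strong signals and shrinks under strong LD, where
  Bayes-factor structure rather than priors drives the within-block
  allocation. The test suite asserts that the EM fixed point coincides
  with the directly optimized maximum-likelihood estimate, so this is a
  property of the estimand, not of the algorithm.

# From variant PIPs to gene PIPs

Let $Z_g$ indicate that gene $g$ is the causal gene of a locus. With a
single causal variant per locus,

$$P(Z_g = 1 \mid D) = \sum_i P(Z_g = 1 \mid \gamma_i = 1)\,
  \mathrm{PIP}_i,$$

so the gene PIP is a weighted sum of SNP PIPs. Raw SNP-to-gene weights
$w_{ig}$ come from four accumulating stages:

1. **Exon or active promoter** (promoter window $[-2000, +500]$ bp around
   the TSS, strand-aware, overlapping open chromatin): $w = 1$.
2. **Enhancer loops**: activity-by-contact links with score $\ge 0.015$,
   promoter-capture Hi-C links, or — because proximity ligation misses
   short-range contacts — open chromatin within 20 kb of an active
   promoter: $w = 1$.
3. **UTR outside open chromatin** (RNA-level regulation): $w = 1$.
4. **Distance decay**, only when stages 1–3 produced nothing:
   $w_{ig} = e^{-d_{ig}/5\times10^4}$ for every gene with a TSS within
   1 Mb, where $d_{ig}$ is the SNP-to-TSS distance.

The 50 kb decay scale puts about 87% of the weight mass within 100 kb
(`weight_mass_within(5e4, 1e5)` = 0.8647), consistent with the observation
that most enhancers act within 100 kb of their promoter. Since a SNP can
support only one causal gene, weights are normalized per SNP
($\tilde w_{ig} = w_{ig} / \sum_g w_{ig}$) before summation, so each SNP
contributes exactly one unit of causal evidence. A gene confined to one
block has gene PIP at most 1; a gene spanning several blocks is flagged and
its PIP is read as the expected number of causal variants targeting it.
Credible gene sets take genes per locus in decreasing order of their
within-locus contribution (ties by gene id — the original convention is not
documented, so we fix a deterministic one) until 80% of the locus's
gene-mapped PIP mass is covered; multi-block genes enter with their local
contribution only.

Design choices that were genuinely open, and how we resolved them:

* $d_{ig}$ is the distance to the TSS (the same convention the
  nearest-gene baseline uses), since the decay formula leaves "SNP–gene
  distance" unspecified;
* stages 1–3 accumulate: a SNP exonic for one gene and looped to another
  links both at $w = 1$, because only the distance fallback is textually
  gated on "not linked by any of the above". A `first-hit` mode is
  available for sensitivity analysis (`link_config(link_mode =
  "first-hit")`);
* the UTR rule checks open-chromatin status against the union peak set.

```{r genemap-example}
fm <- data.frame(block_id = "L1", variant_id = c("s1", "s2"),
                 pip = c(0.6, 0.4))
w <- normalize_weights(data.frame(
  variant_id = c("s1", "s2", "s2"), gene_id = c("g1", "g1", "g2"),
  weight = 1, method = c("Exon", "PCHiC", "PCHiC"), distance = NA_real_))
compute_gene_pips(fm, w)$genes
```

# Partitioning PIPs and assigning cell types to loci

Summed PIPs over a disjoint annotation category estimate the expected
number of causal variants in that category (genome-wide) or the probability
that the locus's causal variant falls in it (per locus). Disjointness is
enforced through a precedence order (default: coding exon > UTR > conserved
> cell-type-specific OCR > shared 2–3 > shared 4+ > non-DA OCR > other).
For locus-level cell-type assignment, loci with less than 0.25 summed PIP
in open chromatin are left unassigned; the remaining loci report cell-type
shares both raw and renormalized over OCR categories — the source
convention does not say which view its per-locus display uses, so both are
emitted.

Open chromatin peaks themselves are classified by sharing: peaks
differentially accessible (DA) in exactly one cell type are cell-type
specific; DA peaks occurring in several cell types are moved to the shared
classes by the number of cell types involved; non-DA peaks are binarized at
the top accessibility quartile per cell type (ties at the threshold
included, making the rule deterministic and order-independent) and labelled
shared in 2–3, shared in 4+, or non-DA.

# eQTL tissue sharing and the dilution power study

For eQTLs discovered in one tissue, the probability $p$ of replication in a
second tissue decomposes exactly over functional categories $c$:

$$p = \sum_c p_c\, w_c,$$

with $w_c$ the proportion of eQTLs in category $c$ and $p_c$ the
within-category sharing probability. The identity holds by construction and
is asserted, not estimated. Categories come from the same annotation
machinery (exon, UTR, intronic OCR by sharing class); eQTL variants in
peaks overlapping exons or UTRs, or in non-DA peaks, are ambiguous and
filtered. Enrichment relative to LD/MAF-matched controls is a simple ratio
of category proportions; the matched controls are supplied by the caller
(real matched-control output can be read from TSV) or generated
synthetically with known folds.

The power study quantifies why bulk tissue under-detects
cell-type-specific regulation: if the causal cell type is a fraction $f$ of
the tissue, a cell-type-specific eQTL contributes slope $f\beta$ to bulk
expression while a shared eQTL contributes $\beta$, with unit Gaussian
noise. Power is the rejection rate of the marginal slope t-test; the
reported ratio power(specific)/power(shared) has a closed-form normal
approximation through the non-centrality $f\beta\,\mathrm{sd}(g)\sqrt n$,
which serves as an independent oracle. The exact design behind the
published "8–40%" range is not reproducible from the main text, so the
closed form — not that printed range — is the package's reference; at
$f = 0.2$, $n = 200$ and effects between 0.15 and 0.35 per allele the
simulated ratios land between roughly 10% and 25%, comfortably inside the
published band.

# The synthetic-data generator

`simulate_annotated_genome()` emulates the statistical structure of the
real pipeline inputs: AR(1) LD within blocks ($R_{jk} = \rho^{|j-k|}$,
default $\rho = 0.9$, realistic for markers spaced about 1 kb apart and
the regime where functional priors actually change fine-mapping
conclusions), exactly one causal variant per block placed with probability
proportional to $e^{\alpha \cdot A_j}$, and z-scores drawn from
$\mathcal N(\lambda R e_{\mathrm{causal}}, R)$. Defaults are 1000 blocks of
100 SNPs, $\lambda = 5$, and one annotation covering 10% of SNPs with
$\alpha = \ln 8$ (log2 fold enrichment 3). With `lambda_dist = "normal"`
the per-block effect is drawn from $\mathcal N(0, \lambda^2)$ — the
well-specified regime in which PIPs are exactly calibrated, used by the
calibration study (10,000 blocks of 25 SNPs, sizes chosen to keep the
default test run fast); with a fixed effect the Bayes-factor model is
mildly misspecified and decile calibration is only approximate.

`simulate_gene_landscape()` builds loci with five genes, promoter open
chromatin at every TSS, and a designated causal gene reached through an
exonic variant (25%), a distal enhancer looped to the promoter (45%, of
which 70% sit nearest to a *different* gene — the configuration where
nearest-gene assignment fails), nearby open chromatin (15%) or TSS
proximity (15%). `simulate_eqtl_records()` and `simulate_eqtl_mixture()`
generate categorized eQTLs with known fold enrichments and sharing
probabilities, and bulk-expression mixtures with known diluted slopes.

What the generator does **not** emulate: realistic human LD panels
(block-diagonal AR(1) only), allele-frequency spectra, multiple causal
variants per block, overlapping genes, strand-asymmetric gene structures,
or confounding between annotation density and local LD. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated assumptions, not performance on any particular real GWAS.

# Numerical conventions and degenerate inputs

* GWAS positions are 1-based; all BED/BEDPE-style intervals are 0-based
  half-open; conversion happens only at the I/O boundary. A 1-based
  position $p$ is inside $[s, e)$ iff $s < p \le e$.
* PIPs sum to 1 per block to within $10^{-12}$; normalized weights sum to 1
  per SNP to the same tolerance.
* EM convergence: max absolute coefficient change below $10^{-4}$ or 200
  iterations; non-convergence returns the fit flagged, with a warning.
* Degenerate inputs: single-SNP blocks get PIP 1; all-zero priors are an
  error; empty summary-statistic files yield an empty result with a
  warning; annotations constant across SNPs are dropped with a warning;
  variants outside every block are dropped with a logged count.
* All generators require explicit seeds; identical configurations
  reproduce identical outputs through R's default Mersenne-Twister stream.

# Known limitations

* The enrichment EM estimates the pseudo-true parameter of the marginal
  single-causal model; under moderate signal this sits slightly above the
  generative relative-risk enrichment (see above). Confidence intervals are
  honest for the model's estimand.
* Grid profiling of $\sigma_0^2$ is coarser than a continuous optimizer;
  boundary fits are flagged rather than refined.
* Multi-causal fine-mapping (`L > 1`), LD-mismatch diagnostics, and
  colocalization are out of scope.
* The gene-mapping weights are heuristic by design; their calibration on
  real data depends on the quality of the supplied loops and peak sets.
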