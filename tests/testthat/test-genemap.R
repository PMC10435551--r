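test_that("distance-decay weight mass has the stated closed form", {
  expect_equal(weight_mass_within(5e4, 1e5), 1 - exp(-2))
  expect_equal(round(weight_mass_within(5e4, 1e5), 2), 0.86)
  expect_equal(weight_mass_within(5e4, 5e4), 1 - exp(-1))
  expect_equal(weight_mass_within(5e4, Inf), 1)
})

test_that("exonic links suppress the distance fallback", {
  genes <- make_genes(
    make_gene("gA", 10000, exons = c(9999, 10500)),
    make_gene("gB", 40100))
  v <- make_variants(10100L, id = "s1")
  w <- link_snp_to_genes(v, genes)
  expect_equal(nrow(w), 1)
  expect_identical(w$gene_id, "gA")
  expect_identical(w$method, "Exon")
  expect_equal(w$weight, 1)
})

test_that("the distance fallback uses the exponential decay over TSSs", {
  genes <- make_genes(make_gene("gA", 110000), make_gene("gB", 150000))
  v <- make_variants(100000L, id = "s1")    # 10 kb and 50 kb from the TSSs
  w <- link_snp_to_genes(v, genes)
  w <- w[order(w$gene_id), ]
  expect_identical(w$method, c("Distance", "Distance"))
  expect_equal(w$weight, c(exp(-0.2), exp(-1)))
  expect_equal(w$distance, c(10000, 50000))

  # normalization of the same pair
  nw <- normalize_weights(w)
  expect_equal(round(nw$norm_weight, 4), c(0.6900, 0.3100))
  expect_equal(sum(nw$norm_weight), 1, tolerance = 1e-12)

  # genes beyond 1 Mb receive nothing
  far <- make_genes(make_gene("gC", 5e6))
  expect_message(w2 <- link_snp_to_genes(v, far), "no gene")
  expect_equal(nrow(w2), 0)
})

test_that("open chromatin near an active promoter links the gene", {
  genes <- make_genes(make_gene("gC", 50000))
  peaks <- data.frame(peak_id = c("prom", "enh"), chrom = "chr1",
                      start = c(49500L, 63000L), end = c(50200L, 63500L),
                      stringsAsFactors = FALSE)
  v <- make_variants(63100L, id = "s1")   # in enh, ~13 kb from the promoter
  w <- link_snp_to_genes(v, genes, peaks = peaks)
  expect_identical(w$method, "NearbyOCR")
  expect_identical(w$gene_id, "gC")
  expect_equal(w$weight, 1)

  # beyond 20 kb: no stage-2 link, falls back to distance
  peaks2 <- peaks
  peaks2$start[2] <- 90000L; peaks2$end[2] <- 90500L
  v2 <- make_variants(90100L, id = "s1")
  w2 <- link_snp_to_genes(v2, genes, peaks = peaks2)
  expect_identical(w2$method, "Distance")
})

test_that("the UTR rule applies only outside open chromatin", {
  genes <- make_genes(make_gene("gA", 10000, exons = c(9999, 12000),
                                utrs = c(30000, 30600)))
  v <- make_variants(30100L, id = "s1")
  w <- link_snp_to_genes(v, genes)
  expect_identical(w$method, "UTR")
  # same SNP inside a peak (away from the promoter): UTR rule suppressed
  peaks <- data.frame(peak_id = "pk", chrom = "chr1",
                      start = 30000L, end = 30600L, stringsAsFactors = FALSE)
  w2 <- link_snp_to_genes(v, genes, peaks = peaks)
  expect_false("UTR" %in% w2$method)
  expect_identical(unique(w2$method), "Distance")
})

test_that("stage 1-3 links accumulate across genes but not per pair", {
  genes <- make_genes(
    make_gene("gA", 10000, exons = c(9999, 10500)),
    make_gene("gB", 300000))
  links <- data.frame(chrom = "chr1", start = 10000L, end = 10400L,
                      gene_id = c("gA", "gB"), link_type = c("ABC", "PCHIC"),
                      score = c(0.05, NA), stringsAsFactors = FALSE)
  v <- make_variants(10100L, id = "s1")
  w <- link_snp_to_genes(v, genes, links = links)
  w <- w[order(w$gene_id), ]
  # gA deduplicated to the exon link; gB linked through the loop
  expect_identical(w$gene_id, c("gA", "gB"))
  expect_identical(w$method, c("Exon", "PCHiC"))
  expect_equal(w$weight, c(1, 1))
  nw <- normalize_weights(w)
  expect_equal(nw$norm_weight, c(0.5, 0.5))

  # first-hit mode keeps only the first linking stage
  w1 <- link_snp_to_genes(v, genes, links = links,
                          cfg = link_config(link_mode = "first-hit"))
  expect_identical(w1$method, "Exon")
})

test_that("gene PIPs reproduce the two-SNP worked example", {
  fm <- data.frame(block_id = "L1", variant_id = c("s1", "s2"),
                   pip = c(0.6, 0.4), stringsAsFactors = FALSE)
  w <- data.frame(variant_id = c("s1", "s2", "s2"),
                  gene_id = c("g1", "g1", "g2"),
                  weight = 1, method = c("Exon", "PCHiC", "PCHiC"),
                  distance = NA_real_, stringsAsFactors = FALSE)
  nw <- normalize_weights(w)
  gp <- compute_gene_pips(fm, nw)
  expect_equal(gp$genes$gene_pip[gp$genes$gene_id == "g1"], 0.8,
               tolerance = 1e-12)
  expect_equal(gp$genes$gene_pip[gp$genes$gene_id == "g2"], 0.2,
               tolerance = 1e-12)
  # conservation: all PIP mass maps to genes
  expect_equal(sum(gp$genes$gene_pip), sum(fm$pip), tolerance = 1e-12)

  cgs <- credible_gene_set(gp, coverage = 0.8)
  expect_identical(cgs$gene_id, "g1")

  # 50/50 contributions need both genes
  contrib <- data.frame(block_id = "L1", gene_id = c("gA", "gB"),
                        contribution = c(0.5, 0.5), stringsAsFactors = FALSE)
  cgs2 <- credible_gene_set(contrib, coverage = 0.8)
  expect_identical(sort(cgs2$gene_id), c("gA", "gB"))
  expect_identical(cgs2$gene_id[1], "gA")  # ties resolved by gene id
})

test_that("multi-block genes are flagged and bounded correctly", {
  fm <- data.frame(block_id = c("B1", "B2"), variant_id = c("s1", "s2"),
                   pip = c(0.7, 0.6), stringsAsFactors = FALSE)
  w <- data.frame(variant_id = c("s1", "s2"), gene_id = "gX", weight = 1,
                  method = "Exon", distance = NA_real_,
                  stringsAsFactors = FALSE)
  gp <- compute_gene_pips(fm, normalize_weights(w))
  expect_equal(gp$genes$gene_pip, 1.3)
  expect_true(gp$genes$multi_block)
  # within each locus the gene contributes only its local share
  cgs <- credible_gene_set(gp)
  expect_equal(cgs$contribution[cgs$block_id == "B1"], 0.7)
  expect_equal(cgs$contribution[cgs$block_id == "B2"], 0.6)

  # single-block gene PIP never exceeds 1
  fm1 <- data.frame(block_id = "B1", variant_id = paste0("s", 1:5),
                    pip = c(0.5, 0.2, 0.1, 0.1, 0.1), stringsAsFactors = FALSE)
  w1 <- data.frame(variant_id = paste0("s", 1:5), gene_id = "gY", weight = 1,
                   method = "Exon", distance = NA_real_,
                   stringsAsFactors = FALSE)
  gp1 <- compute_gene_pips(fm1, normalize_weights(w1))
  expect_lte(gp1$genes$gene_pip, 1)
})

test_that("weight conservation holds and decay scaling is monotone", {
  set.seed(11)
  land <- simulate_gene_landscape(landscape_config(n_loci = 10, seed = 8))
  fm <- finemap_blocks(land$variants)
  w <- normalize_weights(link_snp_to_genes(land$variants, land$gene_models,
                                           peaks = land$peaks,
                                           links = land$links))
  sums <- tapply(w$norm_weight, w$variant_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  gp <- compute_gene_pips(fm, w)
  # conservation: mapped gene mass cannot exceed the PIP mass per locus
  by_locus <- tapply(gp$locus_contrib$contribution,
                     gp$locus_contrib$block_id, sum)
  pip_mass <- tapply(fm$pip, fm$block_id, sum)
  expect_true(all(by_locus <= pip_mass[names(by_locus)] + 1e-9))

  # doubling the decay scale never decreases the farther gene's share
  genes <- make_genes(make_gene("gA", 110000), make_gene("gB", 180000))
  v <- make_variants(100000L, id = "s1")
  share_far <- function(scale) {
    nw <- normalize_weights(
      link_snp_to_genes(v, genes, cfg = link_config(decay_bp = scale)))
    nw$norm_weight[nw$gene_id == "gB"]
  }
  expect_gte(share_far(1e5), share_far(5e4))
  expect_gte(share_far(2e5), share_far(1e5))
})

test_that("precision and the nearest-gene baseline behave as defined", {
  expect_equal(evaluate_precision(c("a", "b", "c", "d"), c("a", "b", "c")),
               0.75)
  expect_equal(evaluate_precision(c("a", "b"), c("a", "b", "c")), 1)
  expect_error(evaluate_precision(character(0), "a"), "empty")

  genes <- make_genes(make_gene("gNear", 105000), make_gene("gFar", 107000))
  top <- data.frame(block_id = "L1", chrom = "chr1", pos = 100000L,
                    stringsAsFactors = FALSE)
  nb <- nearest_gene_baseline(top, genes)
  expect_identical(nb$gene_id, "gNear")
  # ties break by ascending gene id
  genes2 <- make_genes(make_gene("gB", 105000), make_gene("gA", 95000))
  expect_identical(nearest_gene_baseline(top, genes2)$gene_id, "gA")
})
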