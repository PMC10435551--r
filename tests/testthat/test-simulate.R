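test_that("AR(1) LD matrices have the stated structure", {
  expect_equal(simulate_ld(4, 0), diag(4))
  R <- simulate_ld(3, 0.5)
  expect_equal(R[1, 2:3], c(0.5, 0.25))
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 3))
  # positive definite even at strong decay
  expect_gt(min(eigen(simulate_ld(200, 0.99), only.values = TRUE)$values), 0)
  expect_error(simulate_ld(5, 1), "rho")
})

test_that("block z-scores have the implied mean and covariance structure", {
  R <- simulate_ld(5, 0.8)
  # reproducibility under a seed
  z1 <- simulate_block(R, 3, 5, seed = 99)
  z2 <- simulate_block(R, 3, 5, seed = 99)
  expect_identical(z1, z2)

  # moments under the null (lambda = 0)
  set.seed(1)
  L <- chol(R)
  draws <- replicate(10000, simulate_block(R, 1, 0, chol_R = L))
  expect_lt(max(abs(rowMeans(draws))), 3 * sqrt(1 / 10000) * 3)
  expect_lt(max(abs(apply(draws, 1, var) - 1)), 0.08)

  # mean structure: causal z has mean lambda, neighbours rho * lambda
  set.seed(2)
  draws5 <- replicate(20000, simulate_block(R, 3, 5, chol_R = L))
  mu <- rowMeans(draws5)
  expect_equal(mu[3], 5, tolerance = 0.05)
  expect_equal(mu[2], 0.8 * 5, tolerance = 0.05)
  # empirical covariance matches R
  S <- cov(t(draws5))
  expect_lt(max(abs(S - R)), 3 * 3 / sqrt(20000) + 0.05)

  expect_error(simulate_block(R, 9, 5), "causal index")
})

test_that("causal placement follows the annotation log-odds", {
  # null enrichment: placement uniform within block
  sim0 <- simulate_annotated_genome(
    sim_config(n_blocks = 5000, snps_per_block = 10,
               annotation_logodds = c(ann = 0),
               annotation_freq = c(ann = 0.1), seed = 55))
  tab <- table(factor(sim0$truth$causal_index, levels = 1:10))
  expect_gt(chisq.test(tab)$p.value, 0.001)

  # ln 8 on a 10% annotation: causal fraction in the annotation near
  # 8 * 0.1 / (8 * 0.1 + 0.9) (blocks large enough for the asymptotic value)
  sim1 <- simulate_annotated_genome(
    sim_config(n_blocks = 5000, snps_per_block = 100, seed = 56))
  frac <- mean(sim1$truth$category == "in_ocr")
  expect_lt(abs(frac - 8 * 0.1 / (8 * 0.1 + 0.9)), 0.03)

  # exactly one causal per block
  expect_equal(nrow(sim1$truth), 5000)
  expect_true(all(sim1$truth$causal_variant_id %in% sim1$variants$variant_id))
  expect_equal(anyDuplicated(sim1$truth$block_id), 0)
})

test_that("generated files parse back through the readers unchanged", {
  sim <- simulate_annotated_genome(
    sim_config(n_blocks = 12, snps_per_block = 15, seed = 77))
  stats <- sim$variants[, c("chrom", "pos", "variant_id", "z")]
  names(stats)[3] <- "id"
  f <- write_stats_file(stats)
  v <- suppressMessages(read_summary_stats(f))
  expect_equal(v$z, sim$variants$z, tolerance = 1e-12)

  fb <- write_bed_file(sim$blocks[, c("chrom", "start", "end", "block_id")])
  blocks <- read_ld_blocks(fb)
  expect_identical(blocks$block_id, sim$blocks$block_id)
  v <- assign_blocks(v, blocks)
  expect_identical(v$block_id, sim$variants$block_id)

  # annotation table round trip preserves the matrix
  fa <- tempfile(fileext = ".tsv")
  write.table(sim$annotations, fa, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read.delim(fa, stringsAsFactors = FALSE)
  expect_identical(back$category, sim$annotations$category)
  expect_identical(back$in_ocr, sim$annotations$in_ocr)

  # determinism: the same config reproduces identical outputs
  sim2 <- simulate_annotated_genome(
    sim_config(n_blocks = 12, snps_per_block = 15, seed = 77))
  expect_identical(sim2$variants, sim$variants)
  expect_identical(sim2$truth, sim$truth)
})

test_that("gene landscapes place the causal variant on a weight-1 path", {
  land <- simulate_gene_landscape(landscape_config(n_loci = 30, seed = 13))
  expect_equal(nrow(land$truth), 30)
  # the generated tables parse through the io layer
  fg <- tempfile()
  write_gene_models(land$gene_models, fg)
  back <- read_gene_models(fg)
  expect_identical(back$gene_id, land$gene_models$gene_id)

  # exon-scenario loci: the causal gene receives at least the causal SNP's
  # full PIP (weight-1 path by construction)
  fm <- finemap_blocks(land$variants)
  w <- normalize_weights(link_snp_to_genes(land$variants, land$gene_models,
                                           peaks = land$peaks,
                                           links = land$links))
  gp <- compute_gene_pips(fm, w)
  ex <- land$truth[land$truth$scenario == "exon", ]
  for (i in seq_len(nrow(ex))) {
    snp_pip <- fm$pip[fm$variant_id == ex$causal_variant_id[i]]
    gene_pip <- gp$genes$gene_pip[gp$genes$gene_id == ex$causal_gene[i]]
    expect_gte(gene_pip + 1e-9, snp_pip)
  }
})
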