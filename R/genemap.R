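# Gene mapping: SNP-to-gene weights, weight normalization, gene-level PIPs,
# credible gene sets, and the benchmarking precision metric.
#
# A gene's PIP is the weighted sum of the PIPs of all SNPs linked to it,
# with per-SNP weights normalized over genes so that each SNP's causal
# evidence is counted once. Weights come from four accumulating stages:
# (1) exon or active promoter, (2) enhancer loops (ABC / PC-HiC) or open
# chromatin within 20 kb of an active promoter, (3) UTR outside open
# chromatin, (4) -- only when stages 1-3 yield nothing -- exponential
# distance decay exp(-d / 5e4) over all genes with a TSS within 1 Mb.

#' Configuration for SNP-to-gene linking
#'
#' @param promoter_upstream,promoter_downstream Strand-aware promoter window
#'   around the TSS in bp (default 2000 up, 500 down). A promoter is
#'   "active" when it overlaps any open chromatin peak.
#' @param abc_min_score ABC links below this score are ignored (default
#'   0.015).
#' @param nearby_ocr_bp A SNP-containing peak within this distance of an
#'   active promoter links the gene (default 20 kb).
#' @param decay_bp Distance-decay scale of the fallback weight
#'   `exp(-d / decay_bp)` (default 50 kb).
#' @param max_distance_bp Fallback linking window around gene TSSs (default
#'   1 Mb).
#' @param link_mode `"accumulate"` (default): stage 1-3 links coexist for a
#'   SNP; `"first-hit"`: the first stage that links anything wins.
#' @return A list of class `link_config`.
#' @export
link_config <- function(promoter_upstream = 2000, promoter_downstream = 500,
                        abc_min_score = 0.015, nearby_ocr_bp = 2e4,
                        decay_bp = 5e4, max_distance_bp = 1e6,
                        link_mode = c("accumulate", "first-hit")) {
  structure(list(promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 abc_min_score = abc_min_score,
                 nearby_ocr_bp = nearby_ocr_bp,
                 decay_bp = decay_bp,
                 max_distance_bp = max_distance_bp,
                 link_mode = match.arg(link_mode)),
            class = "link_config")
}

# Strand-aware promoter windows as 0-based half-open intervals.
promoter_intervals <- function(gene_models, cfg) {
  up <- cfg$promoter_upstream
  down <- cfg$promoter_downstream
  plus <- gene_models$strand == "+"
  start1 <- ifelse(plus, gene_models$tss - up, gene_models$tss - down)
  end1 <- ifelse(plus, gene_models$tss + down, gene_models$tss + up)
  data.frame(gene_id = gene_models$gene_id, chrom = gene_models$chrom,
             start = pmax(start1 - 1L, 0L), end = end1,
             stringsAsFactors = FALSE)
}

#' Link SNPs to genes with raw weights
#'
#' @param variants Data frame with `variant_id`, `chrom`, `pos`.
#' @param gene_models Gene-model data frame ([read_gene_models()]).
#' @param peaks Optional open-chromatin peak data frame (`chrom`, `start`,
#'   `end`); needed for active promoters, nearby-OCR links and the UTR rule.
#' @param links Optional link data frame from [read_links()].
#' @param cfg A [link_config()].
#' @return Data frame with `variant_id`, `gene_id`, `weight`, `method`
#'   (`Exon`, `ActivePromoter`, `ABC`, `PCHiC`, `NearbyOCR`, `UTR`,
#'   `Distance`) and `distance` (bp to the TSS; `NA` except for `Distance`
#'   links). SNPs with no link of any kind yield no rows (counted in a
#'   message).
#' @export
link_snp_to_genes <- function(variants, gene_models, peaks = NULL,
                              links = NULL, cfg = link_config()) {
  stopifnot(inherits(cfg, "link_config"))
  m <- nrow(variants)
  gv <- granges_snps(variants$chrom, variants$pos)
  method_rank <- c(Exon = 1, ActivePromoter = 2, ABC = 3, PCHiC = 4,
                   NearbyOCR = 5, UTR = 6, Distance = 7)
  stage_of <- c(Exon = 1, ActivePromoter = 1, ABC = 2, PCHiC = 2,
                NearbyOCR = 2, UTR = 3, Distance = 4)

  out <- list()
  add <- function(vidx, gene_id, method) {
    if (length(vidx) == 0) return()
    out[[length(out) + 1]] <<- data.frame(
      variant_id = variants$variant_id[vidx], gene_id = gene_id,
      weight = 1, method = method, distance = NA_real_,
      stringsAsFactors = FALSE)
  }

  ## stage 1: exon / active promoter
  ex <- expand_gene_intervals(gene_models, "exons")
  if (nrow(ex) > 0) {
    ov <- GenomicRanges::findOverlaps(gv, granges_0based(ex$chrom, ex$start, ex$end))
    add(S4Vectors::queryHits(ov), ex$gene_id[S4Vectors::subjectHits(ov)], "Exon")
  }
  gpk <- NULL
  active <- rep(FALSE, nrow(gene_models))
  prom <- promoter_intervals(gene_models, cfg)
  gprom <- granges_0based(prom$chrom, prom$start, prom$end)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    gpk <- granges_0based(peaks$chrom, peaks$start, peaks$end)
    active <- IRanges::overlapsAny(gprom, gpk)
    ov <- GenomicRanges::findOverlaps(gv, gprom[active])
    add(S4Vectors::queryHits(ov),
        prom$gene_id[active][S4Vectors::subjectHits(ov)], "ActivePromoter")
  }

  ## stage 2: enhancer loops (ABC / PC-HiC) and open chromatin near an
  ## active promoter
  if (!is.null(links) && nrow(links) > 0) {
    keep <- links$link_type != "ABC" |
      (is.finite(links$score) & links$score >= cfg$abc_min_score)
    lk <- links[keep, , drop = FALSE]
    if (nrow(lk) > 0) {
      gl <- granges_0based(lk$chrom, lk$start, lk$end)
      ov <- GenomicRanges::findOverlaps(gv, gl)
      hit_type <- lk$link_type[S4Vectors::subjectHits(ov)]
      add(S4Vectors::queryHits(ov)[hit_type == "ABC"],
          lk$gene_id[S4Vectors::subjectHits(ov)][hit_type == "ABC"], "ABC")
      add(S4Vectors::queryHits(ov)[hit_type != "ABC"],
          lk$gene_id[S4Vectors::subjectHits(ov)][hit_type != "ABC"], "PCHiC")
    }
  }
  snp_peak <- NULL
  if (!is.null(gpk)) {
    snp_peak <- GenomicRanges::findOverlaps(gv, gpk)
    if (any(active)) {
      near <- GenomicRanges::findOverlaps(gpk, gprom[active],
                                          maxgap = cfg$nearby_ocr_bp)
      # peak index -> genes with an active promoter within range
      near_df <- unique(data.frame(
        peak = S4Vectors::queryHits(near),
        gene_id = prom$gene_id[active][S4Vectors::subjectHits(near)],
        stringsAsFactors = FALSE))
      sp <- data.frame(vidx = S4Vectors::queryHits(snp_peak),
                       peak = S4Vectors::subjectHits(snp_peak))
      mg <- merge(sp, near_df, by = "peak")
      add(mg$vidx, mg$gene_id, "NearbyOCR")
    }
  }

  ## stage 3: UTR outside open chromatin
  ut <- expand_gene_intervals(gene_models, "utrs")
  if (nrow(ut) > 0) {
    in_peak <- if (is.null(gpk)) rep(FALSE, m) else IRanges::overlapsAny(gv, gpk)
    ov <- GenomicRanges::findOverlaps(gv, granges_0based(ut$chrom, ut$start, ut$end))
    qh <- S4Vectors::queryHits(ov)
    keep <- !in_peak[qh]
    add(qh[keep], ut$gene_id[S4Vectors::subjectHits(ov)][keep], "UTR")
  }

  linked <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(variant_id = character(), gene_id = character(),
               weight = numeric(), method = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  if (cfg$link_mode == "first-hit" && nrow(linked) > 0) {
    stg <- stage_of[linked$method]
    best_stage <- tapply(stg, linked$variant_id, min)
    linked <- linked[stg == best_stage[linked$variant_id], , drop = FALSE]
  }
  # deduplicate snp-gene pairs, keeping the strongest method
  if (nrow(linked) > 0) {
    ord <- order(linked$variant_id, linked$gene_id, method_rank[linked$method])
    linked <- linked[ord, , drop = FALSE]
    linked <- linked[!duplicated(linked[c("variant_id", "gene_id")]), ,
                     drop = FALSE]
  }

  ## stage 4: distance decay for SNPs with no link
  unlinked <- setdiff(variants$variant_id, linked$variant_id)
  if (length(unlinked) > 0) {
    vi <- match(unlinked, variants$variant_id)
    gw <- GenomicRanges::GRanges(
      gene_models$chrom,
      IRanges::IRanges(start = pmax(gene_models$tss - cfg$max_distance_bp, 1L),
                       end = gene_models$tss + cfg$max_distance_bp))
    ov <- GenomicRanges::findOverlaps(gv[vi], gw)
    if (length(ov) > 0) {
      qi <- vi[S4Vectors::queryHits(ov)]
      gi <- S4Vectors::subjectHits(ov)
      d <- abs(variants$pos[qi] - gene_models$tss[gi])
      out4 <- data.frame(variant_id = variants$variant_id[qi],
                         gene_id = gene_models$gene_id[gi],
                         weight = exp(-d / cfg$decay_bp),
                         method = "Distance", distance = as.numeric(d),
                         stringsAsFactors = FALSE)
      linked <- rbind(linked, out4)
    }
    still <- setdiff(unlinked, linked$variant_id)
    if (length(still) > 0) {
      message(length(still),
              " SNP(s) with no gene within range and no links; no entries")
    }
  }
  rownames(linked) <- NULL
  linked
}

#' Normalize SNP-to-gene weights over genes
#'
#' Adds `norm_weight = weight / sum(weight over genes of the same SNP)` so
#' that each SNP distributes exactly one unit of causal evidence.
#'
#' @param weights Data frame from [link_snp_to_genes()].
#' @return `weights` with an added `norm_weight` column.
#' @export
normalize_weights <- function(weights) {
  if (nrow(weights) == 0) {
    weights$norm_weight <- numeric(0)
    return(weights)
  }
  tot <- stats::ave(weights$weight, weights$variant_id, FUN = sum)
  bad <- tot <= 0
  if (any(bad)) {
    message("dropping ", length(unique(weights$variant_id[bad])),
            " SNP(s) with zero total weight")
    weights <- weights[!bad, , drop = FALSE]
    tot <- tot[!bad]
  }
  weights$norm_weight <- weights$weight / tot
  weights
}

#' Compute gene PIPs from fine-mapping results and normalized weights
#'
#' `gene_pip_g = sum_i pip_i * norm_weight_ig` over all blocks. For a gene
#' confined to one block the gene PIP is bounded by 1; a gene drawing from
#' several blocks is flagged `multi_block` and its PIP is interpreted as the
#' expected number of causal variants targeting the gene.
#'
#' @param finemap Data frame with `block_id`, `variant_id`, `pip` (e.g. from
#'   [finemap_blocks()]).
#' @param weights Normalized weight table from [normalize_weights()].
#' @param report_threshold Fractional-PIP cutoff for the support table
#'   (default 0.1).
#' @return An object of class `gene_pip_result` with elements `genes` (gene,
#'   gene_pip, n_blocks, multi_block), `support` (SNPs with
#'   `fractional_pip >= report_threshold`), `locus_contrib` (per block x
#'   gene summed fractional PIPs) and `full` (every SNP-gene contribution).
#' @export
compute_gene_pips <- function(finemap, weights, report_threshold = 0.1) {
  stopifnot(all(c("block_id", "variant_id", "pip") %in% names(finemap)),
            "norm_weight" %in% names(weights))
  full <- merge(weights,
                finemap[, c("block_id", "variant_id", "pip")],
                by = "variant_id")
  full$fractional_pip <- full$pip * full$norm_weight
  gene_pip <- tapply(full$fractional_pip, full$gene_id, sum)
  n_blocks <- tapply(full$block_id, full$gene_id, function(b) length(unique(b)))
  genes <- data.frame(gene_id = names(gene_pip),
                      gene_pip = as.numeric(gene_pip),
                      n_blocks = as.integer(n_blocks[names(gene_pip)]),
                      stringsAsFactors = FALSE)
  genes$multi_block <- genes$n_blocks > 1
  genes <- genes[order(-genes$gene_pip, genes$gene_id), ]
  rownames(genes) <- NULL

  support <- full[full$fractional_pip >= report_threshold,
                  c("gene_id", "variant_id", "pip", "norm_weight",
                    "fractional_pip", "method"), drop = FALSE]
  support <- support[order(support$gene_id, -support$fractional_pip), ]
  rownames(support) <- NULL

  agg <- stats::aggregate(fractional_pip ~ block_id + gene_id, data = full, sum)
  names(agg)[names(agg) == "fractional_pip"] <- "contribution"
  structure(list(genes = genes, support = support, locus_contrib = agg,
                 full = full, report_threshold = report_threshold),
            class = "gene_pip_result")
}

#' @export
print.gene_pip_result <- function(x, ...) {
  cat("Gene PIPs for", nrow(x$genes), "gene(s);",
      sum(x$genes$gene_pip >= 0.8), "at gene PIP >= 0.8\n")
  print(utils::head(x$genes, 10), row.names = FALSE)
  invisible(x)
}

#' Credible gene set per locus
#'
#' For each locus, genes are ranked by their within-locus contribution
#' (descending, ties by gene id) and the smallest prefix whose contribution
#' sum reaches `coverage` times the locus's total gene-mapped PIP is
#' returned. Multi-block genes contribute only their within-locus share.
#'
#' @param result A `gene_pip_result` (or its `locus_contrib` data frame).
#' @param coverage Coverage level in `(0, 1]` (default 0.8).
#' @return Data frame with `block_id`, `rank`, `gene_id`, `contribution`,
#'   `cumulative`. Loci with no gene links are absent (flagged by message).
#' @export
credible_gene_set <- function(result, coverage = 0.8) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]")
  }
  contrib <- if (inherits(result, "gene_pip_result")) result$locus_contrib
             else result
  stopifnot(all(c("block_id", "gene_id", "contribution") %in% names(contrib)))
  out <- lapply(split(contrib, contrib$block_id), function(d) {
    d <- d[order(-d$contribution, d$gene_id), , drop = FALSE]
    total <- sum(d$contribution)
    if (total <= 0) return(NULL)
    cum <- cumsum(d$contribution)
    n <- which(cum >= coverage * total - 1e-12)[1]
    data.frame(block_id = d$block_id[seq_len(n)], rank = seq_len(n),
               gene_id = d$gene_id[seq_len(n)],
               contribution = d$contribution[seq_len(n)],
               cumulative = cum[seq_len(n)], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of distance-decay weight mass within a cutoff
#'
#' For the exponential decay weight `exp(-d / decay_scale)`, the fraction of
#' total weight mass within distance `cutoff` is
#' `1 - exp(-cutoff / decay_scale)`. At the default 50 kb scale, about 87%
#' of the mass lies within 100 kb.
#'
#' @param decay_scale Decay scale in bp (> 0).
#' @param cutoff Distance cutoff in bp (> 0).
#' @return The mass fraction in `[0, 1]`.
#' @examples
#' weight_mass_within(5e4, 1e5)   # 1 - exp(-2)
#' @export
weight_mass_within <- function(decay_scale, cutoff) {
  stopifnot(decay_scale > 0, cutoff > 0)
  1 - exp(-cutoff / decay_scale)
}

#' Precision of a nominated gene set
#'
#' @param nominated Non-empty character vector of nominated genes.
#' @param plausible Character vector of plausible (true) genes.
#' @return `length(intersect) / length(nominated)` over unique genes.
#' @export
evaluate_precision <- function(nominated, plausible) {
  nominated <- unique(nominated)
  if (length(nominated) == 0) stop("empty nominated gene set")
  length(intersect(nominated, plausible)) / length(nominated)
}

#' Nearest-gene baseline
#'
#' Nominates, for each locus, the gene whose TSS is closest to the locus's
#' top SNP (ties broken by ascending gene id).
#'
#' @param top_snps Data frame with `block_id`, `chrom`, `pos` (one row per
#'   locus, typically the largest-|z| SNP).
#' @param gene_models Gene-model data frame.
#' @return Data frame with `block_id`, `gene_id`, `distance`.
#' @export
nearest_gene_baseline <- function(top_snps, gene_models) {
  out <- lapply(seq_len(nrow(top_snps)), function(i) {
    g <- gene_models[gene_models$chrom == top_snps$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- abs(g$tss - top_snps$pos[i])
    ord <- order(d, g$gene_id)
    data.frame(block_id = top_snps$block_id[i], gene_id = g$gene_id[ord[1]],
               distance = d[ord[1]], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
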