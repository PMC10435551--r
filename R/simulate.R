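# Synthetic-data generators. These produce every input the pipeline reads,
# with the statistical structure the models assume and with ground truth for
# recovery tests: AR(1)-correlated z-scores with a single causal variant per
# block placed preferentially in annotated SNPs, gene landscapes with
# enhancer loops, and cell-type-mixture eQTL effects.

#' Simulate an AR(1) LD correlation matrix
#'
#' `R[j, k] = rho^|j - k|`; symmetric positive-definite with unit diagonal.
#'
#' @param m Number of SNPs (>= 1).
#' @param rho AR(1) decay in `[0, 1)`.
#' @return m x m correlation matrix.
#' @export
simulate_ld <- function(m, rho) {
  stopifnot(m >= 1)
  if (!is.numeric(rho) || rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  rho^abs(outer(seq_len(m), seq_len(m), `-`))
}

#' Simulate z-scores for one LD block
#'
#' Draws `z ~ MVN(lambda * R[, causal], R)`: the causal SNP's expected
#' z-score is `lambda` and its LD neighbours inherit the signal
#' proportionally to their correlation (the standard summary-statistic
#' likelihood).
#'
#' @param R LD correlation matrix.
#' @param causal_index Index of the causal SNP.
#' @param lambda Causal effect on the z-score scale (`sqrt(n) * beta`).
#' @param seed Optional seed for a reproducible draw.
#' @param chol_R Optional pre-computed upper Cholesky factor of `R`.
#' @return Numeric z-score vector.
#' @export
simulate_block <- function(R, causal_index, lambda, seed = NULL,
                           chol_R = NULL) {
  m <- nrow(R)
  if (causal_index < 1 || causal_index > m) stop("invalid causal index")
  if (!is.null(seed)) set.seed(seed)
  L <- chol_R %||% chol(R)
  drop(lambda * R[, causal_index] + crossprod(L, stats::rnorm(m)))
}

#' Simulation configuration for an annotated genome
#'
#' Defaults match the study conditions used throughout the test suite:
#' 1000 LD blocks of 100 SNPs, AR(1) LD with `rho = 0.9`, a causal effect of
#' `lambda = 5` on the z-score scale, and one binary annotation covering 10%
#' of SNPs in which causal variants are enriched 8-fold (`ln 8` log-odds).
#'
#' @param n_blocks,snps_per_block Genome dimensions.
#' @param ar1_rho AR(1) LD decay in `[0, 1)`.
#' @param lambda Causal effect size on the z scale; with
#'   `lambda_dist = "normal"` it is the standard deviation of a
#'   block-specific effect drawn from `N(0, lambda^2)` (the well-specified
#'   regime for calibration studies).
#' @param lambda_dist `"fixed"` or `"normal"`.
#' @param annotation_logodds Named vector of true enrichment log-odds.
#' @param annotation_freq Named vector (same names) of annotation SNP
#'   fractions; must sum to < 1 (the remainder is category `other`).
#' @param seed Mandatory random seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 1000, snps_per_block = 100, ar1_rho = 0.9,
                       lambda = 5, lambda_dist = c("fixed", "normal"),
                       annotation_logodds = c(in_ocr = log(8)),
                       annotation_freq = c(in_ocr = 0.1),
                       seed = 1) {
  stopifnot(identical(sort(names(annotation_logodds)),
                      sort(names(annotation_freq))),
            sum(annotation_freq) < 1, ar1_rho >= 0, ar1_rho < 1)
  structure(list(n_blocks = n_blocks, snps_per_block = snps_per_block,
                 ar1_rho = ar1_rho, lambda = lambda,
                 lambda_dist = match.arg(lambda_dist),
                 annotation_logodds = annotation_logodds,
                 annotation_freq = annotation_freq, seed = seed),
            class = "sim_config")
}

#' Simulate an annotated genome with enriched causal placement
#'
#' Each block carries exactly one causal variant, placed among the block's
#' SNPs with probability proportional to `exp(alpha . A_j)`; z-scores are
#' drawn from the block's LD-aware likelihood. Annotation categories are
#' mutually exclusive by construction, so the returned annotation table is
#' disjoint.
#'
#' @param cfg A [sim_config()].
#' @return List with `variants` (variant_id, chrom, pos, z, block_id),
#'   `blocks` (BED-convention data frame), `annotations` (disjoint table as
#'   from [build_snp_annotations()]), `truth` (block_id, causal_variant_id,
#'   causal_index, effect, category) and `R` (the shared LD matrix).
#' @export
simulate_annotated_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nb <- cfg$n_blocks
  m <- cfg$snps_per_block
  total <- nb * m
  cats <- names(cfg$annotation_logodds)
  freq <- cfg$annotation_freq[cats]

  category <- sample(c(cats, "other"), total, replace = TRUE,
                     prob = c(freq, 1 - sum(freq)))
  A <- matrix(0L, nrow = total, ncol = length(cats),
              dimnames = list(NULL, cats))
  for (k in seq_along(cats)) A[category == cats[k], k] <- 1L

  # causal placement within block: prob proportional to exp(alpha . A)
  w <- exp(drop(A %*% cfg$annotation_logodds[cats]))
  block_of <- rep(seq_len(nb), each = m)
  causal_local <- vapply(seq_len(nb), function(b) {
    sample.int(m, 1, prob = w[block_of == b])
  }, 1L)

  effect <- switch(cfg$lambda_dist,
                   fixed = rep(cfg$lambda, nb),
                   normal = stats::rnorm(nb, 0, cfg$lambda))

  R <- simulate_ld(m, cfg$ar1_rho)
  L <- chol(R)
  E <- matrix(stats::rnorm(total), nrow = m, ncol = nb)
  Z <- crossprod(L, E) +
    R[, causal_local, drop = FALSE] %*% diag(effect, nrow = nb)

  block_id <- paste0("B", block_of)
  local_idx <- rep(seq_len(m), times = nb)
  block_span <- m * 1000
  variants <- data.frame(
    variant_id = paste0("b", block_of, "_s", local_idx),
    chrom = "chr1",
    pos = as.integer((block_of - 1) * block_span + (local_idx - 1) * 1000 + 1),
    z = as.numeric(Z),
    block_id = block_id,
    stringsAsFactors = FALSE)

  blocks <- data.frame(block_id = paste0("B", seq_len(nb)), chrom = "chr1",
                       start = as.integer((seq_len(nb) - 1) * block_span),
                       end = as.integer(seq_len(nb) * block_span),
                       stringsAsFactors = FALSE)

  annotations <- data.frame(variant_id = variants$variant_id,
                            category = category, stringsAsFactors = FALSE)
  annotations <- cbind(annotations, as.data.frame(A, check.names = FALSE))
  attr(annotations, "disjoint") <- TRUE
  attr(annotations, "precedence") <- cats

  causal_global <- (seq_len(nb) - 1) * m + causal_local
  truth <- data.frame(block_id = paste0("B", seq_len(nb)),
                      causal_variant_id = variants$variant_id[causal_global],
                      causal_index = causal_local,
                      effect = effect,
                      category = category[causal_global],
                      stringsAsFactors = FALSE)
  list(variants = variants, blocks = blocks, annotations = annotations,
       truth = truth, R = R)
}

#' Configuration for the gene-landscape simulator
#'
#' The generator emulates GWAS loci in which a single causal variant targets
#' a single causal gene through one of four routes: an exonic variant
#' (`p_exon`), a distal enhancer linked to the gene's promoter by an ABC
#' loop (`p_loop`; with probability `p_loop_decoy` the enhancer sits closer
#' to a different, non-target gene, the situation where nearest-gene
#' assignment fails), open chromatin near the active promoter (`p_nearby`),
#' or plain TSS proximity (the remainder).
#'
#' @param n_loci,genes_per_locus,snps_per_locus Landscape dimensions.
#' @param ar1_rho,lambda LD decay and causal z-scale effect.
#' @param p_exon,p_loop,p_nearby Scenario probabilities (remainder =
#'   distance scenario).
#' @param p_loop_decoy Probability that a loop enhancer is placed nearest to
#'   a decoy gene.
#' @param seed Mandatory random seed.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_loci = 100, genes_per_locus = 5,
                             snps_per_locus = 40, ar1_rho = 0.5, lambda = 6,
                             p_exon = 0.25, p_loop = 0.45, p_nearby = 0.15,
                             p_loop_decoy = 0.7, seed = 1) {
  stopifnot(p_exon + p_loop + p_nearby <= 1, genes_per_locus >= 2)
  structure(list(n_loci = n_loci, genes_per_locus = genes_per_locus,
                 snps_per_locus = snps_per_locus, ar1_rho = ar1_rho,
                 lambda = lambda, p_exon = p_exon, p_loop = p_loop,
                 p_nearby = p_nearby, p_loop_decoy = p_loop_decoy,
                 seed = seed),
            class = "landscape_config")
}

#' Simulate gene landscapes with a designated causal gene per locus
#'
#' @param cfg A [landscape_config()].
#' @return List with `variants`, `blocks`, `gene_models`, `peaks`, `links`,
#'   and `truth` (block_id, causal_gene, causal_variant_id, scenario).
#' @export
simulate_gene_landscape <- function(cfg = landscape_config()) {
  stopifnot(inherits(cfg, "landscape_config"))
  set.seed(cfg$seed)
  span <- 3e6
  locus_parts <- lapply(seq_len(cfg$n_loci), function(i) {
    o <- (i - 1) * span
    slots <- o + 1e6 + (0:16) * 6e4
    tss <- sort(sample(slots, cfg$genes_per_locus)) +
      sample(-5000:5000, cfg$genes_per_locus, replace = TRUE)
    gid <- paste0("L", i, "_g", seq_len(cfg$genes_per_locus))
    genes <- data.frame(gene_id = gid, chrom = "chr1", strand = "+",
                        tss = as.integer(tss), stringsAsFactors = FALSE)
    genes$exons <- lapply(tss, function(t) {
      matrix(as.integer(c(t - 1, t + 8999, t + 18999,
                          t + 499, t + 9499, t + 19999)),
             ncol = 2, dimnames = list(NULL, c("start", "end")))
    })
    genes$utrs <- lapply(tss, function(t) {
      matrix(as.integer(c(t + 19999, t + 20499)), ncol = 2,
             dimnames = list(NULL, c("start", "end")))
    })
    # promoter open chromatin at every TSS: all promoters are active
    peaks <- data.frame(peak_id = paste0(gid, "_prom"), chrom = "chr1",
                        start = as.integer(tss - 1500),
                        end = as.integer(tss + 200),
                        stringsAsFactors = FALSE)
    links <- NULL

    cg <- sample.int(cfg$genes_per_locus, 1)
    ct <- tss[cg]
    u <- stats::runif(1)
    if (u < cfg$p_exon) {
      scenario <- "exon"
      causal_pos <- ct + 100
    } else if (u < cfg$p_exon + cfg$p_loop) {
      scenario <- "loop"
      target <- if (stats::runif(1) < cfg$p_loop_decoy && cfg$genes_per_locus > 1) {
        sample(setdiff(seq_len(cfg$genes_per_locus), cg), 1)
      } else cg
      center <- NA
      for (try in 1:50) {
        cand <- tss[target] + sample(c(-1, 1), 1) * round(stats::runif(1, 3e4, 5e4))
        if (min(abs(cand - tss)) >= 2.6e4 &&
            !any(cand > tss & cand < tss + 2.1e4)) {
          center <- cand
          break
        }
      }
      if (is.na(center)) center <- tss[target] - 4e4
      peaks <- rbind(peaks, data.frame(
        peak_id = paste0("L", i, "_enh"), chrom = "chr1",
        start = as.integer(center - 250), end = as.integer(center + 250),
        stringsAsFactors = FALSE))
      links <- data.frame(chrom = "chr1", start = as.integer(center - 250),
                          end = as.integer(center + 250),
                          gene_id = gid[cg], link_type = "ABC", score = 0.05,
                          stringsAsFactors = FALSE)
      causal_pos <- center
    } else if (u < cfg$p_exon + cfg$p_loop + cfg$p_nearby) {
      scenario <- "nearby_ocr"
      center <- ct + 12e3 + round(stats::runif(1, 0, 4e3))
      peaks <- rbind(peaks, data.frame(
        peak_id = paste0("L", i, "_near"), chrom = "chr1",
        start = as.integer(center - 250), end = as.integer(center + 250),
        stringsAsFactors = FALSE))
      causal_pos <- center
    } else {
      scenario <- "distance"
      causal_pos <- ct - round(stats::runif(1, 5e3, 2e4))
    }

    null_pos <- round(stats::runif(cfg$snps_per_locus - 1,
                                   o + 0.95e6, o + 2.15e6))
    pos <- as.integer(c(causal_pos, null_pos))
    while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1L
    ord <- order(pos)
    pos <- pos[ord]
    causal_idx <- which(ord == 1)
    R <- simulate_ld(cfg$snps_per_locus, cfg$ar1_rho)
    z <- simulate_block(R, causal_idx, cfg$lambda)
    variants <- data.frame(
      variant_id = paste0("L", i, "_s", seq_len(cfg$snps_per_locus)),
      chrom = "chr1", pos = pos, z = z, block_id = paste0("L", i),
      stringsAsFactors = FALSE)
    list(genes = genes, peaks = peaks, links = links, variants = variants,
         block = data.frame(block_id = paste0("L", i), chrom = "chr1",
                            start = as.integer(o), end = as.integer(o + span),
                            stringsAsFactors = FALSE),
         truth = data.frame(block_id = paste0("L", i),
                            causal_gene = gid[cg],
                            causal_variant_id = variants$variant_id[causal_idx],
                            scenario = scenario, stringsAsFactors = FALSE))
  })
  bind <- function(el) {
    do.call(rbind, lapply(locus_parts, `[[`, el))
  }
  list(variants = bind("variants"), blocks = bind("block"),
       gene_models = bind("genes"), peaks = bind("peaks"),
       links = bind("links"), truth = bind("truth"))
}

#' Simulate categorized eQTL records and matched controls
#'
#' Generates fine-mapped eQTL records whose category proportions are the
#' control (background) proportions multiplied by known fold enrichments,
#' with category-specific tissue-sharing probabilities; controls follow the
#' background proportions (emulating LD/MAF-matched control SNPs).
#'
#' @param n_eqtl,n_control Record counts.
#' @param control_props Named vector of background category proportions
#'   (sums to 1).
#' @param folds Named vector (same names) of true fold enrichments.
#' @param p_share Named vector (same names) of tissue-sharing probabilities.
#' @param n_tissues_max Number of possible secondary tissues (default 48).
#' @param seed Mandatory random seed.
#' @return List with `eqtls` (variant_id, gene_id, pip, category,
#'   n_tissues_active, shared), `controls` (variant_id, category), and
#'   `truth` (the generating parameters).
#' @export
simulate_eqtl_records <- function(n_eqtl = 1000, n_control = 1000,
                                  control_props = c("intron_ocr:specific:CM" = 0.02,
                                                    "intron_ocr:shared_2_3" = 0.02,
                                                    "intron_ocr:shared_4plus" = 0.01,
                                                    exon = 0.05,
                                                    unassigned = 0.90),
                                  folds = c("intron_ocr:specific:CM" = 9,
                                            "intron_ocr:shared_2_3" = 2,
                                            "intron_ocr:shared_4plus" = 26,
                                            exon = 3,
                                            unassigned = NA),
                                  p_share = c("intron_ocr:specific:CM" = 0.3,
                                              "intron_ocr:shared_2_3" = 0.7,
                                              "intron_ocr:shared_4plus" = 0.9,
                                              exon = 0.8,
                                              unassigned = 0.6),
                                  n_tissues_max = 48, seed = 1) {
  stopifnot(identical(names(control_props), names(folds)),
            identical(names(control_props), names(p_share)),
            abs(sum(control_props) - 1) < 1e-8)
  set.seed(seed)
  cats <- names(control_props)
  # the unassigned (residual) fold absorbs the normalization
  f <- folds
  raw <- control_props * ifelse(is.na(f), 1, f)
  free <- is.na(f)
  if (any(free)) {
    raw[free] <- pmax(1 - sum(raw[!free]), 0) *
      control_props[free] / sum(control_props[free])
  }
  eqtl_props <- raw / sum(raw)
  cat_e <- sample(cats, n_eqtl, replace = TRUE, prob = eqtl_props)
  shared <- stats::rbinom(n_eqtl, 1, p_share[cat_e]) == 1
  n_tissues <- 1L + stats::rbinom(n_eqtl, n_tissues_max,
                                  0.85 * p_share[cat_e])
  eqtls <- data.frame(variant_id = paste0("eqtn", seq_len(n_eqtl)),
                      gene_id = paste0("gene", seq_len(n_eqtl)),
                      pip = stats::runif(n_eqtl, 0.8, 1),
                      category = cat_e,
                      n_tissues_active = n_tissues,
                      shared = shared, stringsAsFactors = FALSE)
  controls <- data.frame(variant_id = paste0("ctrl", seq_len(n_control)),
                         category = sample(cats, n_control, replace = TRUE,
                                           prob = control_props),
                         stringsAsFactors = FALSE)
  list(eqtls = eqtls, controls = controls,
       truth = list(eqtl_props = eqtl_props, control_props = control_props,
                    folds = eqtl_props / control_props, p_share = p_share))
}

#' Simulate a bulk-tissue eQTL mixture
#'
#' Bulk expression of one gene in `n` individuals: a cell-type-specific
#' eQTL contributes a diluted slope `cell_fraction * beta` (the effect is
#' present in one cell type occupying `cell_fraction` of the tissue), a
#' shared eQTL the full slope `beta`; residual noise is standard normal.
#'
#' @param n Sample size.
#' @param beta Per-allele effect size.
#' @param cell_fraction Causal cell-type fraction in `(0, 1]`.
#' @param specific Logical; simulate the cell-type-specific (`TRUE`) or
#'   shared (`FALSE`) eQTL.
#' @param maf Minor allele frequency (default 0.3).
#' @param seed Mandatory random seed.
#' @return List with `data` (genotype, expression) and `truth` (the bulk
#'   slope).
#' @export
simulate_eqtl_mixture <- function(n = 200, beta = 0.3, cell_fraction = 0.2,
                                  specific = TRUE, maf = 0.3, seed = 1) {
  if (cell_fraction <= 0 || cell_fraction > 1) {
    stop("cell_fraction must be in (0, 1]")
  }
  set.seed(seed)
  slope <- if (specific) cell_fraction * beta else beta
  g <- stats::rbinom(n, 2, maf)
  y <- slope * g + stats::rnorm(n)
  list(data = data.frame(genotype = g, expression = y),
       truth = list(bulk_slope = slope))
}
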