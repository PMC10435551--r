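# PIP partitioning: summed PIPs by disjoint annotation category, genome-wide
# or per locus; locus-level cell-type assignment from OCR subcategories.

#' Partition SNP PIPs into disjoint annotation categories
#'
#' The summed PIP of a category is interpretable as the expected number of
#' causal variants in that category (genome-wide scope) or, per locus, as
#' the probability that the locus's causal variant falls into the category.
#'
#' @param finemap Data frame with `variant_id`, `block_id`, `pip`.
#' @param annot Disjoint annotation table from [build_snp_annotations()]
#'   (`variant_id`, `category`; attribute `disjoint` must be `TRUE`), or any
#'   data frame with those columns plus a true `disjoint` attribute.
#' @param scope `"genomewide"` or `"by_locus"`.
#' @return Data frame with `scope`/`block_id`, `category`, `summed_pip`,
#'   `proportion` (proportions sum to 1 within each scope).
#' @export
partition_pips <- function(finemap, annot,
                           scope = c("genomewide", "by_locus")) {
  scope <- match.arg(scope)
  if (!isTRUE(attr(annot, "disjoint"))) {
    stop("annotation matrix must be disjoint for PIP partitioning")
  }
  d <- merge(finemap[, c("variant_id", "block_id", "pip")],
             annot[, c("variant_id", "category")], by = "variant_id")
  if (scope == "genomewide") {
    s <- tapply(d$pip, d$category, sum)
    out <- data.frame(scope = "genomewide", category = names(s),
                      summed_pip = as.numeric(s),
                      proportion = as.numeric(s) / sum(s),
                      stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(pip ~ block_id + category, data = d, sum)
    tot <- stats::ave(agg$pip, agg$block_id, FUN = sum)
    out <- data.frame(block_id = agg$block_id, category = agg$category,
                      summed_pip = agg$pip, proportion = agg$pip / tot,
                      stringsAsFactors = FALSE)
    out <- out[order(out$block_id, -out$summed_pip), ]
  }
  rownames(out) <- NULL
  out
}

#' Locus-level cell-type assignment from OCR categories
#'
#' Loci whose total PIP mass in open chromatin falls below `ocr_floor` are
#' excluded. For the remaining loci the table reports, per OCR category,
#' both the raw per-locus proportion and the share renormalized over OCR
#' categories only (the cell-type probability view).
#'
#' @param locus_partition Per-locus partition from
#'   `partition_pips(..., scope = "by_locus")`.
#' @param ocr_categories Character vector naming the OCR categories (e.g.
#'   `specific:CM`, `shared_2_3`, ...).
#' @param ocr_floor Minimum summed OCR PIP for a locus to be assigned
#'   (default 0.25).
#' @return Data frame with `block_id`, `category`, `summed_pip`,
#'   `proportion` (raw, of the locus total) and `share_ocr` (renormalized
#'   over OCR categories).
#' @export
locus_celltype_assignment <- function(locus_partition, ocr_categories,
                                      ocr_floor = 0.25) {
  stopifnot(all(c("block_id", "category", "summed_pip", "proportion") %in%
                  names(locus_partition)))
  d <- locus_partition[locus_partition$category %in% ocr_categories, ,
                       drop = FALSE]
  if (nrow(d) == 0) return(d)
  ocr_tot_prop <- tapply(d$proportion, d$block_id, sum)
  keep_blocks <- names(ocr_tot_prop)[ocr_tot_prop >= ocr_floor]
  d <- d[d$block_id %in% keep_blocks, , drop = FALSE]
  if (nrow(d) == 0) return(d)
  tot <- stats::ave(d$summed_pip, d$block_id, FUN = sum)
  d$share_ocr <- d$summed_pip / tot
  d <- d[order(d$block_id, -d$share_ocr), ]
  rownames(d) <- NULL
  d
}
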