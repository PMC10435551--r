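# SNP-level functional annotation: peak sharing classes, disjoint annotation
# categories with precedence, and eQTL category assignment.

#' Classify open chromatin peaks by cell-type sharing
#'
#' Peaks labelled differentially accessible (DA) in exactly one cell type are
#' cell-type-specific. DA peaks occurring in multiple cell types are moved to
#' the shared classes according to the number of cell types in which they are
#' DA. Non-DA peaks are binarized per cell type at the top accessibility
#' quantile (default top 25%, ties at the threshold value included) and
#' classified by the number of cell types in which they are highly
#' accessible: 2-3 gives `shared_2_3`, 4 or more gives `shared_4plus`, and
#' peaks highly accessible in at most one cell type remain `non_DA`.
#'
#' @param acc Numeric matrix of normalized accessibility, peaks x cell types
#'   (column names are the cell-type labels; row names the peak ids).
#' @param da List (length `nrow(acc)`) of character vectors naming the cell
#'   types in which each peak is DA (`character(0)` for non-DA peaks).
#' @param q Quantile defining "highly accessible" (default 0.75).
#' @return Character vector of categories (`specific:<ct>`, `shared_2_3`,
#'   `shared_4plus`, `non_DA`), named by peak id when `acc` has row names.
#' @export
classify_peak_sharing <- function(acc, da, q = 0.75) {
  stopifnot(is.matrix(acc), ncol(acc) >= 2, !is.null(colnames(acc)))
  if (any(acc < 0)) stop("accessibility values must be >= 0")
  if (length(da) != nrow(acc)) stop("da must have one entry per peak")
  cell_types <- colnames(acc)
  unknown <- setdiff(unique(unlist(da)), cell_types)
  if (length(unknown) > 0) {
    stop("unknown cell type(s) in da labels: ", paste(unknown, collapse = ", "))
  }
  thr <- apply(acc, 2, stats::quantile, probs = q, names = FALSE)
  top <- sweep(acc, 2, thr, `>=`)
  n_top <- rowSums(top)
  n_da <- lengths(da)
  cat <- character(nrow(acc))
  cat[n_da == 1] <- paste0("specific:", vapply(da[n_da == 1], `[`, "", 1))
  cat[n_da >= 2 & n_da <= 3] <- "shared_2_3"
  cat[n_da >= 4] <- "shared_4plus"
  nda <- n_da == 0
  cat[nda & n_top >= 2 & n_top <= 3] <- "shared_2_3"
  cat[nda & n_top >= 4] <- "shared_4plus"
  cat[nda & n_top <= 1] <- "non_DA"
  names(cat) <- rownames(acc)
  cat
}

#' Build disjoint SNP-level annotations
#'
#' Overlaps each variant with a named list of interval tracks and assigns the
#' highest-precedence overlapping track as its category; variants overlapping
#' nothing get category `other`. A 1-based SNP position overlaps a 0-based
#' half-open track interval `[s, e)` iff `s < pos <= e`.
#'
#' @param variants Data frame with `variant_id`, `chrom`, `pos`.
#' @param tracks Named list of interval data frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param precedence Character vector ordering track names from highest to
#'   lowest precedence; must cover all of `names(tracks)` when
#'   `disjoint = TRUE`.
#' @param disjoint Logical; if `TRUE` (default) each SNP gets exactly one
#'   category and the one-hot rows sum to at most 1.
#' @return Data frame with `variant_id`, `category`, and one binary column
#'   per track; attributes `disjoint` and `precedence` record the
#'   configuration.
#' @export
build_snp_annotations <- function(variants, tracks,
                                  precedence = names(tracks),
                                  disjoint = TRUE) {
  stopifnot(is.list(tracks), length(tracks) > 0, !is.null(names(tracks)))
  if (disjoint && length(setdiff(names(tracks), precedence)) > 0) {
    stop("precedence must cover all track names when disjoint = TRUE: missing ",
         paste(setdiff(names(tracks), precedence), collapse = ", "))
  }
  precedence <- intersect(precedence, names(tracks))
  gv <- granges_snps(variants$chrom, variants$pos)
  m <- nrow(variants)
  hits <- matrix(FALSE, nrow = m, ncol = length(precedence),
                 dimnames = list(NULL, precedence))
  for (nm in precedence) {
    trk <- tracks[[nm]]
    if (nrow(trk) == 0) next
    gt <- granges_0based(trk$chrom, trk$start, trk$end)
    ov <- GenomicRanges::findOverlaps(gv, gt)
    hits[unique(S4Vectors::queryHits(ov)), nm] <- TRUE
  }
  if (disjoint) {
    first_hit <- apply(hits, 1, function(r) {
      w <- which(r)
      if (length(w) == 0) NA_integer_ else w[1]
    })
    category <- ifelse(is.na(first_hit), "other", precedence[first_hit])
    onehot <- matrix(0L, nrow = m, ncol = length(precedence),
                     dimnames = list(NULL, precedence))
    assigned <- which(!is.na(first_hit))
    onehot[cbind(assigned, first_hit[assigned])] <- 1L
  } else {
    category <- rep(NA_character_, m)
    onehot <- hits + 0L
  }
  out <- data.frame(variant_id = variants$variant_id, category = category,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(onehot, check.names = FALSE))
  attr(out, "disjoint") <- disjoint
  attr(out, "precedence") <- precedence
  out
}

#' Extract the numeric annotation matrix from a SNP annotation table
#'
#' @param annot Result of [build_snp_annotations()].
#' @param drop Annotation columns to exclude (the residual `other` category
#'   is never a column).
#' @return Numeric matrix variants x annotations.
#' @export
as_annotation_matrix <- function(annot, drop = character(0)) {
  cols <- setdiff(attr(annot, "precedence"), drop)
  as.matrix(annot[, cols, drop = FALSE]) * 1.0
}

#' Assign heart eQTL variants to functional categories
#'
#' Variants in peaks that overlap exons/UTRs, and variants in non-DA peaks,
#' are ambiguous and marked `filtered`. Variants in intronic peaks are
#' labelled by the peak sharing class (`intron_ocr:<class>`). Variants in an
#' exon or UTR outside any peak are `exon` / `utr`; everything else is
#' `unassigned`.
#'
#' @param eqtls Data frame with `variant_id`, `chrom`, `pos`.
#' @param peaks Data frame with `chrom`, `start`, `end`, `category` (from
#'   [classify_peak_sharing()]).
#' @param gene_models Gene-model data frame ([read_gene_models()]).
#' @return `eqtls` with an added `category` column.
#' @export
assign_eqtl_category <- function(eqtls, peaks, gene_models) {
  stopifnot(all(c("chrom", "start", "end", "category") %in% names(peaks)))
  gv <- granges_snps(eqtls$chrom, eqtls$pos)
  gp <- granges_0based(peaks$chrom, peaks$start, peaks$end)
  ex <- expand_gene_intervals(gene_models, "exons")
  ut <- expand_gene_intervals(gene_models, "utrs")
  gex <- granges_0based(ex$chrom, ex$start, ex$end)
  gut <- granges_0based(ut$chrom, ut$start, ut$end)
  body <- gene_body_intervals(gene_models)
  gbody <- granges_0based(body$chrom, body$start, body$end)

  peak_in_exut <- rep(FALSE, nrow(peaks))
  if (length(gex) > 0) {
    peak_in_exut <- peak_in_exut |
      IRanges::overlapsAny(gp, gex)
  }
  if (length(gut) > 0) {
    peak_in_exut <- peak_in_exut | IRanges::overlapsAny(gp, gut)
  }

  hit <- GenomicRanges::findOverlaps(gv, gp, select = "first")
  in_exon <- IRanges::overlapsAny(gv, gex)
  in_utr <- IRanges::overlapsAny(gv, gut)
  in_body <- IRanges::overlapsAny(gv, gbody)

  category <- rep("unassigned", nrow(eqtls))
  has_peak <- !is.na(hit)
  pk <- hit[has_peak]
  pk_cat <- peaks$category[pk]
  pk_ambig <- peak_in_exut[pk] | pk_cat == "non_DA"
  intronic <- in_body[has_peak] & !in_exon[has_peak] & !in_utr[has_peak]
  lab <- rep("unassigned", sum(has_peak))
  lab[intronic] <- paste0("intron_ocr:", pk_cat[intronic])
  lab[pk_ambig] <- "filtered"
  category[has_peak] <- lab
  category[!has_peak & in_exon] <- "exon"
  category[!has_peak & !in_exon & in_utr] <- "utr"
  eqtls$category <- category
  eqtls
}

# Flatten a gene-model list-column into one interval per row.
expand_gene_intervals <- function(gene_models, col = c("exons", "utrs")) {
  col <- match.arg(col)
  n_iv <- vapply(gene_models[[col]], nrow, 1L)
  idx <- rep(seq_len(nrow(gene_models)), n_iv)
  iv <- do.call(rbind, gene_models[[col]])
  if (is.null(iv)) iv <- matrix(integer(), ncol = 2)
  data.frame(gene_id = gene_models$gene_id[idx],
             chrom = gene_models$chrom[idx],
             start = iv[, 1], end = iv[, 2],
             stringsAsFactors = FALSE)
}

# Gene body span: from the first exon start to the last exon end.
gene_body_intervals <- function(gene_models) {
  start <- vapply(gene_models$exons, function(m)
    if (nrow(m) > 0) min(m[, 1]) else NA_integer_, 1L)
  end <- vapply(gene_models$exons, function(m)
    if (nrow(m) > 0) max(m[, 2]) else NA_integer_, 1L)
  keep <- !is.na(start)
  data.frame(gene_id = gene_models$gene_id[keep],
             chrom = gene_models$chrom[keep],
             start = start[keep], end = end[keep],
             stringsAsFactors = FALSE)
}
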