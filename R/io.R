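# Readers and writers for the standard file formats consumed by the
# pipeline. Conventions: GWAS positions are 1-based; every BED/BEDPE-style
# interval is 0-based half-open. Conversion happens here and nowhere else.

#' Read GWAS summary statistics
#'
#' Reads a tab-separated table of per-SNP association z-scores. Allele
#' columns, if present, are ignored (fine-mapping consumes z-scores and LD
#' only); this is noted once per call.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping the required fields
#'   (`chrom`, `pos`, `id`, `z`) to column names in the file.
#' @return A data frame of variant records with columns `variant_id`,
#'   `chrom`, `pos` (1-based integer), `z`, and `block_id` (`NA` until
#'   [assign_blocks()] is called).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(data.frame(chrom = "chr1", pos = c(101L, 201L), id = c("rs1", "rs2"),
#'                        z = c(1.5, -2)),
#'             f, sep = "\t", quote = FALSE, row.names = FALSE)
#' read_summary_stats(f)
#' @export
read_summary_stats <- function(path,
                               schema = c(chrom = "chrom", pos = "pos",
                                          id = "id", z = "z")) {
  if (!file.exists(path)) stop("summary statistics file not found: ", path)
  required <- c("chrom", "pos", "id", "z")
  if (!all(required %in% names(schema))) {
    stop("schema must map all of: ", paste(required, collapse = ", "))
  }
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema[required]), names(tab))
  if (length(missing_cols) > 0) {
    stop("summary statistics file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(tab), unname(schema))
  if (length(extra) > 0) {
    message("ignoring ", length(extra), " extra column(s) (e.g. alleles): ",
            paste(utils::head(extra, 4), collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("summary statistics file is empty: ", path)
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), z = numeric(), block_id = character(),
                      stringsAsFactors = FALSE))
  }
  z_chr <- tab[[schema[["z"]]]]
  z <- suppressWarnings(as.numeric(z_chr))
  bad <- which(!is.finite(z))
  if (length(bad) > 0) {
    stop("non-numeric or non-finite z-score at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value '", z_chr[bad[1]], "')")
  }
  pos_chr <- tab[[schema[["pos"]]]]
  pos <- suppressWarnings(as.integer(pos_chr))
  bad_pos <- which(is.na(pos) | pos < 1L)
  if (length(bad_pos) > 0) {
    stop("invalid position at data row(s): ",
         paste(utils::head(bad_pos, 5), collapse = ", "))
  }
  out <- data.frame(variant_id = tab[[schema[["id"]]]],
                    chrom = tab[[schema[["chrom"]]]],
                    pos = pos, z = z,
                    block_id = NA_character_,
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[c("chrom", "pos", "variant_id")])
  if (any(dup)) {
    stop("duplicated (chrom, pos, id) record(s) at data row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  sex <- out$chrom %in% c("chrX", "chrY", "X", "Y")
  if (any(sex)) {
    warning(sum(sex), " record(s) on chrX/chrY; inputs are expected to be ",
            "pre-filtered to autosomes")
  }
  message("read ", nrow(out), " variant record(s) from ", path)
  out
}

#' Read LD block definitions from BED
#'
#' @param path BED file (chrom, start, end, optionally name) with 0-based
#'   half-open intervals. Blocks without a name column are labelled
#'   `B1, B2, ...` in file order.
#' @return Data frame with columns `block_id`, `chrom`, `start`, `end`.
#' @export
read_ld_blocks <- function(path) {
  if (!file.exists(path)) stop("block BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("block BED needs at least 3 columns")
  blocks <- data.frame(
    block_id = if (ncol(tab) >= 4) as.character(tab[[4]]) else
      paste0("B", seq_len(nrow(tab))),
    chrom = as.character(tab[[1]]),
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    stringsAsFactors = FALSE)
  bad <- which(blocks$start >= blocks$end)
  if (length(bad) > 0) {
    stop("malformed interval (start >= end) at block row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyDuplicated(blocks$block_id)) stop("duplicated block ids")
  blocks
}

#' Assign variants to LD blocks
#'
#' A 1-based position `p` lies inside the 0-based half-open block
#' `[start, end)` iff `start < p <= end`. Variants falling in no block are
#' dropped with a logged count.
#'
#' @param variants Data frame from [read_summary_stats()].
#' @param blocks Data frame from [read_ld_blocks()]; blocks must not overlap
#'   within a chromosome.
#' @return `variants` restricted to covered positions, with `block_id` set.
#' @export
assign_blocks <- function(variants, blocks) {
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping LD blocks on ", ch)
    }
  }
  if (nrow(variants) == 0) return(variants)
  gv <- granges_snps(variants$chrom, variants$pos)
  gb <- granges_0based(blocks$chrom, blocks$start, blocks$end)
  hit <- GenomicRanges::findOverlaps(gv, gb)
  block_id <- rep(NA_character_, nrow(variants))
  block_id[S4Vectors::queryHits(hit)] <- blocks$block_id[S4Vectors::subjectHits(hit)]
  dropped <- sum(is.na(block_id))
  if (dropped > 0) {
    warning(dropped, " variant(s) outside all LD blocks were dropped")
  }
  variants$block_id <- block_id
  variants[!is.na(block_id), , drop = FALSE]
}

#' Read SNP/region-to-promoter links
#'
#' Reads a BEDPE-derived link table with one anchor interval per row
#' (columns: chrom, start, end, gene_id, link_type, score; `.` for a missing
#' score). ABC links must carry a score and are filtered at the activity
#' threshold; promoter-capture Hi-C links may have a null score.
#'
#' @param path Tab-separated link file without header.
#' @param abc_min_score Minimum ABC score retained (default 0.015).
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, `link_type` (`ABC`, `PCHIC` or `PROXIMAL_OCR`),
#'   `score` (`NA` allowed for non-ABC links).
#' @export
read_links <- function(path, abc_min_score = 0.015) {
  if (!file.exists(path)) stop("link file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "gene_id", "link_type", "score"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character", "character"))
  bad <- which(tab$start >= tab$end)
  if (length(bad) > 0) {
    stop("malformed interval (start >= end) at link row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ok_types <- c("ABC", "PCHIC", "PROXIMAL_OCR")
  if (!all(tab$link_type %in% ok_types)) {
    stop("unknown link type(s): ",
         paste(setdiff(unique(tab$link_type), ok_types), collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(ifelse(tab$score == ".", NA, tab$score)))
  if (any(tab$link_type == "ABC" & !is.finite(score))) {
    stop("ABC link(s) without a score at row(s): ",
         paste(utils::head(which(tab$link_type == "ABC" & !is.finite(score)), 5),
               collapse = ", "))
  }
  if (any(score[is.finite(score)] < 0)) stop("negative link score")
  tab$score <- score
  keep <- tab$link_type != "ABC" | tab$score >= abc_min_score
  if (any(!keep)) {
    message("filtered ", sum(!keep), " ABC link(s) below score ", abc_min_score)
  }
  tab[keep, , drop = FALSE]
}

#' Read gene models
#'
#' Reads a simplified gene-model table (one row per gene, longest-transcript
#' convention) with columns `gene_id`, `chrom`, `strand`, `tss` (1-based),
#' `exon_starts`, `exon_ends`, `utr_starts`, `utr_ends`. Interval columns are
#' comma-separated 0-based half-open coordinates; `.` or an empty field means
#' no intervals.
#'
#' @param path Tab-separated file with a header.
#' @return Data frame with list-columns `exons` and `utrs`, each a two-column
#'   integer matrix (`start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss",
            "exon_starts", "exon_ends", "utr_starts", "utr_ends")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("gene model file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  parse_iv <- function(s, e, row) {
    if (s %in% c("", ".") || e %in% c("", ".")) {
      return(matrix(integer(), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    st <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    en <- as.integer(strsplit(e, ",", fixed = TRUE)[[1]])
    if (length(st) != length(en) || any(is.na(st)) || any(is.na(en))) {
      stop("malformed interval list at gene row ", row)
    }
    if (any(st >= en)) stop("malformed interval (start >= end) at gene row ", row)
    if (is.unsorted(st)) stop("intervals not sorted at gene row ", row)
    matrix(c(st, en), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  out <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                    strand = tab$strand, tss = as.integer(tab$tss),
                    stringsAsFactors = FALSE)
  out$exons <- lapply(seq_len(nrow(tab)), function(i)
    parse_iv(tab$exon_starts[i], tab$exon_ends[i], i))
  out$utrs <- lapply(seq_len(nrow(tab)), function(i)
    parse_iv(tab$utr_starts[i], tab$utr_ends[i], i))
  if (anyDuplicated(out$gene_id)) stop("duplicated gene ids")
  out
}

#' Write gene models in the format read by [read_gene_models()]
#' @param genes Gene-model data frame with list-columns `exons`, `utrs`.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  fmt <- function(m, col) {
    if (nrow(m) == 0) "." else paste(m[, col], collapse = ",")
  }
  tab <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss = genes$tss,
                    exon_starts = vapply(genes$exons, fmt, "", col = 1L),
                    exon_ends = vapply(genes$exons, fmt, "", col = 2L),
                    utr_starts = vapply(genes$utrs, fmt, "", col = 1L),
                    utr_ends = vapply(genes$utrs, fmt, "", col = 2L),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables to a directory
#'
#' Writes each named element of `tables` to `<out_dir>/<name>.tsv`. Reals are
#' written with 15 significant digits so that a write/read round trip
#' reproduces integers bit-exactly and reals to at least 12 significant
#' digits.
#'
#' @param tables Named list of data frames (no list-columns).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (any(vapply(tab, is.list, TRUE))) {
      stop("table '", nm, "' has list-columns and cannot be written")
    }
    tab <- as.data.frame(lapply(tab, function(col) {
      if (is.double(col)) signif(col, 15) else col
    }), stringsAsFactors = FALSE, check.names = FALSE)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a BED file of intervals (e.g. peaks or annotation tracks)
#' @param path BED path (chrom, start, end, optional name as 4th column).
#' @param prefix Label prefix used when the file has no name column.
#' @return Data frame `name`, `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path, prefix = "iv") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(
    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else
      paste0(prefix, seq_len(nrow(tab))),
    chrom = as.character(tab[[1]]),
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    stop("malformed interval (start >= end) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Write intervals as BED
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally a
#'   name column (`name`, `peak_id` or `block_id`).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  name_col <- intersect(c("name", "peak_id", "block_id"), names(intervals))[1]
  tab <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    if (!is.na(name_col)) intervals[[name_col]] else ".",
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
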