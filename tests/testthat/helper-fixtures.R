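# Small programmatic fixtures shared across test files.

# One-row-per-gene model table with list-column intervals.
make_gene <- function(gene_id, tss, chrom = "chr1", strand = "+",
                      exons = NULL, utrs = NULL) {
  empty <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  tss = as.integer(tss), stringsAsFactors = FALSE)
  g$exons <- list(if (is.null(exons)) empty else
    matrix(as.integer(exons), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("start", "end"))))
  g$utrs <- list(if (is.null(utrs)) empty else
    matrix(as.integer(utrs), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("start", "end"))))
  g
}

make_genes <- function(...) do.call(rbind, list(...))

make_variants <- function(pos, chrom = "chr1", id = NULL, z = 0) {
  data.frame(variant_id = id %||% paste0("v", seq_along(pos)),
             chrom = chrom, pos = as.integer(pos),
             z = rep_len(z, length(pos)), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_bed_file <- function(df, path = tempfile(fileext = ".bed")) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}
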