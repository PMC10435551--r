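# Internal numeric helpers shared across modules.

# log(sum(exp(x))) with guard against overflow; -Inf input allowed.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(1 + exp(x)) computed stably.
log1pexp <- function(x) {
  ifelse(x > 35, x, log1p(exp(x)))
}

# Build a GRanges from 0-based half-open intervals.
granges_0based <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

# Build a width-1 GRanges from 1-based SNP positions.
granges_snps <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
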