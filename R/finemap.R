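# Single-effect Bayesian fine-mapping from z-scores. With a single causal
# signal per block, posterior weights depend only on the z-scores and the
# per-SNP priors; the LD matrix enters only through credible-set purity.

#' Log approximate Bayes factor for one SNP
#'
#' Wakefield-style approximate Bayes factor for a single-SNP effect on the
#' z-score scale (marginal standard error normalized to 1):
#' `logBF = 0.5 * log(1 / (1 + s2)) + (z^2 / 2) * s2 / (1 + s2)` where `s2`
#' is the prior effect variance.
#'
#' @param z Numeric vector of z-scores.
#' @param sigma0_sq Prior effect variance (scalar, >= 0).
#' @return Numeric vector of log Bayes factors against the null.
#' @examples
#' log_abf(0, 1)        # -0.5 * log(2)
#' log_abf(4, 1)        # 4 - 0.5 * log(2)
#' @export
log_abf <- function(z, sigma0_sq) {
  if (!is.numeric(sigma0_sq) || length(sigma0_sq) != 1 ||
      !is.finite(sigma0_sq) || sigma0_sq < 0) {
    stop("sigma0_sq must be a single finite value >= 0")
  }
  if (any(!is.finite(z))) stop("z must be finite")
  0.5 * log(1 / (1 + sigma0_sq)) + (z^2 / 2) * sigma0_sq / (1 + sigma0_sq)
}

#' Default prior-variance grid
#'
#' 21 log-spaced points in `[1e-3, 1e3]`, shared between fine-mapping and the
#' enrichment EM for profiling the effect-size prior variance.
#' @return Numeric vector of candidate `sigma0_sq` values.
#' @export
default_sigma0_grid <- function() {
  10^seq(-3, 3, length.out = 21)
}

#' Fine-map a single LD block under the single-effect model
#'
#' Computes per-SNP posterior inclusion probabilities
#' `pip_j = prior_j * BF_j / sum_k prior_k * BF_k` with a log-sum-exp guard.
#' This conditions on exactly one causal variant in the block (the regime for
#' genome-wide-significant loci); the explicit no-causal configuration is
#' used only inside the enrichment EM.
#'
#' @param z Numeric vector of z-scores.
#' @param priors Per-SNP prior causal probabilities; `NULL` for uniform.
#'   Must be non-negative with a positive sum; renormalized to sum to 1.
#' @param sigma0_sq Prior effect variance, or `"estimate"` to maximize the
#'   single-effect marginal likelihood `sum_k prior_k * BF_k` over
#'   `sigma0_grid`.
#' @param sigma0_grid Grid used when `sigma0_sq = "estimate"`.
#' @param variant_id,pos Optional identifiers and 1-based positions carried
#'   into the result (positions break credible-set ties).
#' @return An object of class `finemap_fit`: a list with `variants` (data
#'   frame `variant_id`, `pos`, `z`, `prior`, `log_abf`, `pip`),
#'   `sigma0_sq`, `loglik` (log of the prior-weighted mean Bayes factor) and
#'   `sigma0_on_boundary`.
#' @examples
#' fit <- finemap_block(c(4, 1, 0), sigma0_sq = 1)
#' fit$variants$pip
#' @export
finemap_block <- function(z, priors = NULL, sigma0_sq = "estimate",
                          sigma0_grid = default_sigma0_grid(),
                          variant_id = NULL, pos = NULL) {
  m <- length(z)
  if (m == 0) stop("empty block")
  if (is.null(priors)) priors <- rep(1 / m, m)
  if (length(priors) != m) stop("priors and z must have the same length")
  if (any(priors < 0)) stop("priors must be >= 0")
  s <- sum(priors)
  if (s <= 0) stop("all-zero priors")
  priors <- priors / s
  lp <- ifelse(priors > 0, log(priors), -Inf)

  boundary <- FALSE
  if (identical(sigma0_sq, "estimate")) {
    ll <- vapply(sigma0_grid, function(s2) logsumexp(lp + log_abf(z, s2)), 0)
    k <- which.max(ll)
    sigma0_sq <- sigma0_grid[k]
    boundary <- k == 1L || k == length(sigma0_grid)
  }
  labf <- log_abf(z, sigma0_sq)
  lw <- lp + labf
  loglik <- logsumexp(lw)
  pip <- exp(lw - loglik)

  variants <- data.frame(
    variant_id = variant_id %||% paste0("snp", seq_len(m)),
    pos = pos %||% seq_len(m),
    z = z, prior = priors, log_abf = labf, pip = pip,
    stringsAsFactors = FALSE)
  structure(list(variants = variants, sigma0_sq = sigma0_sq,
                 loglik = loglik, sigma0_on_boundary = boundary),
            class = "finemap_fit")
}

#' @export
print.finemap_fit <- function(x, ...) {
  cat("Single-effect fine-mapping fit:", nrow(x$variants), "SNPs,",
      "sigma0_sq =", format(x$sigma0_sq, digits = 4),
      if (x$sigma0_on_boundary) "(grid boundary)" else "", "\n")
  top <- x$variants[order(-x$variants$pip), ][seq_len(min(5, nrow(x$variants))), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Credible set for a fine-mapped block
#'
#' The smallest set of SNPs, taken in decreasing-PIP order (ties broken by
#' ascending position), whose PIP sum reaches the coverage level. When an LD
#' matrix is supplied, the set is discarded (`NULL`) if its minimum absolute
#' pairwise correlation (purity) falls below `purity_min`.
#'
#' @param fit A `finemap_fit` from [finemap_block()].
#' @param coverage Requested coverage in `(0, 1]` (default 0.95).
#' @param R Optional LD correlation matrix in block SNP order.
#' @param purity_min Minimum purity when `R` is given (default 0.5).
#' @return A list with `variants`, `indices`, `coverage` (achieved) and
#'   `purity` (`NA` without `R`), or `NULL` when the set fails the purity
#'   filter.
#' @export
credible_set <- function(fit, coverage = 0.95, R = NULL, purity_min = 0.5) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1) {
    stop("coverage must be in (0, 1]")
  }
  v <- fit$variants
  ord <- order(-v$pip, v$pos)
  cum <- cumsum(v$pip[ord])
  n <- which(cum >= coverage - 1e-12)[1]
  if (is.na(n)) n <- nrow(v)
  idx <- sort(ord[seq_len(n)])
  purity <- NA_real_
  if (!is.null(R)) {
    sub <- abs(R[idx, idx, drop = FALSE])
    purity <- min(sub)
    if (purity < purity_min) return(NULL)
  }
  list(variants = v$variant_id[idx], indices = idx,
       coverage = cum[n], purity = purity)
}

#' Fine-map every LD block in a variant table
#'
#' @param variants Data frame with `variant_id`, `pos`, `z`, `block_id`
#'   (e.g. from [assign_blocks()] or [simulate_annotated_genome()]).
#' @param priors Optional numeric vector of per-SNP prior probabilities
#'   aligned with `variants` rows (renormalized within block), e.g. from
#'   [priors_from_model()].
#' @param sigma0_sq Prior effect variance or `"estimate"` (profiled per
#'   block).
#' @param sigma0_grid Grid for estimation.
#' @return Data frame with one row per SNP: `block_id`, `variant_id`, `pos`,
#'   `z`, `prior`, `log_abf`, `pip`.
#' @export
finemap_blocks <- function(variants, priors = NULL, sigma0_sq = "estimate",
                           sigma0_grid = default_sigma0_grid()) {
  stopifnot(all(c("variant_id", "pos", "z", "block_id") %in% names(variants)))
  if (!is.null(priors) && length(priors) != nrow(variants)) {
    stop("priors must align with variants rows")
  }
  idx_by_block <- split(seq_len(nrow(variants)), variants$block_id)
  res <- lapply(names(idx_by_block), function(b) {
    i <- idx_by_block[[b]]
    fit <- finemap_block(variants$z[i],
                         priors = if (is.null(priors)) NULL else priors[i],
                         sigma0_sq = sigma0_sq, sigma0_grid = sigma0_grid,
                         variant_id = variants$variant_id[i],
                         pos = variants$pos[i])
    cbind(block_id = b, fit$variants, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
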