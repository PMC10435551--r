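# eQTL tissue-sharing decomposition by functional category, enrichment
# versus matched controls, and the cell-fraction dilution power study.

#' Decompose eQTL tissue sharing by functional category
#'
#' The overall probability `p` that an eQTL discovered in the first tissue
#' replicates in a second tissue decomposes exactly as
#' `p = sum_c p_c * w_c`, where `w_c` is the proportion of eQTLs in category
#' `c` and `p_c` the sharing probability within the category. The identity
#' holds by construction and is asserted.
#'
#' @param records Data frame with `category` and a logical column named by
#'   `second_tissue_flag` indicating activity in the second tissue.
#' @param second_tissue_flag Column name of the sharing indicator (default
#'   `"shared"`).
#' @return Object of class `sharing_decomposition`: a list with `table`
#'   (category, n, w, p_c) and `p` (overall sharing probability).
#' @examples
#' rec <- data.frame(category = c("a", "a", "b"), shared = c(TRUE, FALSE, TRUE))
#' decompose_sharing(rec)
#' @export
decompose_sharing <- function(records, second_tissue_flag = "shared") {
  if (nrow(records) == 0) stop("empty eQTL record table")
  stopifnot("category" %in% names(records),
            second_tissue_flag %in% names(records))
  flag <- as.logical(records[[second_tissue_flag]])
  n_c <- tapply(flag, records$category, length)
  k_c <- tapply(flag, records$category, sum)
  tab <- data.frame(category = names(n_c), n = as.integer(n_c),
                    w = as.numeric(n_c) / nrow(records),
                    p_c = as.numeric(k_c) / as.numeric(n_c),
                    stringsAsFactors = FALSE)
  p <- mean(flag)
  stopifnot(abs(p - sum(tab$p_c * tab$w)) < 1e-12)
  structure(list(table = tab, p = p), class = "sharing_decomposition")
}

#' @export
print.sharing_decomposition <- function(x, ...) {
  cat("eQTL tissue-sharing decomposition: p =", format(x$p, digits = 4), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-category summary of the number of active tissues
#'
#' @param records Data frame with `category` and `n_tissues_active`.
#' @return Data frame with `category`, `n`, `q1`, `median`, `q3`. Categories
#'   with no records are omitted with a warning (when `records$category` is
#'   a factor with unused levels).
#' @export
sharing_summary <- function(records) {
  stopifnot(all(c("category", "n_tissues_active") %in% names(records)))
  if (is.factor(records$category)) {
    empty <- setdiff(levels(records$category),
                     unique(as.character(records$category)))
    if (length(empty) > 0) {
      warning("omitting empty categor(ies): ", paste(empty, collapse = ", "))
    }
  }
  cat <- as.character(records$category)
  qs <- function(v, p) as.numeric(stats::quantile(v, p, names = FALSE))
  out <- do.call(rbind, lapply(split(records$n_tissues_active, cat), function(v)
    data.frame(n = length(v), q1 = qs(v, 0.25),
               median = stats::median(v), q3 = qs(v, 0.75))))
  out <- cbind(category = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fold enrichment of eQTL categories versus matched controls
#'
#' @param records Categorized eQTL records (column `category`).
#' @param controls Categorized control variants, annotated through the same
#'   pipeline (column `category`).
#' @return Data frame with `category`, `eqtl_prop`, `control_prop`, `fold`
#'   (`Inf` with `fold_undefined = TRUE` when the control proportion is 0).
#' @export
category_enrichment <- function(records, controls) {
  stopifnot("category" %in% names(records), "category" %in% names(controls))
  cats <- sort(unique(c(records$category, controls$category)))
  if (nrow(controls) < 10 * length(cats)) {
    warning("control set is small relative to the number of categories; ",
            "fold estimates will be noisy")
  }
  ep <- table(factor(records$category, levels = cats)) / nrow(records)
  cp <- table(factor(controls$category, levels = cats)) / nrow(controls)
  out <- data.frame(category = cats,
                    eqtl_prop = as.numeric(ep),
                    control_prop = as.numeric(cp),
                    stringsAsFactors = FALSE)
  out$fold <- ifelse(out$control_prop > 0, out$eqtl_prop / out$control_prop,
                     ifelse(out$eqtl_prop > 0, Inf, NA_real_))
  out$fold_undefined <- out$control_prop == 0 & out$eqtl_prop > 0
  out
}

#' Power ratio for cell-type-specific versus shared eQTLs in bulk tissue
#'
#' Simulates bulk expression where a cell-type-specific eQTL contributes a
#' diluted slope `f * beta` (the causal cell type is a fraction `f` of the
#' tissue) while a shared eQTL contributes the full slope `beta`, with unit
#' Gaussian noise. Power is the rejection rate of the marginal slope t-test
#' at level `alpha`; the ratio of powers quantifies the detection penalty
#' for cell-type-specific regulatory variants.
#'
#' @param f Causal cell-type fraction in `(0, 1]`.
#' @param effect_grid Numeric vector of per-allele effect sizes `beta`.
#' @param n Sample size per simulated study (default 200).
#' @param alpha Test level (default 0.05).
#' @param reps Simulation replicates per grid point (>= 1000).
#' @param seed Random seed (required).
#' @param maf Minor allele frequency of the simulated genotype (default
#'   0.3).
#' @return Data frame with `effect`, `power_specific`, `power_shared`,
#'   `ratio`.
#' @export
power_ratio_simulation <- function(f, effect_grid, n = 200, alpha = 0.05,
                                   reps = 2000, seed, maf = 0.3) {
  if (!is.numeric(f) || length(f) != 1 || f <= 0 || f > 1) {
    stop("f must be in (0, 1]")
  }
  if (reps < 1000) stop("reps must be >= 1000")
  set.seed(seed)
  crit <- stats::qt(1 - alpha / 2, df = n - 2)
  out <- do.call(rbind, lapply(effect_grid, function(beta) {
    # common random numbers across the two arms: the same genotypes and
    # residual noise are reused, which leaves each arm's power unbiased
    # while sharply reducing the Monte-Carlo variance of their ratio
    G <- matrix(stats::rbinom(n * reps, 2, maf), nrow = n)
    E <- matrix(stats::rnorm(n * reps), nrow = n)
    one_power <- function(slope) {
      Y <- slope * G + E
      gc_ <- scale(G, scale = FALSE)
      yc <- scale(Y, scale = FALSE)
      r <- colSums(gc_ * yc) /
        sqrt(colSums(gc_^2) * colSums(yc^2))
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      mean(abs(tstat) > crit)
    }
    ps <- one_power(f * beta)
    pb <- one_power(beta)
    data.frame(effect = beta, power_specific = ps, power_shared = pb,
               ratio = ps / pb)
  }))
  rownames(out) <- NULL
  out
}

#' Closed-form normal-approximation power ratio
#'
#' Independent analytic counterpart of [power_ratio_simulation()]: the slope
#' test statistic is approximately normal with non-centrality
#' `slope * sd(genotype) * sqrt(n)` (unit residual noise), so the power at
#' level `alpha` is `P(|Z + ncp| > z_{1 - alpha/2})`.
#'
#' @inheritParams power_ratio_simulation
#' @param beta Per-allele effect size(s).
#' @return Data frame with `effect`, `power_specific`, `power_shared`,
#'   `ratio`.
#' @export
power_ratio_normal_approx <- function(f, beta, n = 200, alpha = 0.05,
                                      maf = 0.3) {
  zq <- stats::qnorm(1 - alpha / 2)
  sd_g <- sqrt(2 * maf * (1 - maf))
  pw <- function(slope) {
    ncp <- slope * sd_g * sqrt(n)
    stats::pnorm(-zq - ncp) + 1 - stats::pnorm(zq - ncp)
  }
  data.frame(effect = beta, power_specific = pw(f * beta),
             power_shared = pw(beta),
             ratio = pw(f * beta) / pw(beta))
}
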