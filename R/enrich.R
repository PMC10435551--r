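# Genome-wide enrichment of causal variants in functional annotations,
# estimated by EM under a logistic prior model and a single causal variant
# per LD block. The per-block likelihood is
#   L_i = prod_k (1 - pi_k) * (1 + sum_j BF_j * pi_j / (1 - pi_j)),
# i.e. the sum over the no-causal configuration and each single-causal
# configuration, with pi_j = logistic(alpha0 + alpha . A_j). The E-step gives
# soft causal labels q_j; the M-step is a weighted logistic regression of q
# on the annotations, which makes the marginal log-likelihood non-decreasing.

#' Fit the enrichment model by EM
#'
#' Estimates the intercept and per-annotation log-odds coefficients of the
#' logistic prior for causal status, alternating between per-block posterior
#' causal probabilities under the current priors (including an explicit
#' no-causal configuration) and a logistic regression of those soft labels
#' on the annotations. The effect-size prior variance is profiled once on
#' `sigma0_grid` before the EM. Wald standard errors are computed from the
#' numerically differentiated observed information of the marginal
#' log-likelihood, so they reflect E-step uncertainty.
#'
#' @param variants Data frame with `z` and `block_id` (at least 2 blocks).
#' @param A Binary annotation matrix, rows aligned with `variants`, named
#'   columns. Annotations constant across all SNPs are dropped with a
#'   warning.
#' @param sigma0_grid Grid of candidate prior effect variances.
#' @param max_iter,tol EM stops when `max(abs(delta))` over coefficients
#'   drops below `tol` (default 1e-4) or after `max_iter` (default 200)
#'   iterations.
#' @param cap Coefficients are capped at `abs(alpha) <= cap` (default 10) to
#'   prevent separation blow-up; capped fits are flagged.
#' @return An object of class `enrichment_model`: `alpha0`, `alpha` (named),
#'   `se` (named, including `(Intercept)`), `converged`, `n_iter`,
#'   `sigma0_sq`, `loglik` (trace of the marginal log-likelihood), `capped`.
#' @export
fit_enrichment_em <- function(variants, A,
                              sigma0_grid = default_sigma0_grid(),
                              max_iter = 200, tol = 1e-4, cap = 10) {
  stopifnot(all(c("z", "block_id") %in% names(variants)))
  A <- as.matrix(A)
  if (nrow(A) != nrow(variants)) stop("A must align with variants rows")
  if (is.null(colnames(A))) stop("A must have column names")
  n_blocks <- length(unique(variants$block_id))
  if (n_blocks < 2) stop("need at least 2 blocks")

  keep <- apply(A, 2, function(col) length(unique(col)) > 1)
  if (any(!keep)) {
    warning("dropping constant annotation(s): ",
            paste(colnames(A)[!keep], collapse = ", "))
    A <- A[, keep, drop = FALSE]
  }
  K <- ncol(A)
  z <- variants$z
  block <- factor(variants$block_id)
  m_bar <- nrow(A) / n_blocks
  X <- cbind("(Intercept)" = 1, A)

  # log-likelihood of the marginal model at coefficients theta, BFs fixed
  marginal_loglik <- function(theta, labf) {
    eta <- pmin(pmax(drop(X %*% theta), -30), 30)
    logr <- pmin(eta + labf, 700)   # log(pi/(1-pi)) + logBF
    S <- rowsum(exp(logr), block)
    sum(-log1pexp(eta)) + sum(log1p(S))
  }

  theta <- c(stats::qlogis(1 / m_bar), rep(0, K))
  names(theta) <- colnames(X)

  # profile sigma0^2 at the initial (flat-annotation) coefficients
  grid_ll <- vapply(sigma0_grid, function(s2)
    marginal_loglik(theta, log_abf(z, s2)), 0)
  sigma0_sq <- sigma0_grid[which.max(grid_ll)]
  labf <- log_abf(z, sigma0_sq)

  loglik_trace <- numeric(0)
  converged <- FALSE
  capped <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- pmin(pmax(drop(X %*% theta), -30), 30)
    logr <- pmin(eta + labf, 700)
    r <- exp(logr)
    S <- rowsum(r, block)
    denom <- 1 + S[as.integer(block)]
    q <- r / denom                       # soft causal label per SNP
    loglik_trace <- c(loglik_trace, sum(-log1pexp(eta)) + sum(log1p(S)))

    fit <- suppressWarnings(
      stats::glm.fit(X, q, family = stats::binomial(), start = theta))
    new_theta <- fit$coefficients
    if (any(abs(new_theta) > cap)) {
      capped <- TRUE
      new_theta <- pmin(pmax(new_theta, -cap), cap)
    }
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  loglik_trace <- c(loglik_trace, marginal_loglik(theta, labf))
  if (!converged) {
    warning("enrichment EM did not converge in ", max_iter, " iterations")
  }

  se <- enrichment_wald_se(theta, function(th) marginal_loglik(th, labf))
  names(se) <- colnames(X)
  structure(list(alpha0 = unname(theta[1]),
                 alpha = theta[-1],
                 se = se,
                 converged = converged,
                 n_iter = iter,
                 sigma0_sq = sigma0_sq,
                 loglik = loglik_trace,
                 capped = capped),
            class = "enrichment_model")
}

# Wald SEs from a numerical Hessian of the marginal log-likelihood.
enrichment_wald_se <- function(theta, loglik_fn) {
  p <- length(theta)
  h <- 1e-4 * (1 + abs(theta))
  f0 <- loglik_fn(theta)
  H <- matrix(NA_real_, p, p)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    e <- rep(0, p); e[i] <- h[i]
    fp[i] <- loglik_fn(theta + e)
    fm[i] <- loglik_fn(theta - e)
    H[i, i] <- (fp[i] + fm[i] - 2 * f0) / h[i]^2
  }
  if (p > 1) {
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        ei <- rep(0, p); ei[i] <- h[i]
        ej <- rep(0, p); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (loglik_fn(theta + ei + ej) - loglik_fn(theta + ei - ej) -
             loglik_fn(theta - ei + ej) + loglik_fn(theta - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  tryCatch({
    cov <- solve(-H)
    d <- diag(cov)
    ifelse(d > 0, sqrt(d), NA_real_)
  }, error = function(e) rep(NA_real_, p))
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat("Enrichment model (logistic prior):\n")
  cat("  alpha0 =", format(x$alpha0, digits = 4),
      " sigma0_sq =", format(x$sigma0_sq, digits = 4), "\n")
  for (nm in names(x$alpha)) {
    cat("  ", nm, ": alpha =", format(x$alpha[[nm]], digits = 4),
        " (log2FE =", format(x$alpha[[nm]] / log(2), digits = 4), ")\n")
  }
  cat("  converged:", x$converged, "after", x$n_iter, "iterations",
      if (x$capped) "(capped)" else "", "\n")
  invisible(x)
}

#' Per-SNP priors from a fitted enrichment model
#'
#' `pi_j = logistic(alpha0 + alpha . A_j)`; when `block_id` is supplied the
#' priors are renormalized to sum to 1 within each block, as required by the
#' single-effect fine-mapping semantics.
#'
#' @param model An `enrichment_model`.
#' @param A Annotation matrix with (at least) the model's annotation columns;
#'   a missing column is an error.
#' @param block_id Optional block labels (same length as rows of `A`).
#' @return Numeric vector of priors aligned with rows of `A`.
#' @export
priors_from_model <- function(model, A, block_id = NULL) {
  A <- as.matrix(A)
  missing_cols <- setdiff(names(model$alpha), colnames(A))
  if (length(missing_cols) > 0) {
    stop("annotation column(s) absent from A: ",
         paste(missing_cols, collapse = ", "))
  }
  eta <- model$alpha0 + drop(A[, names(model$alpha), drop = FALSE] %*% model$alpha)
  pi <- stats::plogis(eta)
  if (!is.null(block_id)) {
    if (length(block_id) != nrow(A)) stop("block_id must align with A rows")
    tot <- stats::ave(pi, block_id, FUN = sum)
    pi <- pi / tot
  }
  pi
}

#' Enrichment report across annotations
#'
#' Converts fitted log-odds coefficients into log2 fold enrichments with
#' Wald confidence intervals and multiplicity-adjusted p-values across the
#' declared family.
#'
#' @param models Named list of `enrichment_model` objects (typically one
#'   single-annotation fit per entry, each fitted one at a time).
#' @param fdr_method Method for [stats::p.adjust()] (default `"BH"`).
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return Data frame with `model`, `annotation`, `log2_fold_enrichment`,
#'   `ci_low`, `ci_high`, `se_log2`, `p`, `p_adj`.
#' @export
enrichment_report <- function(models, fdr_method = "BH", conf_level = 0.95) {
  if (inherits(models, "enrichment_model")) models <- list(fit = models)
  stopifnot(length(models) >= 1)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    ann <- names(m$alpha)
    se <- m$se[ann]
    l2 <- m$alpha / log(2)
    se2 <- se / log(2)
    wald_z <- ifelse(m$alpha == 0, 0, m$alpha / se)
    p <- 2 * stats::pnorm(-abs(wald_z))
    data.frame(model = nm, annotation = ann,
               log2_fold_enrichment = unname(l2),
               ci_low = unname(l2 - zq * se2),
               ci_high = unname(l2 + zq * se2),
               se_log2 = unname(se2),
               p = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = fdr_method)
  rownames(out) <- NULL
  out
}
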