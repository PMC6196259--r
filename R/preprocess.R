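#' Per-sample array quality surrogate
#'
#' A GNUSE-like unitless quality score computed without external reference
#' data: for each sample, the median absolute deviation of its values from
#' the gene-wise consensus (the across-sample median), rescaled so the
#' cohort mean score is 1. Typical samples score near 1; degraded arrays
#' score higher.
#'
#' @param expr Genes x samples numeric matrix.
#' @return Named numeric vector of scores, one per sample, mean 1.
#' @export
quality_surrogate <- function(expr) {
  consensus <- apply(expr, 1, stats::median)
  dev <- abs(sweep(expr, 1, consensus))
  q <- apply(dev, 2, stats::median)
  q / mean(q)
}

#' Filter samples by array quality score
#'
#' Retains samples whose quality score does not exceed the cutoff
#' (boundary inclusive: a sample scoring exactly the cutoff is kept).
#' Excluded sample ids are reported via \code{message}.
#'
#' @param expr Genes x samples matrix.
#' @param scores Named per-sample quality scores covering every column of
#'   \code{expr} (e.g. from [quality_surrogate()]).
#' @param cutoff Positive threshold; default 1.25, the conventional cutoff
#'   for GNUSE-style scores.
#' @return \code{expr} restricted to passing samples, original order kept.
#' @export
quality_filter <- function(expr, scores, cutoff = 1.25) {
  stopifnot(cutoff > 0)
  samples <- colnames(expr)
  missing <- setdiff(samples, names(scores))
  if (length(missing))
    stop("no quality score for sample(s): ", paste(missing, collapse = ", "))
  sc <- scores[samples]
  drop <- sc > cutoff
  if (any(drop))
    message("quality_filter: excluding ", sum(drop), " sample(s) with score > ",
            cutoff, ": ", paste(samples[drop], collapse = ", "))
  out <- expr[, !drop, drop = FALSE]
  attr(out, "scale") <- attr(expr, "scale")
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample column onto a common distribution: the row-wise mean
#' of the sorted input columns. Ties within a column receive the mean of the
#' quantile values they span. Idempotent.
#'
#' @param expr Genes x samples matrix, no missing values, at least 2 samples.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(expr) {
  if (ncol(expr) < 2) stop("quantile normalization needs at least 2 samples")
  if (anyNA(expr)) stop("missing values present; impute before normalizing")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  attr(out, "scale") <- attr(expr, "scale")
  out
}

#' Empirical-Bayes batch adjustment (location/scale)
#'
#' ComBat-style parametric adjustment for merging datasets measured in
#' batches, applied to log-scale expression. Per gene, batch means are
#' shrunk toward a common mean and batch variances toward a pooled variance
#' via parametric empirical-Bayes priors estimated across genes; each batch
#' is then standardized and re-scaled to the pooled moments. Gene-wise grand
#' means are preserved.
#'
#' Genes with zero variance within any batch (or zero pooled variance)
#' bypass the scale adjustment and receive a location-only correction, so
#' degenerate inputs remain well-defined.
#'
#' @param expr Genes x samples matrix on the log scale, finite values.
#' @param batches Batch label per sample; at least 2 batches with at least 2
#'   samples each.
#' @return Adjusted matrix, same shape and dimnames.
#' @export
batch_adjust <- function(expr, batches) {
  if (any(!is.finite(expr))) stop("batch_adjust: non-finite values in input")
  batches <- as.character(batches)
  if (length(batches) != ncol(expr))
    stop("batch_adjust: one batch label per sample required")
  tab <- table(batches)
  if (length(tab) < 2) stop("batch_adjust: need at least 2 batches")
  if (any(tab < 2))
    stop("batch_adjust: batch(es) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))

  n <- ncol(expr)
  levs <- names(tab)
  grand <- rowMeans(expr)
  # pooled variance of within-batch residuals (batch means removed)
  resid <- expr
  for (b in levs) {
    sel <- batches == b
    resid[, sel] <- expr[, sel, drop = FALSE] -
      rowMeans(expr[, sel, drop = FALSE])
  }
  pooled_var <- rowSums(resid^2) / n
  batch_var_zero <- Reduce(`|`, lapply(levs, function(b) {
    apply(expr[, batches == b, drop = FALSE], 1, stats::var) < 1e-12
  }))
  degenerate <- batch_var_zero | pooled_var < 1e-12

  out <- expr
  # location-only path for degenerate genes: remove batch means, keep grand mean
  if (any(degenerate)) {
    for (b in levs) {
      sel <- batches == b
      bm <- rowMeans(expr[degenerate, sel, drop = FALSE])
      out[degenerate, sel] <- expr[degenerate, sel, drop = FALSE] - bm + grand[degenerate]
    }
  }

  ok <- !degenerate
  if (sum(ok) > 0) {
    X <- expr[ok, , drop = FALSE]
    sd_g <- sqrt(pooled_var[ok])
    Z <- (X - grand[ok]) / sd_g
    Zadj <- Z
    for (b in levs) {
      sel <- batches == b
      nb <- sum(sel)
      Zb <- Z[, sel, drop = FALSE]
      gamma_hat <- rowMeans(Zb)
      delta2_hat <- apply(Zb, 1, stats::var)
      post <- eb_posterior(Zb, gamma_hat, delta2_hat, nb)
      Zadj[, sel] <- (Zb - post$gamma) / sqrt(post$delta2)
    }
    out[ok, ] <- Zadj * sd_g + grand[ok]
  }
  # EB shrinkage can leave a small gene-wise offset; restore grand means
  out <- out - rowMeans(out) + grand
  dimnames(out) <- dimnames(expr)
  attr(out, "scale") <- attr(expr, "scale")
  out
}

# Parametric EB posteriors for one batch's standardized location (normal
# prior) and scale (inverse-gamma prior), hyperparameters estimated across
# genes by moments; falls back to the raw estimates when too few genes to
# estimate priors.
eb_posterior <- function(Zb, gamma_hat, delta2_hat, nb) {
  G <- length(gamma_hat)
  delta2_hat <- pmax(delta2_hat, 1e-12)
  if (G < 3) return(list(gamma = gamma_hat, delta2 = delta2_hat))
  gbar <- mean(gamma_hat)
  t2 <- stats::var(gamma_hat)
  m <- mean(delta2_hat)
  s2 <- stats::var(delta2_hat)
  if (!is.finite(t2) || t2 < 1e-12 || !is.finite(s2) || s2 < 1e-12)
    return(list(gamma = gamma_hat, delta2 = delta2_hat))
  aprior <- (2 * s2 + m^2) / s2
  bprior <- (m * s2 + m^3) / s2
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  sum_sq <- function(g_star) rowSums((Zb - g_star)^2)
  for (it in seq_len(100)) {
    g_new <- (nb * t2 * gamma_hat + delta2_star * gbar) / (nb * t2 + delta2_star)
    d_new <- (0.5 * sum_sq(g_new) + bprior) / (nb / 2 + aprior - 1)
    change <- max(abs(g_new - gamma_star), abs(d_new - delta2_star))
    gamma_star <- g_new
    delta2_star <- d_new
    if (change < 1e-6) break
  }
  list(gamma = gamma_star, delta2 = pmax(delta2_star, 1e-12))
}

#' Remove genes with low variability
#'
#' Default rule (\code{rule = "deviation"}): a gene is retained only if no
#' more than \code{min_samples} samples sit within \code{delta} of the
#' gene's median — i.e. at least \code{n - min_samples} samples deviate from
#' the median by more than \code{delta}. The alternative
#' (\code{rule = "kOverA"}) retains genes whose absolute expression exceeds
#' \code{delta} in at least \code{n - min_samples} samples.
#'
#' @param expr Genes x samples matrix.
#' @param min_samples Tolerated count of low-variability samples (default 20).
#' @param delta Positive deviation (or level, for \code{"kOverA"}) threshold.
#' @param rule Filtering semantics; see Details.
#' @return Filtered matrix; the number of genes removed is reported.
#' @export
variability_filter <- function(expr, min_samples = 20L, delta,
                               rule = c("deviation", "kOverA")) {
  rule <- match.arg(rule)
  if (delta <= 0) stop("variability_filter: delta must be positive")
  n <- ncol(expr)
  keep <- switch(rule,
    deviation = {
      med <- apply(expr, 1, stats::median)
      rowSums(abs(expr - med) <= delta) <= min_samples
    },
    kOverA = rowSums(expr > delta) >= (n - min_samples)
  )
  message("variability_filter(", rule, "): retained ", sum(keep), " of ",
          nrow(expr), " genes")
  out <- expr[keep, , drop = FALSE]
  attr(out, "scale") <- attr(expr, "scale")
  out
}
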