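#' Estimate leukocyte fractions by nu-support-vector regression
#'
#' Signature-based deconvolution of bulk linear-scale expression into
#' relative leukocyte-RNA fractions over the reference cell types, in the
#' style of CIBERSORT: per sample, the mixture is regressed on the signature
#' columns with linear-kernel nu-SVR over a small grid of \code{nu} values;
#' the fit minimizing reconstruction RMSE is kept, negative coefficients are
#' clipped to zero and the rest renormalized to the unit simplex.
#' Significance is assessed against an empirical null distribution of
#' mixture-reconstruction correlations obtained from permuted mixtures drawn
#' at random from the full expression matrix.
#'
#' @param expr Genes x samples matrix, linear scale. Signature genes are
#'   matched case-insensitively; at least half must be present.
#' @param signature Genes x cell-types reference matrix.
#' @param nus Grid of nu values for the SVR (default \code{c(0.25, 0.5, 0.75)}).
#' @param permutations Number of permuted mixtures for the null distribution
#'   (default 1000; 0 disables the permutation test, \code{perm_p} = NA).
#' @param seed Integer seed controlling the permutations.
#' @return Object of class \code{deconv_result}: list with \code{fractions}
#'   (cell types x samples, each column on the unit simplex), \code{rmse},
#'   \code{pearson_r}, \code{perm_p} (in \code{[1/(P+1), 1]}) and
#'   \code{chosen_nu} per sample.
#' @export
deconvolve <- function(expr, signature, nus = c(0.25, 0.5, 0.75),
                       permutations = 1000L, seed = 1L) {
  m <- match_signature_genes(expr, signature)
  X0 <- m$signature
  Y0 <- m$mixtures
  k <- ncol(X0)
  n <- ncol(Y0)

  # signature standardized jointly (global moments), mixtures per sample
  X <- (X0 - mean(X0)) / stats::sd(as.vector(X0))

  fit_one <- function(y) {
    if (all(y == 0)) stop("all-zero mixture column")
    ys <- (y - mean(y)) / stats::sd(y)
    best <- NULL
    for (nu in nus) {
      fit <- e1071::svm(X, ys, type = "nu-regression", kernel = "linear",
                        nu = nu, cost = 1, scale = FALSE)
      w <- as.numeric(t(fit$coefs) %*% fit$SV)
      w <- pmax(w, 0)
      f <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
      recon <- as.numeric(X %*% f)
      rmse <- sqrt(mean((recon - ys)^2))
      r <- suppressWarnings(stats::cor(recon, ys))
      if (!is.finite(r)) r <- 0
      if (is.null(best) || rmse < best$rmse)
        best <- list(f = f, rmse = rmse, r = r, nu = nu)
    }
    best
  }

  fits <- apply(Y0, 2, fit_one)
  fractions <- vapply(fits, `[[`, numeric(k), "f")
  rownames(fractions) <- colnames(X0)
  colnames(fractions) <- colnames(Y0)
  rmse <- vapply(fits, `[[`, numeric(1), "rmse")
  pearson_r <- vapply(fits, `[[`, numeric(1), "r")
  chosen_nu <- vapply(fits, `[[`, numeric(1), "nu")

  perm_p <- rep(NA_real_, n)
  P <- as.integer(permutations)
  if (P > 0) {
    pool <- as.vector(expr)
    null_r <- with_seed(seed, {
      vapply(seq_len(P), function(i) {
        yr <- sample(pool, nrow(X0))
        if (stats::sd(yr) == 0) return(0)
        fit_one(yr)$r
      }, numeric(1))
    })
    perm_p <- vapply(pearson_r, function(r) (1 + sum(null_r >= r)) / (P + 1),
                     numeric(1))
  }
  names(perm_p) <- colnames(Y0)

  structure(list(fractions = fractions, rmse = rmse, pearson_r = pearson_r,
                 perm_p = perm_p, chosen_nu = chosen_nu,
                 permutations = P, nus = nus),
            class = "deconv_result")
}

#' Non-negative least squares deconvolution (reference oracle)
#'
#' Per-sample non-negative least squares of the mixture on the signature
#' columns, normalized to the unit simplex. On low-noise data it should
#' agree closely with [deconvolve()]; it serves as an independent
#' cross-check built on a different optimization principle.
#'
#' @inheritParams deconvolve
#' @return Object of class \code{deconv_result} (no permutation p-values).
#' @export
nnls_oracle <- function(expr, signature) {
  m <- match_signature_genes(expr, signature)
  X <- m$signature
  if (qr(X)$rank < ncol(X))
    stop("signature matrix is rank-deficient (collinear cell-type columns); ",
         "fractions are not identifiable")
  k <- ncol(X)
  res <- apply(m$mixtures, 2, function(y) {
    if (all(y == 0)) stop("all-zero mixture column")
    w <- pracma::lsqnonneg(X, y)$x
    f <- if (sum(w) > 0) w / sum(w) else rep(1 / k, k)
    recon <- as.numeric(X %*% w)
    r <- suppressWarnings(stats::cor(recon, y))
    list(f = f, rmse = sqrt(mean((recon - y)^2)),
         r = if (is.finite(r)) r else 0)
  })
  fractions <- vapply(res, `[[`, numeric(k), "f")
  rownames(fractions) <- colnames(X)
  colnames(fractions) <- colnames(m$mixtures)
  structure(list(fractions = fractions,
                 rmse = vapply(res, `[[`, numeric(1), "rmse"),
                 pearson_r = vapply(res, `[[`, numeric(1), "r"),
                 perm_p = rep(NA_real_, ncol(fractions)),
                 chosen_nu = rep(NA_real_, ncol(fractions))),
            class = "deconv_result")
}

# Case-insensitive intersection of signature genes with expression rows;
# errors when fewer than half the signature genes are found.
match_signature_genes <- function(expr, signature) {
  idx <- match(toupper(rownames(signature)), toupper(rownames(expr)))
  found <- !is.na(idx)
  if (mean(found) < 0.5)
    stop("only ", sum(found), " of ", nrow(signature),
         " signature genes found in the expression matrix (< 50%)")
  list(signature = signature[found, , drop = FALSE],
       mixtures = expr[idx[found], , drop = FALSE])
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("deconvolution of", ncol(x$fractions), "samples into",
      nrow(x$fractions), "cell types\n")
  cat("  mean RMSE:", signif(mean(x$rmse), 3),
      " mean r:", signif(mean(x$pearson_r), 3), "\n")
  if (!all(is.na(x$perm_p)))
    cat("  samples with permutation p < 0.05:", sum(x$perm_p < 0.05), "\n")
  invisible(x)
}

#' Cell fractions as percentages of leukocyte RNA
#'
#' @param result A \code{deconv_result}.
#' @return Cell types x samples matrix on the 0-100 scale.
#' @export
fractions_percent <- function(result) {
  result$fractions * 100
}
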