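#' Welch two-sample t-test per gene
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p-value for every gene, comparing recurrent against
#' non-recurrent samples. By design no multiplicity adjustment is applied
#' (the screen operates at a nominal threshold).
#'
#' @param expr Genes x samples matrix.
#' @param groups Per-sample labels with exactly two levels; the first level
#'   (alphabetically, or of the factor) is the reference, and t > 0 means
#'   higher expression in the second level. Both groups need >= 2 samples.
#' @return Data frame: gene, t, df, p, flag. Degenerate genes (zero
#'   variance in both groups) get t = 0, p = 1 when the means agree and an
#'   "infinite t" flag when they do not.
#' @export
welch_test <- function(expr, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("welch_test: exactly 2 groups required")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (n1 < 2 || n2 < 2) stop("welch_test: both groups need >= 2 samples")
  x1 <- expr[, g == levels(g)[1], drop = FALSE]
  x2 <- expr[, g == levels(g)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  flag <- rep("", nrow(expr))
  degen <- v1 == 0 & v2 == 0
  eq <- degen & m1 == m2
  ne <- degen & m1 != m2
  t[eq] <- 0; p[eq] <- 1; df[degen] <- NA
  t[ne] <- sign(m2[ne] - m1[ne]) * Inf; p[ne] <- 0
  flag[ne] <- "infinite t (zero variance, unequal means)"
  data.frame(gene = rownames(expr), t = t, df = df, p = p, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene modules by Markov clustering of the correlation network
#'
#' Builds the gene-gene graph with edges wherever the absolute pairwise
#' correlation exceeds \code{r_threshold} (edge weight = |r|, self-loops of
#' weight 1), then runs Markov Clustering: column-normalize, alternate
#' expansion (matrix squaring) and inflation (entrywise power, then
#' renormalization) until the matrix changes by less than 1e-6 or 200
#' iterations. Clusters are read off the limit matrix as connected
#' components; singleton modules are dropped.
#'
#' @param expr Genes x samples matrix (>= 3 genes).
#' @param r_threshold Absolute-correlation edge threshold (default 0.30).
#' @param inflation MCL inflation parameter controlling granularity
#'   (default 2.5).
#' @return List of class \code{module_set}: \code{modules} (list of gene
#'   name vectors, disjoint, each of size >= 2), \code{r_threshold},
#'   \code{inflation}, \code{iterations}.
#' @export
find_modules <- function(expr, r_threshold = 0.30, inflation = 2.5) {
  if (nrow(expr) < 3) stop("find_modules: need at least 3 genes")
  genes <- rownames(expr)
  r <- suppressWarnings(stats::cor(t(expr)))
  r[!is.finite(r)] <- 0
  A <- abs(r)
  A[A <= r_threshold] <- 0
  diag(A) <- 1  # self-loops stabilize the random walk
  if (all(A[upper.tri(A)] == 0))
    return(structure(list(modules = list(), r_threshold = r_threshold,
                          inflation = inflation, iterations = 0L),
                     class = "module_set"))
  normalize <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
  M <- normalize(A)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    M2 <- normalize((M %*% M)^inflation)
    M2[M2 < 1e-12] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-6 || iter >= 200L) break
  }
  # connected components of the limit matrix define the clusters
  adj <- (M > 1e-6) | t(M > 1e-6)
  comp <- components_of(adj)
  modules <- split(genes, comp)
  modules <- unname(modules[vapply(modules, length, 1L) >= 2])
  structure(list(modules = modules, r_threshold = r_threshold,
                 inflation = inflation, iterations = iter),
            class = "module_set")
}

# connected components of a logical adjacency matrix (BFS)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Rank genes by association with recurrence (GSEA-style)
#'
#' Ranks every gene by the signal-to-noise statistic
#' \eqn{(\mu_{rec} - \mu_{nonrec}) / (\sigma_{rec} + \sigma_{nonrec})}
#' (each group SD floored at 20\% of the group mean's magnitude, and at
#' 0.2 absolute, the conventional stabilization). Rank 1 is the gene most
#' associated with
#' recurrence; the bottom of the list is most associated with freedom from
#' recurrence.
#'
#' @param expr Genes x samples matrix.
#' @param groups Per-sample labels; the level named \code{"recurrent"} (or
#'   the second factor level) is the recurrent group. Both groups need
#'   >= 3 samples.
#' @return Data frame sorted by decreasing statistic: gene, s2n, rank.
#' @export
gsea_rank <- function(expr, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("gsea_rank: exactly 2 groups required")
  rec_level <- if ("recurrent" %in% levels(g)) "recurrent" else levels(g)[2]
  if (min(table(g)) < 3) stop("gsea_rank: both groups need >= 3 samples")
  xr <- expr[, g == rec_level, drop = FALSE]
  xn <- expr[, g != rec_level, drop = FALSE]
  mr <- rowMeans(xr); mn <- rowMeans(xn)
  floor_sd <- function(s, m) pmax(s, 0.2 * abs(m), 0.2)
  sr <- floor_sd(apply(xr, 1, stats::sd), mr)
  sn <- floor_sd(apply(xn, 1, stats::sd), mn)
  s2n <- (mr - mn) / (sr + sn)
  ord <- order(s2n, decreasing = TRUE)
  data.frame(gene = rownames(expr)[ord], s2n = s2n[ord],
             rank = seq_along(ord), row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag genes in the bottom 5\% of a ranked list
#'
#' The \code{floor(q * G)} lowest-ranked genes (most associated with
#' freedom from recurrence) are flagged.
#'
#' @param ranked Data frame from [gsea_rank()].
#' @param genes Optional gene names to look up; every one must be in the
#'   list.
#' @param q Tail fraction (default 0.05).
#' @return Named logical vector over \code{genes} (or over all genes).
#' @export
bottom5pct <- function(ranked, genes = NULL, q = 0.05) {
  G <- nrow(ranked)
  k <- floor(q * G)
  flags <- stats::setNames(ranked$rank > G - k, ranked$gene)
  if (is.null(genes)) return(flags)
  missing <- setdiff(genes, ranked$gene)
  if (length(missing))
    stop("gene(s) absent from the ranked list: ", paste(missing, collapse = ", "))
  flags[genes]
}

#' Weighted Kolmogorov-Smirnov enrichment score for a gene set
#'
#' Walks the ranked list from the top; hitting a set member increments the
#' running sum by its |statistic|^weight share, missing decrements by
#' 1/(G - n_set). The enrichment score is the running-sum deviation of
#' maximal magnitude (signed).
#'
#' @param ranked Data frame from [gsea_rank()].
#' @param set Gene names forming the set (must be a proper nonempty subset
#'   of the list).
#' @param weight Weighting exponent on the ranking statistic (default 1;
#'   0 gives the classical unweighted KS statistic).
#' @return List: \code{es}, \code{position} (index of the extreme),
#'   \code{running} (the full running sum).
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  G <- nrow(ranked)
  inset <- ranked$gene %in% set
  nh <- sum(inset)
  if (nh == 0) stop("gsea_es: empty gene set (no members in the ranked list)")
  if (nh == G) stop("gsea_es: set contains every ranked gene; ES is degenerate")
  w <- abs(ranked$s2n)^weight
  hit_inc <- ifelse(inset, w / sum(w[inset]), 0)
  miss_dec <- ifelse(inset, 0, 1 / (G - nh))
  running <- cumsum(hit_inc - miss_dec)
  pos <- which.max(abs(running))
  list(es = running[pos], position = pos, running = running)
}

#' Candidate prognostic genes from modules, Welch and Cox screens
#'
#' A gene is a candidate when it belongs to a correlation-network module
#' and passes either the univariate Cox screen or the Welch differential
#' test at the nominal level.
#'
#' @param modules A \code{module_set} from [find_modules()].
#' @param welch_p Named per-gene Welch p-values.
#' @param cox_p Named per-gene Cox p-values.
#' @param alpha Nominal significance level (default 0.05).
#' @return Character vector of candidate gene names (possibly empty).
#' @export
prioritize <- function(modules, welch_p, cox_p, alpha = 0.05) {
  in_module <- unique(unlist(modules$modules))
  pass <- function(p, g) !is.na(p[g]) & p[g] < alpha
  in_module[pass(cox_p, in_module) | pass(welch_p, in_module)]
}
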