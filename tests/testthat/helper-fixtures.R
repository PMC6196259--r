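# Shared fixtures, built in code at test time.

# default 22-type signature, built once per test run
default_sig <- make_signature(sim_config(seed = 1))

# small signature for fast cohort property loops (44 genes, 22 types)
small_cfg <- function(seed = 1, ...) {
  sim_config(n_genes = 44L, seed = seed, ...)
}
small_sig <- make_signature(small_cfg(seed = 1))

# planted-block expression: `k` blocks of `size` genes sharing a latent
# factor with loading sqrt(r2); between-block correlation 0
planted_blocks <- function(k = 3, size = 10, n = 100, r2 = 0.8, seed = 11) {
  with_seed_test(seed, {
    blocks <- rep(seq_len(k), each = size)
    f <- matrix(rnorm(k * n), k, n)
    X <- t(sapply(seq_along(blocks), function(g) {
      sqrt(r2) * f[blocks[g], ] + sqrt(1 - r2) * rnorm(n)
    }))
    dimnames(X) <- list(sprintf("g%02d", seq_along(blocks)),
                        sprintf("s%03d", seq_len(n)))
    list(expr = X, blocks = blocks)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# map a module_set to an integer assignment over `genes` (0 = unclustered)
module_assignment <- function(ms, genes) {
  a <- stats::setNames(rep(0L, length(genes)), genes)
  for (i in seq_along(ms$modules)) a[ms$modules[[i]]] <- i
  a
}

# brute-force k-group log-rank: sum over distinct event times of
# observed-minus-expected events per group, hypergeometric variance
logrank_bruteforce <- function(groups, times, events) {
  g <- factor(groups)
  k <- nlevels(g)
  ts <- sort(unique(times[events == 1]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(events == 1 & times == t)
    ni <- sapply(levels(g), function(l) sum(at_risk & g == l))
    di <- sapply(levels(g), function(l) sum(at_risk & g == l & events == 1 & times == t))
    O <- O + di
    E <- E + d * ni / n
    if (n > 1) {
      for (i in seq_len(k)) for (j in seq_len(k)) {
        V[i, j] <- V[i, j] + d * (n - d) / (n - 1) *
          (ni[i] * (i == j) / n - ni[i] * ni[j] / n^2)
      }
    }
  }
  dev <- (O - E)[-1]
  chi2 <- as.numeric(t(dev) %*% solve(V[-1, -1, drop = FALSE]) %*% dev)
  chi2
}
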