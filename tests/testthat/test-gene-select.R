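test_that("Welch test matches stats::t.test and its limits", {
  with_seed_test(2, {
    X <- matrix(rnorm(20 * 12, 5), 20, 12,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:12)))
    g <- rep(c("non-recurrent", "recurrent"), each = 6)
    res <- welch_test(X, g)
    for (i in c(1, 7, 20)) {
      tt <- t.test(X[i, g == "recurrent"], X[i, g == "non-recurrent"])
      expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
      expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-9)
    }

    # equal-variance, equal-n limit agrees with the pooled t test
    tp <- t.test(X[1, g == "recurrent"], X[1, g == "non-recurrent"],
                 var.equal = TRUE)
    expect_equal(res$t[1], unname(tp$statistic), tolerance = 1e-9)
  })

  ident <- matrix(rep(c(1, 2, 2, 1, 3, 3, 1, 2, 2, 1, 3, 3), 2), 2, 12,
                  byrow = TRUE, dimnames = list(c("a", "b"), NULL))
  same <- welch_test(ident, rep(c("x", "y"), each = 6))
  expect_true(all(abs(same$t) < 1e-12 | is.na(same$t)))

  degen <- matrix(c(rep(1, 4), rep(1, 4), rep(1, 4), rep(2, 4)), 2, 8,
                  byrow = TRUE, dimnames = list(c("flat", "jump"), NULL))
  dd <- welch_test(degen, rep(c("x", "y"), each = 4))
  expect_equal(dd$t[1], 0); expect_equal(dd$p[1], 1)
  expect_true(is.infinite(dd$t[2]))
  expect_match(dd$flag[2], "infinite")
})

test_that("Welch screen holds its nominal size on null genes", {
  with_seed_test(14, {
    X <- matrix(rnorm(1000 * 40), 1000, 40,
                dimnames = list(sprintf("g%04d", 1:1000), NULL))
    res <- welch_test(X, rep(c("a", "b"), each = 20))
    frac <- mean(res$p < 0.05)
    expect_gte(frac, 0.02)
    expect_lte(frac, 0.09)
  })
})

test_that("MCL modules recover planted correlation structure", {
  pb <- planted_blocks(k = 3, size = 10, n = 100, r2 = 0.8, seed = 11)
  ms <- find_modules(pb$expr)
  expect_s3_class(ms, "module_set")
  # disjoint modules of size >= 2
  all_genes <- unlist(ms$modules)
  expect_equal(anyDuplicated(all_genes), 0L)
  expect_true(all(lengths(ms$modules) >= 2))
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(module_assignment(ms, rownames(pb$expr)),
                                   pb$blocks)
  expect_gte(ari, 0.9)
})

test_that("MCL handles disconnected, fully-connected and empty graphs", {
  with_seed_test(8, {
    # two disconnected near-duplicate blocks of 4 genes
    b1 <- rep(1, 4) %o% rnorm(20) + matrix(rnorm(80, 0, 0.01), 4, 20)
    b2 <- rep(1, 4) %o% rnorm(20) + matrix(rnorm(80, 0, 0.01), 4, 20)
    Y <- rbind(b1, b2)
    dimnames(Y) <- list(sprintf("h%d", 1:8), sprintf("s%d", 1:20))
    m2 <- find_modules(Y)
    expect_equal(lengths(m2$modules), c(4L, 4L), ignore_attr = TRUE)

    # fully connected uniform graph collapses to one module
    one <- rep(1, 5) %o% rnorm(30) + matrix(rnorm(150, 0, 0.01), 5, 30)
    dimnames(one) <- list(sprintf("u%d", 1:5), sprintf("s%d", 1:30))
    m1 <- find_modules(one)
    expect_equal(length(m1$modules), 1L)
    expect_equal(length(m1$modules[[1]]), 5L)

    # empty edge set is a valid empty result
    iid <- matrix(rnorm(5 * 500), 5, 500,
                  dimnames = list(sprintf("z%d", 1:5), NULL))
    m0 <- find_modules(iid, r_threshold = 0.9)
    expect_equal(length(m0$modules), 0L)
  })
})

test_that("module partition is invariant to gene ordering", {
  pb <- planted_blocks(k = 2, size = 6, n = 80, r2 = 0.85, seed = 23)
  ms <- find_modules(pb$expr)
  perm <- c(7, 3, 12, 1, 9, 5, 11, 2, 8, 4, 10, 6)
  ms_p <- find_modules(pb$expr[perm, ])
  canon <- function(m) sort(sapply(m$modules, function(g) paste(sort(g), collapse = "+")))
  expect_identical(canon(ms), canon(ms_p))
})

test_that("GSEA ranking is antisymmetric and the tail flag counts floor(0.05 G)", {
  with_seed_test(4, {
    X <- matrix(rnorm(100 * 20, 5), 100, 20,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
    g <- rep(c("non-recurrent", "recurrent"), each = 10)
    rk <- gsea_rank(X, g)
    expect_equal(sort(rk$rank), 1:100)

    swapped <- gsea_rank(X, rev(g))
    expect_identical(rk$gene, rev(swapped$gene))

    flags <- bottom5pct(rk)
    expect_equal(sum(flags), 5L)
    expect_identical(names(which(flags)), rk$gene[96:100])
    expect_error(bottom5pct(rk, "nope"), "nope")
  })
})

test_that("enrichment score equals the brute-force prefix scan", {
  with_seed_test(19, {
    X <- matrix(rnorm(10 * 12, 5), 10, 12,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
    rk <- gsea_rank(X, rep(c("a", "b"), each = 6))

    brute_es <- function(ranked, set, weight) {
      G <- nrow(ranked)
      inset <- ranked$gene %in% set
      nh <- sum(inset)
      w <- abs(ranked$s2n)^weight
      best <- 0; run <- 0
      for (i in seq_len(G)) {
        run <- run + if (inset[i]) w[i] / sum(w[inset]) else -1 / (G - nh)
        if (abs(run) > abs(best)) best <- run
      }
      best
    }

    top3 <- rk$gene[1:3]
    expect_equal(gsea_es(rk, top3, weight = 0)$es, 1)  # max prefix deviation
    expect_equal(gsea_es(rk, top3, weight = 0)$es, brute_es(rk, top3, 0))

    scattered <- rk$gene[c(2, 5, 9)]
    for (w in c(0, 1)) {
      expect_equal(gsea_es(rk, scattered, weight = w)$es,
                   brute_es(rk, scattered, w), tolerance = 1e-12)
    }
    expect_error(gsea_es(rk, rk$gene), "degenerate")
    expect_error(gsea_es(rk, character(0)), "empty")
  })
})

test_that("prioritization requires module membership and either screen", {
  ms <- structure(list(modules = list(c("gA", "gB", "gC"), c("gD", "gE"))),
                  class = "module_set")
  welch_p <- c(gA = 0.9, gB = 0.01, gC = 0.5, gD = 0.2, gE = 0.04, gZ = 0.001)
  cox_p <- c(gA = 0.01, gB = 0.9, gC = 0.6, gD = 0.3, gE = 0.9, gZ = 0.001)
  out <- prioritize(ms, welch_p, cox_p)
  expect_setequal(out, c("gA", "gB", "gE"))  # OR semantics, module required
  expect_false("gZ" %in% out)                # significant but outside modules

  none <- prioritize(ms, c(gA = 0.9), c(gA = 0.9))
  expect_length(none, 0)
})
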