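test_that("composite groups follow the defining arithmetic", {
  uniform <- matrix(1 / 22, 22, 3,
                    dimnames = list(lm22_cell_types(), c("a", "b", "c")))
  comp <- build_composites(uniform)
  expect_equal(unname(comp["Monocyte-macrophage system", ]), rep(4 / 22, 3))
  expect_equal(unname(comp["Total B cells", ]), rep(2 / 22, 3))
  expect_equal(unname(comp["Total nonTreg CD4", ]), rep(4 / 22, 3))
  expect_equal(unname(comp["Total T cells", ]), rep(7 / 22, 3))
  expect_equal(unname(comp["Eosinophil-mast cells", ]), rep(3 / 22, 3))
  expect_equal(unname(comp["Lymphocytes", ] + comp["Non-lymphocytic leukocytes", ]),
               rep(1, 3), tolerance = 1e-9)

  all_plasma <- matrix(0, 22, 1, dimnames = list(lm22_cell_types(), "p"))
  all_plasma["Plasma cells", ] <- 1
  cp <- build_composites(all_plasma)
  expect_equal(unname(cp["Lymphocytes", ]), 1)
  expect_equal(unname(cp["Non-lymphocytic leukocytes", ]), 0)
  # zero denominators become NA, never Inf
  expect_true(is.na(cp["Tregs/NonTreg", ]))
  expect_true(is.na(cp["Lymphocyte/non-lymphocyte", ]))
})

test_that("composite rows carry the standard derived labels", {
  uniform <- matrix(1 / 22, 22, 1, dimnames = list(lm22_cell_types(), "a"))
  comp <- build_composites(uniform)
  expect_true(all(c("Total B cells", "Total T cells", "Total nonTreg CD4",
                    "Tregs/NonTreg", "Total NK", "Monocyte-macrophage system",
                    "Dendritic cells", "Eosinophil-mast cells") %in%
                    rownames(comp)))
  bad <- uniform[-3, , drop = FALSE]
  expect_error(build_composites(bad), "Plasma cells")
})

test_that("Tfh membership in the non-Treg CD4 composite is switchable", {
  uniform <- matrix(1 / 22, 22, 1, dimnames = list(lm22_cell_types(), "a"))
  with_tfh <- build_composites(uniform, tfh_in_nontreg = TRUE)
  without <- build_composites(uniform, tfh_in_nontreg = FALSE)
  expect_equal(unname(with_tfh["Total nonTreg CD4", ] -
                        without["Total nonTreg CD4", ]), 1 / 22)
  # Total T unchanged either way
  expect_equal(with_tfh["Total T cells", ], without["Total T cells", ])
})

test_that("summed composites are linear in the fractions", {
  with_seed_test(5, {
    f1 <- matrix(rexp(22 * 4), 22, 4, dimnames = list(lm22_cell_types(), NULL))
    f1 <- sweep(f1, 2, colSums(f1), "/")
    f2 <- matrix(rexp(22 * 4), 22, 4, dimnames = list(lm22_cell_types(), NULL))
    f2 <- sweep(f2, 2, colSums(f2), "/")
    a <- 0.3
    sums <- setdiff(rownames(build_composites(f1)),
                    c("Tregs/NonTreg", "Treg/T cells", "Lymphocyte/non-lymphocyte"))
    mix <- build_composites(a * f1 + (1 - a) * f2)[sums, ]
    lin <- a * build_composites(f1)[sums, ] + (1 - a) * build_composites(f2)[sums, ]
    expect_equal(mix, lin, tolerance = 1e-12)
  })
})

test_that("correlation handles binary, ordinal and degenerate inputs", {
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(correlate(y, y)$r, 1)
  expect_equal(correlate(c(6, 5, 4, 3, 2, 1), 1:6, "spearman")$r, -1)

  # hand-worked 6-point Spearman fixture: one adjacent swap per pair
  x <- c(1, 2, 3, 4, 5, 6)
  yy <- c(2, 1, 4, 3, 6, 5)
  # sum d^2 = 6 -> rho = 1 - 6*6/(6*35) = 0.8285714...
  expect_equal(correlate(x, yy, "spearman")$r, 1 - 36 / 210, tolerance = 1e-12)

  expect_equal(correlate(x, yy)$r, correlate(yy, x)$r)
  expect_equal(correlate(10 + 3 * x, yy)$r, correlate(x, yy)$r, tolerance = 1e-12)

  expect_error(correlate(1:2, 1:2), "3 paired")
  expect_error(correlate(1:5, rep(1, 5)), "distinct")
  expect_warning(res <- correlate(rep(2, 5), c(0, 1, 0, 1, 0)), "zero variance")
  expect_true(is.na(res$r))
})

test_that("Dunn's comparisons match the hand-computed rank-sum value", {
  # fully separated groups, n = 5 each: mean ranks 3 and 8,
  # z = (3 - 8) / sqrt((10*11/12) * (2/5)) = -2.61116...
  vals <- c(1:5, 6:10)
  groups <- rep(c("A", "B"), each = 5)
  gc <- group_compare(vals, groups)
  expect_equal(gc$pairs$z, -5 / sqrt((10 * 11 / 12) * (2 / 5)), tolerance = 1e-12)
  expect_equal(gc$pairs$p_adjusted, min(1, gc$pairs$p_unadjusted * 1))

  # identical distributions: all z = 0
  same <- group_compare(rep(1:4, 2), rep(c("A", "B"), each = 4))
  expect_equal(same$pairs$z, 0)

  # planted shift: the shifted group's two comparisons dominate
  with_seed_test(9, {
    x <- c(rnorm(20), rnorm(20), rnorm(20, 3))
    g <- rep(c("control", "non-recurrent", "recurrent"), each = 20)
    gc3 <- group_compare(x, g)
    expect_equal(nrow(gc3$pairs), 3L)
    involved <- grepl("recurrent$", gc3$pairs$group1) |
      grepl("^recurrent$", gc3$pairs$group2)
    zr <- abs(gc3$pairs$z[gc3$pairs$group1 == "recurrent" |
                            gc3$pairs$group2 == "recurrent"])
    zo <- abs(gc3$pairs$z[!(gc3$pairs$group1 == "recurrent" |
                              gc3$pairs$group2 == "recurrent")])
    expect_true(min(zr) > max(zo))
    # Bonferroni over the 3 pairwise comparisons
    expect_equal(gc3$pairs$p_adjusted,
                 pmin(1, gc3$pairs$p_unadjusted * 3))
  })

  expect_error(group_compare(1:5, c("a", "a", "b", "b", "c")), "< 2 members")
})

test_that("cohort correlation table reproduces the sign structure", {
  co <- simulate_cohort(small_cfg(seed = 4), small_sig)
  vals <- rbind(t(co$truth$fractions), build_composites(t(co$truth$fractions)))
  tab <- correlation_table(vals, co$clinical)
  get <- function(ct, col) tab[tab$cell_type == ct, col]
  expect_gt(get("T regs", "r_recurrence"), 0)
  expect_lt(get("Plasma cells", "r_recurrence"), 0)
  expect_gt(get("Monocyte-macrophage system", "r_recurrence"), 0)
  expect_true(all(abs(tab$r_recurrence) <= 1, na.rm = TRUE))
})
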