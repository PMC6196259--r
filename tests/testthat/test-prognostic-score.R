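# fractions matrix realizing all 16 high/low combinations of the four
# prognostic quantities (values 0/1, median split puts 1 = high)
all_combos <- function() {
  grid <- expand.grid(plasma = 0:1, nontreg = 0:1, treg = 0:1, mono = 0:1)
  m <- t(as.matrix(grid))
  rownames(m) <- c("Plasma cells", "Total nonTreg CD4", "T regs",
                   "Monocyte-macrophage system")
  colnames(m) <- sprintf("P%02d", seq_len(ncol(m)))
  m
}

test_that("net score takes 5 values with multiplicities 1/4/6/4/1 over all combinations", {
  st <- score_patients(all_combos())
  expect_equal(sort(unique(st$net_score)), -2:2)
  expect_equal(unname(table(st$net_score)), c(1L, 4L, 6L, 4L, 1L),
               ignore_attr = TRUE)
  expect_equal(levels(st$stratum), c("a", "b", "c", "d", "e"))
  expect_equal(unname(table(st$stratum)), c(1L, 4L, 6L, 4L, 1L),
               ignore_attr = TRUE)
  # positive and negative scores live on the 0-2 scale
  expect_equal(range(st$pos_score), c(0L, 2L))
  expect_equal(range(st$neg_score), c(0L, 2L))
  expect_equal(st$net_score, st$neg_score - st$pos_score)
})

test_that("score arithmetic and stratum mapping follow the definitions", {
  m <- all_combos()
  st <- score_patients(m)
  # double positive, no negative -> net -2, best stratum
  best <- st[st$plasma == "high" & st$nontreg_cd4 == "high" &
               st$treg == "low" & st$monomac == "low", ]
  expect_equal(best$net_score, -2L)
  expect_equal(as.character(best$stratum), "a")
  # all four high -> pos 2, neg 2, net 0, middle stratum
  mid <- st[st$plasma == "high" & st$nontreg_cd4 == "high" &
              st$treg == "high" & st$monomac == "high", ]
  expect_equal(mid$pos_score, 2L)
  expect_equal(mid$neg_score, 2L)
  expect_equal(as.character(mid$stratum), "c")

  # net score is antisymmetric under swapping the positive and negative sets
  swapped <- m
  rownames(swapped) <- c("T regs", "Monocyte-macrophage system",
                         "Plasma cells", "Total nonTreg CD4")
  st_sw <- score_patients(swapped)
  expect_equal(st_sw$net_score, -st$net_score)

  expect_error(score_patients(m[-1, , drop = FALSE]), "Plasma cells")
})

test_that("pairwise 2x2 categories follow the caption ordering", {
  m <- all_combos()
  st <- score_patients(m)
  # category 1 = high/high ... 4 = low/low for each pair
  expect_equal(st$cat_treg_monomac[st$treg == "high" & st$monomac == "high"][1], 1L)
  expect_equal(st$cat_treg_monomac[st$treg == "high" & st$monomac == "low"][1], 2L)
  expect_equal(st$cat_treg_monomac[st$treg == "low" & st$monomac == "high"][1], 3L)
  expect_equal(st$cat_treg_monomac[st$treg == "low" & st$monomac == "low"][1], 4L)
  expect_setequal(unique(st$cat_nontreg_plasma), 1:4)
  expect_equal(st$cat_plasma_monomac[st$plasma == "high" & st$monomac == "high"][1], 1L)
  expect_equal(st$cat_plasma_monomac[st$plasma == "low" & st$monomac == "low"][1], 4L)
})

test_that("median scoring is invariant to monotone per-cell-type transforms", {
  co <- simulate_cohort(small_cfg(seed = 31), small_sig)
  fr <- t(co$truth$fractions)
  st <- score_patients(fr)
  frt <- rbind(fr, build_composites(fr))
  types <- prognostic_cell_types()
  frt[types, ] <- exp(3 * frt[types, ])  # strictly increasing transform
  st_t <- score_patients(frt)
  expect_equal(st_t$net_score, st$net_score)
  expect_equal(as.character(st_t$stratum), as.character(st$stratum))
})

test_that("net score tracks the generator's latent score", {
  rho <- vapply(1:10, function(s) {
    co <- simulate_cohort(small_cfg(seed = 600 + s), small_sig)
    st <- score_patients(t(co$truth$fractions))
    cor(st$net_score, co$truth$latent_score, method = "spearman")
  }, numeric(1))
  expect_gte(median(rho), 0.6)
})

test_that("stratum survival orders risk and handles edge cases", {
  co <- simulate_cohort(small_cfg(seed = 77), small_sig)
  st <- score_patients(t(co$truth$fractions))
  ss <- stratum_survival(st, co$clinical, at_months = 80)
  expect_equal(ss$logrank$df, length(ss$curves) - 1L)
  expect_true(all(ss$freedom_at$surv >= 0 & ss$freedom_at$surv <= 1))
  expect_true(all(ss$freedom_at$lower <= ss$freedom_at$surv, na.rm = TRUE))

  # worst stratum has at least the event rate of the best across simulations
  wins <- vapply(1:50, function(s) {
    c2 <- simulate_cohort(small_cfg(seed = 700 + s), small_sig)
    s2 <- score_patients(t(c2$truth$fractions))
    ev <- tapply(c2$clinical$event, s2$stratum, mean)
    isTRUE(ev[["e"]] >= ev[["a"]])
  }, logical(1))
  expect_gte(mean(wins), 0.90)

  # single populated stratum: log-rank skipped with a warning
  one <- st
  one$stratum <- factor("c", levels = letters[1:5])
  expect_warning(ss1 <- stratum_survival(one, co$clinical), "one stratum|empty")
  expect_null(ss1$logrank)
})

test_that("null hazard gives a null 5-group log-rank", {
  pvals <- vapply(1:200, function(s) {
    c2 <- simulate_cohort(small_cfg(seed = 3000 + s, hazard_beta = 0), small_sig)
    s2 <- score_patients(t(c2$truth$fractions))
    suppressWarnings(
      stratum_survival(s2, c2$clinical)$logrank$p
    )
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.09)
})
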