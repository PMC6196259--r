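#' Composite immune cell groups and ratios
#'
#' Aggregates the 22 deconvolved leukocyte types into the composite groups
#' and ratios used for cohort-level comparison: total B cells, total T
#' cells, total non-Treg CD4+ T cells, NK cells, the monocyte-macrophage
#' system, dendritic cells, eosinophil-mast cells, lymphocytes vs
#' non-lymphocytic leukocytes, and the Treg/non-Treg, Treg/T-cell and
#' lymphocyte/non-lymphocyte ratios.
#'
#' T follicular helper cells are counted inside "Total nonTreg CD4" by
#' default (\code{tfh_in_nontreg}); "Total T cells" includes Tregs.
#' Ratios with a zero denominator are reported as \code{NA} so they drop
#' out of downstream rank statistics instead of propagating infinities.
#'
#' @param fractions Cell types x samples matrix carrying the standard 22
#'   labels (e.g. \code{$fractions} from [deconvolve()]), or a
#'   \code{deconv_result}.
#' @param tfh_in_nontreg Count T follicular helper cells in the non-Treg
#'   CD4 composite (default TRUE).
#' @return Matrix composites x samples, same units as the input for sums;
#'   ratios are unitless.
#' @export
build_composites <- function(fractions, tfh_in_nontreg = TRUE) {
  if (inherits(fractions, "deconv_result")) fractions <- fractions$fractions
  need <- lm22_cell_types()
  missing <- setdiff(need, rownames(fractions))
  if (length(missing))
    stop("fractions lack cell type(s): ", paste(missing, collapse = ", "))
  f <- fractions
  add <- function(rows) colSums(f[rows, , drop = FALSE])

  nontreg_members <- c("T cells CD4 naive", "T cells CD4 memory resting",
                       "T cells CD4 memory activated")
  if (tfh_in_nontreg)
    nontreg_members <- c(nontreg_members, "T cells follicular helper")

  total_b <- add(c("B cells naive", "B cells memory"))
  nontreg <- add(nontreg_members)
  total_t <- nontreg + add(c("T regs", "T cells CD8", "T cells gamma delta")) +
    (if (tfh_in_nontreg) 0 else add("T cells follicular helper"))
  total_nk <- add(c("NK cells resting", "NK cells activated"))
  monomac <- add(c("Monocytes", "M0-macrophages", "M1-macrophage", "M2-macrophages"))
  dc <- add(c("Dendritic cells resting", "Dendritic cells activated"))
  eos_mast <- add(c("Eosinophils", "Mast cells resting", "Mast cells activated"))
  lymph <- total_b + add("Plasma cells") + total_t + total_nk
  nonlymph <- colSums(f) - lymph

  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  out <- rbind(
    "Total B cells" = total_b,
    "Total T cells" = total_t,
    "Total nonTreg CD4" = nontreg,
    "Tregs/NonTreg" = ratio(add("T regs"), nontreg),
    "Treg/T cells" = ratio(add("T regs"), total_t),
    "Total NK" = total_nk,
    "Monocyte-macrophage system" = monomac,
    "Dendritic cells" = dc,
    "Eosinophil-mast cells" = eos_mast,
    "Lymphocytes" = lymph,
    "Non-lymphocytic leukocytes" = nonlymph,
    "Lymphocyte/non-lymphocyte" = ratio(lymph, nonlymph)
  )
  colnames(out) <- colnames(f)
  out
}

#' Correlation of a per-sample quantity with a clinical outcome
#'
#' Pearson (point-biserial when the outcome is binary 0/1) or Spearman
#' correlation with a two-sided p-value from the t approximation. Pairs
#' with missing values are dropped.
#'
#' @param values Per-sample numeric vector.
#' @param outcome Per-sample binary (0/1) or ordinal outcome.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return List with \code{r}, \code{p}, \code{n} (pairs used) and
#'   \code{method}. Zero variance in either vector yields \code{r = NA}
#'   with a warning — never a silent 0.
#' @export
correlate <- function(values, outcome, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(values) & is.finite(outcome)
  x <- values[ok]; y <- outcome[ok]
  if (length(x) < 3) stop("correlate: need at least 3 paired observations")
  if (length(unique(y)) < 2) stop("correlate: outcome has fewer than 2 distinct values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlate: zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x), method = method))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), method = method)
}

#' Kruskal-Wallis ranks with Dunn's pairwise comparisons
#'
#' Nonparametric multi-group comparison: pooled ranks, tie-corrected
#' Kruskal-Wallis omnibus test, and Dunn's pairwise z statistics with
#' Bonferroni adjustment over the number of pairwise comparisons.
#'
#' @param values Per-sample numeric vector.
#' @param groups Group label per sample; at least 2 groups with at least 2
#'   members each.
#' @return List: \code{kruskal} (htest from [stats::kruskal.test()]) and
#'   \code{pairs}, a data frame with columns \code{group1}, \code{group2},
#'   \code{z}, \code{p_unadjusted}, \code{p_adjusted}.
#' @export
group_compare <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  x <- values[ok]
  g <- factor(groups[ok])
  tab <- table(g)
  if (length(tab) < 2) stop("group_compare: need at least 2 groups")
  if (any(tab < 2))
    stop("group_compare: group(s) with < 2 members: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  vfac <- N * (N + 1) / 12 - tie_term

  levs <- levels(g)
  cmb <- utils::combn(levs, 2)
  m <- ncol(cmb)
  res <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                    z = NA_real_, p_unadjusted = NA_real_,
                    p_adjusted = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt(vfac * (1 / tab[[a]] + 1 / tab[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    res$z[i] <- z
    res$p_unadjusted[i] <- p
    res$p_adjusted[i] <- min(1, p * m)
  }
  kw <- stats::kruskal.test(x, g)
  list(kruskal = kw, pairs = res)
}

#' Cohort correlation table of cell types with recurrence and stage
#'
#' For every row of a fractions-plus-composites matrix, the point-biserial
#' correlation with recurrence status (0/1) and with ordinal tumor stage
#' (IA = 1, IB = 2), with two-sided p-values.
#'
#' @param values Cell types (and composites) x samples matrix.
#' @param clinical Clinical data frame with \code{recurrence} and
#'   \code{stage} for the same samples (matched by \code{sample_id} against
#'   the column names).
#' @param method Correlation method passed to [correlate()].
#' @return Data frame: cell_type, r_recurrence, p_recurrence, r_stage,
#'   p_stage.
#' @export
correlation_table <- function(values, clinical, method = "pearson") {
  idx <- match(colnames(values), clinical$sample_id)
  if (anyNA(idx)) stop("clinical table lacks some samples")
  rec <- clinical$recurrence[idx]
  stage <- ifelse(clinical$stage[idx] == "IB", 2, 1)
  one <- function(v, o) {
    res <- tryCatch(correlate(v, o, method), warning = function(w) NULL,
                    error = function(e) NULL)
    if (is.null(res)) c(NA_real_, NA_real_) else c(res$r, res$p)
  }
  rows <- t(apply(values, 1, function(v) c(one(v, rec), one(v, stage))))
  data.frame(cell_type = rownames(values),
             r_recurrence = rows[, 1], p_recurrence = rows[, 2],
             r_stage = rows[, 3], p_stage = rows[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}
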