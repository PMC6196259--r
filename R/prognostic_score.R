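#' The four prognostic cell quantities of the net score
#'
#' Two positive prognostic quantities (plasma cells, total non-Treg CD4+
#' T cells) and two negative ones (Tregs, the monocyte-macrophage system).
#'
#' @return Named character vector mapping score roles to row labels.
#' @export
prognostic_cell_types <- function() {
  c(plasma = "Plasma cells",
    nontreg_cd4 = "Total nonTreg CD4",
    treg = "T regs",
    monomac = "Monocyte-macrophage system")
}

#' Score patients by their net prognostic immune phenotype
#'
#' Each of the four prognostic cell quantities is dichotomized high/low
#' across the cohort. The positive prognostic score (0-2) counts high calls
#' for plasma cells and non-Treg CD4+ T cells; the negative prognostic
#' score (0-2) counts high calls for Tregs and the monocyte-macrophage
#' system. The net score is negative minus positive, so higher net score
#' means a worse immune configuration, and maps the cohort onto five strata
#' a (net -2, best prognosis) through e (net +2, worst).
#'
#' The three pairwise 2x2 stratifications are also emitted, with category
#' numbers ordered high/high (1), high/low (2), low/high (3), low/low (4):
#' Treg x monocyte-macrophage (negative factors), non-Treg CD4 x plasma
#' (positive factors), and plasma x monocyte-macrophage.
#'
#' @param fractions Cell types x samples matrix containing the 22 base
#'   types (composites are added automatically), or a matrix already
#'   containing the four rows of [prognostic_cell_types()].
#' @param method Dichotomization method, \code{"median"} (default) or
#'   \code{"mean"}; passed to [dichotomize()].
#' @return Data frame of class \code{score_table}: sample_id, the four
#'   high/low calls, pos_score, neg_score, net_score, stratum, and the
#'   three 2x2 category columns \code{cat_treg_monomac},
#'   \code{cat_nontreg_plasma}, \code{cat_plasma_monomac}.
#' @export
score_patients <- function(fractions, method = c("median", "mean")) {
  method <- match.arg(method)
  if (inherits(fractions, "deconv_result")) fractions <- fractions$fractions
  types <- prognostic_cell_types()
  if (!all(types %in% rownames(fractions))) {
    if (all(lm22_cell_types() %in% rownames(fractions))) {
      fractions <- rbind(fractions, build_composites(fractions))
    }
    missing <- setdiff(types, rownames(fractions))
    if (length(missing))
      stop("fractions lack required quantities: ", paste(missing, collapse = ", "))
  }
  calls <- vapply(types, function(ct) {
    dichotomize(fractions[ct, ], method = method)$label == "high"
  }, logical(ncol(fractions)))
  colnames(calls) <- names(types)

  pos <- calls[, "plasma"] + calls[, "nontreg_cd4"]
  neg <- calls[, "treg"] + calls[, "monomac"]
  net <- neg - pos
  stratum <- c("a", "b", "c", "d", "e")[net + 3]

  cat22 <- function(a, b) {
    # 1 = high/high, 2 = high/low, 3 = low/high, 4 = low/low
    ifelse(a & b, 1L, ifelse(a & !b, 2L, ifelse(!a & b, 3L, 4L)))
  }
  out <- data.frame(
    sample_id = colnames(fractions),
    plasma = ifelse(calls[, "plasma"], "high", "low"),
    nontreg_cd4 = ifelse(calls[, "nontreg_cd4"], "high", "low"),
    treg = ifelse(calls[, "treg"], "high", "low"),
    monomac = ifelse(calls[, "monomac"], "high", "low"),
    pos_score = as.integer(pos),
    neg_score = as.integer(neg),
    net_score = as.integer(net),
    stratum = factor(stratum, levels = c("a", "b", "c", "d", "e")),
    cat_treg_monomac = cat22(calls[, "treg"], calls[, "monomac"]),
    cat_nontreg_plasma = cat22(calls[, "nontreg_cd4"], calls[, "plasma"]),
    cat_plasma_monomac = cat22(calls[, "plasma"], calls[, "monomac"]),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Freedom from recurrence by prognostic stratum
#'
#' Kaplan-Meier curve per stratum, the overall k-group log-rank test, and
#' per-stratum freedom from recurrence at a queried time with Greenwood
#' confidence intervals. Empty strata are dropped with a warning.
#'
#' @param scores A \code{score_table} from [score_patients()] (or any data
#'   frame with \code{sample_id} and a stratum column).
#' @param clinical Clinical data frame with \code{sample_id},
#'   \code{time_months}, \code{event}.
#' @param stratum_col Column of \code{scores} defining the strata
#'   (default \code{"stratum"}).
#' @param at_months Time at which to report freedom from recurrence
#'   (default 80).
#' @return List: \code{curves} (named list of \code{km_curve}),
#'   \code{logrank} (or NULL when only one stratum is populated),
#'   \code{freedom_at} (data frame stratum / n / events / surv / lower /
#'   upper at \code{at_months}).
#' @export
stratum_survival <- function(scores, clinical, stratum_col = "stratum",
                             at_months = 80) {
  idx <- match(scores$sample_id, clinical$sample_id)
  if (anyNA(idx)) stop("clinical table lacks some scored samples")
  times <- clinical$time_months[idx]
  events <- clinical$event[idx]
  if (sum(events) < 1) stop("stratum_survival: no events observed")
  strata <- factor(scores[[stratum_col]])
  present <- levels(strata)[table(strata) > 0]
  if (length(present) < nlevels(strata))
    warning("dropping empty strata: ",
            paste(setdiff(levels(strata), present), collapse = ", "))
  strata <- factor(as.character(strata), levels = present)

  curves <- lapply(present, function(s) {
    sel <- strata == s
    km_estimate(times[sel], events[sel])
  })
  names(curves) <- present

  lr <- NULL
  if (length(present) >= 2) {
    lr <- logrank(strata, times, events)
  } else {
    warning("all patients in one stratum; log-rank skipped")
  }

  freedom <- do.call(rbind, lapply(present, function(s) {
    sel <- strata == s
    at <- km_at(curves[[s]], at_months)
    data.frame(stratum = s, n = sum(sel), events = sum(events[sel]),
               surv = at$surv, lower = at$lower, upper = at$upper,
               stringsAsFactors = FALSE)
  }))
  list(curves = curves, logrank = lr, freedom_at = freedom,
       at_months = at_months)
}
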