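#' Configuration for the synthetic early-stage lung adenocarcinoma cohort
#'
#' Bundles and validates every parameter of the cohort generator. The
#' defaults describe a merged multi-batch microarray cohort of 280
#' early-stage (IA/IB) patients: 22 leukocyte types whose relative RNA
#' fractions follow group-dependent Dirichlet distributions, with the
#' recurrent group enriched for Tregs and M0/M2 macrophages and depleted of
#' plasma cells and non-Treg CD4+ T cells; recurrence times follow a
#' proportional-hazards model driven by the latent immune composition, with
#' independent exponential right-censoring.
#'
#' @param n_patients Cohort size (default 280, the merged analysis cohort).
#' @param n_genes Number of signature genes simulated (default 440; every
#'   gene is a marker for one of the cell types).
#' @param n_cell_types Number of leukocyte types (default 22).
#' @param n_batches Number of source batches/datasets merged (default 3).
#' @param recurrent_fraction Proportion of patients in the recurrent group,
#'   in (0,1); default 0.3.
#' @param dirichlet_base Positive Dirichlet concentration per cell type for
#'   the non-recurrent group. The default encodes a plausible tumor
#'   leukocyte profile dominated by plasma cells, macrophages and T cells.
#' @param effect_shift Signed log-scale shift applied to the concentrations
#'   of the recurrent group (concentration = base * exp(shift)). Defaults
#'   raise Tregs and M0/M2 macrophages and lower plasma cells and the
#'   non-Treg CD4 subsets, matching the direction of the cohort
#'   correlations.
#' @param noise_sd SD of multiplicative log-normal measurement noise on the
#'   expression values (default 0.2).
#' @param batch_shift_sd SD of the per-batch gene-wise additive shift on the
#'   log2 scale (default 0.3).
#' @param batch_scale_sd SD of the per-batch gene-wise log scale factor
#'   applied on the log2 scale (default 0.05).
#' @param hazard_baseline Baseline recurrence hazard, events/month (default
#'   0.0035: a realistic recurrence tempo for resected stage IA/IB disease).
#' @param hazard_beta Log-hazard per unit latent net immune score (default
#'   0.3).
#' @param censor_rate Rate of the independent exponential censoring process,
#'   per month (default 0.008).
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 280L,
                       n_genes = 440L,
                       n_cell_types = 22L,
                       n_batches = 3L,
                       recurrent_fraction = 0.3,
                       dirichlet_base = NULL,
                       effect_shift = NULL,
                       noise_sd = 0.2,
                       batch_shift_sd = 0.3,
                       batch_scale_sd = 0.05,
                       hazard_baseline = 0.0035,
                       hazard_beta = 0.3,
                       censor_rate = 0.008,
                       seed = 1L) {
  k <- as.integer(n_cell_types)
  if (is.null(dirichlet_base)) dirichlet_base <- default_dirichlet_base(k)
  if (is.null(effect_shift)) effect_shift <- default_effect_shift(k)
  cfg <- list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
              n_cell_types = k, n_batches = as.integer(n_batches),
              recurrent_fraction = recurrent_fraction,
              dirichlet_base = dirichlet_base, effect_shift = effect_shift,
              noise_sd = noise_sd, batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd,
              hazard_baseline = hazard_baseline, hazard_beta = hazard_beta,
              censor_rate = censor_rate, seed = as.integer(seed))
  num <- unlist(cfg[c("recurrent_fraction", "dirichlet_base", "effect_shift",
                      "noise_sd", "batch_shift_sd", "batch_scale_sd",
                      "hazard_baseline", "hazard_beta", "censor_rate")])
  if (any(!is.finite(num))) stop("sim_config: all numeric fields must be finite")
  if (cfg$n_patients < 1L || cfg$n_genes < 1L || k < 1L || cfg$n_batches < 1L)
    stop("sim_config: sizes must be positive")
  if (cfg$recurrent_fraction <= 0 || cfg$recurrent_fraction >= 1)
    stop("sim_config: recurrent_fraction must lie strictly in (0, 1)")
  if (length(dirichlet_base) != k || length(effect_shift) != k)
    stop("sim_config: dirichlet_base and effect_shift must have one entry per cell type")
  if (any(dirichlet_base <= 0))
    stop("sim_config: Dirichlet concentrations must be strictly positive")
  if (any(dirichlet_base * exp(effect_shift) <= 0))
    stop("sim_config: shifted Dirichlet concentrations must remain positive")
  if (noise_sd < 0 || batch_shift_sd < 0 || batch_scale_sd < 0)
    stop("sim_config: noise and batch SDs must be nonnegative")
  if (hazard_baseline <= 0 || censor_rate <= 0)
    stop("sim_config: hazard_baseline and censor_rate must be positive")
  if (cfg$n_genes < k)
    stop("sim_config: n_genes must be >= n_cell_types for identifiability")
  structure(cfg, class = "sim_config")
}

# Plausible leukocyte-RNA concentration profile (sums to ~20, so fractions
# have realistic sampling variability). Order follows lm22_cell_types().
default_dirichlet_base <- function(k) {
  if (k == 22L) {
    c(`B cells naive` = 0.8, `B cells memory` = 0.4, `Plasma cells` = 2.5,
      `T cells CD8` = 1.5, `T cells CD4 naive` = 0.4,
      `T cells CD4 memory resting` = 2.0, `T cells CD4 memory activated` = 0.6,
      `T cells follicular helper` = 0.8, `T regs` = 0.8,
      `T cells gamma delta` = 0.4, `NK cells resting` = 0.8,
      `NK cells activated` = 0.4, `Monocytes` = 0.8, `M0-macrophages` = 2.5,
      `M1-macrophage` = 0.8, `M2-macrophages` = 2.0,
      `Dendritic cells resting` = 0.4, `Dendritic cells activated` = 0.3,
      `Mast cells resting` = 0.8, `Mast cells activated` = 0.2,
      Eosinophils = 0.2, Neutrophils = 0.6)
  } else {
    stats::setNames(rep(1, k), sprintf("CellType%02d", seq_len(k)))
  }
}

# Log-scale concentration shifts for the recurrent group: up for Tregs and
# M0/M2 macrophages, down for plasma cells and the non-Treg CD4 subsets.
default_effect_shift <- function(k) {
  if (k != 22L) return(stats::setNames(rep(0, k), sprintf("CellType%02d", seq_len(k))))
  s <- stats::setNames(rep(0, 22L), names(default_dirichlet_base(22L)))
  s["T regs"] <- 0.45
  s["M0-macrophages"] <- 0.22
  s["M2-macrophages"] <- 0.14
  s["Plasma cells"] <- -0.26
  s["T cells CD4 naive"] <- -0.08
  s["T cells CD4 memory resting"] <- -0.10
  s["T cells CD4 memory activated"] <- -0.15
  s
}

#' Simulate a multi-batch expression cohort with survival outcomes
#'
#' Draws per-patient leukocyte fractions from group-dependent Dirichlet
#' distributions, forms bulk expression as signature x fractions perturbed
#' by log-normal noise, applies per-batch gene-wise location/scale effects
#' on the log2 scale, and generates recurrence times from a
#' proportional-hazards model whose linear predictor is the latent net
#' immune score
#' \eqn{(z(\mathrm{Treg}) + z(\mathrm{monomac})) - (z(\mathrm{plasma}) + z(\mathrm{nonTregCD4}))}
#' computed from the true fractions. Censoring is exponential and
#' independent of covariates; the observed time is the minimum of event and
#' censoring time.
#'
#' @param config A [sim_config()].
#' @param signature Signature matrix from [make_signature()]; its column
#'   count must equal \code{config$n_cell_types}.
#' @return List with components \code{expression} (genes x samples, linear
#'   scale, \code{attr(,"scale") == "linear"}), \code{clinical} (data frame:
#'   sample_id, recurrence, time_months, event, stage, batch), and
#'   \code{truth} (true fractions, group/batch labels, true event and censor
#'   times, latent score).
#' @export
simulate_cohort <- function(config, signature = make_signature(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (ncol(signature) != config$n_cell_types)
    stop("signature has ", ncol(signature), " columns but config expects ",
         config$n_cell_types, " cell types")
  n <- config$n_patients
  k <- config$n_cell_types
  types <- colnames(signature)

  with_seed(config$seed, {
    ids <- sprintf("S%04d", seq_len(n))
    n_rec <- max(1L, min(n - 1L, round(n * config$recurrent_fraction)))
    group <- rep("non-recurrent", n)
    group[sample.int(n, n_rec)] <- "recurrent"
    batch <- sample(rep_len(sprintf("batch%d", seq_len(config$n_batches)), n))

    alpha_nr <- config$dirichlet_base
    alpha_r <- config$dirichlet_base * exp(config$effect_shift)
    fractions <- matrix(NA_real_, n, k, dimnames = list(ids, types))
    is_rec <- group == "recurrent"
    if (any(!is_rec)) fractions[!is_rec, ] <- rdirichlet(sum(!is_rec), alpha_nr)
    if (any(is_rec)) fractions[is_rec, ] <- rdirichlet(sum(is_rec), alpha_r)

    # bulk expression: signature %*% fractions', then log-normal noise
    expr <- signature %*% t(fractions)
    if (config$noise_sd > 0)
      expr <- expr * exp(matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                                nrow(expr), ncol(expr)))

    # batch effects: gene-wise location/scale on the log2 scale
    if (config$batch_shift_sd > 0 || config$batch_scale_sd > 0) {
      l2 <- log2(expr)
      for (b in unique(batch)) {
        sel <- batch == b
        shift <- stats::rnorm(nrow(expr), 0, config$batch_shift_sd)
        scale <- exp(stats::rnorm(nrow(expr), 0, config$batch_scale_sd))
        l2[, sel] <- l2[, sel] * scale + shift
      }
      expr <- 2^l2
    }
    attr(expr, "scale") <- "linear"

    latent <- if (all(c("T regs", "Plasma cells") %in% types)) {
      latent_net_score(fractions)
    } else {
      rep(0, n)  # no immune-driven hazard without the prognostic cell types
    }
    rate <- config$hazard_baseline * exp(config$hazard_beta * latent)
    true_event <- stats::rexp(n, rate = rate)
    censor <- stats::rexp(n, rate = config$censor_rate)
    time_obs <- pmin(true_event, censor)
    event <- as.integer(true_event <= censor)

    # stage IB more likely in the recurrent group (stage-recurrence link)
    p_ib <- ifelse(is_rec, 0.60, 0.42)
    stage <- ifelse(stats::runif(n) < p_ib, "IB", "IA")

    clinical <- data.frame(sample_id = ids,
                           recurrence = as.integer(is_rec),
                           time_months = time_obs,
                           event = event,
                           stage = stage,
                           batch = batch,
                           stringsAsFactors = FALSE)
    truth <- list(fractions = fractions, group = group, batch = batch,
                  true_event_times = true_event, censor_times = censor,
                  latent_score = latent)
    list(expression = expr, clinical = clinical, truth = truth)
  })
}

#' Latent net immune score from true cell fractions
#'
#' Cohort-standardized (z-scored) combination of the four prognostic cell
#' quantities: \code{z(Tregs) + z(monocyte-macrophage) - z(plasma cells) -
#' z(non-Treg CD4)}. Higher values mean a worse immune configuration.
#'
#' @param fractions Patients x cell-types fraction matrix with the standard
#'   22 column labels.
#' @return Numeric vector, one score per patient.
#' @export
latent_net_score <- function(fractions) {
  need <- c("T regs", "Plasma cells")
  missing <- setdiff(need, colnames(fractions))
  if (length(missing)) stop("fractions lack cell types: ", paste(missing, collapse = ", "))
  monomac <- rowSums(fractions[, intersect(c("Monocytes", "M0-macrophages",
                                             "M1-macrophage", "M2-macrophages"),
                                           colnames(fractions)), drop = FALSE])
  nontreg <- rowSums(fractions[, intersect(c("T cells CD4 naive",
                                             "T cells CD4 memory resting",
                                             "T cells CD4 memory activated",
                                             "T cells follicular helper"),
                                           colnames(fractions)), drop = FALSE])
  (zscore(fractions[, "T regs"]) + zscore(monomac)) -
    (zscore(fractions[, "Plasma cells"]) + zscore(nontreg))
}

#' Write a simulated cohort to plain-text files
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param signature Optional signature matrix to write alongside.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, signature = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             fractions = file.path(dir, "true_fractions.tsv"))
  write_matrix_tsv(cohort$expression, paths["expression"], id_col = "gene")
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$truth$fractions, paths["fractions"], id_col = "sample_id")
  if (!is.null(signature)) {
    paths <- c(paths, signature = file.path(dir, "signature.tsv"))
    write_matrix_tsv(signature, paths["signature"], id_col = "gene")
  }
  invisible(paths)
}
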