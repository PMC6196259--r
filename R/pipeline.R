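#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with
#' defaults matching the study's stated settings: array-quality cutoff
#' 1.25, 1000 deconvolution permutations, MCL inflation 2.5 over the
#' |r| > 0.30 correlation graph, nominal alpha 0.05.
#'
#' @param expression,clinical,signature Input file paths (TSV), or NULL
#'   when \code{simulate = TRUE}.
#' @param simulate Generate the cohort with [simulate_cohort()] instead of
#'   reading files.
#' @param sim Optional [sim_config()] used when simulating.
#' @param qc_cutoff Array-quality cutoff (default 1.25).
#' @param nus nu grid for the SVR (default c(0.25, 0.5, 0.75)).
#' @param permutations Deconvolution permutations (default 1000).
#' @param alpha Nominal significance level (default 0.05).
#' @param r_threshold Module-graph correlation threshold (default 0.30).
#' @param inflation MCL inflation (default 2.5).
#' @param split_method Dichotomization method, "median" or "mean".
#' @param var_delta,var_min_samples Variability-filter parameters (log2
#'   deviation threshold, tolerated low-variability sample count).
#' @param at_months Time at which freedom from recurrence is reported.
#' @param seed Integer seed for every stochastic stage.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expression = NULL, clinical = NULL,
                            signature = NULL, simulate = is.null(expression),
                            sim = NULL, qc_cutoff = 1.25,
                            nus = c(0.25, 0.5, 0.75), permutations = 1000L,
                            alpha = 0.05, r_threshold = 0.30, inflation = 2.5,
                            split_method = "median", var_delta = 0.02,
                            var_min_samples = 20L, at_months = 80,
                            seed = 1L) {
  if (!simulate && (is.null(expression) || is.null(clinical) || is.null(signature)))
    stop("pipeline_config: expression, clinical and signature paths are ",
         "required unless simulate = TRUE")
  structure(list(expression = expression, clinical = clinical,
                 signature = signature, simulate = simulate,
                 sim = sim %||% sim_config(seed = seed),
                 qc_cutoff = qc_cutoff, nus = nus,
                 permutations = as.integer(permutations), alpha = alpha,
                 r_threshold = r_threshold, inflation = inflation,
                 split_method = split_method, var_delta = var_delta,
                 var_min_samples = as.integer(var_min_samples),
                 at_months = at_months, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat-key YAML pipeline configuration
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full recurrence analysis pipeline
#'
#' simulate/load -> quality filter -> quantile normalize -> batch adjust ->
#' variability filter -> deconvolve -> composites & correlations -> gene
#' screens & modules -> prognostic score -> stratified survival. Every
#' stage's output is written under \code{out_dir} together with a
#' provenance manifest (parameters, seed, file checksums). Reruns with the
#' same config and seed are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("inputs", {
    if (config$simulate) {
      sig <- make_signature(config$sim)
      cohort <- simulate_cohort(config$sim, sig)
      write_cohort(cohort, out_dir, signature = sig)
      list(expr = cohort$expression, clinical = cohort$clinical,
           signature = sig, truth = cohort$truth)
    } else {
      list(expr = read_matrix_tsv(config$expression, scale = "linear"),
           clinical = read_clinical_tsv(config$clinical),
           signature = read_matrix_tsv(config$signature), truth = NULL)
    }
  })

  pre <- stage("preprocess", {
    scores <- quality_surrogate(log2(inputs$expr + 1))
    kept <- quality_filter(inputs$expr, scores, cutoff = config$qc_cutoff)
    l2 <- log2(kept + 1)
    l2 <- quantile_normalize(l2)
    batches <- inputs$clinical$batch[match(colnames(l2), inputs$clinical$sample_id)]
    adj <- if (length(unique(batches)) >= 2) batch_adjust(l2, batches) else l2
    filt <- variability_filter(adj, min_samples = config$var_min_samples,
                               delta = config$var_delta)
    list(scores = scores, log2_adjusted = adj, filtered = filt,
         linear_adjusted = pmax(2^adj - 1, 0))
  })
  write_matrix_tsv(pre$filtered, file.path(out_dir, "expression_preprocessed.tsv"),
                   id_col = "gene")

  clin <- drop_missing_followup(inputs$clinical)
  clin <- clin[clin$sample_id %in% colnames(pre$linear_adjusted), , drop = FALSE]

  dec <- stage("deconvolution",
    deconvolve(pre$linear_adjusted, inputs$signature, nus = config$nus,
               permutations = config$permutations, seed = config$seed))
  write_matrix_tsv(fractions_percent(dec), file.path(out_dir, "fractions_percent.tsv"),
                   id_col = "cell_type")

  comp <- stage("composition", {
    composites <- build_composites(dec)
    all_vals <- rbind(dec$fractions, composites)
    ct <- correlation_table(all_vals[, clin$sample_id, drop = FALSE], clin)
    list(composites = composites, table = ct)
  })
  utils::write.table(comp$table, file.path(out_dir, "correlation_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- stage("gene_select", {
    ex <- pre$filtered[, clin$sample_id, drop = FALSE]
    if (nrow(ex) == 0)
      stop("no genes survive the variability filter; lower var_delta")
    grp <- factor(ifelse(clin$recurrence == 1, "recurrent", "non-recurrent"),
                  levels = c("non-recurrent", "recurrent"))
    welch <- welch_test(ex, grp)
    cox <- cox_screen(ex, clin$time_months, clin$event)
    mods <- if (nrow(ex) >= 3) {
      find_modules(ex, r_threshold = config$r_threshold,
                   inflation = config$inflation)
    } else {
      structure(list(modules = list(), r_threshold = config$r_threshold,
                     inflation = config$inflation, iterations = 0L),
                class = "module_set")
    }
    ranked <- gsea_rank(ex, grp)
    cand <- prioritize(mods, stats::setNames(welch$p, welch$gene),
                       stats::setNames(cox$p, cox$gene), alpha = config$alpha)
    tail_flag <- bottom5pct(ranked, if (length(cand)) cand else NULL)
    list(welch = welch, cox = cox, modules = mods, ranked = ranked,
         candidates = cand, candidate_bottom5 = tail_flag)
  })
  utils::write.table(genes$ranked, file.path(out_dir, "gsea_ranked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(genes$candidates, file.path(out_dir, "candidate_genes.txt"))

  score <- stage("prognostic_score", {
    fr <- dec$fractions[, clin$sample_id, drop = FALSE]
    st <- score_patients(fr, method = config$split_method)
    surv <- stratum_survival(st, clin, at_months = config$at_months)
    list(table = st, survival = surv)
  })
  utils::write.table(score$table, file.path(out_dir, "score_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(score$survival$freedom_at,
                     file.path(out_dir, "freedom_from_recurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- stage("manifest", {
    rel <- list.files(out_dir, recursive = TRUE)
    rel <- rel[rel != "manifest.json"]
    files <- stats::setNames(file.path(out_dir, rel), rel)
    params <- config[c("qc_cutoff", "permutations", "alpha", "r_threshold",
                       "inflation", "split_method", "var_delta",
                       "var_min_samples", "at_months", "seed")]
    params$nus <- config$nus
    m <- list(parameters = params,
              simulated = config$simulate,
              n_samples = ncol(pre$linear_adjusted),
              n_genes_retained = nrow(pre$filtered),
              checksums = as.list(stats::setNames(unname(tools::md5sum(files)), rel)))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    m
  })

  invisible(list(inputs = inputs, preprocess = pre, clinical = clin,
                 deconvolution = dec, composition = comp, genes = genes,
                 score = score, manifest = manifest))
}
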