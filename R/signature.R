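#' The 22 leukocyte types resolved by the default reference signature
#'
#' Cell-type labels for the 22 leukocyte populations of the LM22-style
#' reference, in the conventional order (B/plasma lineage, T lineage, NK,
#' monocyte-macrophage lineage, dendritic cells, mast cells, eosinophils,
#' neutrophils).
#'
#' @return Character vector of length 22.
#' @export
lm22_cell_types <- function() {
  c("B cells naive", "B cells memory", "Plasma cells",
    "T cells CD8", "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T regs", "T cells gamma delta",
    "NK cells resting", "NK cells activated",
    "Monocytes", "M0-macrophages", "M1-macrophage", "M2-macrophages",
    "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells resting", "Mast cells activated",
    "Eosinophils", "Neutrophils")
}

#' Build a marker-structured synthetic reference signature matrix
#'
#' Constructs a nonnegative genes x cell-types reference profile matrix in
#' which every cell type owns a set of marker genes strongly over-expressed
#' (by construction more than 5-fold) relative to every other type. This is
#' the structural stand-in for an LM22-like leukocyte signature: it is not a
#' biological gene list, but it has the property deconvolution relies on --
#' well-conditioned, marker-dominated columns.
#'
#' Genes are assigned to cell types round-robin, so each type receives at
#' least \code{floor(n_genes / n_cell_types)} markers.
#'
#' @param config A [sim_config()] object (fields \code{n_genes},
#'   \code{n_cell_types}, \code{seed} are used).
#' @return Numeric matrix (\code{n_genes} x \code{n_cell_types}) with gene
#'   row names and cell-type column names; when \code{n_cell_types} is 22
#'   the columns carry the standard labels of [lm22_cell_types()].
#' @export
make_signature <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- config$n_genes
  k <- config$n_cell_types
  if (n_genes < k) {
    stop("n_genes (", n_genes, ") must be >= n_cell_types (", k,
         "): the deconvolution problem is unidentifiable otherwise")
  }
  types <- if (k == 22L) lm22_cell_types() else sprintf("CellType%02d", seq_len(k))

  with_seed(config$seed + 1000L, {
    # background: modest, gene-specific baseline shared across types
    base <- matrix(stats::runif(n_genes * k, min = 0.1, max = 1.0),
                   nrow = n_genes, ncol = k)
    marker_type <- rep_len(seq_len(k), n_genes)
    fold <- stats::runif(n_genes, min = 6, max = 12)
    for (g in seq_len(n_genes)) {
      # marker value strictly > 5x the largest non-marker value in the row
      base[g, marker_type[g]] <- fold[g] * max(base[g, -marker_type[g]])
    }
    dimnames(base) <- list(sprintf("GENE%04d", seq_len(n_genes)), types)
    base
  })
}
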