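#' Read a genes-in-rows expression (or signature) TSV
#'
#' First column holds row identifiers; remaining columns are numeric.
#'
#' @param path File path.
#' @param scale Declared scale of the values, \code{"linear"} or
#'   \code{"log2"}; stored as an attribute on the returned matrix.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  attr(m, "scale") <- scale
  m
}

#' Write a matrix as TSV with an identifier column
#'
#' @param m Matrix with row names.
#' @param path Output path.
#' @param id_col Name of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table TSV
#'
#' Expects columns \code{sample_id}, \code{recurrence}, \code{time_months},
#' \code{event}, and optionally \code{stage} and \code{batch}.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "recurrence", "time_months", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' Drop samples with unusable follow-up information
#'
#' Removes samples whose follow-up time or event flag is missing or
#' non-finite, mirroring the exclusion of patients without follow-up data
#' from a survival cohort.
#'
#' @param clinical Clinical data frame.
#' @return Filtered data frame; excluded ids are reported via \code{message}.
#' @export
drop_missing_followup <- function(clinical) {
  bad <- !is.finite(clinical$time_months) | !is.finite(clinical$event) |
    clinical$time_months < 0
  if (any(bad))
    message("excluding ", sum(bad), " sample(s) without usable follow-up: ",
            paste(clinical$sample_id[bad], collapse = ", "))
  clinical[!bad, , drop = FALSE]
}
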