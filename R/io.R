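# Tab-separated readers/writers for profile matrices, clinical tables
# and network exports (SIF / GraphML / edge-list TSV, all
# Cytoscape-loadable).  Dialect: tab separator, one header row, missing
# tokens "", "NA", "NaN".

.na_tokens <- c("", "NA", "NaN")

#' Read a genomic profile matrix from TSV
#'
#' Layout: first column gene ids, remaining column names are patient
#' ids, cells numeric (or GISTIC integers in -2..2).  Missing cells may
#' use any of the tokens `""`, `"NA"`, `"NaN"`.
#'
#' @param path file path.
#' @param kind `"continuous"` or `"gistic"` (validates the value set).
#' @param na_tokens tokens treated as missing.
#' @return Numeric genes x patients matrix with dimnames.
#' @export
read_profile_tsv <- function(path, kind = c("continuous", "gistic"),
                             na_tokens = .na_tokens) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = na_tokens, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("profile file needs a gene column and >= 1 patient")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  patients <- colnames(df)[-1L]
  if (anyDuplicated(patients)) stop("duplicate patient columns in ", path)
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  bad <- is.na(vals) & !is.na(as.matrix(df[-1L]))
  if (any(bad)) stop("non-numeric cell(s) outside the NA token set in ", path)
  if (kind == "gistic" && !all(vals[!is.na(vals)] %in% -2:2))
    stop("GISTIC profile has values outside -2..2 in ", path)
  dimnames(vals) <- list(genes, patients)
  vals
}

#' Write a genomic profile matrix as TSV
#' @param x genes x patients matrix with dimnames.
#' @param path output path.
#' @export
write_profile_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `patient_id`, `months` (overall survival in months)
#' and `status` (`living`/`deceased`); unknown or empty statuses become
#' `NA`.
#'
#' @param path file path.
#' @param na_tokens tokens treated as missing.
#' @return data.frame `patient_id`, `months`, `status`.
#' @export
read_clinical_tsv <- function(path, na_tokens = .na_tokens) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = na_tokens, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("patient_id", "months", "status")
  if (!all(req %in% names(df)))
    stop("clinical file must have columns: ", paste(req, collapse = ", "))
  st <- as.character(df$status)
  st[!is.na(st) & !(st %in% c("living", "deceased"))] <- NA
  data.frame(patient_id = as.character(df$patient_id),
             months = as.numeric(df$months), status = st,
             stringsAsFactors = FALSE)
}

#' Write a clinical table as TSV
#' @param clinical data.frame `patient_id`, `months`, `status`.
#' @param path output path.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an outcome network for Cytoscape
#'
#' SIF rows are `geneA pair geneB`; GraphML carries the `mi` and
#' `profiles` edge attributes; the edge-list TSV carries all edge
#' columns.  Row order is deterministic (sorted by gene ids).
#'
#' @param net an `outcome_network`.
#' @param path output path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "outcome_network"))
  format <- match.arg(format)
  e <- net$edges
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$gene_i, "pair", e$gene_j) else character(),
               path)
  } else if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}
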