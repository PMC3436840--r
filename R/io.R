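## Plain-text IO helpers shared across modules. All matrices travel as TSV
## with a header row and the entity ids in the first column.

write_matrix_tsv <- function(m, path, id_col = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read / write a similarity matrix as square TSV
#'
#' Square tab-separated text with matching row/column id headers. A JSON
#' sidecar (`<path>.meta.json`) records the kind and parameters for
#' provenance.
#'
#' @param S Symmetric numeric matrix with identical row and column names.
#' @param path Output path.
#' @param kind Label stored in the sidecar, e.g. `"aersfreq"`, `"chem"`,
#'   `"geno"`, `"integrated"`.
#' @param params Named list of parameters recorded in the sidecar.
#' @export
write_similarity <- function(S, path, kind = "unknown", params = list()) {
  stopifnot(identical(rownames(S), colnames(S)))
  write_matrix_tsv(S, path, id_col = "id")
  jsonlite::write_json(list(kind = kind, n = nrow(S), params = params),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  S <- read_matrix_tsv(path)
  stopifnot(nrow(S) == ncol(S))
  colnames(S) <- rownames(S)
  S
}

#' Read / write a drug-target interaction edge list
#'
#' Two-column TSV: `drug_id`, `target_id`, one known interaction per row.
#'
#' @param path File path.
#' @return Data frame with character columns `drug_id` and `target_id`.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("drug_id", "target_id") %in% names(df)))
  df[, c("drug_id", "target_id")]
}

#' @rdname read_interactions
#' @param edges Data frame with columns `drug_id`, `target_id`.
#' @export
write_interactions <- function(edges, path) {
  utils::write.table(edges[, c("drug_id", "target_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint table
#'
#' TSV with columns `drug_id` and `bits`, where `bits` is a 0/1 string
#' (constant length across drugs).
#'
#' @param path File path.
#' @return Binary matrix, drugs x bits.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("drug_id", "bits") %in% names(df)))
  lens <- nchar(df$bits)
  if (length(unique(lens)) != 1)
    stop("fingerprint bitstrings have unequal lengths")
  m <- t(vapply(strsplit(df$bits, ""),
                function(b) as.numeric(b == "1"), numeric(lens[1])))
  rownames(m) <- df$drug_id
  colnames(m) <- paste0("b", seq_len(ncol(m)))
  m
}

#' @rdname read_fingerprints
#' @param fp Binary matrix with drug row names.
#' @export
write_fingerprints <- function(fp, path) {
  utils::write.table(
    data.frame(drug_id = rownames(fp),
               bits = apply(fp, 1, paste, collapse = "")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
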