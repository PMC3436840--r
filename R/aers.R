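#' Parse a quarterly adverse-event report file pair
#'
#' Reads one quarter of AERS-dialect data: a DRUG file (one row per drug
#' mention, with a role code) and a REAC file (one row per reported side
#' effect), joined on the report identifier (ISR). Reports present in only
#' one of the two files are dropped; the counts are recorded in the
#' `parse_log` attribute.
#'
#' The real files are `$`-delimited with a header line, but layouts changed
#' across quarters, so both the delimiter and the column names are
#' configurable. Drug identifiers are treated as opaque strings; an optional
#' two-column synonym map (reported name -> canonical id) can be applied.
#'
#' @param drug_file Path to the DRUG-dialect file (report id, role code,
#'   drug name per row).
#' @param reac_file Path to the REAC-dialect file (report id, reaction
#'   keyword per row).
#' @param sep Field delimiter (default `"$"`).
#' @param columns Named list mapping the logical fields `isr`, `role`,
#'   `drug`, `reaction` to the column names used in the files.
#' @param synonym_map Optional data frame with columns `reported_name` and
#'   `canonical_id`; drug names found in it are replaced by the canonical id.
#' @return A `report_set` object: a list with elements `isr` (character
#'   vector of report ids), `drugs` (list of data frames with columns
#'   `drug_id`, `role`), and `keywords` (list of character vectors), plus a
#'   `parse_log` attribute counting dropped records.
#' @export
aers_parse_quarter <- function(drug_file, reac_file, sep = "$",
                               columns = list(isr = "ISR", role = "ROLE_COD",
                                              drug = "DRUGNAME", reaction = "PT"),
                               synonym_map = NULL) {
  for (f in c(drug_file, reac_file)) {
    if (!file.exists(f)) stop("cannot read file: ", f)
  }
  drug_tab <- read_delim_table(drug_file, sep)
  reac_tab <- read_delim_table(reac_file, sep)
  log <- list(malformed_drug = attr(drug_tab, "n_malformed"),
              malformed_reac = attr(reac_tab, "n_malformed"))

  need_d <- c(columns$isr, columns$role, columns$drug)
  need_r <- c(columns$isr, columns$reaction)
  if (!all(need_d %in% names(drug_tab)))
    stop("DRUG file ", drug_file, " lacks columns: ",
         paste(setdiff(need_d, names(drug_tab)), collapse = ", "))
  if (!all(need_r %in% names(reac_tab)))
    stop("REAC file ", reac_file, " lacks columns: ",
         paste(setdiff(need_r, names(reac_tab)), collapse = ", "))

  d_isr <- as.character(drug_tab[[columns$isr]])
  r_isr <- as.character(reac_tab[[columns$isr]])
  role <- toupper(trimws(as.character(drug_tab[[columns$role]])))
  drug <- trimws(as.character(drug_tab[[columns$drug]]))
  reac <- tolower(trimws(as.character(reac_tab[[columns$reaction]])))

  bad_role <- !(role %in% c("PS", "SS", "C", "I"))
  if (any(bad_role)) {
    warning(sum(bad_role), " drug record(s) with unknown role code skipped")
    log$bad_role <- sum(bad_role)
    d_isr <- d_isr[!bad_role]; role <- role[!bad_role]; drug <- drug[!bad_role]
  } else log$bad_role <- 0L

  if (!is.null(synonym_map)) {
    stopifnot(all(c("reported_name", "canonical_id") %in% names(synonym_map)))
    hit <- match(drug, synonym_map$reported_name)
    drug[!is.na(hit)] <- synonym_map$canonical_id[hit[!is.na(hit)]]
  }

  common <- intersect(unique(d_isr), unique(r_isr))
  log$drug_only <- length(setdiff(unique(d_isr), common))
  log$reac_only <- length(setdiff(unique(r_isr), common))

  keep_d <- d_isr %in% common
  keep_r <- r_isr %in% common
  drugs <- split(data.frame(drug_id = drug[keep_d], role = role[keep_d],
                            stringsAsFactors = FALSE),
                 factor(d_isr[keep_d], levels = common))
  keywords <- lapply(split(reac[keep_r], factor(r_isr[keep_r], levels = common)),
                     unique)
  new_report_set(common, drugs, keywords, parse_log = log)
}

read_delim_table <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("cannot read file (empty): ", path)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, sep, fixed = TRUE)
  ok <- lengths(fields) == length(header)
  if (any(!ok))
    warning(sum(!ok), " malformed line(s) skipped in ", basename(path))
  mat <- do.call(rbind, fields[ok])
  tab <- as.data.frame(mat, stringsAsFactors = FALSE)
  if (is.null(mat)) tab <- as.data.frame(matrix(character(), 0, length(header)))
  names(tab) <- header
  attr(tab, "n_malformed") <- sum(!ok)
  tab
}

new_report_set <- function(isr, drugs, keywords, parse_log = list()) {
  stopifnot(!anyDuplicated(isr),
            length(isr) == length(drugs), length(isr) == length(keywords))
  structure(list(isr = isr, drugs = unname(drugs), keywords = unname(keywords)),
            parse_log = parse_log, class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat("report_set:", length(x$isr), "reports,",
      length(unique(unlist(lapply(x$drugs, `[[`, "drug_id")))), "distinct drugs,",
      length(unique(unlist(x$keywords))), "distinct keywords\n")
  invisible(x)
}

#' @export
length.report_set <- function(x) length(x$isr)

#' Keep only suspect drugs (roles PS and SS)
#'
#' Retains drug entries labeled primary suspect (PS) or secondary suspect
#' (SS); concomitant (C) and interacting (I) entries are removed. Reports
#' left with no drug entry are dropped entirely.
#'
#' @param reports A `report_set`.
#' @return A filtered `report_set`.
#' @export
aers_filter_suspect <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  drugs <- lapply(reports$drugs, function(d) d[d$role %in% c("PS", "SS"), , drop = FALSE])
  keep <- vapply(drugs, nrow, 0L) > 0L
  new_report_set(reports$isr[keep], drugs[keep], reports$keywords[keep],
                 parse_log = attr(reports, "parse_log"))
}

#' Build the retained side-effect keyword vocabulary
#'
#' Each keyword's frequency is `d_k = report_count / n_reports`, where
#' `report_count` is the number of distinct reports mentioning it. Keywords
#' that are too frequent (`d_k > max_freq`) or too rare
#' (`report_count < min_reports`) are removed. `sigma` is the arithmetic
#' mean of the retained `d_k`, the scale on which the keyword weights of
#' [keyword_weights()] are computed.
#'
#' @param reports A `report_set` (typically already role-filtered).
#' @param max_freq Upper bound on `d_k` (default 0.001, the scale used for
#'   full AERS quarters; raise it for small datasets).
#' @param min_reports Lower bound on the report count (default 5).
#' @param h Positive weight-bandwidth parameter carried into the vocabulary
#'   (default 1).
#' @return A `keyword_vocabulary`: list with `keyword`, `report_count`,
#'   `d_k` (parallel vectors, sorted by keyword), `sigma`, `h`, `K`,
#'   `n_reports`.
#' @export
aers_vocabulary <- function(reports, max_freq = 0.001, min_reports = 5, h = 1) {
  stopifnot(inherits(reports, "report_set"), length(reports) > 0, h > 0)
  counts <- table(unlist(lapply(reports$keywords, unique)))
  n <- length(reports)
  d_k <- as.numeric(counts) / n
  keep <- as.numeric(counts) >= min_reports & d_k <= max_freq
  if (!any(keep))
    stop("no keyword survives filtering (max_freq = ", max_freq,
         ", min_reports = ", min_reports,
         "); relax the thresholds for this dataset size")
  kw <- names(counts)[keep]
  ord <- order(kw)
  structure(list(keyword = kw[ord],
                 report_count = as.integer(counts)[keep][ord],
                 d_k = d_k[keep][ord],
                 sigma = mean(d_k[keep]),
                 h = h, K = sum(keep), n_reports = n),
            class = "keyword_vocabulary")
}

#' @export
print.keyword_vocabulary <- function(x, ...) {
  cat("keyword_vocabulary:", x$K, "keywords from", x$n_reports,
      "reports; sigma =", signif(x$sigma, 4), "h =", x$h, "\n")
  invisible(x)
}

#' Build drug side-effect profiles
#'
#' One row per drug appearing (with a suspect role) in at least one report;
#' one column per retained vocabulary keyword. In `bit` mode an entry is 1
#' iff the drug co-occurs with the keyword in at least one report. In
#' `freq` mode the entry is the drug-conditional frequency: the number of
#' reports containing both the drug and the keyword divided by the number
#' of reports containing the drug (set `denominator = "global"` to divide
#' by the total report count instead).
#'
#' @param reports A `report_set` (role-filtered).
#' @param vocab A `keyword_vocabulary` built from these (or a superset of
#'   these) reports.
#' @param mode `"freq"` or `"bit"`.
#' @param denominator For `freq` mode, `"drug"` (default) or `"global"`.
#' @return Numeric matrix, drugs x keywords, with `mode` attribute. Drugs
#'   whose reports contain no retained keyword get a zero row.
#' @export
aers_profiles <- function(reports, vocab, mode = c("freq", "bit"),
                          denominator = c("drug", "global")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  stopifnot(inherits(reports, "report_set"), inherits(vocab, "keyword_vocabulary"))
  drug_sets <- lapply(reports$drugs, function(d) unique(d$drug_id))
  all_drugs <- sort(unique(unlist(drug_sets)))
  K <- vocab$K
  prof <- matrix(0, length(all_drugs), K,
                 dimnames = list(all_drugs, vocab$keyword))
  n_drug_reports <- integer(length(all_drugs))
  names(n_drug_reports) <- all_drugs
  for (r in seq_along(reports$isr)) {
    kw <- intersect(reports$keywords[[r]], vocab$keyword)
    ds <- drug_sets[[r]]
    n_drug_reports[ds] <- n_drug_reports[ds] + 1L
    if (length(kw) == 0) next
    prof[ds, kw] <- prof[ds, kw, drop = FALSE] + 1
  }
  if (mode == "bit") {
    prof[] <- as.numeric(prof > 0)
  } else {
    den <- if (denominator == "drug") n_drug_reports else
      rep(length(reports), length(all_drugs))
    prof <- prof / pmax(den, 1L)
  }
  empty <- rowSums(prof) == 0
  if (any(empty))
    message(sum(empty), " drug(s) with no retained keyword (zero profile): ",
            paste(utils::head(all_drugs[empty], 5), collapse = ", "))
  attr(prof, "mode") <- mode
  prof
}

#' Write / read a profile matrix as TSV
#'
#' Rows are drug ids, columns are keywords; plain tab-separated text with a
#' header row and row names in the first column.
#'
#' @param profiles Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  write_matrix_tsv(profiles, path, id_col = "drug_id")
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) read_matrix_tsv(path)

#' Write a keyword vocabulary as TSV
#'
#' @param vocab A `keyword_vocabulary`.
#' @param path Output path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(keyword = vocab$keyword, report_count = vocab$report_count,
               d_k = vocab$d_k),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
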