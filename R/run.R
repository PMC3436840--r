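#' Assemble a run configuration
#'
#' Collects the input paths and tunables for one end-to-end run. The
#' `method` selector enumerates the seven prediction approaches: the four
#' single-source pharmacogenomic kernels (`AERS-freq`, `AERS-bit`,
#' `SIDER`, `JAPIC`), the chemogenomic kernel (`CHEM`), the integrated
#' pharmacological kernel `INTEG-P` (sum of the AERS-freq, SIDER and JAPIC
#' similarities) and the pharmaco-chemical kernel `INTEG-PC` (adding the
#' chemical similarity). Every method pairs its drug kernel with the
#' genomic sequence kernel on the target side.
#'
#' @param method One of `"AERS-freq"`, `"AERS-bit"`, `"SIDER"`, `"JAPIC"`,
#'   `"CHEM"`, `"INTEG-P"`, `"INTEG-PC"`.
#' @param drug_files,reac_files Character vectors of AERS-dialect quarter
#'   file paths (needed by the AERS-based and integrated methods).
#' @param sider_profiles,japic_profiles Paths to externally supplied
#'   binary profile TSVs (drug x keyword).
#' @param fingerprints Path to the fingerprint TSV (CHEM / INTEG-PC).
#' @param fasta Path to the protein FASTA.
#' @param interactions Path to the gold-standard edge TSV.
#' @param max_freq,min_reports,h Vocabulary and weight parameters (see
#'   [aers_vocabulary()]).
#' @param jitter Ridge regularization of the closed-form solve, also the
#'   kernel conditioner (see [run_cv()]; default 1).
#' @param q SVD truncation rank, `NULL` for unregularized.
#' @param scheme,folds,repeats Cross-validation design (see [cv_plan()]).
#' @param threshold_quantile Score quantile reported by the prediction
#'   ranking (default 0.999).
#' @param seed Master seed.
#' @param out Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(method = c("AERS-freq", "AERS-bit", "SIDER", "JAPIC",
                                  "CHEM", "INTEG-P", "INTEG-PC"),
                       drug_files = NULL, reac_files = NULL,
                       sider_profiles = NULL, japic_profiles = NULL,
                       fingerprints = NULL, fasta = NULL,
                       interactions = NULL,
                       max_freq = 0.001, min_reports = 5, h = 1,
                       jitter = 1, q = NULL,
                       scheme = "pairwise", folds = 3, repeats = 5,
                       threshold_quantile = 0.999, seed = 1, out = NULL) {
  method <- match.arg(method)
  structure(as.list(environment()), class = "run_config")
}

needs <- function(config, what) {
  miss <- what[vapply(config[what], is.null, logical(1))]
  if (length(miss) > 0)
    stop("method ", config$method, " requires missing input(s): ",
         paste(miss, collapse = ", "))
}

aers_drug_similarity <- function(config, mode) {
  needs(config, c("drug_files", "reac_files"))
  stopifnot(length(config$drug_files) == length(config$reac_files))
  quarters <- Map(aers_parse_quarter, config$drug_files, config$reac_files)
  reports <- if (length(quarters) == 1) quarters[[1]] else {
    new_report_set(unlist(lapply(quarters, `[[`, "isr")),
                   do.call(c, lapply(quarters, `[[`, "drugs")),
                   do.call(c, lapply(quarters, `[[`, "keywords")))
  }
  reports <- aers_filter_suspect(reports)
  vocab <- aers_vocabulary(reports, max_freq = config$max_freq,
                           min_reports = config$min_reports, h = config$h)
  prof <- aers_profiles(reports, vocab, mode = mode)
  pharm_similarity(prof, vocab)
}

profile_similarity_from_tsv <- function(path) {
  prof <- read_profiles(path)
  ## externally supplied binary profiles: uniform weights (no report
  ## frequencies available), i.e. plain cosine
  pharm_similarity(prof, weights = rep(1, ncol(prof)))
}

#' Build the drug-side similarity for a configured method
#'
#' @param config A [run_config()].
#' @return Symmetric drug similarity matrix.
#' @export
drug_similarity_for <- function(config) {
  switch(config$method,
    "AERS-freq" = aers_drug_similarity(config, "freq"),
    "AERS-bit"  = aers_drug_similarity(config, "bit"),
    "SIDER" = { needs(config, "sider_profiles")
                profile_similarity_from_tsv(config$sider_profiles) },
    "JAPIC" = { needs(config, "japic_profiles")
                profile_similarity_from_tsv(config$japic_profiles) },
    "CHEM"  = { needs(config, "fingerprints")
                chem_similarity(read_fingerprints(config$fingerprints)) },
    "INTEG-P" = {
      needs(config, c("sider_profiles", "japic_profiles"))
      integrate_similarity(list(
        aers_drug_similarity(config, "freq"),
        profile_similarity_from_tsv(config$sider_profiles),
        profile_similarity_from_tsv(config$japic_profiles)))
    },
    "INTEG-PC" = {
      needs(config, c("sider_profiles", "japic_profiles", "fingerprints"))
      integrate_similarity(list(
        aers_drug_similarity(config, "freq"),
        profile_similarity_from_tsv(config$sider_profiles),
        profile_similarity_from_tsv(config$japic_profiles),
        chem_similarity(read_fingerprints(config$fingerprints))))
    })
}

#' Run one end-to-end experiment
#'
#' Assembles the drug kernel for the configured method and the genomic
#' sequence kernel for the targets, aligns both to the gold standard
#' (entities without similarity data get zero rows, then the conditioning
#' ridge), and either cross-validates (`task = "cv"`) or trains on the
#' full gold standard and ranks novel predictions (`task = "predict"`).
#' When `config$out` is set, results and a resolved-config echo are
#' written there.
#'
#' @param config A [run_config()].
#' @param task `"cv"` or `"predict"`.
#' @return The `cv_result`, or the ranked prediction data frame.
#' @export
run_method <- function(config, task = c("cv", "predict")) {
  stopifnot(inherits(config, "run_config"))
  task <- match.arg(task)
  needs(config, c("fasta", "interactions"))
  gold <- read_interactions(config$interactions)
  S_drug <- drug_similarity_for(config)
  S_geno <- seq_similarity(config$fasta)
  drug_ids <- sort(unique(c(rownames(S_drug), gold$drug_id)))
  target_ids <- sort(unique(c(rownames(S_geno), gold$target_id)))
  S_drug <- integrate_similarity(list(S_drug), drug_ids)
  S_geno <- integrate_similarity(list(S_geno), target_ids)

  result <- if (task == "cv") {
    run_cv(S_drug, S_geno, gold,
           cv_plan(config$scheme, config$folds, config$repeats, config$seed),
           q = config$q, jitter = config$jitter)
  } else {
    K_x <- condition_kernel(S_drug, jitter = config$jitter)
    K_y <- condition_kernel(S_geno, jitter = config$jitter)
    Z <- dti_label_matrix(gold, drug_ids, target_ids)
    model <- pkr_fit(K_x, K_y, Z,
                     q = if (is.null(config$q)) min(dim(Z)) else config$q)
    rank_predictions(pkr_predict(model, kx_new = S_drug, ky_new = S_geno),
                     known = gold, quantile = config$threshold_quantile)
  }

  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    echo <- config[!vapply(config, is.null, logical(1))]
    jsonlite::write_json(c(echo, list(task = task)),
                         file.path(config$out, "run_config.json"),
                         auto_unbox = TRUE)
    if (task == "cv") {
      jsonlite::write_json(
        list(scheme = result$plan$scheme, auc = result$auc,
             aupr = result$aupr, auc_mean = result$auc_mean,
             auc_sd = result$auc_sd, aupr_mean = result$aupr_mean,
             aupr_sd = result$aupr_sd),
        file.path(config$out, "cv_result.json"), auto_unbox = TRUE,
        digits = NA)
    } else {
      utils::write.table(result, file.path(config$out, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  result
}
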