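#' Build the interaction label matrix Z
#'
#' `z_ij = label_scale` for known interacting pairs and 0 elsewhere. Pairs
#' listed in `test_mask` are forced to 0 regardless of membership in the
#' known set — this is how cross-validation hides test-fold labels from the
#' fit while keeping the matrix shape.
#'
#' @param e_plus Data frame of known interactions (`drug_id`, `target_id`).
#' @param drug_ids,target_ids Ordered entity vectors defining the matrix.
#' @param test_mask Optional data frame of pairs whose labels are zeroed.
#' @param label_scale Value coded for a known pair (default 1).
#' @return Numeric `length(drug_ids) x length(target_ids)` matrix with
#'   dimnames.
#' @export
dti_label_matrix <- function(e_plus, drug_ids, target_ids, test_mask = NULL,
                             label_scale = 1) {
  Z <- matrix(0, length(drug_ids), length(target_ids),
              dimnames = list(drug_ids, target_ids))
  idx <- pair_index(e_plus, drug_ids, target_ids)
  Z[idx] <- label_scale
  if (!is.null(test_mask) && nrow(test_mask) > 0)
    Z[pair_index(test_mask, drug_ids, target_ids)] <- 0
  Z
}

pair_index <- function(pairs, drug_ids, target_ids) {
  i <- match(pairs$drug_id, drug_ids)
  j <- match(pairs$target_id, target_ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(pairs$drug_id[is.na(i)], pairs$target_id[is.na(j)]))
    stop("pair references unknown entity id(s): ",
         paste(bad, collapse = ", "))
  }
  cbind(i, j)
}

#' Fit a pairwise kernel regression model
#'
#' The model scores a drug-target pair (x, y) as a weighted sum of
#' tensor-product kernel evaluations against all training pairs,
#' `f(x, y) = sum_ij beta_ij k_x(x, x_i) k_y(y, y_j)`. Because the pairwise
#' kernel factorizes, the weight matrix never has to be formed in the
#' `n_x n_y`-dimensional pairwise space: minimizing the squared loss
#' `||Z - K_x B K_y||^2` gives the closed form
#' \deqn{B = K_x^{-1} Z K_y^{-1}}
#' computed here as two symmetric positive-definite linear solves (never an
#' explicit inverse). With `q < min(n_x, n_y)` the fit is regularized by
#' replacing Z with its best rank-`q` approximation `U_q D_q V_q^T` from
#' the singular value decomposition; `q = min(n_x, n_y)` (the default) is
#' the exact unregularized solution.
#'
#' @param K_x Drug kernel matrix, `n_x x n_x`, positive definite (apply
#'   [condition_kernel()] to a raw similarity matrix first).
#' @param K_y Target kernel matrix, `n_y x n_y`, positive definite.
#' @param Z Label matrix from [dti_label_matrix()].
#' @param q Rank of the SVD truncation of Z, `1 <= q <= min(n_x, n_y)`.
#' @return A `pkr_model`: list with the weight matrix `B`, entity orders,
#'   `q`, and the training kernels.
#' @export
pkr_fit <- function(K_x, K_y, Z, q = min(nrow(Z), ncol(Z))) {
  stopifnot(nrow(K_x) == ncol(K_x), nrow(K_y) == ncol(K_y),
            nrow(Z) == nrow(K_x), ncol(Z) == nrow(K_y))
  if (q < 1 || q > min(dim(Z)))
    stop("q must be in [1, min(n_x, n_y)] = [1, ", min(dim(Z)), "], got ", q)
  Zq <- if (q < min(dim(Z))) {
    sv <- svd(Z, nu = q, nv = q)
    sv$u %*% (sv$d[seq_len(q)] * t(sv$v))
  } else Z
  cx <- tryCatch(chol(K_x), error = function(e)
    stop("drug kernel is not positive definite; raise the jitter in ",
         "condition_kernel()", call. = FALSE))
  cy <- tryCatch(chol(K_y), error = function(e)
    stop("target kernel is not positive definite; raise the jitter in ",
         "condition_kernel()", call. = FALSE))
  ## B = K_x^{-1} Zq K_y^{-1} via triangular solves on both sides
  B <- backsolve(cx, forwardsolve(t(cx), Zq))
  B <- t(backsolve(cy, forwardsolve(t(cy), t(B))))
  dimnames(B) <- dimnames(Z)
  structure(list(B = B, q = q,
                 drug_ids = rownames(Z), target_ids = colnames(Z),
                 K_x = K_x, K_y = K_y),
            class = "pkr_model")
}

#' @export
print.pkr_model <- function(x, ...) {
  cat("pkr_model:", length(x$drug_ids), "drugs x", length(x$target_ids),
      "targets, q =", x$q, "\n")
  invisible(x)
}

#' Score drug-target pairs with a fitted model
#'
#' `f(x, y) = k_x(x, .) B k_y(y, .)^T` where the kernel rows are evaluated
#' against the training drugs and targets. Query rows with an all-zero
#' kernel row (entities with no similarity data) score 0 everywhere.
#'
#' @param model A `pkr_model`.
#' @param kx_new Query-drug kernel rows, columns aligned to the training
#'   drug order (defaults to the training kernel: score the training grid).
#' @param ky_new Query-target kernel rows, columns aligned to the training
#'   target order.
#' @return Numeric matrix of scores, query drugs x query targets.
#' @export
pkr_predict <- function(model, kx_new = model$K_x, ky_new = model$K_y) {
  stopifnot(inherits(model, "pkr_model"))
  if (ncol(kx_new) != length(model$drug_ids))
    stop("kx_new must have ", length(model$drug_ids),
         " columns (training drug order)")
  if (ncol(ky_new) != length(model$target_ids))
    stop("ky_new must have ", length(model$target_ids),
         " columns (training target order)")
  if (!is.null(colnames(kx_new)) &&
      !identical(colnames(kx_new), model$drug_ids))
    stop("kx_new column order does not match the training drug order")
  if (!is.null(colnames(ky_new)) &&
      !identical(colnames(ky_new), model$target_ids))
    stop("ky_new column order does not match the training target order")
  kx_new %*% model$B %*% t(ky_new)
}

#' Rank novel predictions above a score threshold
#'
#' Returns the non-known pairs scoring at or above `threshold`, sorted by
#' descending score with ties broken lexicographically by
#' (drug_id, target_id). The threshold can be given directly or as a score
#' quantile over the non-known pairs.
#'
#' @param scores Score matrix (drugs x targets, with dimnames).
#' @param known Data frame of known pairs (`drug_id`, `target_id`) to
#'   exclude from the ranking.
#' @param threshold Minimum score to report (default `-Inf`: report all).
#' @param quantile If not `NULL`, overrides `threshold` with this score
#'   quantile of the non-known pairs (e.g. 0.999).
#' @return Data frame `drug_id`, `target_id`, `score`, sorted.
#' @export
rank_predictions <- function(scores, known = NULL, threshold = -Inf,
                             quantile = NULL) {
  stopifnot(!is.null(rownames(scores)), !is.null(colnames(scores)))
  df <- data.frame(
    drug_id = rep(rownames(scores), times = ncol(scores)),
    target_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores), stringsAsFactors = FALSE)
  if (!is.null(known) && nrow(known) > 0) {
    key <- paste(df$drug_id, df$target_id, sep = "\r")
    df <- df[!(key %in% paste(known$drug_id, known$target_id, sep = "\r")), ]
  }
  if (!is.null(quantile))
    threshold <- stats::quantile(df$score, quantile, names = FALSE)
  df <- df[df$score >= threshold, ]
  df <- df[order(-df$score, df$drug_id, df$target_id), ]
  rownames(df) <- NULL
  df
}

#' Save / load a fitted model as plain text
#'
#' Writes the weight matrix and kernels as TSV and the parameters as JSON
#' into a directory.
#'
#' @param model A `pkr_model`.
#' @param dir Directory path (created if absent).
#' @export
write_pkr_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(model$B, file.path(dir, "B.tsv"), id_col = "drug_id")
  write_matrix_tsv(model$K_x, file.path(dir, "Kx.tsv"), id_col = "drug_id")
  write_matrix_tsv(model$K_y, file.path(dir, "Ky.tsv"), id_col = "target_id")
  jsonlite::write_json(list(q = model$q, drug_ids = model$drug_ids,
                            target_ids = model$target_ids),
                       file.path(dir, "model.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_pkr_model
#' @export
read_pkr_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  structure(list(B = read_matrix_tsv(file.path(dir, "B.tsv")),
                 q = meta$q, drug_ids = meta$drug_ids,
                 target_ids = meta$target_ids,
                 K_x = read_matrix_tsv(file.path(dir, "Kx.tsv")),
                 K_y = read_matrix_tsv(file.path(dir, "Ky.tsv"))),
            class = "pkr_model")
}
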