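#' Cross-validation plans
#'
#' Two complementary designs for drug-target interaction benchmarks:
#'
#' * **pair-wise**: the full drug x target pair grid is split into folds by
#'   pair. This simulates finding additional targets (off-targets) of drugs
#'   that already have at least one known target.
#' * **block-wise**: drugs are split into folds; a fold's test set is all
#'   pairs of its drugs with every target, and those drugs contribute no
#'   training labels. This simulates drugs with no known target at all,
#'   and is the harder problem.
#'
#' @param scheme `"pairwise"` or `"blockwise"`.
#' @param n_folds Number of folds (default 3).
#' @param n_repeats Number of repetitions with re-randomized folds
#'   (default 5).
#' @param seed Master RNG seed; per-repeat substreams are derived from it.
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(scheme = c("pairwise", "blockwise"), n_folds = 3,
                    n_repeats = 5, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(scheme = scheme, n_folds = n_folds,
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Assign drug-target pairs to folds (pair-wise scheme)
#'
#' Splits the full pair universe (every drug crossed with every target)
#' into `n_folds` folds of sizes differing by at most one. Deterministic
#' given the seed.
#'
#' @param drug_ids,target_ids Entity vectors defining the pair universe.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return Integer fold matrix, drugs x targets, entries in `1:n_folds`.
#' @export
cv_split_pairs <- function(drug_ids, target_ids, n_folds = 3, seed = 1) {
  n <- length(drug_ids) * length(target_ids)
  if (n < n_folds)
    stop("fewer pairs (", n, ") than folds (", n_folds, ")")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  matrix(fold, length(drug_ids), length(target_ids),
         dimnames = list(drug_ids, target_ids))
}

#' Assign drugs to folds (block-wise scheme)
#'
#' @param drug_ids Drug id vector.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return Named integer vector of fold labels, one per drug.
#' @export
cv_split_drugs <- function(drug_ids, n_folds = 3, seed = 1) {
  if (length(drug_ids) < n_folds)
    stop("fewer drugs (", length(drug_ids), ") than folds (", n_folds, ")")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), length(drug_ids)))
  names(fold) <- drug_ids
  fold
}

#' Area under the ROC curve (rank-based)
#'
#' The Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted 1/2. Equals 1 for a
#' perfect ranking and 0.5 in expectation for label-independent scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels of the same length; both classes must be
#'   present.
#' @return Scalar in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step-curve area: scores are swept in descending order
#' and the area accumulates precision at each recall increment (tied scores
#' are processed as one block). Equals 1 for a perfect ranking.
#'
#' @inheritParams auc_score
#' @return Scalar in (0, 1\].
#' @export
aupr_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("AUPR undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ## block-cumulate over tied scores so ties within a threshold count once
  blocks <- cumsum(!duplicated(s))
  tp <- cumsum(y); n_seen <- seq_along(y)
  last <- !duplicated(blocks, fromLast = TRUE)
  tp <- tp[last]; n_seen <- n_seen[last]
  prec <- tp / n_seen
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Run a cross-validation experiment
#'
#' For each repeat and fold: hide the test labels (pair-wise scheme: the
#' fold's pairs are zeroed in Z; block-wise scheme: the fold's drugs are
#' excluded from the training rows), fit the kernel regression on the
#' training labels, score every test pair, and compute AUC and AUPR of the
#' scores against gold-standard membership. Per-fold metrics are averaged
#' within each repeat; means and SDs are taken over repeats (set
#' `pool_folds = TRUE` to instead pool all fold scores before computing
#' the metrics).
#'
#' The raw similarity matrices are conditioned with
#' [condition_kernel()]`(jitter)` for the closed-form solve, while test
#' pairs are scored with the raw similarity rows — the kernel function
#' itself. The ridge `jitter` therefore acts as the model's regularization
#' strength: near 0 the fit interpolates the training labels, large
#' values smooth predictions fully onto the kernel neighborhood
#' structure.
#'
#' @param S_x,S_y Raw drug and target similarity matrices covering all
#'   gold-standard entities (entities with no similarity data carry zero
#'   rows).
#' @param gold Data frame of known interactions (`drug_id`, `target_id`).
#' @param plan A [cv_plan()].
#' @param q Rank for the regularized fit; `NULL` means unregularized.
#' @param jitter Ridge added by [condition_kernel()] before solving
#'   (default 1).
#' @param label_scale Label value for known pairs (see
#'   [dti_label_matrix()]).
#' @param pool_folds Pool scores across folds before computing metrics.
#' @return A `cv_result`: per-repeat AUC/AUPR, their means and SDs, and
#'   the configuration echo.
#' @export
run_cv <- function(S_x, S_y, gold, plan, q = NULL, jitter = 1,
                   label_scale = 1, pool_folds = FALSE) {
  stopifnot(inherits(plan, "cv_plan"))
  drug_ids <- rownames(S_x)
  target_ids <- rownames(S_y)
  stopifnot(!is.null(drug_ids), !is.null(target_ids))
  missing_ent <- c(setdiff(gold$drug_id, drug_ids),
                   setdiff(gold$target_id, target_ids))
  if (length(missing_ent) > 0)
    stop("gold standard references entities absent from the kernels: ",
         paste(unique(missing_ent), collapse = ", "))
  if (is.null(q)) q <- min(length(drug_ids), length(target_ids))
  K_x <- condition_kernel(S_x, jitter = jitter)
  K_y <- condition_kernel(S_y, jitter = jitter)
  Z_full <- dti_label_matrix(gold, drug_ids, target_ids,
                             label_scale = label_scale)
  auc_rep <- aupr_rep <- numeric(plan$n_repeats)
  fold_log <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    rep_seed <- plan$seed + 7919L * (r - 1L)
    fold_auc <- fold_aupr <- numeric(plan$n_folds)
    pool_scores <- pool_labels <- NULL
    if (plan$scheme == "pairwise") {
      folds <- cv_split_pairs(drug_ids, target_ids, plan$n_folds, rep_seed)
    } else {
      folds <- cv_split_drugs(drug_ids, plan$n_folds, rep_seed)
    }
    fold_log[[r]] <- folds
    for (f in seq_len(plan$n_folds)) {
      if (plan$scheme == "pairwise") {
        test <- folds == f
        Z_train <- Z_full
        Z_train[test] <- 0
        model <- pkr_fit(K_x, K_y, Z_train, q = min(q, min(dim(Z_train))))
        scores <- pkr_predict(model, kx_new = S_x, ky_new = S_y)[test]
        labels <- as.numeric(Z_full[test] > 0)
      } else {
        test_drugs <- names(folds)[folds == f]
        train_drugs <- names(folds)[folds != f]
        Z_train <- Z_full[train_drugs, , drop = FALSE]
        model <- pkr_fit(K_x[train_drugs, train_drugs, drop = FALSE], K_y,
                         Z_train, q = min(q, min(dim(Z_train))))
        sc <- pkr_predict(model,
                          kx_new = S_x[test_drugs, train_drugs, drop = FALSE],
                          ky_new = S_y)
        scores <- as.vector(sc)
        labels <- as.vector(Z_full[test_drugs, , drop = FALSE] > 0) * 1
      }
      if (pool_folds) {
        pool_scores <- c(pool_scores, scores)
        pool_labels <- c(pool_labels, labels)
      } else {
        fold_auc[f] <- auc_score(scores, labels)
        fold_aupr[f] <- aupr_score(scores, labels)
      }
    }
    if (pool_folds) {
      auc_rep[r] <- auc_score(pool_scores, pool_labels)
      aupr_rep[r] <- aupr_score(pool_scores, pool_labels)
    } else {
      auc_rep[r] <- mean(fold_auc)
      aupr_rep[r] <- mean(fold_aupr)
    }
  }
  structure(list(auc = auc_rep, aupr = aupr_rep,
                 auc_mean = mean(auc_rep), auc_sd = stats::sd(auc_rep),
                 aupr_mean = mean(aupr_rep), aupr_sd = stats::sd(aupr_rep),
                 plan = plan, q = q, pool_folds = pool_folds,
                 folds = fold_log),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s, %d folds x %d repeats):\n",
              x$plan$scheme, x$plan$n_folds, x$plan$n_repeats))
  cat(sprintf("  AUC  = %.4f (SD %.4f)\n", x$auc_mean,
              ifelse(is.na(x$auc_sd), 0, x$auc_sd)))
  cat(sprintf("  AUPR = %.4f (SD %.4f)\n", x$aupr_mean,
              ifelse(is.na(x$aupr_sd), 0, x$aupr_sd)))
  invisible(x)
}
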