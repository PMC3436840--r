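#' Keyword weights emphasizing infrequent side effects
#'
#' Rare side-effect keywords (agnosia, variant angina, ...) are more
#' informative about a drug's phenotype than ubiquitous ones (nausea,
#' rash, ...), so each keyword gets a weight that decreases with its
#' report frequency:
#' \deqn{w_k = \exp(-d_k^2 / (h\sigma)^2)}
#' where `d_k` is the keyword's report frequency, `sigma` the mean of the
#' retained `d_k` and `h` a bandwidth parameter (default 1). The functional
#' form is pluggable via `fun`; any strictly decreasing positive function
#' of `d_k` is admissible.
#'
#' @param vocab A `keyword_vocabulary`.
#' @param fun Optional replacement weight function taking `(d_k, sigma, h)`.
#' @return Named numeric vector of positive weights in vocabulary order.
#' @export
keyword_weights <- function(vocab, fun = NULL) {
  stopifnot(inherits(vocab, "keyword_vocabulary"))
  if (vocab$sigma <= 0)
    stop("degenerate vocabulary: sigma = 0, weights undefined")
  if (is.null(fun)) fun <- function(d, sigma, h) exp(-d^2 / (h * sigma)^2)
  w <- fun(vocab$d_k, vocab$sigma, vocab$h)
  stopifnot(all(w > 0))
  names(w) <- vocab$keyword
  w
}

#' Weighted cosine similarity between two profiles
#'
#' \deqn{s(x, x') = \frac{\sum_k w_k x_k x'_k}
#'   {\sqrt{\sum_k w_k x_k^2}\sqrt{\sum_k w_k x'^2_k}}}
#' Returns 0 when either profile has zero weighted norm (the missing-data
#' convention: a drug without any retained side effect is dissimilar to
#' everything, itself included).
#'
#' @param x,x2 Numeric profile vectors over the same keyword order.
#' @param w Non-negative weight vector of the same length.
#' @return Scalar in \[0, 1\] for non-negative profiles.
#' @export
weighted_cosine <- function(x, x2, w) {
  if (length(x) != length(x2) || length(x) != length(w))
    stop("profile/weight length mismatch: ", length(x), ", ", length(x2),
         ", ", length(w))
  nx <- sqrt(sum(w * x^2))
  ny <- sqrt(sum(w * x2^2))
  if (nx == 0 || ny == 0) return(0)
  sum(w * x * x2) / (nx * ny)
}

#' Pharmacological similarity matrix
#'
#' Pairwise weighted cosine over all drug profile rows, computed in one
#' matrix product: with `W = diag(w)`, the Gram matrix is
#' `X W X^T` normalized by the weighted row norms. Zero-norm rows give zero
#' rows/columns (including the diagonal).
#'
#' @param profiles Drugs x keywords matrix (from [aers_profiles()] or an
#'   externally supplied binary profile table).
#' @param vocab The `keyword_vocabulary` the profiles are aligned to.
#' @param weights Optional precomputed weight vector; defaults to
#'   [keyword_weights()] on `vocab`.
#' @return Symmetric drugs x drugs matrix with `kind` attribute
#'   `"pharmacological"`.
#' @export
pharm_similarity <- function(profiles, vocab = NULL, weights = NULL) {
  if (is.null(weights)) weights <- keyword_weights(vocab)
  stopifnot(ncol(profiles) == length(weights))
  G <- profiles %*% (weights * t(profiles))
  nrm <- sqrt(diag(G))
  S <- G / outer(nrm, nrm)
  S[nrm == 0, ] <- 0
  S[, nrm == 0] <- 0
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  attr(S, "kind") <- "pharmacological"
  S
}

#' Chemical similarity from binary fingerprints (Tanimoto)
#'
#' Surrogate chemical kernel: the Tanimoto coefficient
#' `|a AND b| / |a OR b|` between fingerprint bit vectors. Drugs with an
#' empty fingerprint get similarity 0 to everything (themselves included).
#'
#' @param fingerprints Binary drugs x bits matrix with drug row names.
#' @return Symmetric drugs x drugs matrix, `kind = "chem"`.
#' @export
chem_similarity <- function(fingerprints) {
  stopifnot(all(fingerprints %in% c(0, 1)))
  fp <- fingerprints
  inter <- fp %*% t(fp)
  sz <- rowSums(fp)
  uni <- outer(sz, sz, `+`) - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  empty <- sz == 0
  if (any(empty))
    message(sum(empty), " empty fingerprint(s): ",
            paste(rownames(fp)[empty], collapse = ", "))
  S[empty, ] <- 0
  S[, empty] <- 0
  dimnames(S) <- list(rownames(fp), rownames(fp))
  attr(S, "kind") <- "chem"
  S
}

#' Genomic similarity from protein sequences (normalized Smith-Waterman)
#'
#' Surrogate sequence kernel: local-alignment (Smith-Waterman) scores
#' normalized as `SW(a,b) / sqrt(SW(a,a) * SW(b,b))`, giving a symmetric
#' matrix in \[0, 1\] with unit diagonal. Alignment is done with
#' `Biostrings::pairwiseAlignment` under a fixed scoring scheme recorded in
#' the matrix attributes.
#'
#' @param sequences Named character vector of amino-acid sequences, or an
#'   `AAStringSet`, or a path to a FASTA file.
#' @param substitution Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return Symmetric proteins x proteins matrix, `kind = "geno"`.
#' @export
seq_similarity <- function(sequences, substitution = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- Biostrings::readAAStringSet(sequences)
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  stopifnot(methods::is(sequences, "AAStringSet"), length(sequences) >= 1)
  subst <- get(data(list = substitution, package = "Biostrings",
                    envir = environment()))
  valid <- rownames(subst)
  letters_used <- Biostrings::uniqueLetters(sequences)
  if (!all(letters_used %in% valid)) {
    per_seq <- vapply(seq_along(sequences), function(i)
      !all(Biostrings::uniqueLetters(sequences[i]) %in% valid), logical(1))
    stop("invalid residue characters in record(s): ",
         paste(names(sequences)[per_seq], collapse = ", "))
  }
  n <- length(sequences)
  sw <- function(a, b) Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = subst,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  self <- vapply(seq_len(n), function(i) sw(sequences[i], sequences[i]),
                 numeric(1))
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      sc <- vapply((i + 1):n, function(j) sw(sequences[i], sequences[j]),
                   numeric(1))
      S[i, (i + 1):n] <- S[(i + 1):n, i] <- sc / sqrt(self[i] * self[(i + 1):n])
    }
  }
  ids <- names(sequences)
  dimnames(S) <- list(ids, ids)
  attr(S, "kind") <- "geno"
  attr(S, "scoring") <- list(substitution = substitution,
                             gap_open = gap_open, gap_extend = gap_extend)
  S
}

#' Integrate similarity matrices over an entity union
#'
#' Aligns each input matrix to `entity_union` (absent entities get zero
#' rows/columns, the missing-data convention) and sums entrywise. Used to
#' build the integrated pharmacological kernel (sum of the per-source
#' pharmacological similarities) and the pharmaco-chemical kernel (adding
#' the chemical similarity).
#'
#' @param similarities List of symmetric matrices, each with entity row
#'   names forming a subset of `entity_union`.
#' @param entity_union Ordered character vector of entity ids; defaults to
#'   the sorted union of the inputs' ids.
#' @return Symmetric matrix over `entity_union`, `kind = "integrated"`.
#' @export
integrate_similarity <- function(similarities, entity_union = NULL) {
  stopifnot(is.list(similarities), length(similarities) >= 1)
  if (is.null(entity_union))
    entity_union <- sort(unique(unlist(lapply(similarities, rownames))))
  if (anyDuplicated(entity_union))
    stop("duplicate entity ids in union: ",
         paste(unique(entity_union[duplicated(entity_union)]), collapse = ", "))
  out <- matrix(0, length(entity_union), length(entity_union),
                dimnames = list(entity_union, entity_union))
  for (S in similarities) {
    ids <- rownames(S)
    if (anyDuplicated(ids)) stop("duplicate entity ids within an input matrix")
    if (!all(ids %in% entity_union))
      stop("input matrix has entities outside the union: ",
           paste(setdiff(ids, entity_union), collapse = ", "))
    out[ids, ids] <- out[ids, ids] + S
  }
  attr(out, "kind") <- "integrated"
  out
}

#' Condition a similarity matrix into a positive-definite kernel
#'
#' Raw similarity matrices can be singular or indefinite, but the kernel
#' regression solves linear systems in them. This adds `jitter` to the
#' diagonal, and (with `shift = TRUE`) first shifts the whole spectrum up
#' by `|lambda_min|` when the smallest eigenvalue is negative, so the
#' result is positive definite with minimum eigenvalue >= `jitter`.
#'
#' @param S Symmetric matrix.
#' @param jitter Positive ridge added to the diagonal (default 0.01).
#' @param shift If `TRUE` (default), correct negative eigenvalues by a
#'   spectral shift before adding the jitter.
#' @return Positive-definite matrix of the same shape.
#' @export
condition_kernel <- function(S, jitter = 0.01, shift = TRUE) {
  stopifnot(isSymmetric(unname(S), tol = 1e-8))
  S <- (S + t(S)) / 2
  if (shift) {
    lmin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin < 0) S <- S + diag(-lmin, nrow(S))
  }
  S + diag(jitter, nrow(S))
}
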