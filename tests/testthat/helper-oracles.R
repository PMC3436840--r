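## Independent brute-force oracles used to check the package's
## implementations. These deliberately share no code with R/.

## Mann-Whitney AUC by exhaustive pair enumeration
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

## connected components of a thresholded similarity graph by BFS
components_bruteforce <- function(S, threshold) {
  ids <- sort(rownames(S))
  A <- S[ids, ids] > threshold
  diag(A) <- FALSE
  n <- length(ids)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  names(comp) <- ids
  comp
}

## Smith-Waterman local alignment score, affine gaps, plain dynamic
## programming (Gotoh)
sw_bruteforce <- function(a, b, subst, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- E <- F <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             E[i + 1, j] - gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             F[i, j + 1] - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + subst[a[i], b[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

## explicit pairwise-space model on the tensor-product kernel: solve the
## n_x*n_y system K_pair alpha = vec(Z), score query pairs with
## kron(ky_new, kx_new) rows (column-major vec convention)
pairwise_space_predict <- function(K_x, K_y, Z, kx_new, ky_new) {
  K_pair <- kronecker(K_y, K_x)
  alpha <- solve(K_pair, as.vector(Z))
  k_new <- kronecker(ky_new, kx_new)
  matrix(k_new %*% alpha, nrow = nrow(kx_new))
}

random_psd_kernel <- function(n, jitter = 1e-6) {
  A <- matrix(stats::rnorm(2 * n * n), 2 * n, n)
  S <- crossprod(A) / (2 * n)
  S <- S / max(diag(S))
  S + diag(jitter, n)
}

## tiny two-report AERS fixture written to tempdir
write_tiny_quarter <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  drug <- file.path(dir, "DRUG.TXT")
  reac <- file.path(dir, "REAC.TXT")
  writeLines(c("ISR$DRUG_SEQ$ROLE_COD$DRUGNAME",
               "R1$1$PS$aspirin", "R1$2$C$ibuprofen",
               "R2$1$SS$warfarin"), drug)
  writeLines(c("ISR$PT", "R1$nausea", "R1$rash", "R2$bleeding"), reac)
  list(drug = drug, reac = reac)
}

## small world shared across tests (cheap: no files)
tiny_world <- function(...) {
  generate_world(world_spec(n_drug_classes = 3, drugs_per_class = 4,
                            n_target_families = 2, targets_per_family = 3,
                            n_keywords = 300, reports_per_drug = 20,
                            signature_size = 12, seq_length = 60,
                            seed = 11, ...))
}

## reference world (generator defaults) with its pharmacological and
## genomic similarities, built once per test session
.ref_cache <- new.env(parent = emptyenv())
ref_world <- function() {
  if (is.null(.ref_cache$tw)) {
    tw <- generate_world(world_spec())
    rs <- aers_filter_suspect(tw$reports)
    vocab <- aers_vocabulary(rs, max_freq = 0.05, min_reports = 5)
    .ref_cache$tw <- tw
    .ref_cache$S_pharm <- pharm_similarity(aers_profiles(rs, vocab, "bit"),
                                           vocab)
    .ref_cache$S_geno <- seq_similarity(tw$sequences)
  }
  list(tw = .ref_cache$tw, S_pharm = .ref_cache$S_pharm,
       S_geno = .ref_cache$S_geno)
}
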