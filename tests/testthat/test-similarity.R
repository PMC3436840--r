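make_vocab <- function(d_k, h = 1) {
  structure(list(keyword = sprintf("k%02d", seq_along(d_k)),
                 report_count = as.integer(round(d_k * 1000)),
                 d_k = d_k, sigma = mean(d_k), h = h, K = length(d_k),
                 n_reports = 1000L),
            class = "keyword_vocabulary")
}

test_that("keyword weights are 1 at zero frequency and strictly decreasing", {
  v <- make_vocab(c(0, 2e-4, 4e-4, 6e-4))
  w <- keyword_weights(v)
  expect_equal(unname(w[1]), 1)
  expect_true(all(diff(w) < 0))
  # hand evaluation of exp(-d^2/(h*sigma)^2)
  sigma <- mean(c(0, 2e-4, 4e-4, 6e-4))
  expect_equal(unname(w), exp(-c(0, 2e-4, 4e-4, 6e-4)^2 / sigma^2))
})

test_that("weight monotonicity holds across a generated vocabulary", {
  tw <- tiny_world()
  vocab <- aers_vocabulary(aers_filter_suspect(tw$reports),
                           max_freq = 0.3, min_reports = 3)
  w <- keyword_weights(vocab)
  ord <- order(vocab$d_k)
  expect_true(all(diff(w[ord]) <= 0))
  expect_true(all(w[ord][diff(vocab$d_k[ord]) > 0] >
                    w[ord][-1][diff(vocab$d_k[ord]) > 0]))
  expect_true(all(w > 0))
  expect_error(keyword_weights(make_vocab(c(0, 0, 0))), "sigma")
})

test_that("weighted cosine: self-similarity 1, disjoint supports 0, hand case", {
  w <- c(1, 1, 1)
  expect_equal(weighted_cosine(c(1, 1, 0), c(1, 1, 0), w), 1)
  expect_equal(weighted_cosine(c(1, 0, 0), c(0, 1, 1), w), 0)
  expect_equal(weighted_cosine(c(1, 1, 0), c(1, 0, 1), w), 0.5)
  # zero-norm convention and length check
  expect_equal(weighted_cosine(c(0, 0, 0), c(1, 0, 1), w), 0)
  expect_error(weighted_cosine(c(1, 0), c(1, 0, 1), w), "mismatch")
})

test_that("weighted cosine with non-uniform weights matches the formula", {
  set.seed(4)
  for (i in 1:20) {
    x <- stats::runif(6); y <- stats::runif(6); w <- stats::runif(6, 0.1, 2)
    expect_equal(weighted_cosine(x, y, w),
                 sum(w * x * y) / sqrt(sum(w * x^2) * sum(w * y^2)))
  }
})

test_that("uniform weights reduce the weighted cosine to plain cosine", {
  set.seed(9)
  for (i in 1:25) {
    x <- stats::rbinom(10, 1, 0.4); y <- stats::rbinom(10, 1, 0.4)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(weighted_cosine(x, y, rep(1, 10)),
                 sum(x * y) / sqrt(sum(x^2) * sum(y^2)), tolerance = 1e-12)
  }
})

test_that("pharmacological similarity matrix equals entrywise weighted cosine", {
  set.seed(2)
  prof <- matrix(stats::runif(5 * 8), 5, 8,
                 dimnames = list(paste0("d", 1:5), paste0("k", 1:8)))
  prof[4, ] <- 0                      # zero profile
  prof[5, ] <- prof[1, ]              # duplicate profile
  w <- stats::runif(8, 0.2, 1)
  S <- pharm_similarity(prof, weights = w)
  for (i in 1:5) for (j in 1:5)
    expect_equal(S[i, j], weighted_cosine(prof[i, ], prof[j, ], w),
                 tolerance = 1e-12)
  expect_equal(S[1, 5], 1)
  expect_true(all(S[4, ] == 0))       # zero row: 0 everywhere incl. diagonal
  expect_true(isSymmetric(S))
})

test_that("similarity is invariant to drug input order", {
  set.seed(3)
  prof <- matrix(stats::runif(4 * 6), 4, 6,
                 dimnames = list(paste0("d", 1:4), paste0("k", 1:6)))
  w <- rep(1, 6)
  S <- pharm_similarity(prof, weights = w)
  perm <- c(3, 1, 4, 2)
  S_perm <- pharm_similarity(prof[perm, ], weights = w)
  expect_equal(S_perm, S[perm, perm], ignore_attr = TRUE)
})

test_that("Tanimoto similarity: identity, disjoint, hand case, empty fingerprint", {
  fp <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0),
              c = c(1, 1, 0, 0), d = c(0, 0, 0, 1), e = c(0, 0, 0, 0))
  expect_message(S <- chem_similarity(fp), "empty")
  expect_equal(S["a", "c"], 1)
  expect_equal(S["a", "d"], 0)
  expect_equal(S["a", "b"], 1 / 3)
  expect_equal(S["a", "a"], 1)
  expect_true(all(S["e", ] == 0))
})

test_that("sequence similarity has unit diagonal and matches a DP oracle", {
  seqs <- c(p1 = "MKVLATGHWC", p2 = "MKVLATGHWW",
            p3 = "PQRSDEFHIK", p4 = "MKVLAT")
  S <- seq_similarity(seqs, gap_open = 10, gap_extend = 0.5)
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_true(isSymmetric(S))
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (pair in list(c(1, 2), c(1, 3), c(2, 4))) {
    i <- pair[1]; j <- pair[2]
    oracle <- sw_bruteforce(seqs[i], seqs[j], BLOSUM62, 10, 0.5) /
      sqrt(sw_bruteforce(seqs[i], seqs[i], BLOSUM62, 10, 0.5) *
             sw_bruteforce(seqs[j], seqs[j], BLOSUM62, 10, 0.5))
    expect_equal(S[i, j], oracle, tolerance = 1e-10)
  }
  expect_error(seq_similarity(c(bad = "MKVU")), "bad")
})

test_that("identical sequences score 1; one-site mutants stay near 1", {
  s <- paste(sample(c("A", "G", "L", "K", "T"), 20, TRUE), collapse = "")
  s2 <- sub("A", "G", s)
  S <- seq_similarity(c(x = s, y = s, z = s2))
  expect_equal(S["x", "y"], 1)
  expect_gt(S["x", "z"], 0.7)
})

test_that("integration aligns entities, zero-fills absences, and sums", {
  ids <- paste0("d", 1:6)
  m1 <- diag(1, 4); dimnames(m1) <- list(ids[1:4], ids[1:4])
  m1[1, 2] <- m1[2, 1] <- 0.5
  m2 <- diag(1, 3); dimnames(m2) <- list(ids[3:5], ids[3:5])
  m2[1, 2] <- m2[2, 1] <- 0.25
  m3 <- diag(1, 2); dimnames(m3) <- list(ids[5:6], ids[5:6])
  out <- integrate_similarity(list(m1, m2, m3), ids)
  manual <- matrix(0, 6, 6, dimnames = list(ids, ids))
  manual[1:4, 1:4] <- m1; manual[3:5, 3:5] <- manual[3:5, 3:5] + m2
  manual[5:6, 5:6] <- manual[5:6, 5:6] + m3
  expect_equal(out, manual, ignore_attr = TRUE)
  # single input: alignment only;  duplicate input: doubling
  expect_equal(integrate_similarity(list(m1), ids[1:4]), m1,
               ignore_attr = TRUE)
  expect_equal(integrate_similarity(list(m1, m1), ids[1:4]), 2 * m1,
               ignore_attr = TRUE)
  expect_error(integrate_similarity(list(m1), c("d1", "d1")), "duplicate")
})

test_that("integration is commutative and associative", {
  set.seed(8)
  mats <- lapply(1:3, function(i) {
    n <- sample(3:5, 1)
    ids <- sample(paste0("d", 1:6), n)
    A <- matrix(stats::runif(n * n), n); A <- (A + t(A)) / 2
    dimnames(A) <- list(ids, ids)
    A
  })
  u <- paste0("d", 1:6)
  expect_equal(integrate_similarity(mats, u),
               integrate_similarity(rev(mats), u))
  ab <- integrate_similarity(mats[1:2], u)
  expect_equal(integrate_similarity(list(ab, mats[[3]]), u),
               integrate_similarity(mats, u), ignore_attr = TRUE)
})

test_that("kernel conditioning yields positive-definite matrices", {
  I2 <- diag(1, 2)
  expect_equal(diag(condition_kernel(I2, 0.1, shift = FALSE)), rep(1.1, 2))
  ones <- matrix(1, 2, 2)
  K <- condition_kernel(ones, 0.01)
  expect_equal(sort(eigen(K)$values), c(0.01, 2.01), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(stats::rnorm(100), 10); A <- (A + t(A)) / 2
    K <- condition_kernel(A, jitter = 0.05)
    expect_gte(min(eigen(K, symmetric = TRUE)$values), 0.05 - 1e-10)
  }
})

test_that("similarity matrices round-trip through square TSV with metadata", {
  tw <- tiny_world()
  S <- chem_similarity(tw$fingerprints)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(S, path, kind = "chem", params = list(bits = ncol(tw$fingerprints)))
  back <- read_similarity(path)
  expect_equal(back, S, ignore_attr = TRUE, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$kind, "chem")
})
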