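test_that("label matrix encodes known pairs and masks test entries", {
  drugs <- paste0("d", 1:4); targets <- paste0("t", 1:3)
  ep <- data.frame(drug_id = c("d1", "d2", "d2", "d3", "d4"),
                   target_id = c("t1", "t1", "t2", "t3", "t2"))
  Z <- dti_label_matrix(ep, drugs, targets)
  expect_equal(sum(Z), 5)
  expect_equal(Z["d1", "t1"], 1)
  mask <- data.frame(drug_id = c("d1", "d2"), target_id = c("t1", "t2"))
  Zm <- dti_label_matrix(ep, drugs, targets, test_mask = mask)
  expect_equal(sum(Zm), 3)
  expect_equal(Zm["d1", "t1"], 0)
  expect_error(dti_label_matrix(data.frame(drug_id = "dX", target_id = "t1"),
                                drugs, targets), "dX")
})

test_that("identity kernels return the label matrix as weights and scores", {
  Z <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3,
              dimnames = list(c("d1", "d2"), c("t1", "t2", "t3")))
  m <- pkr_fit(diag(2), diag(3), Z)
  expect_equal(m$B, Z)
  expect_equal(pkr_predict(m), Z, ignore_attr = TRUE)
})

test_that("closed form matches explicit 2x2 inversion", {
  K <- matrix(c(1, 0.5, 0.5, 1), 2)
  Z <- matrix(c(1, 0, 0, 0), 2, dimnames = list(paste0("d", 1:2),
                                                paste0("t", 1:2)))
  m <- pkr_fit(K, K, Z)
  expect_equal(m$B, solve(K) %*% Z %*% solve(K), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("unregularized fit reconstructs Z through the kernels", {
  set.seed(11)
  for (i in 1:10) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    Kx <- random_psd_kernel(nx, 1e-3)
    Ky <- random_psd_kernel(ny, 1e-3)
    Z <- matrix(stats::rbinom(nx * ny, 1, 0.3), nx, ny,
                dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
    m <- pkr_fit(Kx, Ky, Z)
    expect_lt(max(abs(Kx %*% m$B %*% Ky - Z)), 1e-8)
  }
})

test_that("full-rank SVD regularization reproduces the exact fit", {
  set.seed(12)
  nx <- 6; ny <- 5
  Kx <- random_psd_kernel(nx, 1e-2); Ky <- random_psd_kernel(ny, 1e-2)
  Z <- matrix(stats::rbinom(nx * ny, 1, 0.4), nx, ny,
              dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
  expect_equal(pkr_fit(Kx, Ky, Z, q = min(nx, ny))$B, pkr_fit(Kx, Ky, Z)$B,
               tolerance = 1e-10)
  # rank-1 Z: q = 1 is lossless
  Z1 <- outer(c(1, 0, 1, 0, 1, 0), c(1, 1, 0, 0, 0))
  dimnames(Z1) <- dimnames(Z)
  expect_equal(pkr_fit(Kx, Ky, Z1, q = 1)$B, pkr_fit(Kx, Ky, Z1)$B,
               tolerance = 1e-8)
  expect_error(pkr_fit(Kx, Ky, Z, q = 0), "q must")
  expect_error(pkr_fit(Kx, Ky, Z, q = 99), "q must")
})

test_that("truncated fit matches an independent SVD computation", {
  set.seed(13)
  nx <- 6; ny <- 5; q <- 2
  Kx <- random_psd_kernel(nx, 1e-2); Ky <- random_psd_kernel(ny, 1e-2)
  Z <- matrix(stats::rnorm(nx * ny), nx, ny,
              dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
  sv <- La.svd(Z)
  Zq <- sv$u[, 1:q] %*% diag(sv$d[1:q]) %*% sv$vt[1:q, ]
  expect_equal(pkr_fit(Kx, Ky, Z, q = q)$B, solve(Kx) %*% Zq %*% solve(Ky),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("reconstruction error is non-increasing in q", {
  set.seed(14)
  nx <- 7; ny <- 6
  Kx <- random_psd_kernel(nx, 1e-2); Ky <- random_psd_kernel(ny, 1e-2)
  Z <- matrix(stats::rbinom(nx * ny, 1, 0.4), nx, ny,
              dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
  err <- vapply(seq_len(min(nx, ny)), function(q) {
    B <- pkr_fit(Kx, Ky, Z, q = q)$B
    norm(Z - Kx %*% B %*% Ky, "F")
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-10))
})

test_that("prediction equals the explicit weighted double sum", {
  set.seed(15)
  nx <- 5; ny <- 4
  Kx <- random_psd_kernel(nx, 1e-2); Ky <- random_psd_kernel(ny, 1e-2)
  Z <- matrix(stats::rbinom(nx * ny, 1, 0.4), nx, ny,
              dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
  m <- pkr_fit(Kx, Ky, Z)
  kx_new <- matrix(stats::runif(3 * nx), 3)
  ky_new <- matrix(stats::runif(2 * ny), 2)
  pred <- pkr_predict(m, kx_new, ky_new)
  for (a in 1:3) for (b in 1:2) {
    manual <- 0
    for (i in 1:nx) for (j in 1:ny)
      manual <- manual + m$B[i, j] * kx_new[a, i] * ky_new[b, j]
    expect_equal(pred[a, b], manual, tolerance = 1e-10)
  }
  # all-zero kernel row scores zero everywhere
  pred0 <- pkr_predict(m, matrix(0, 1, nx), ky_new)
  expect_true(all(pred0 == 0))
  expect_error(pkr_predict(m, kx_new[, 1:3], ky_new), "columns")
})

test_that("factorized prediction agrees with the explicit pairwise-space model", {
  set.seed(16)
  for (i in 1:8) {
    nx <- sample(3:10, 1); ny <- sample(3:min(10, 100 %/% nx), 1)
    Kx <- random_psd_kernel(nx, 1e-6)
    Ky <- random_psd_kernel(ny, 1e-6)
    Z <- matrix(stats::rbinom(nx * ny, 1, 0.3), nx, ny,
                dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
    m <- pkr_fit(Kx, Ky, Z)
    kx_new <- matrix(stats::runif(2 * nx), 2)
    ky_new <- matrix(stats::runif(2 * ny), 2)
    expect_lt(max(abs(pkr_predict(m, kx_new, ky_new) -
                        pairwise_space_predict(Kx, Ky, Z, kx_new, ky_new))),
              1e-8)
  }
})

test_that("consistent permutation of entities permutes B and preserves scores", {
  set.seed(17)
  nx <- 5; ny <- 4
  Kx <- random_psd_kernel(nx, 1e-2); Ky <- random_psd_kernel(ny, 1e-2)
  Z <- matrix(stats::rbinom(nx * ny, 1, 0.4), nx, ny,
              dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
  m <- pkr_fit(Kx, Ky, Z)
  p <- sample(nx); r <- sample(ny)
  mp <- pkr_fit(Kx[p, p], Ky[r, r], Z[p, r])
  expect_equal(mp$B, m$B[p, r], tolerance = 1e-9)
  kx_new <- matrix(stats::runif(2 * nx), 2); ky_new <- matrix(stats::runif(2 * ny), 2)
  expect_equal(pkr_predict(mp, kx_new[, p, drop = FALSE],
                           ky_new[, r, drop = FALSE]),
               pkr_predict(m, kx_new, ky_new), tolerance = 1e-9)
})

test_that("scores are linear in the labels", {
  set.seed(18)
  nx <- 5; ny <- 4
  Kx <- random_psd_kernel(nx, 1e-2); Ky <- random_psd_kernel(ny, 1e-2)
  Z <- matrix(stats::rbinom(nx * ny, 1, 0.4), nx, ny,
              dimnames = list(paste0("d", 1:nx), paste0("t", 1:ny)))
  kx_new <- matrix(stats::runif(2 * nx), 2); ky_new <- matrix(stats::runif(2 * ny), 2)
  s1 <- pkr_predict(pkr_fit(Kx, Ky, Z), kx_new, ky_new)
  s2 <- pkr_predict(pkr_fit(Kx, Ky, 2 * Z), kx_new, ky_new)
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
})

test_that("ranking filters known pairs, applies thresholds, breaks ties lexicographically", {
  scores <- matrix(c(5, 3, 3, 2, 3, 1), 2, 3,
                   dimnames = list(c("d2", "d1"), c("t1", "t2", "t3")))
  known <- data.frame(drug_id = "d2", target_id = "t1")
  out <- rank_predictions(scores, known)
  expect_equal(nrow(out), 5)
  expect_false(any(out$drug_id == "d2" & out$target_id == "t1"))
  # the three tied scores of 3 are ordered by (drug_id, target_id)
  tied <- out[out$score == 3, ]
  expect_equal(paste(tied$drug_id, tied$target_id),
               c("d1 t1", "d2 t2", "d2 t3"))
  expect_true(all(diff(out$score) <= 0))
  expect_equal(nrow(rank_predictions(scores, known, threshold = 99)), 0)
  top <- rank_predictions(scores, known, quantile = 0.9)
  expect_true(all(top$score >= stats::quantile(out$score, 0.9)))
})

test_that("models round-trip through the plain-text serialization", {
  set.seed(19)
  Kx <- random_psd_kernel(3, 1e-2); Ky <- random_psd_kernel(2, 1e-2)
  dimnames(Kx) <- list(paste0("d", 1:3), paste0("d", 1:3))
  dimnames(Ky) <- list(paste0("t", 1:2), paste0("t", 1:2))
  Z <- matrix(c(1, 0, 0, 1, 0, 0), 3, 2,
              dimnames = list(paste0("d", 1:3), paste0("t", 1:2)))
  m <- pkr_fit(Kx, Ky, Z)
  dir <- withr::local_tempdir()
  write_pkr_model(m, dir)
  back <- read_pkr_model(dir)
  expect_equal(back$B, m$B, tolerance = 1e-12)
  expect_equal(back$drug_ids, m$drug_ids)
  expect_equal(pkr_predict(back), pkr_predict(m), tolerance = 1e-10)
})
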