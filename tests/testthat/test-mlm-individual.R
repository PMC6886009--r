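test_that("pseudo-inverse square root inverts PSD matrices", {
  expect_equal(inverse_sqrt_psd(diag(3)), diag(3), tolerance = 1e-12)
  expect_equal(inverse_sqrt_psd(diag(c(4, 9))), diag(c(1 / 2, 1 / 3)),
               tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    A <- matrix(rnorm(36), 6, 6)
    M <- crossprod(A) + 0.1 * diag(6)
    W <- inverse_sqrt_psd(M)
    expect_lt(max(abs(W %*% M %*% W - diag(6))), 1e-10)
    expect_lt(max(abs(W - t(W))), 1e-10)
  }

  # rank-deficient input: inverse on the retained subspace only
  M <- diag(c(4, 9, 0))
  W <- inverse_sqrt_psd(M)
  expect_equal(diag(W), c(1 / 2, 1 / 3, 0), tolerance = 1e-12)

  expect_error(inverse_sqrt_psd(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(inverse_sqrt_psd(diag(c(1, -1))), "negative eigenvalue")
})

test_that("AR(1) covariance is the Toeplitz correlation matrix", {
  S <- ar1_covariance(4, 0.5)
  expect_equal(S[1, ], 0.5^(0:3))
  expect_equal(S, t(S))
  expect_equal(ar1_covariance(5, 0), diag(5))
  expect_error(ar1_covariance(5, 1), "rho")
})

test_that("individual MLM reduces to the plain cross-covariance for an
           orthonormal design and identity covariance", {
  set.seed(31)
  d <- orthonormal_design(12)
  Y <- matrix(rnorm(12 * 40), 12, 40)
  dec <- individual_mlm(Y, d, sigma = "identity", center = FALSE)
  Z <- crossprod(d$values, Y)

  # U Lambda V' reconstructs Z = Xc'Y
  rec <- dec$clinical_loadings %*% (dec$eigenvalues * dec$eigenimages)
  expect_equal(rec, Z, tolerance = 1e-10, ignore_attr = TRUE)

  # matches the eigendecomposition-of-ZZ' oracle
  eig <- eigen(Z %*% t(Z), symmetric = TRUE)
  expect_equal(dec$eigenvalues, sqrt(eig$values), tolerance = 1e-10)
  for (k in 1:3)
    expect_equal(abs(cosine(dec$clinical_loadings[, k], eig$vectors[, k])),
                 1, tolerance = 1e-10)

  # invariants: descending non-negative eigenvalues, orthonormal rows
  expect_true(all(diff(dec$eigenvalues) <= 1e-12))
  expect_true(all(dec$eigenvalues >= 0))
  expect_equal(tcrossprod(dec$eigenimages), diag(3), tolerance = 1e-10)
  expect_equal(crossprod(dec$clinical_loadings), diag(3), tolerance = 1e-10)
})

test_that("rank-1 noise-free data yields a single component", {
  set.seed(32)
  d <- orthonormal_design(15)
  v <- rnorm(50); v <- v / sqrt(sum(v^2))
  b <- c(2, -1, 0.5)
  Y <- d$values %*% b %*% t(v)
  dec <- individual_mlm(Y, d, sigma = "identity", center = FALSE)
  expect_gt(dec$eigenvalues[1], 1e-8)
  expect_lt(dec$eigenvalues[2] / dec$eigenvalues[1], 1e-10)
  expect_equal(abs(cosine(dec$eigenimages[1, ], v)), 1, tolerance = 1e-10)
})

test_that("scaling the data scales eigenvalues and leaves U, V invariant", {
  set.seed(33)
  d <- orthonormal_design(12)
  Y <- matrix(rnorm(12 * 30), 12, 30)
  d1 <- individual_mlm(Y, d, sigma = "identity", center = FALSE)
  d3 <- individual_mlm(3 * Y, d, sigma = "identity", center = FALSE)
  expect_equal(d3$eigenvalues, 3 * d1$eigenvalues, tolerance = 1e-10)
  for (k in 1:3) {
    expect_equal(abs(cosine(d3$eigenimages[k, ], d1$eigenimages[k, ])), 1,
                 tolerance = 1e-10)
    expect_equal(abs(cosine(d3$clinical_loadings[, k],
                            d1$clinical_loadings[, k])), 1, tolerance = 1e-10)
  }
})

test_that("noise-free planted components are recovered exactly", {
  cfg <- tiny_config(noise_sd = 0, subject_amp_sd = 0, drift_amplitude = 0,
                     seed = 3)
  su <- simulate_subject(cfg, 1, "depression")
  par <- paradigm_from_config(cfg)
  des <- build_design_matrix(par, cfg$tr, nrow(su$bold$values), su$motion)
  dec <- individual_mlm(su$bold, des, sigma = "ar1", rho = cfg$rho)
  maps <- mlmfmri:::component_maps(cfg)
  for (k in 1:3)
    expect_gte(abs(cosine(dec$eigenimages[k, ], maps[k, ])), 0.99)
  # eigenvalues approximate the planted amplitudes (motion partialling and
  # boundary effects perturb them slightly)
  expect_equal(dec$eigenvalues, su$truth$amplitudes, tolerance = 0.1)
})

test_that("contrast guards reject nuisance columns and excess components", {
  cfg <- tiny_config(seed = 4)
  su <- simulate_subject(cfg, 1, "schizophrenia")
  par <- paradigm_from_config(cfg)
  des <- build_design_matrix(par, cfg$tr, nrow(su$bold$values), su$motion)
  Cbad <- condition_contrast(des)
  Cbad[1, "motion1"] <- 1
  expect_error(individual_mlm(su$bold, des, contrast = Cbad),
               "nuisance|condition columns")
  expect_error(individual_mlm(su$bold, des, n_components = 4),
               "n_components")
})

test_that("alignment fixes signs against the reference subject", {
  set.seed(41)
  U <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  V <- matrix(rnorm(3 * 20), 3, 20)
  V <- V / sqrt(rowSums(V^2))
  base <- fake_decomp(U, c(3, 2, 1), V)
  flipped <- base
  flipped$clinical_loadings[, 2] <- -flipped$clinical_loadings[, 2]
  flipped$eigenimages[2, ] <- -flipped$eigenimages[2, ]

  out <- align_decompositions(list(base, flipped), reference_index = 1)
  expect_equal(out[[2]]$clinical_loadings, base$clinical_loadings)
  expect_equal(out[[2]]$eigenimages, base$eigenimages)

  # idempotence
  again <- align_decompositions(out, reference_index = 1)
  expect_identical(again, out)

  # alignment preserves each subject's reconstruction U Lambda V'
  rec_before <- flipped$clinical_loadings %*%
    (flipped$eigenvalues * flipped$eigenimages)
  rec_after <- out[[2]]$clinical_loadings %*%
    (out[[2]]$eigenvalues * out[[2]]$eigenimages)
  expect_equal(rec_before, rec_after, tolerance = 1e-12)

  zero <- base
  zero$clinical_loadings[, 1] <- 0
  expect_error(align_decompositions(list(base, zero)), "zero clinical")
})

test_that("aligned cohorts share a common loading structure", {
  cfg <- tiny_config(seed = 5)
  co <- simulate_cohort(cfg)
  par <- paradigm_from_config(cfg)
  decs <- lapply(co$subjects, function(su) {
    des <- build_design_matrix(par, cfg$tr, nrow(su$bold$values), su$motion,
                               drift_period = cfg$drift_period)
    individual_mlm(su$bold, des, sigma = "ar1", rho = cfg$rho)
  })
  aligned <- align_decompositions(decs, 1)
  for (k in 1:3) {
    Uk <- sapply(aligned, function(d) d$clinical_loadings[, k])
    cs <- crossprod(Uk)  # columns are unit vectors: entries are cosines
    expect_gte(mean(cs[upper.tri(cs)]), 0.8)
  }
})
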