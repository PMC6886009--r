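make_stack <- function(values, rank = 1, mask = array(TRUE, c(2, 2, 2))) {
  structure(list(rank = rank, values = values, mask = mask, affine = diag(4),
                 weighting = "none"),
            class = "eigenimage_stack")
}

demo_df <- function(n = 10, groups = rep(c("schizophrenia", "depression"),
                                         each = n / 2)) {
  set.seed(71)
  data.frame(group = groups,
             age = round(runif(n, 20, 60), 1),
             sex = rep_len(c("M", "F"), n),
             stringsAsFactors = FALSE)
}

test_that("eigenimage stacking preserves rows and checks masks", {
  set.seed(51)
  mask <- array(TRUE, c(2, 2, 2))
  decs <- lapply(1:4, function(i) {
    U <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    V <- matrix(rnorm(3 * 8), 3, 8); V <- V / sqrt(rowSums(V^2))
    fake_decomp(U, c(3, 2, 1), V, mask)
  })
  st <- stack_eigenimages(decs, 2)
  expect_equal(dim(st$values), c(4, 8))
  for (i in 1:4) expect_equal(st$values[i, ], decs[[i]]$eigenimages[2, ])

  # eigenvalue weighting scales each row by the subject's eigenvalue
  stw <- stack_eigenimages(decs, 2, weighting = "eigenvalue")
  expect_equal(stw$values, 2 * st$values)

  decs[[2]]$mask <- array(c(TRUE, FALSE), c(2, 2, 2))
  expect_error(stack_eigenimages(decs, 2), "common mask")
  expect_error(stack_eigenimages(decs[1], 4), "out of range")
})

test_that("confound residualization matches the explicit hat-matrix oracle", {
  set.seed(52)
  dd <- demo_df(10)
  gd <- group_design(dd)
  Y <- matrix(rnorm(10 * 25), 10, 25)
  rc <- residualize_confounds(make_stack(Y), gd)

  C <- cbind(1, gd$values[, c("age", "sex")])
  P <- diag(10) - C %*% solve(crossprod(C)) %*% t(C)
  expect_equal(rc$stack$values, P %*% Y, tolerance = 1e-10)
  expect_equal(rc$design$values, P %*% gd$values[, "group", drop = FALSE],
               tolerance = 1e-10, ignore_attr = TRUE)

  # adjusted stack is orthogonal to the confounds
  expect_lt(max(abs(crossprod(C, rc$stack$values))) / max(abs(Y)), 1e-8)

  # a stack built entirely from the age confound is annihilated
  Yc <- gd$values[, "age"] %*% t(rnorm(25))
  rc2 <- residualize_confounds(make_stack(Yc), gd)
  expect_lt(max(abs(rc2$stack$values)) / max(abs(Yc)), 1e-8)

  # already-orthogonal stack changes only by mean removal
  Yo <- P %*% Y
  rc3 <- residualize_confounds(make_stack(Yo), gd)
  expect_equal(rc3$stack$values, Yo, tolerance = 1e-10)
})

test_that("group MLM separates noise-free opposite group patterns", {
  set.seed(53)
  pat <- rnorm(40); pat <- pat / sqrt(sum(pat^2))
  g <- rep(c(1, -1), each = 5)
  Y <- outer(g, pat) * 2
  des <- structure(list(values = matrix(g, dimnames = list(NULL, "group")),
                        group_labels = ifelse(g > 0, "schizophrenia",
                                              "depression")),
                   class = "group_design")
  gd <- group_mlm(make_stack(Y), des)
  expect_equal(abs(cosine(gd$signature, pat)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(gd$signature^2)), 1, tolerance = 1e-10)
  # loadings perfectly separate the groups
  expect_true(min(gd$subject_loadings[g > 0]) >
                max(gd$subject_loadings[g < 0]) ||
              max(gd$subject_loadings[g > 0]) <
                min(gd$subject_loadings[g < 0]))
  # subject loadings are the projections onto the signature
  expect_equal(gd$subject_loadings, drop(Y %*% gd$signature),
               tolerance = 1e-12)
})

test_that("group MLM reconstructs Z_G and is confound invariant", {
  set.seed(54)
  dd <- demo_df(6)
  gd0 <- group_design(dd)
  Y <- matrix(rnorm(6 * 20), 6, 20)
  rc <- residualize_confounds(make_stack(Y), gd0)
  g <- group_mlm(rc$stack, rc$design)
  expect_equal(dim(g$Z_G), c(1, 20))
  # U_G Lambda_G V_G' reconstructs Z_G (one-row case: lambda * signature)
  expect_equal(abs(g$Z_G), abs(g$eigenvalues[1] * matrix(g$signature, 1)),
               tolerance = 1e-10)

  # adding a linear-in-confounds component leaves the result unchanged
  C <- gd0$values[, c("age", "sex")]
  Y2 <- Y + C %*% matrix(rnorm(2 * 20), 2, 20) + 5
  rc2 <- residualize_confounds(make_stack(Y2), gd0)
  g2 <- group_mlm(rc2$stack, rc2$design)
  expect_equal(abs(cosine(g$signature, g2$signature)), 1, tolerance = 1e-8)
  expect_equal(abs(g$subject_loadings), abs(g2$subject_loadings),
               tolerance = 1e-6)

  expect_error(group_mlm(make_stack(matrix(0, 6, 20)), rc$design),
               "identically zero")
})

test_that("null stacks give weak group association (Monte-Carlo)", {
  # in-sample loadings are only calibrated when voxels << subjects: the
  # projection onto a signature estimated from all subjects overfits
  # idiosyncratic noise as the voxel count grows, which is why the pipeline
  # re-estimates signatures inside CV folds (see test-acceptance.R)
  set.seed(55)
  n_hit <- 0
  labels <- rep(c("schizophrenia", "depression"), c(16, 14))
  for (i in 1:200) {
    dd <- data.frame(group = labels, age = runif(30, 20, 60),
                     sex = sample(rep_len(c("M", "F"), 30)))
    gd0 <- group_design(dd)
    Y <- matrix(rnorm(30 * 3), 30, 3)
    rc <- residualize_confounds(make_stack(Y), gd0)
    g <- group_mlm(rc$stack, rc$design)
    r <- cor(g$subject_loadings, ifelse(labels == "schizophrenia", 1, -1))
    if (abs(r) <= 0.5) n_hit <- n_hit + 1
  }
  expect_gte(n_hit / 200, 0.95)
})

test_that("weighted clinical loadings average by subject loading", {
  set.seed(56)
  decs <- lapply(1:4, function(i) {
    U <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    dimnames(U) <- list(c("DS", "PS", "DN"), NULL)
    V <- matrix(rnorm(3 * 8), 3, 8); V <- V / sqrt(rowSums(V^2))
    fake_decomp(U, c(3, 2, 1), V)
  })
  mk_group <- function(w) structure(list(subject_loadings = w),
                                    class = "group_decomposition")
  groups_eq <- list(mk_group(rep(2, 4)), mk_group(rep(2, 4)),
                    mk_group(rep(2, 4)))
  w_eq <- weighted_clinical_loadings(decs, groups_eq)
  manual <- sapply(1:3, function(r)
    rowMeans(sapply(decs, function(d) d$clinical_loadings[, r])))
  expect_equal(w_eq, manual, ignore_attr = TRUE, tolerance = 1e-12)

  groups_one <- list(mk_group(c(0, -3, 0, 0)), mk_group(c(0, -3, 0, 0)),
                     mk_group(c(0, -3, 0, 0)))
  w_one <- weighted_clinical_loadings(decs, groups_one)
  expect_equal(w_one[, 1], -decs[[2]]$clinical_loadings[, 1],
               ignore_attr = TRUE, tolerance = 1e-12)

  groups_zero <- list(mk_group(rep(0, 4)), mk_group(rep(0, 4)),
                      mk_group(rep(0, 4)))
  expect_error(weighted_clinical_loadings(decs, groups_zero), "zero")
})

test_that("signature T map uses correlation t statistics and df = s - 2", {
  # the study threshold: 30 subjects, one-sided p = 0.05 -> critical t 1.70
  expect_equal(round(tmap_critical_t(30, 0.05), 2), 1.70)

  set.seed(57)
  Y <- matrix(rnorm(30 * 500), 30, 500)
  load <- rnorm(30)
  Y[, 1] <- load                      # perfectly correlated voxel
  Y[, 2] <- 7                        # constant voxel
  tm <- signature_tmap(make_stack(Y), load)
  expect_equal(tm$df, 28)
  expect_equal(tm$tvalues[1], 1e8)
  expect_equal(tm$tvalues[2], 0)
  expect_equal(tm$n_constant, 1)
  expect_equal(tm$n_capped, 1)

  # agreement with cor.test's t statistic on an ordinary voxel
  ct <- cor.test(load, Y[, 3])
  expect_equal(tm$tvalues[3], unname(ct$statistic), tolerance = 1e-10)

  expect_error(signature_tmap(make_stack(Y), rep(1, 30)), "constant")
})

test_that("permuted loadings exceed the threshold at the nominal rate", {
  set.seed(58)
  Y <- matrix(rnorm(30 * 4000), 30, 4000)
  load <- rnorm(30)
  tm <- signature_tmap(make_stack(Y), load, p = 0.05)
  frac <- mean(abs(tm$tvalues) > tm$critical_t)
  expect_lt(abs(frac - 0.10), 0.02)
})

test_that("a group effect planted in rank 3 is recovered there and not in
           ranks 1-2 (high-SNR cohort)", {
  cfg <- cohort_config(grid = c(12, 12, 6), noise_sd = 0.25,
                       subject_amp_sd = 5, seed = 9)
  co <- simulate_cohort(cfg)
  res <- analyze_cohort(co, seed = 7, repeats = 20)
  g <- ifelse(co$manifest$group == "schizophrenia", 1, -1)
  pb <- sapply(res$groups, function(gd) abs(cor(gd$subject_loadings, g)))
  expect_gte(pb[3], 0.8)
  expect_lt(pb[1], 0.5)
  expect_lt(pb[2], 0.5)
  # the rank-3 signature matches the planted difference map
  expect_gte(abs(cosine(res$groups[[3]]$signature,
                        co$truth$group_difference_map)), 0.8)
})
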