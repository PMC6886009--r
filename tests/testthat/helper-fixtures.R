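# shared fixtures: everything is generated in code, seeded

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# small, fast cohort configuration (full default paradigm, reduced grid)
tiny_config <- function(...) {
  cohort_config(grid = c(6, 6, 6), ...)
}

# hand-built design with orthonormal condition columns and no nuisance,
# for tests that need the whitener to reduce to the identity
orthonormal_design <- function(n_scans = 12) {
  q <- qr.Q(qr(matrix(stats::rnorm(n_scans * 3), n_scans, 3)))
  colnames(q) <- c("DS", "PS", "DN")
  structure(list(values = q, tr = 1, conditions = c("DS", "PS", "DN")),
            class = "design_matrix")
}

# minimal mlm_decomposition for group-level unit tests
fake_decomp <- function(U, lambda, V, mask = array(TRUE, c(2, 2, 2))) {
  structure(list(clinical_loadings = U, eigenvalues = lambda,
                 eigenimages = V, n_components = ncol(U),
                 rho = 0, sigma_form = "identity",
                 mask = mask, affine = diag(4)),
            class = "mlm_decomposition")
}

pearson_chi2 <- function(m) {
  n <- sum(m)
  n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    prod(rowSums(m)) / prod(colSums(m))
}
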