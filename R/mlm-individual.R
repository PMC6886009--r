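#' Inverse square root of a symmetric positive semi-definite matrix
#'
#' Eigendecomposition-based pseudo-inverse square root: eigenvalues below
#' `tol` times the largest are treated as zero, so the result `W` satisfies
#' `W %*% M %*% W = I` on the retained subspace.
#'
#' @param m Symmetric PSD matrix.
#' @param tol Relative eigenvalue cutoff (default 1e-12).
#' @return Symmetric matrix of the same dimension.
#' @export
inverse_sqrt_psd <- function(m, tol = 1e-12) {
  m <- as.matrix(m)
  scale <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > 1e-10 * scale)
    stop("input matrix is not symmetric")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  cutoff <- tol * max(e$values, 0)
  if (any(e$values < -max(cutoff, 1e-10 * scale)))
    stop("input matrix has a negative eigenvalue; not PSD")
  d <- ifelse(e$values > cutoff, 1 / sqrt(pmax(e$values, cutoff)), 0)
  e$vectors %*% (d * t(e$vectors))
}

#' AR(1) temporal covariance matrix
#'
#' Toeplitz correlation matrix with entries `rho^|t - s|`; `rho = 0` gives
#' the identity.
#'
#' @param n_scans Dimension.
#' @param rho AR(1) coefficient in (-1, 1).
#' @return n_scans x n_scans matrix.
#' @export
ar1_covariance <- function(n_scans, rho) {
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1)")
  idx <- seq_len(n_scans)
  rho^abs(outer(idx, idx, "-"))
}

# canonical sign + degenerate-eigenvalue ordering for an SVD: near-ties
# (relative gap < 1e-8) are ordered by the first nonzero element of the
# corresponding left singular vector; each left vector's largest-magnitude
# entry is made positive (V flipped jointly so U d V' is preserved)
canonicalize_svd <- function(u, d, v) {
  k <- length(d)
  ord <- seq_len(k)
  if (k > 1) {
    for (j in seq_len(k - 1)) {
      gap <- abs(d[j] - d[j + 1]) / max(d[1], .Machine$double.xmin)
      if (gap < 1e-8) {
        f1 <- u[which(abs(u[, ord[j]]) > 1e-12)[1], ord[j]]
        f2 <- u[which(abs(u[, ord[j + 1]]) > 1e-12)[1], ord[j + 1]]
        if (isTRUE(f2 > f1)) ord[c(j, j + 1)] <- ord[c(j + 1, j)]
      }
    }
  }
  u <- u[, ord, drop = FALSE]; v <- v[, ord, drop = FALSE]; d <- d[ord]
  for (j in seq_len(k)) {
    s <- sign(u[which.max(abs(u[, j])), j])
    if (s < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  list(u = u, d = d, v = v)
}

#' Individual-level multivariate linear model
#'
#' Computes the whitened cross-covariance between the condition regressors
#' and the voxel data, `Z = (Xc' Sigma Xc)^(-1/2) Xc' Y`, and its singular
#' value decomposition `Z = U Lambda V'`. The left singular vectors `U` are
#' the clinical loadings (condition-space directions), the right singular
#' vectors `V` the eigenimages (voxel patterns).
#'
#' Nuisance regressors (motion, drift, intercept) are partialled out of both
#' the data and the condition columns before whitening, so the decomposition
#' lives in the 3-dimensional space spanned by the adjusted condition
#' regressors.
#'
#' @param bold A `bold_matrix` or scans x voxels matrix.
#' @param design A `design_matrix`.
#' @param sigma Temporal covariance: `"ar1"` (default, coefficient `rho`)
#'   or `"identity"`.
#' @param rho AR(1) coefficient used when `sigma = "ar1"`. If `NULL`, it is
#'   estimated from the GLM residuals via [estimate_ar1()].
#' @param contrast Contrast matrix selecting the condition columns
#'   (default [condition_contrast()]); it must not touch nuisance columns.
#' @param n_components Components to retain (1-3, default 3).
#' @param center Mean-center each voxel time course first (default TRUE;
#'   with an intercept in the design this is a no-op for the result).
#' @return Object of class `mlm_decomposition`: `clinical_loadings`
#'   (3 x k, rows DS/PS/DN), `eigenvalues` (length k, descending),
#'   `eigenimages` (k x voxels, orthonormal rows), `n_components`, `rho`,
#'   plus the mask/affine carried from `bold` when present.
#' @export
individual_mlm <- function(bold, design, sigma = c("ar1", "identity"),
                           rho = NULL, contrast = condition_contrast(design),
                           n_components = 3, center = TRUE) {
  sigma <- match.arg(sigma)
  Y <- bold_values(bold)
  X <- design$values
  stopifnot(nrow(Y) == nrow(X))
  C <- as.matrix(contrast)
  if (ncol(C) != ncol(X)) stop("contrast incompatible with design")
  cond_idx <- which(colnames(X) %in% design$conditions)
  if (any(abs(C[, -cond_idx, drop = FALSE]) > 0))
    stop("contrast must select only the condition columns")
  if (n_components < 1 || n_components > length(cond_idx))
    stop("`n_components` must be between 1 and ", length(cond_idx))

  if (center) Y <- sweep(Y, 2, colMeans(Y))
  Xc <- X[, cond_idx, drop = FALSE]
  Xn <- X[, -cond_idx, drop = FALSE]
  if (ncol(Xn) > 0) {
    qn <- qr(Xn)
    Y <- qr.resid(qn, Y)
    Xc <- qr.resid(qn, Xc)
  }

  if (is.null(rho)) {
    rho <- if (sigma == "ar1") {
      qf <- qr(cbind(Xc, Xn))
      estimate_ar1(qr.resid(qf, Y))
    } else 0
  }
  Sig <- if (sigma == "ar1") ar1_covariance(nrow(Xc), rho) else diag(nrow(Xc))
  W <- inverse_sqrt_psd(crossprod(Xc, Sig %*% Xc))
  Z <- W %*% crossprod(Xc, Y)
  rownames(Z) <- design$conditions

  sv <- svd(Z, nu = min(nrow(Z), ncol(Z)), nv = min(nrow(Z), ncol(Z)))
  cs <- canonicalize_svd(sv$u, sv$d, sv$v)
  k <- n_components
  structure(list(
    clinical_loadings = structure(cs$u[, seq_len(k), drop = FALSE],
                                  dimnames = list(design$conditions, NULL)),
    eigenvalues = cs$d[seq_len(k)],
    eigenimages = t(cs$v[, seq_len(k), drop = FALSE]),
    n_components = as.integer(k),
    rho = if (sigma == "ar1") rho else 0,
    sigma_form = sigma,
    mask = attr_or_null(bold, "mask"),
    affine = attr_or_null(bold, "affine")
  ), class = "mlm_decomposition")
}

attr_or_null <- function(x, field) {
  if (is.list(x) && !is.null(x[[field]])) x[[field]] else NULL
}

#' @export
print.mlm_decomposition <- function(x, ...) {
  cat(sprintf("individual MLM: %d components over %d voxels (rho = %.3f)\n",
              x$n_components, ncol(x$eigenimages), x$rho))
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Align individual decompositions to a reference subject
#'
#' Resolves the sign indeterminacy of each component: for every subject and
#' component rank, the clinical-loading column is flipped (jointly with the
#' matching eigenimage row, so `U Lambda V'` is unchanged) whenever its dot
#' product with the reference subject's column is negative. Component order
#' (descending eigenvalue) is untouched.
#'
#' @param decomps List of `mlm_decomposition` objects.
#' @param reference_index Index of the reference subject (default 1).
#' @return List of aligned `mlm_decomposition` objects.
#' @export
align_decompositions <- function(decomps, reference_index = 1) {
  stopifnot(length(decomps) >= 1,
            reference_index >= 1, reference_index <= length(decomps))
  k <- unique(vapply(decomps, function(d) d$n_components, integer(1)))
  if (length(k) != 1) stop("decompositions differ in n_components")
  ref <- decomps[[reference_index]]$clinical_loadings
  for (d in decomps)
    if (any(colSums(abs(d$clinical_loadings)) == 0))
      stop("zero clinical-loading column: sign undefined")
  lapply(seq_along(decomps), function(i) {
    d <- decomps[[i]]
    if (i == reference_index) return(d)
    for (j in seq_len(k)) {
      if (sum(d$clinical_loadings[, j] * ref[, j]) < 0) {
        d$clinical_loadings[, j] <- -d$clinical_loadings[, j]
        d$eigenimages[j, ] <- -d$eigenimages[j, ]
      }
    }
    d
  })
}
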