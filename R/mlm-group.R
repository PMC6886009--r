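#' Group design matrix
#'
#' Subjects x covariates design for the group-level MLM: a single +/-1
#' diagnosis contrast column (+1 = schizophrenia, -1 = depression), centered
#' age, and a +/-1 sex code (+1 = M, -1 = F).
#'
#' @param demographics Data frame with columns `group`
#'   (schizophrenia/depression), `age` (years) and `sex` (M/F), one row per
#'   subject in manifest order.
#' @return Object of class `group_design`: list with `values` (subjects x 3
#'   labelled matrix) and `group_labels` (the input diagnosis per subject).
#' @export
group_design <- function(demographics) {
  stopifnot(all(c("group", "age", "sex") %in% names(demographics)))
  g <- as.character(demographics$group)
  if (!all(g %in% c("schizophrenia", "depression")))
    stop("group must be 'schizophrenia' or 'depression'")
  sx <- as.character(demographics$sex)
  if (!all(sx %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  v <- cbind(group = ifelse(g == "schizophrenia", 1, -1),
             age = demographics$age - mean(demographics$age),
             sex = ifelse(sx == "M", 1, -1))
  if (qr(v)$rank < ncol(v)) stop("group design is rank deficient")
  structure(list(values = v, group_labels = g), class = "group_design")
}

#' Stack one component's eigenimages across subjects
#'
#' Row i of the stack is subject i's rank-`rank` aligned eigenimage, in
#' manifest order. All subjects must share the same mask. With
#' `weighting = "eigenvalue"` each row is scaled by the subject's rank-k
#' eigenvalue, so between-subject differences in component strength are
#' carried into the group analysis (the pipeline default); `"none"` stacks
#' the unit-norm eigenimages as stored.
#'
#' @param aligned List of aligned `mlm_decomposition` objects.
#' @param rank Component rank (1 to n_components).
#' @param weighting `"none"` (default) or `"eigenvalue"`.
#' @return Object of class `eigenimage_stack`: `rank`, `values`
#'   (subjects x voxels), `mask`, `affine`, `weighting`.
#' @export
stack_eigenimages <- function(aligned, rank,
                              weighting = c("none", "eigenvalue")) {
  weighting <- match.arg(weighting)
  stopifnot(length(aligned) >= 1)
  k <- aligned[[1]]$n_components
  if (rank < 1 || rank > k) stop("`rank` out of range 1..", k)
  masks <- lapply(aligned, `[[`, "mask")
  for (m in masks[-1])
    if (!identical(dim(m), dim(masks[[1]])) || !identical(c(m), c(masks[[1]])))
      stop("subjects do not share a common mask")
  values <- t(vapply(aligned, function(d) {
    w <- if (weighting == "eigenvalue") d$eigenvalues[rank] else 1
    w * d$eigenimages[rank, ]
  }, numeric(ncol(aligned[[1]]$eigenimages))))
  structure(list(rank = rank, values = values,
                 mask = masks[[1]], affine = aligned[[1]]$affine,
                 weighting = weighting),
            class = "eigenimage_stack")
}

#' Remove age and sex confounds from the stack and the group contrast
#'
#' Both the eigenimage stack and the retained group column are replaced by
#' their residuals from regression on the confounds plus an intercept, so
#' downstream signatures cannot reflect age or sex structure.
#'
#' @param stack An `eigenimage_stack`.
#' @param design A `group_design`.
#' @param confounds Confound column labels (default `c("age", "sex")`).
#' @return List with `stack` (adjusted `eigenimage_stack`) and `design`
#'   (reduced `group_design` holding the residualized group column only).
#' @export
residualize_confounds <- function(stack, design, confounds = c("age", "sex")) {
  stopifnot(inherits(stack, "eigenimage_stack"), inherits(design, "group_design"))
  missing_c <- setdiff(confounds, colnames(design$values))
  if (length(missing_c)) stop("confounds not in design: ",
                              paste(missing_c, collapse = ", "))
  C <- cbind(intercept = 1, design$values[, confounds, drop = FALSE])
  qc <- qr(C)
  if (qc$rank < ncol(C)) stop("confound matrix is rank deficient")
  keep <- setdiff(colnames(design$values), confounds)
  red <- qr.resid(qc, design$values[, keep, drop = FALSE])
  colnames(red) <- keep
  adj <- stack
  adj$values <- qr.resid(qc, stack$values)
  list(stack = adj,
       design = structure(list(values = red, group_labels = design$group_labels),
                          class = "group_design"))
}

#' Group-level multivariate linear model
#'
#' Computes `Z_G = (X_G' X_G)^(-1/2) X_G' Y_G` (subject covariance taken as
#' identity — subjects are exchangeable) over the confound-adjusted
#' eigenimage stack and decomposes it by SVD. The leading right singular
#' vector is the group brain signature for this component rank; per-subject
#' loadings are the projections of each subject's adjusted eigenimage onto
#' the signature, and the design-space projection is the hat-matrix image of
#' those loadings.
#'
#' @param adjusted_stack Confound-adjusted `eigenimage_stack`.
#' @param reduced_design Reduced `group_design` from [residualize_confounds()].
#' @return Object of class `group_decomposition` with fields `rank`, `Z_G`,
#'   `group_loadings` (U_G, design space), `eigenvalues`, `signature` (unit
#'   norm voxel vector), `subject_loadings`, `design_projection`,
#'   `sigma_G_form`, `mask`, `affine`, `group_labels`.
#' @export
group_mlm <- function(adjusted_stack, reduced_design) {
  Y <- adjusted_stack$values
  X <- reduced_design$values
  stopifnot(nrow(Y) == nrow(X))
  if (all(Y == 0)) stop("adjusted stack is identically zero")
  W <- inverse_sqrt_psd(crossprod(X))
  Z <- W %*% crossprod(X, Y)
  sv <- svd(Z, nu = min(dim(Z)), nv = min(dim(Z)))
  cs <- canonicalize_svd(sv$u, sv$d, sv$v)
  signature <- cs$v[, 1]
  loadings <- drop(Y %*% signature)
  H <- X %*% solve(crossprod(X), t(X))
  structure(list(
    rank = adjusted_stack$rank,
    Z_G = Z,
    group_loadings = cs$u,
    eigenvalues = cs$d,
    signature = signature,
    subject_loadings = loadings,
    design_projection = drop(H %*% loadings),
    sigma_G_form = "identity",
    mask = adjusted_stack$mask,
    affine = adjusted_stack$affine,
    group_labels = reduced_design$group_labels
  ), class = "group_decomposition")
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat(sprintf("group MLM (rank %d): %d subjects, %d voxels\n",
              x$rank, length(x$subject_loadings), length(x$signature)))
  invisible(x)
}

#' Cohort clinical loadings weighted by subject loadings
#'
#' For each component rank, the weighted average of the subjects'
#' individual-level clinical loadings, the weight of subject i being its
#' group-level subject loading:
#' `sum_i w_i U_i[, rank] / sum_i |w_i|`.
#'
#' @param individual List of (aligned) `mlm_decomposition` objects.
#' @param groups List of `group_decomposition` objects, one per rank.
#' @return Conditions x ranks matrix of weighted clinical loadings.
#' @export
weighted_clinical_loadings <- function(individual, groups) {
  k <- individual[[1]]$n_components
  stopifnot(length(groups) == k)
  conds <- rownames(individual[[1]]$clinical_loadings)
  out <- matrix(0, length(conds), k, dimnames = list(conds, paste0("rank", 1:k)))
  for (r in seq_len(k)) {
    w <- groups[[r]]$subject_loadings
    if (all(w == 0)) stop("all subject loadings are zero for rank ", r)
    num <- Reduce(`+`, lapply(seq_along(individual), function(i)
      w[i] * individual[[i]]$clinical_loadings[, r]))
    out[, r] <- num / sum(abs(w))
  }
  out
}

#' Critical t value for the signature map threshold
#'
#' One-sided critical t at significance `p` with `n_subjects - 2` degrees of
#' freedom (the correlation-test degrees of freedom used by
#' [signature_tmap()]).
#'
#' @param n_subjects Number of subjects.
#' @param p One-sided uncorrected significance level.
#' @return Scalar critical t.
#' @export
tmap_critical_t <- function(n_subjects, p = 0.05) {
  stopifnot(n_subjects >= 3, p > 0, p < 1)
  stats::qt(1 - p, df = n_subjects - 2)
}

#' Voxelwise signature T map
#'
#' Per voxel, the Pearson correlation between the subject loadings and the
#' adjusted eigenimage values, converted to a t statistic
#' `T = r sqrt((s - 2) / (1 - r^2))` with `s - 2` degrees of freedom, plus
#' positive/negative threshold masks at an uncorrected one-sided level.
#'
#' Voxels with constant values across subjects get `T = 0` (counted in
#' `n_constant`); perfectly correlated voxels are capped at `t_cap`.
#'
#' @param adjusted_stack Confound-adjusted `eigenimage_stack`.
#' @param subject_loadings Per-subject scalar loadings.
#' @param p One-sided uncorrected significance level (default 0.05).
#' @param t_cap Cap on |T| for r = +/-1 voxels (default 1e8).
#' @return List: `tvalues`, `df`, `critical_t`, `pos_mask`, `neg_mask`
#'   (logical, per voxel), `n_constant`, `n_capped`.
#' @export
signature_tmap <- function(adjusted_stack, subject_loadings, p = 0.05,
                           t_cap = 1e8) {
  Y <- adjusted_stack$values
  s <- nrow(Y)
  if (s < 3) stop("need at least 3 subjects")
  if (stats::sd(subject_loadings) == 0) stop("subject loadings are constant")
  yc <- sweep(Y, 2, colMeans(Y))
  lc <- subject_loadings - mean(subject_loadings)
  ys <- sqrt(colSums(yc^2))
  constant <- ys == 0
  r <- numeric(ncol(Y))
  r[!constant] <- drop(crossprod(yc[, !constant, drop = FALSE], lc)) /
    (ys[!constant] * sqrt(sum(lc^2)))
  r <- pmin(pmax(r, -1), 1)
  tt <- ifelse(abs(r) >= 1 - 1e-15,
               sign(r) * t_cap,
               r * sqrt((s - 2) / (1 - r^2)))
  tt[constant] <- 0
  crit <- tmap_critical_t(s, p)
  list(tvalues = tt, df = s - 2, critical_t = crit,
       pos_mask = tt > crit, neg_mask = tt < -crit,
       n_constant = sum(constant),
       n_capped = sum(abs(tt) >= t_cap & !constant))
}
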