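#' Canonical haemodynamic response function
#'
#' Double-gamma HRF (peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' undershoot ratio 1/6), sampled at the repetition time over a 32 s support
#' and scaled to unit peak.
#'
#' @param tr Repetition time in seconds (> 0).
#' @param duration Kernel support in seconds (default 32).
#' @return Numeric vector of length `ceiling(duration / tr)`.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("`tr` must be a single positive number")
  t <- seq(0, by = tr, length.out = ceiling(duration / tr))
  h <- hrf_double_gamma(t)
  h / max(h)
}

# closed-form double gamma, evaluable on any time grid (used by tests on a
# fine grid to locate the peak)
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_delay / peak_disp, rate = 1 / peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          rate = 1 / undershoot_disp)
}

#' Build a block paradigm
#'
#' Constructs the block timing of the self-rating task: active blocks of
#' consecutive statements for each of the three conditions (DS = depression
#' specific, PS = paranoia specific, DN = diagnostically neutral), each
#' followed by a rest block, cycling through `order` until every condition
#' has `blocks_per_condition` blocks, with optional lead-in/lead-out rest.
#'
#' The defaults reproduce the study paradigm: 4 blocks per condition of
#' four 8 s statements (32 s active blocks), 20 s rest after each, and 40 s
#' of rest at either end, for a total of 704 s.
#'
#' @param blocks_per_condition Number of active blocks per condition.
#' @param statement_duration Duration of one statement in seconds.
#' @param statements_per_block Statements per active block.
#' @param rest_duration Rest block duration in seconds (0 to omit).
#' @param order Condition cycle, a character vector drawn from DS, PS, DN.
#' @param lead_in,lead_out Rest padding in seconds at start/end (0 to omit).
#' @return An object of class `paradigm`: list with `blocks` (data.frame
#'   of condition, onset, duration) and `total_duration` (seconds).
#' @export
build_paradigm <- function(blocks_per_condition = 4,
                           statement_duration = 8,
                           statements_per_block = 4,
                           rest_duration = 20,
                           order = c("DS", "DN", "PS"),
                           lead_in = 40, lead_out = 40) {
  if (blocks_per_condition < 1 || statements_per_block < 1)
    stop("block and statement counts must be positive")
  if (statement_duration <= 0)
    stop("`statement_duration` must be positive")
  if (rest_duration < 0 || lead_in < 0 || lead_out < 0)
    stop("rest durations must be non-negative")
  bad <- setdiff(order, c("DS", "PS", "DN"))
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))

  active_dur <- statements_per_block * statement_duration
  sequence <- rep(order, length.out = blocks_per_condition * length(unique(order)))
  cond <- character(0); onset <- numeric(0); dur <- numeric(0)
  t <- 0
  if (lead_in > 0) {
    cond <- "rest"; onset <- 0; dur <- lead_in; t <- lead_in
  }
  for (cn in sequence) {
    cond <- c(cond, cn); onset <- c(onset, t); dur <- c(dur, active_dur)
    t <- t + active_dur
    if (rest_duration > 0) {
      cond <- c(cond, "rest"); onset <- c(onset, t); dur <- c(dur, rest_duration)
      t <- t + rest_duration
    }
  }
  if (lead_out > 0) {
    cond <- c(cond, "rest"); onset <- c(onset, t); dur <- c(dur, lead_out)
    t <- t + lead_out
  }
  structure(list(
    blocks = data.frame(condition = cond, onset = onset, duration = dur,
                        stringsAsFactors = FALSE),
    total_duration = t
  ), class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  n_active <- sum(x$blocks$condition != "rest")
  cat(sprintf("paradigm: %d active blocks, total duration %g s\n",
              n_active, x$total_duration))
  invisible(x)
}

condition_names <- c("DS", "PS", "DN")

# direct (non-FFT) causal convolution truncated to length(x): exact for
# delta kernels, no round-off from frequency-domain methods
convolve_truncated <- function(x, h) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(h)) {
    if (j > n) break
    idx <- seq_len(n - j + 1)
    out[idx + j - 1] <- out[idx + j - 1] + h[j] * x[idx]
  }
  out
}

#' Build the first-level design matrix
#'
#' One regressor per condition (the condition boxcar sampled at scan onsets
#' and convolved with the HRF kernel), six motion parameters, an optional
#' cosine drift regressor, and an intercept.
#'
#' @param paradigm A [build_paradigm()] object.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of volumes; `n_scans * tr` must cover the paradigm.
#' @param motion `n_scans` x 6 matrix of rigid-body motion parameters.
#' @param hrf HRF kernel sampled at `tr` (default [canonical_hrf()]).
#' @param drift_period Period in seconds of a cosine drift regressor, or
#'   `NULL` (default) for none.
#' @return Object of class `design_matrix`: list with `values` (n_scans x p
#'   labelled matrix), `tr`, and `conditions` (the condition column labels).
#' @export
build_design_matrix <- function(paradigm, tr, n_scans, motion,
                                hrf = canonical_hrf(tr),
                                drift_period = NULL) {
  stopifnot(inherits(paradigm, "paradigm"), tr > 0, n_scans >= 1)
  if (paradigm$total_duration > n_scans * tr + 1e-9)
    stop(sprintf("paradigm duration (%g s) exceeds scan coverage (%g s)",
                 paradigm$total_duration, n_scans * tr))
  motion <- as.matrix(motion)
  if (nrow(motion) != n_scans || ncol(motion) != 6L)
    stop("`motion` must have n_scans rows and 6 columns")

  times <- (seq_len(n_scans) - 1) * tr
  cond_cols <- sapply(condition_names, function(cn) {
    bl <- paradigm$blocks[paradigm$blocks$condition == cn, , drop = FALSE]
    box <- numeric(n_scans)
    for (b in seq_len(nrow(bl)))
      box[times >= bl$onset[b] - 1e-9 &
            times < bl$onset[b] + bl$duration[b] - 1e-9] <- 1
    convolve_truncated(box, hrf)
  })
  colnames(cond_cols) <- condition_names
  x <- cbind(cond_cols, motion)
  colnames(x) <- c(condition_names, paste0("motion", 1:6))
  if (!is.null(drift_period)) {
    if (drift_period <= 0) stop("`drift_period` must be positive")
    x <- cbind(x, drift = cos(2 * pi * times / drift_period))
  }
  x <- cbind(x, intercept = 1)
  structure(list(values = x, tr = tr, conditions = condition_names),
            class = "design_matrix")
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares of every voxel time course on the design.
#'
#' @param bold A `bold_matrix` (see [read_bold()]) or a scans x voxels matrix.
#' @param design A `design_matrix`.
#' @return Object of class `glm_fit`: `betas` (regressors x voxels),
#'   `residuals` (scans x voxels), `dof` (scans - rank(X)).
#' @export
fit_glm <- function(bold, design) {
  Y <- bold_values(bold)
  X <- design$values
  if (nrow(Y) != nrow(X))
    stop("design rows must equal number of scans")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient")
  betas <- qr.coef(qx, Y)
  rownames(betas) <- colnames(X)
  res <- Y - X %*% betas
  structure(list(betas = betas, residuals = res,
                 dof = nrow(X) - qx$rank),
            class = "glm_fit")
}

#' Pooled lag-1 autocorrelation of GLM residuals
#'
#' Single AR(1) coefficient pooled over voxels:
#' sum over voxels of \eqn{\sum_t e_t e_{t-1}} divided by the pooled sum of
#' squares \eqn{\sum_t e_t^2}.
#'
#' @param residuals scans x voxels matrix (or a `glm_fit`).
#' @return Scalar in (-1, 1).
#' @export
estimate_ar1 <- function(residuals) {
  if (inherits(residuals, "glm_fit")) residuals <- residuals$residuals
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  if (n < 3) stop("need at least 3 scans")
  den <- sum(residuals^2)
  if (den == 0) stop("residuals are identically zero")
  sum(residuals[-1, , drop = FALSE] * residuals[-n, , drop = FALSE]) / den
}

#' Contrast selecting the condition regressors
#'
#' Rows of the identity picking out the DS, PS and DN columns of a design —
#' the F-contrast spanning the space of interest.
#'
#' @param design A `design_matrix`.
#' @return A 3 x p contrast matrix with column names matching the design.
#' @export
condition_contrast <- function(design) {
  p <- ncol(design$values)
  C <- matrix(0, length(design$conditions), p,
              dimnames = list(design$conditions, colnames(design$values)))
  for (cn in design$conditions) C[cn, cn] <- 1
  C
}

#' Voxelwise F statistic for a contrast
#'
#' Standard extra-sum-of-squares F test of `contrast %*% beta = 0` at every
#' voxel, with (rank(contrast), dof) degrees of freedom.
#'
#' @param fit A `glm_fit`.
#' @param design The `design_matrix` the fit used.
#' @param contrast Contrast matrix, rows x regressors.
#' @return Numeric vector of F values (one per voxel), with attributes
#'   `df1` and `df2`.
#' @export
f_statistic_map <- function(fit, design, contrast) {
  C <- as.matrix(contrast)
  X <- design$values
  if (ncol(C) != ncol(X))
    stop("contrast column count must match the design")
  r <- qr(C)$rank
  if (r < 1) stop("contrast matrix has rank zero")
  XtX_inv <- chol2inv(chol(crossprod(X)))
  CB <- C %*% fit$betas
  M <- C %*% XtX_inv %*% t(C)
  quad <- colSums(CB * solve(M, CB))
  s2 <- colSums(fit$residuals^2) / fit$dof
  f <- (quad / r) / s2
  attr(f, "df1") <- r
  attr(f, "df2") <- fit$dof
  f
}
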