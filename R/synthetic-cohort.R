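#' Configuration for a synthetic cohort
#'
#' Bundles every knob of the synthetic-cohort generator with defaults that
#' emulate the study conditions: two diagnostic groups of 16 (schizophrenia)
#' and 14 (depression) subjects, a 3-condition block paradigm (four 32 s
#' active blocks per condition, 20 s rests, 40 s lead-in/lead-out; 704 s at
#' TR = 2 s, i.e. 352 scans), AR(1) temporal noise, a cosine drift, and
#' group-dependent amplitude differences confined to configurable component
#' ranks.
#'
#' Components are planted as exact singular components of the design-data
#' cross-covariance the individual MLM estimates: component k pairs a fixed
#' condition-space direction (the k-th right singular vector of the whitened
#' design geometry) with a unit-norm spatial map, scaled by a per-subject
#' amplitude `component_amplitudes[k] + jitter`. `group_effect` plants a
#' between-group amplitude difference on a component rank (default: +30 on
#' rank 3, schizophrenia minus depression), so the effect is confined to
#' that component by construction. Ages are drawn from group normals (means
#' 36.4 and 45.3 years, SD 12.5) truncated to 18-65; sex counts are exactly
#' 10M/6F and 5M/9F.
#'
#' @param n_per_group Named subject counts (schizophrenia, depression).
#' @param grid Voxel grid dimensions (all >= 4).
#' @param tr Repetition time in seconds.
#' @param blocks_per_condition,statement_duration,statements_per_block,rest_duration,order,lead_in,lead_out
#'   Paradigm parameters, see [build_paradigm()].
#' @param rho AR(1) noise coefficient in `[0, 1)`.
#' @param noise_sd Marginal standard deviation of the BOLD noise (>= 0).
#' @param drift_amplitude,drift_period Cosine drift amplitude and period (s).
#' @param component_amplitudes Base amplitudes of the three planted
#'   components, descending (they become the expected eigenvalue order).
#' @param subject_amp_sd SD of the per-subject amplitude jitter.
#' @param group_effect Named numeric vector: names are component ranks
#'   ("1".."3"), values the schizophrenia-minus-depression amplitude
#'   difference planted on that component. Empty vector for a null cohort.
#' @param n_blobs Gaussian blobs per component spatial map.
#' @param age_mean,age_sd,age_range Age sampling parameters per group.
#' @param sex_counts 2 x 2 matrix of exact per-group M/F counts.
#' @param seed Integer seed; together with the config it fully determines
#'   every generated byte.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(schizophrenia = 16, depression = 14),
                          grid = c(16, 16, 8),
                          tr = 2,
                          blocks_per_condition = 4,
                          statement_duration = 8,
                          statements_per_block = 4,
                          rest_duration = 20,
                          order = c("DS", "DN", "PS"),
                          lead_in = 40, lead_out = 40,
                          rho = 0.3,
                          noise_sd = 1,
                          drift_amplitude = 1,
                          drift_period = 128,
                          component_amplitudes = c(150, 100, 50),
                          subject_amp_sd = 10,
                          group_effect = c("3" = 30),
                          n_blobs = 3,
                          age_mean = c(schizophrenia = 36.4, depression = 45.3),
                          age_sd = 12.5,
                          age_range = c(18, 65),
                          sex_counts = rbind(schizophrenia = c(M = 10, F = 6),
                                             depression = c(M = 5, F = 9)),
                          seed = 1) {
  if (length(n_per_group) != 2 || any(n_per_group < 2))
    stop("`n_per_group` must give two groups of at least 2 subjects")
  if (length(grid) != 3 || any(grid < 4))
    stop("`grid` must be three dimensions, each >= 4")
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (tr <= 0) stop("`tr` must be positive")
  if (length(component_amplitudes) != 3 || any(component_amplitudes <= 0) ||
      is.unsorted(rev(component_amplitudes)))
    stop("`component_amplitudes` must be 3 positive values, descending")
  if (length(group_effect) &&
      !all(names(group_effect) %in% as.character(1:3)))
    stop("`group_effect` names must be component ranks 1..3")
  structure(list(
    n_per_group = n_per_group, grid = grid, tr = tr,
    blocks_per_condition = blocks_per_condition,
    statement_duration = statement_duration,
    statements_per_block = statements_per_block,
    rest_duration = rest_duration, order = order,
    lead_in = lead_in, lead_out = lead_out,
    rho = rho, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, drift_period = drift_period,
    component_amplitudes = component_amplitudes,
    subject_amp_sd = subject_amp_sd,
    group_effect = group_effect, n_blobs = n_blobs,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    sex_counts = sex_counts, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Paradigm implied by a cohort configuration
#'
#' @param config A `cohort_config`.
#' @return A `paradigm` object (see [build_paradigm()]).
#' @export
paradigm_from_config <- function(config) {
  build_paradigm(blocks_per_condition = config$blocks_per_condition,
                 statement_duration = config$statement_duration,
                 statements_per_block = config$statements_per_block,
                 rest_duration = config$rest_duration,
                 order = config$order,
                 lead_in = config$lead_in, lead_out = config$lead_out)
}

# deterministic sub-seed, kept below 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 104729) %% 2147483647)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# smooth unit-norm spatial map per component: seeded Gaussian blobs confined
# to disjoint z slabs, so the three maps are exactly orthogonal
component_maps <- function(config) {
  grid <- config$grid
  nvox <- prod(grid)
  coords <- cbind(
    x = rep(seq_len(grid[1]), times = grid[2] * grid[3]),
    y = rep(rep(seq_len(grid[2]), each = grid[1]), times = grid[3]),
    z = rep(seq_len(grid[3]), each = grid[1] * grid[2]))
  slab <- split(seq_len(grid[3]), cut(seq_len(grid[3]), 3, labels = FALSE))
  maps <- matrix(0, 3, nvox)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 1))
  for (k in 1:3) {
    zs <- slab[[k]]
    m <- numeric(nvox)
    for (b in seq_len(config$n_blobs)) {
      centre <- c(stats::runif(1, 2, grid[1] - 1),
                  stats::runif(1, 2, grid[2] - 1),
                  stats::runif(1, min(zs), max(zs)))
      width <- stats::runif(1, 1.2, 2.2)
      d2 <- (coords[, 1] - centre[1])^2 + (coords[, 2] - centre[2])^2 +
        (coords[, 3] - centre[3])^2
      m <- m + exp(-d2 / (2 * width^2))
    }
    m[!(coords[, 3] %in% zs)] <- 0
    maps[k, ] <- m / sqrt(sum(m^2))
  }
  maps
}

# whitened design geometry the individual MLM will see: condition regressors
# adjusted for the nuisance set (motion + drift + intercept; motion columns
# per subject when supplied), whitened with the true rho, and decomposed so
# planted components are exact singular components of
# T = (Xc' Sigma Xc)^(-1/2) (Xc' Xc)
design_geometry <- function(config, motion = NULL) {
  paradigm <- paradigm_from_config(config)
  n_scans <- as.integer(ceiling(paradigm$total_duration / config$tr))
  if (is.null(motion)) motion <- matrix(0, n_scans, 6)
  design <- build_design_matrix(
    paradigm, config$tr, n_scans, motion,
    drift_period = if (config$drift_amplitude != 0) config$drift_period else NULL)
  X <- design$values
  cond_idx <- match(condition_names, colnames(X))
  Xc <- X[, cond_idx, drop = FALSE]
  Xn <- X[, setdiff(which(colSums(abs(X)) > 0), cond_idx), drop = FALSE]
  Xc_adj <- qr.resid(qr(Xn), Xc)
  Sig <- ar1_covariance(n_scans, config$rho)
  W <- inverse_sqrt_psd(crossprod(Xc_adj, Sig %*% Xc_adj))
  T_mat <- W %*% crossprod(Xc_adj)
  sv <- svd(T_mat)
  # fix the SVD sign indeterminacy with the same convention the analysis
  # uses for U, so planted components carry consistent signs across subjects
  cs <- canonicalize_svd(sv$u, sv$d, sv$v)
  P <- cs$u; S <- cs$d; Q <- cs$v
  if (!is.null(motion) && any(motion != 0)) {
    # condition symmetry of the block design makes the two leading singular
    # values nearly degenerate, so each subject's SVD basis is arbitrary
    # within that plane; rotate it (orthogonal Procrustes, applied jointly
    # to P and Q so T is preserved up to the degeneracy gap) onto the
    # motion-free reference basis to keep planted directions consistent
    # across subjects
    ref <- design_geometry(config, motion = NULL)
    pr <- svd(crossprod(Q, ref$Q))
    R <- pr$u %*% t(pr$v)
    Q <- Q %*% R; P <- P %*% R
  }
  list(paradigm = paradigm, n_scans = n_scans,
       times = (seq_len(n_scans) - 1) * config$tr,
       Xc = Xc, P = P, S = S, Q = Q)
}

#' Ground-truth group difference map
#'
#' The voxelwise between-group difference in planted component images
#' implied by `group_effect`: the sum over planted ranks of the amplitude
#' difference times that rank's spatial map. Zero everywhere when no effect
#' is planted.
#'
#' @param config A `cohort_config`.
#' @return Voxel vector (length `prod(grid)`).
#' @export
group_difference_map <- function(config) {
  maps <- component_maps(config)
  out <- numeric(prod(config$grid))
  for (rn in names(config$group_effect))
    out <- out + config$group_effect[[rn]] * maps[as.integer(rn), ]
  out
}

#' Simulate one subject's BOLD run
#'
#' Realizes the generative model the analysis assumes:
#' `Y = Xc B + drift + AR(1) noise`. The coefficient matrix `B` superposes
#' three planted components, each a condition-space direction times a shared
#' unit-norm spatial map scaled by the subject's component amplitude; the
#' configured group effect adds half the amplitude difference to
#' schizophrenia subjects and subtracts it from depression subjects on the
#' affected component. Motion parameters are smooth low-amplitude random
#' walks and enter only as nuisance regressors, never the signal.
#'
#' @param config A `cohort_config`.
#' @param subject_index Integer subject index (determines the RNG stream).
#' @param group_label `"schizophrenia"` or `"depression"`.
#' @param seed Base seed (default `config$seed`).
#' @return List: `bold` (a `bold_matrix`), `motion` (scans x 6 matrix),
#'   `truth` (list with per-component `amplitudes`, the coefficient matrix
#'   `betas` (conditions x voxels), and `group`).
#' @export
simulate_subject <- function(config, subject_index, group_label,
                             seed = config$seed) {
  if (!group_label %in% c("schizophrenia", "depression"))
    stop("invalid group label: ", group_label)
  maps <- component_maps(config)
  paradigm <- paradigm_from_config(config)
  n_scans <- as.integer(ceiling(paradigm$total_duration / config$tr))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 100 + subject_index))

  a <- config$component_amplitudes +
    stats::rnorm(3, 0, config$subject_amp_sd)
  for (rn in names(config$group_effect)) {
    delta <- config$group_effect[[rn]]
    r <- as.integer(rn)
    a[r] <- a[r] + if (group_label == "schizophrenia") delta / 2 else -delta / 2
  }

  motion <- sapply(1:6, function(j)
    cumsum(stats::rnorm(n_scans, 0, 0.005)))
  # per-subject geometry: this subject's motion is part of the nuisance set
  # the analysis will partial out
  geom <- design_geometry(config, motion = motion)

  # B = Q diag(a / s) M  =>  Z = T B = P diag(a) M exactly
  B <- geom$Q %*% ((a / geom$S) * maps)
  Y <- geom$Xc %*% B
  if (config$drift_amplitude != 0)
    Y <- Y + config$drift_amplitude *
      cos(2 * pi * geom$times / config$drift_period)
  if (config$noise_sd > 0) {
    nvox <- prod(config$grid)
    e <- matrix(stats::rnorm(geom$n_scans * nvox), geom$n_scans, nvox)
    if (config$rho > 0) {
      e <- e * (config$noise_sd * sqrt(1 - config$rho^2))
      e[1, ] <- stats::rnorm(nvox, 0, config$noise_sd)
      for (t in 2:geom$n_scans) e[t, ] <- e[t, ] + config$rho * e[t - 1, ]
    } else {
      e <- e * config$noise_sd
    }
    Y <- Y + e
  }

  mask <- array(TRUE, dim = config$grid)
  affine <- diag(c(3, 3, 3, 1))
  rownames(B) <- condition_names
  list(bold = bold_matrix(Y, mask, affine),
       motion = motion,
       truth = list(amplitudes = a, betas = B, group = group_label))
}

#' Simulate a full synthetic cohort
#'
#' Generates every subject (BOLD, motion, ground truth) plus demographics:
#' exact per-group sex counts and truncated-normal ages. With `dir = NULL`
#' (default) everything is returned in memory; with a directory, NIfTI
#' volumes (`sub-XX_bold.nii.gz`), a shared `mask.nii.gz`, SPM-style
#' `rp_sub-XX.txt` motion files, a BIDS-style `participants.tsv` manifest
#' and `ground_truth.json` are written.
#'
#' @param config A `cohort_config`.
#' @param dir Output directory, or `NULL` for in-memory.
#' @param overwrite Overwrite an existing non-empty output directory.
#' @return Object of class `synthetic_cohort`: list with `manifest`
#'   (data.frame: subject_id, group, age, sex, plus file paths when
#'   written), `subjects` (per-subject `bold`/`motion`/`truth`), `truth`
#'   (component maps, planted clinical directions, amplitude matrix, group
#'   difference map, rho, seed), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), dir = NULL,
                            overwrite = FALSE) {
  groups <- rep(names(config$n_per_group), config$n_per_group)
  s <- length(groups)
  ids <- sprintf("sub-%02d", seq_len(s))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 2))
  age <- numeric(s); sex <- character(s)
  for (g in names(config$n_per_group)) {
    idx <- which(groups == g)
    a <- numeric(length(idx))
    for (i in seq_along(a)) {
      repeat {
        draw <- stats::rnorm(1, config$age_mean[[g]], config$age_sd)
        if (draw >= config$age_range[1] && draw <= config$age_range[2]) break
      }
      a[i] <- draw
    }
    age[idx] <- round(a, 1)
    sx <- rep(colnames(config$sex_counts), config$sex_counts[g, ])
    sex[idx] <- sample(sx)
  }
  .Random.seed_restore(old)

  subjects <- lapply(seq_len(s), function(i)
    simulate_subject(config, i, groups[i], seed = config$seed))

  amp <- t(vapply(subjects, function(su) su$truth$amplitudes, numeric(3)))
  rownames(amp) <- ids
  colnames(amp) <- paste0("rank", 1:3)
  geom <- design_geometry(config)
  maps <- component_maps(config)
  delta <- numeric(3)
  if (length(config$group_effect))
    delta[as.integer(names(config$group_effect))] <-
      unlist(config$group_effect)
  truth <- list(component_maps = maps,
                clinical_directions = geom$P,
                amplitudes = amp,
                groups = groups,
                group_difference_map = group_difference_map(config),
                # expected schizophrenia-minus-depression GLM beta difference
                beta_difference = geom$Q %*% ((delta / geom$S) * maps),
                rho = config$rho,
                seed = config$seed)
  manifest <- data.frame(subject_id = ids, group = groups,
                         age = age, sex = sex, stringsAsFactors = FALSE)
  out <- structure(list(manifest = manifest, subjects = subjects,
                        truth = truth, config = config),
                   class = "synthetic_cohort")
  if (!is.null(dir)) out <- write_cohort(out, dir, overwrite = overwrite)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%s), grid %s, seed %d\n",
              nrow(x$manifest),
              paste(table(x$manifest$group)[unique(x$manifest$group)],
                    collapse = "/"),
              paste(x$config$grid, collapse = "x"), x$config$seed))
  invisible(x)
}

# write a simulated cohort to disk in the package's file dialect
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- cohort$config
  mask <- array(TRUE, dim = config$grid)
  affine <- diag(c(3, 3, 3, 1))
  mask_path <- file.path(dir, "mask.nii.gz")
  write_volume(as.numeric(mask), mask, affine, mask_path)
  man <- cohort$manifest
  man$bold <- file.path(dir, paste0(man$subject_id, "_bold.nii.gz"))
  man$motion <- file.path(dir, paste0("rp_", man$subject_id, ".txt"))
  man$mask <- mask_path
  for (i in seq_len(nrow(man))) {
    su <- cohort$subjects[[i]]
    write_volume(su$bold$values, mask, affine, man$bold[i], tr = config$tr)
    utils::write.table(format(su$motion, digits = 10), man$motion[i],
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  man_rel <- man
  for (pc in c("bold", "motion", "mask")) man_rel[[pc]] <- basename(man[[pc]])
  utils::write.table(man_rel, file.path(dir, "participants.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(groups = cohort$truth$groups,
         amplitudes = cohort$truth$amplitudes,
         group_difference_map = cohort$truth$group_difference_map,
         rho = cohort$truth$rho, seed = cohort$truth$seed),
    file.path(dir, "ground_truth.json"),
    digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  cohort$manifest <- man
  cohort$dir <- dir
  cohort
}
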