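#' Run the full two-level MLM analysis on a cohort in memory
#'
#' Executes, for every subject, design construction, the voxelwise GLM with
#' pooled AR(1) estimation, and the individual MLM; aligns component signs
#' to the first subject; then, for each component rank, stacks the
#' eigenimages, removes age/sex confounds, runs the group MLM, computes the
#' signature T map, and classifies diagnosis from the subject loadings by
#' LDA under repeated stratified k-fold cross-validation.
#'
#' @param cohort A `synthetic_cohort` (from [simulate_cohort()]) or a list
#'   with elements `subjects` (each holding `bold` and `motion`) and
#'   `manifest` (data.frame with subject_id, group, age, sex).
#' @param paradigm A `paradigm`; defaults to the cohort config's paradigm
#'   when available, else [build_paradigm()] defaults.
#' @param tr Repetition time (defaults to the cohort config's, else 2).
#' @param sigma Temporal covariance form for the individual MLM
#'   (`"ar1"` or `"identity"`).
#' @param n_components Components per subject (default 3).
#' @param drift_period Cosine drift regressor period in seconds for the
#'   design, or `NULL` for none. Defaults to the cohort config's
#'   `drift_period` when the generating model includes a drift.
#' @param k,repeats Cross-validation folds and repeats (defaults 2 and 100).
#' @param seed Classification seed (per-rank seeds are derived from it).
#' @param p_threshold One-sided uncorrected p for the T-map masks.
#' @return Object of class `mlm_pipeline_result`: `individual` (aligned
#'   decompositions), `groups`, `tmaps`, `classification` (one
#'   `classification_result` per rank), `weighted_clinical_loadings`,
#'   `rho` (per-subject AR(1) estimates), `f_maps`, `manifest`, `seed`.
#' @export
analyze_cohort <- function(cohort, paradigm = NULL, tr = NULL,
                           sigma = c("ar1", "identity"),
                           n_components = 3, drift_period = NULL,
                           k = 2, repeats = 100, seed = 1,
                           p_threshold = 0.05) {
  sigma <- match.arg(sigma)
  manifest <- cohort$manifest
  subjects <- cohort$subjects
  stopifnot(length(subjects) == nrow(manifest))
  cfg <- cohort$config
  if (is.null(tr)) tr <- if (!is.null(cfg)) cfg$tr else 2
  if (is.null(paradigm))
    paradigm <- if (!is.null(cfg)) paradigm_from_config(cfg)
  else build_paradigm()
  if (is.null(drift_period) && !is.null(cfg) && cfg$drift_amplitude != 0)
    drift_period <- cfg$drift_period

  decomps <- vector("list", length(subjects))
  rho <- numeric(length(subjects))
  f_maps <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    su <- subjects[[i]]
    n_scans <- nrow(su$bold$values)
    design <- build_design_matrix(paradigm, tr, n_scans, su$motion,
                                  drift_period = drift_period)
    fit <- fit_glm(su$bold, design)
    rho[i] <- estimate_ar1(fit)
    f_maps[[i]] <- f_statistic_map(fit, design, condition_contrast(design))
    decomps[[i]] <- individual_mlm(su$bold, design, sigma = sigma,
                                   rho = if (sigma == "ar1") rho[i] else NULL,
                                   n_components = n_components)
  }
  aligned <- align_decompositions(decomps, reference_index = 1)

  gdes <- group_design(manifest)
  groups <- vector("list", n_components)
  tmaps <- vector("list", n_components)
  classification <- vector("list", n_components)
  for (r in seq_len(n_components)) {
    st <- stack_eigenimages(aligned, r, weighting = "eigenvalue")
    rc <- residualize_confounds(st, gdes)
    gd <- group_mlm(rc$stack, rc$design)
    groups[[r]] <- gd
    tmaps[[r]] <- signature_tmap(rc$stack, gd$subject_loadings,
                                 p = p_threshold)
    # features are re-derived inside every training fold: the group signature
    # is estimated from training subjects only and held-out subjects are
    # projected onto it, so their loadings never reflect their own data
    Yadj <- rc$stack$values; Xred <- rc$design$values
    extractor <- local({
      Yadj <- Yadj; Xred <- Xred; st <- rc$stack; labs <- manifest$group
      function(tr, te) {
        st_tr <- st; st_tr$values <- Yadj[tr, , drop = FALSE]
        des_tr <- structure(list(values = Xred[tr, , drop = FALSE],
                                 group_labels = labs[tr]),
                            class = "group_design")
        sig <- group_mlm(st_tr, des_tr)$signature
        list(train = Yadj[tr, , drop = FALSE] %*% sig,
             test = Yadj[te, , drop = FALSE] %*% sig)
      }
    })
    classification[[r]] <- repeated_kfold_accuracy(
      extractor, manifest$group, k = k, repeats = repeats,
      seed = derive_seed(seed, 300 + r))
  }
  structure(list(
    individual = aligned, groups = groups, tmaps = tmaps,
    classification = classification,
    weighted_clinical_loadings = weighted_clinical_loadings(aligned, groups),
    rho = rho, f_maps = f_maps, manifest = manifest, seed = seed
  ), class = "mlm_pipeline_result")
}

#' @export
print.mlm_pipeline_result <- function(x, ...) {
  cat(sprintf("two-level MLM pipeline: %d subjects, %d components\n",
              nrow(x$manifest), length(x$groups)))
  for (r in seq_along(x$classification)) {
    cr <- x$classification[[r]]
    cat(sprintf("  signature %d: median CV accuracy %.3f [%.3f, %.3f], AUC %.3f\n",
                r, cr$median, cr$q25, cr$q75, cr$auc))
  }
  invisible(x)
}

#' Run the file-based pipeline
#'
#' Loads a `participants.tsv` manifest with bold/motion/mask path columns,
#' runs [analyze_cohort()], and writes all artifacts: per-rank signature and
#' T-map NIfTI volumes, subject-loading tables, classification JSONs, the
#' weighted clinical loadings, and a provenance record.
#'
#' @param manifest Path to a manifest file or a data.frame from
#'   [read_manifest()].
#' @param out_dir Output directory (created; must be empty unless
#'   `overwrite`).
#' @param overwrite Allow writing into a non-empty directory.
#' @param ... Passed to [analyze_cohort()] (paradigm, tr, sigma, k,
#'   repeats, seed, ...).
#' @return The `mlm_pipeline_result`, invisibly, with an `out_dir` field.
#' @export
run_pipeline <- function(manifest, out_dir, overwrite = FALSE, ...) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  need <- c("bold", "motion", "mask")
  if (!all(need %in% names(manifest)))
    stop("manifest needs bold, motion and mask path columns")
  subjects <- lapply(seq_len(nrow(manifest)), function(i)
    list(bold = read_bold(manifest$bold[i], manifest$mask[i]),
         motion = read_motion(manifest$motion[i])))
  res <- analyze_cohort(list(subjects = subjects, manifest = manifest), ...)

  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mask <- subjects[[1]]$bold$mask
  affine <- subjects[[1]]$bold$affine
  files <- character(0)
  for (r in seq_along(res$groups)) {
    gd <- res$groups[[r]]
    f_sig <- file.path(out_dir, sprintf("signature_rank%d.nii.gz", r))
    write_volume(gd$signature, mask, affine, f_sig)
    f_t <- file.path(out_dir, sprintf("tmap_rank%d.nii.gz", r))
    write_volume(res$tmaps[[r]]$tvalues, mask, affine, f_t)
    f_load <- file.path(out_dir, sprintf("subject_loadings_rank%d.tsv", r))
    utils::write.table(
      data.frame(subject_id = manifest$subject_id, group = manifest$group,
                 loading = gd$subject_loadings,
                 design_projection = gd$design_projection),
      f_load, sep = "\t", row.names = FALSE, quote = FALSE)
    cr <- res$classification[[r]]
    f_clf <- file.path(out_dir, sprintf("classification_rank%d.json", r))
    jsonlite::write_json(
      list(rank = r, accuracies = cr$accuracies, median = cr$median,
           q25 = cr$q25, q75 = cr$q75, auc = cr$auc,
           auc_insample = cr$auc_insample, roc = cr$roc,
           positive_label = cr$positive_label, k = cr$k,
           repeats = cr$repeats, seed = cr$seed),
      f_clf, digits = NA, auto_unbox = TRUE, dataframe = "columns")
    files <- c(files, f_sig, f_t, f_load, f_clf)
  }
  f_wcl <- file.path(out_dir, "weighted_clinical_loadings.tsv")
  utils::write.table(
    data.frame(condition = rownames(res$weighted_clinical_loadings),
               res$weighted_clinical_loadings),
    f_wcl, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f_wcl)

  cfg_json <- jsonlite::toJSON(list(seed = res$seed,
                                    n_components = length(res$groups)),
                               auto_unbox = TRUE, digits = NA)
  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(package = "mlmfmri",
         version = as.character(utils::packageVersion("mlmfmri")),
         seed = res$seed,
         config = jsonlite::fromJSON(cfg_json),
         config_hash = sum(utf8ToInt(as.character(cfg_json))),
         rho = res$rho,
         files = basename(files)),
    prov, digits = NA, auto_unbox = TRUE)
  res$out_dir <- out_dir
  invisible(res)
}
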