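#' Masked BOLD data matrix
#'
#' Container pairing the scans x voxels data matrix with the voxel-to-volume
#' mapping. Voxels are the in-mask voxels in R's column-major (x fastest,
#' then y, then z) flattening order, so the matrix round-trips losslessly to
#' and from volumes.
#'
#' @param values Scans x voxels numeric matrix.
#' @param mask Logical 3D array; `sum(mask)` must equal `ncol(values)`.
#' @param affine 4 x 4 voxel-to-world transform.
#' @return Object of class `bold_matrix`.
#' @export
bold_matrix <- function(values, mask, affine = diag(4)) {
  values <- as.matrix(values)
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (sum(mask) == 0) stop("mask contains no voxels")
  if (ncol(values) != sum(mask))
    stop("`values` columns must equal the number of in-mask voxels")
  if (any(!is.finite(values)))
    stop(sum(!is.finite(values)), " non-finite voxel values")
  structure(list(values = values, mask = mask,
                 affine = as.matrix(affine)),
            class = "bold_matrix")
}

#' @export
print.bold_matrix <- function(x, ...) {
  cat(sprintf("bold_matrix: %d scans x %d voxels (grid %s)\n",
              nrow(x$values), ncol(x$values),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

# accept a bold_matrix or a bare matrix wherever time x voxel data is needed
bold_values <- function(x) {
  if (inherits(x, "bold_matrix")) x$values else as.matrix(x)
}

#' Read a 4D BOLD NIfTI into a masked data matrix
#'
#' @param bold_path Path to a 4D NIfTI-1 file.
#' @param mask_path Path to a 3D NIfTI-1 mask on the same grid (voxels > 0.5
#'   are in-mask).
#' @return A [bold_matrix()].
#' @export
read_bold <- function(bold_path, mask_path) {
  img <- RNifti::readNifti(bold_path)
  msk <- RNifti::readNifti(mask_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4) stop("BOLD file must be 3D or 4D")
  grid <- dim(arr)[1:3]
  if (!identical(dim(as.array(msk))[1:3], grid))
    stop("mask grid does not match BOLD grid")
  a_img <- unclass(RNifti::xform(img)); a_msk <- unclass(RNifti::xform(msk))
  if (max(abs(a_img - a_msk)) > 1e-4)
    stop("mask affine does not match BOLD affine")
  mask <- array(as.array(msk) > 0.5, dim = grid)
  if (sum(mask) == 0) stop("mask contains no voxels")
  flat <- matrix(arr, prod(grid), dim(arr)[4])
  values <- t(flat[c(mask), , drop = FALSE])
  bad <- sum(!is.finite(values))
  if (bad > 0) stop(bad, " non-finite voxel values in ", bold_path)
  affine <- rbind(a_img, c(0, 0, 0, 1))[1:4, 1:4]
  bold_matrix(values, mask, affine)
}

#' Write voxel data back into a NIfTI volume
#'
#' The inverse of [read_bold()]'s masking: a voxel vector becomes a 3D
#' volume, a k x voxels matrix a 4D series, with zeros outside the mask and
#' the affine stored in the qform (bit-exact round trip).
#'
#' @param values Voxel vector or k x voxels matrix (in-mask voxels, column-
#'   major order).
#' @param mask Logical 3D array.
#' @param affine 4 x 4 voxel-to-world transform.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param tr Repetition time stored in the 4th pixdim for 4D output.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, mask, affine, path, tr = 1) {
  grid <- dim(mask)
  mask <- array(as.logical(mask), dim = grid)
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) != sum(mask))
    stop("`values` columns must equal the number of in-mask voxels")
  k <- nrow(values)
  arr <- array(0, dim = c(grid, k))
  flat <- matrix(0, prod(grid), k)
  flat[c(mask), ] <- t(values)
  arr <- array(flat, dim = c(grid, k))
  if (k == 1) dim(arr) <- grid
  img <- RNifti::asNifti(arr)
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- if (k == 1) pd else c(pd, tr)
  img <- RNifti::`qform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort manifest (participants.tsv)
#'
#' @param path Tab-separated manifest with columns subject_id, group, age,
#'   sex and (for file-based pipelines) bold, motion, mask path columns.
#' @param check_paths Verify that referenced files exist (default TRUE when
#'   path columns are present).
#' @return Data frame.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  missing_c <- setdiff(need, names(man))
  if (length(missing_c))
    stop("manifest lacks columns: ", paste(missing_c, collapse = ", "))
  if (anyDuplicated(man$subject_id)) stop("duplicate subject_ids")
  if (!all(man$group %in% c("schizophrenia", "depression")))
    stop("unknown group labels in manifest")
  if (any(man$age < 18 | man$age > 65))
    stop("ages outside the 18-65 inclusion range")
  pathcols <- intersect(c("bold", "motion", "mask"), names(man))
  base <- dirname(path)
  for (pc in pathcols) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[pc]])
    man[[pc]][rel] <- file.path(base, man[[pc]][rel])
    if (check_paths) {
      gone <- !file.exists(man[[pc]])
      if (any(gone))
        stop("missing ", pc, " files: ",
             paste(man[[pc]][gone], collapse = ", "))
    }
  }
  man
}

#' Read an SPM-style motion parameter file
#'
#' @param path Whitespace-delimited text file with six columns (three
#'   translations, three rotations).
#' @return Scans x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion file must have 6 columns")
  dimnames(m) <- NULL
  m
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Pearson statistic without continuity correction,
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`, with the p-value from the chi-square
#' distribution on 1 degree of freedom — the form that reproduces the
#' printed sex-distribution comparison (10/6 vs 5/9, p = 0.143).
#'
#' @param table 2 x 2 matrix of non-negative counts with positive margins.
#' @return List: `statistic`, `p_value`, `df` (= 1).
#' @export
chi_square_2x2 <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2, 2))) stop("need a 2 x 2 table")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("all margins must be positive")
  n <- sum(x)
  stat <- n * (x[1, 1] * x[2, 2] - x[1, 2] * x[2, 1])^2 /
    prod(rowSums(x)) / prod(colSums(x))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1)
}
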