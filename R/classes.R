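#' Masked 4D BOLD time series
#'
#' Container for a single subject's resting-state BOLD acquisition: a 4D
#' array (x, y, z, t), a 3D brain mask, voxel geometry, and the repetition
#' time. All preprocessing and connectivity operations read and write only
#' in-mask voxels; outside-mask values are carried through untouched.
#'
#' @param data Numeric 4D array (x, y, z, t).
#' @param mask Logical 3D array with the same spatial dimensions as `data`.
#'   Defaults to all-`TRUE`.
#' @param voxel_size_mm Numeric length-3 voxel edge lengths in mm.
#' @param tr_s Repetition time in seconds.
#' @param subject Subject identifier.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, mask = NULL, voxel_size_mm = c(0.23, 0.23, 0.6),
                        tr_s = 1, subject = "subject") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  dims <- dim(data)
  if (dims[4] < 2L) stop("need at least 2 timepoints")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  if (!identical(dim(mask), dims[1:3]))
    stop("mask dimensions must match the spatial dimensions of `data`")
  mask <- array(as.logical(mask), dims[1:3])
  if (!any(mask)) stop("mask is empty")
  vals <- data[rep(mask, dims[4])]
  if (any(!is.finite(vals))) stop("non-finite values inside mask")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0), tr_s > 0)
  structure(
    list(data = data, mask = mask, voxel_size_mm = as.numeric(voxel_size_mm),
         tr_s = as.numeric(tr_s), subject = as.character(subject),
         provenance = character(0)),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %s: %dx%dx%d voxels x %d frames, TR %gs, %d in mask\n",
              x$subject, d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

n_timepoints <- function(b) dim(b$data)[4]

# t x V matrix of in-mask voxel time courses (column order = which(mask))
mask_matrix <- function(b) {
  d <- dim(b$data)
  m <- matrix(b$data, prod(d[1:3]), d[4])
  t(m[as.vector(b$mask), , drop = FALSE])
}

# write a t x V matrix back into the in-mask voxels of a bold_series
set_mask_matrix <- function(b, tc) {
  d <- dim(b$data)
  m <- matrix(b$data, prod(d[1:3]), d[4])
  m[as.vector(b$mask), ] <- t(tc)
  b$data <- array(m, d)
  b
}

record_step <- function(b, step) {
  b$provenance <- c(b$provenance, step)
  b
}

#' Per-subject nuisance regressor set
#'
#' Six rigid-body motion traces (three translations, three rotations) and the
#' mean ventricular BOLD signal, each of length t.
#'
#' @param motion Numeric t x 6 matrix (columns tx, ty, tz, rx, ry, rz).
#' @param ventricular Numeric vector of length t.
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(motion, ventricular) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns")
  if (nrow(motion) != length(ventricular))
    stop("motion and ventricular traces must have equal length")
  if (any(!is.finite(motion)) || any(!is.finite(ventricular)))
    stop("non-finite nuisance values")
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(motion = motion, ventricular = as.numeric(ventricular)),
            class = "nuisance_set")
}

#' Per-subject 3D connectivity map
#'
#' @param map Numeric 3D array; `NaN` outside the mask.
#' @param kind One of `"global"`, `"local"`, `"seed"`.
#' @param mask Logical 3D array.
#' @param subject Subject identifier.
#' @param provenance List of parameters that produced the map (radius, seed).
#' @return An object of class `connectivity_map`.
#' @export
connectivity_map <- function(map, kind, mask, subject = "subject",
                             provenance = list()) {
  kind <- match.arg(kind, c("global", "local", "seed"))
  if (!identical(dim(map), dim(mask))) stop("map/mask dimension mismatch")
  structure(list(map = map, kind = kind, mask = array(as.logical(mask), dim(mask)),
                 subject = subject, provenance = provenance),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  v <- x$map[x$mask]
  cat(sprintf("<connectivity_map> %s (%s): %d in-mask voxels, %d NaN, mean %.4f\n",
              x$subject, x$kind, length(v), sum(is.nan(v)),
              mean(v, na.rm = TRUE)))
  invisible(x)
}

#' Seed region specification
#'
#' A rectangular voxel block (default 3 x 3 x 1) whose mean time course is
#' the seed signal for seed-based correlation mapping.
#'
#' @param center Integer length-3 voxel coordinates of the block center.
#' @param extent Integer length-3 block extent in voxels; default `c(3, 3, 1)`.
#' @param label Seed label.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(center, extent = c(3L, 3L, 1L), label = "seed") {
  stopifnot(length(center) == 3L, length(extent) == 3L, all(extent >= 1))
  structure(list(center = as.integer(center), extent = as.integer(extent),
                 label = as.character(label)),
            class = "seed_spec")
}

seed_voxels <- function(s, dims) {
  half_lo <- (s$extent - 1L) %/% 2L
  half_hi <- s$extent %/% 2L
  lo <- s$center - half_lo
  hi <- s$center + half_hi
  if (any(lo < 1L) || any(hi > dims))
    stop("seed block extends outside the volume")
  as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
}

#' Validate a 2x2 factorial design table
#'
#' Checks a subject-level design data frame: `subject` unique, `sex` in
#' {M, F}, `genotype` in {WT, MUT}, optional numeric covariates.
#'
#' @param design Data frame with columns `subject`, `sex`, `genotype`.
#' @param require_covariates Character vector of covariate columns that must
#'   be present and numeric.
#' @return The design with `sex`/`genotype` as factors with fixed level order
#'   (`F`/`M`, `WT`/`MUT`).
#' @export
validate_design <- function(design, require_covariates = character(0)) {
  need <- c("subject", "sex", "genotype")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$subject))
    stop("duplicate subject IDs in design")
  if (!all(design$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (!all(design$genotype %in% c("WT", "MUT")))
    stop("genotype must be 'WT' or 'MUT'")
  for (cv in require_covariates) {
    if (is.null(design[[cv]])) stop("design is missing covariate: ", cv)
    if (!is.numeric(design[[cv]])) stop("covariate not numeric: ", cv)
  }
  design$sex <- factor(design$sex, levels = c("F", "M"))
  design$genotype <- factor(design$genotype, levels = c("WT", "MUT"))
  design
}

# +/-1 effect coding: F = -1, M = +1; WT = -1, MUT = +1
effect_codes <- function(design) {
  list(sex = ifelse(design$sex == "M", 1, -1),
       genotype = ifelse(design$genotype == "MUT", 1, -1))
}
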