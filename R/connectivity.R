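#' Global connectivity (weighted degree centrality)
#'
#' For each in-mask voxel, the mean temporal correlation with every other
#' in-mask voxel: Pearson r per pair, Fisher r-to-z, averaged. Zero-variance
#' voxels are excluded from target sets and flagged `NaN` in the output.
#'
#' @param b A preprocessed [bold_series()].
#' @param average_domain Average on the `"z"` scale (default) or the raw
#'   `"r"` scale.
#' @param block Number of voxels per correlation block (memory control).
#' @return A [connectivity_map()] of kind `"global"`.
#' @export
global_connectivity <- function(b, average_domain = c("z", "r"),
                                block = 1024L) {
  stopifnot(inherits(b, "bold_series"))
  average_domain <- match.arg(average_domain)
  Z <- standardize_cols(mask_matrix(b))
  V <- ncol(Z)
  if (V < 2L) stop("need at least 2 in-mask voxels")
  valid <- !is.na(Z[1, ])
  nval <- sum(valid)
  if (nval == 0L) stop("all in-mask voxels have zero variance")
  if (nval < V)
    msg("global_connectivity: %d zero-variance voxels flagged NaN", V - nval)
  Zv <- Z[, valid, drop = FALSE]
  vals <- rep(NaN, V)
  acc <- numeric(nval)
  for (start in seq(1L, nval, by = block)) {
    idx <- start:min(start + block - 1L, nval)
    R <- crossprod(Zv, Zv[, idx, drop = FALSE])
    G <- if (average_domain == "z") fisher_z(R) else R
    # drop self-correlation from each column's sum
    acc[idx] <- colSums(G) - G[cbind(idx, seq_along(idx))]
  }
  vals[valid] <- if (nval > 1L) acc / (nval - 1L) else NaN
  map <- array(NaN, dim(b$mask))
  map[b$mask] <- vals
  connectivity_map(map, "global", b$mask, b$subject,
                   list(average_domain = average_domain))
}

# unordered voxel offsets with 0 < euclidean norm <= radius
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g <- g[rowSums(g^2) <= radius^2 & rowSums(g^2) > 0, , drop = FALSE]
  # keep one of each (d, -d) pair
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g[keep, , drop = FALSE]
}

#' Local connectivity (sphere-limited degree centrality)
#'
#' As [global_connectivity()], but each voxel's target set is restricted to
#' in-mask voxels within a Euclidean distance of `radius_vox` voxels
#' (default 6, the "six voxels in-plane" sphere). Voxels with no in-radius
#' neighbor are flagged `NaN`.
#'
#' @param b A preprocessed [bold_series()].
#' @param radius_vox Sphere radius in voxels (>= 1). A radius given in mm
#'   (`radius_mm`) is converted using the in-plane voxel size, with a
#'   warning, since printed mm values and voxel counts can disagree.
#' @param radius_mm Optional radius in mm (overrides `radius_vox`).
#' @param average_domain `"z"` (default) or `"r"`.
#' @return A [connectivity_map()] of kind `"local"`.
#' @export
local_connectivity <- function(b, radius_vox = 6, radius_mm = NULL,
                               average_domain = c("z", "r")) {
  stopifnot(inherits(b, "bold_series"))
  average_domain <- match.arg(average_domain)
  if (!is.null(radius_mm)) {
    radius_vox <- radius_mm / b$voxel_size_mm[1]
    warning(sprintf("radius %g mm converted to %.3g voxels (in-plane voxel %g mm)",
                    radius_mm, radius_vox, b$voxel_size_mm[1]))
  }
  if (radius_vox < 1) stop("radius_vox must be >= 1")
  dims <- dim(b$mask)
  V <- prod(dims)
  Zfull <- matrix(NA_real_, n_timepoints(b), V)
  Zfull[, as.vector(b$mask)] <- standardize_cols(mask_matrix(b))
  idx3 <- array(seq_len(V), dims)
  usable <- as.vector(b$mask) & !is.na(Zfull[1, ])
  nz_excl <- sum(b$mask) - sum(usable)
  if (nz_excl > 0) msg("local_connectivity: %d zero-variance voxels flagged NaN", nz_excl)

  offsets <- sphere_offsets(radius_vox)
  acc <- numeric(V)
  cnt <- integer(V)
  for (o in seq_len(nrow(offsets))) {
    d <- offsets[o, ]
    if (any(dims - abs(d) < 1)) next   # offset larger than the grid
    xa <- max(1, 1 - d[1]):min(dims[1], dims[1] - d[1])
    ya <- max(1, 1 - d[2]):min(dims[2], dims[2] - d[2])
    za <- max(1, 1 - d[3]):min(dims[3], dims[3] - d[3])
    A <- as.vector(idx3[xa, ya, za, drop = FALSE])
    B <- as.vector(idx3[xa + d[1], ya + d[2], za + d[3], drop = FALSE])
    ok <- usable[A] & usable[B]
    A <- A[ok]; B <- B[ok]
    if (!length(A)) next
    r <- colSums(Zfull[, A, drop = FALSE] * Zfull[, B, drop = FALSE])
    g <- if (average_domain == "z") fisher_z(r) else r
    acc[A] <- acc[A] + g; cnt[A] <- cnt[A] + 1L
    acc[B] <- acc[B] + g; cnt[B] <- cnt[B] + 1L
  }
  vals <- rep(NaN, V)
  has <- usable & cnt > 0L
  vals[has] <- acc[has] / cnt[has]
  map <- array(NaN, dims)
  map[b$mask] <- vals[as.vector(b$mask)]
  connectivity_map(map, "local", b$mask, b$subject,
                   list(radius_vox = radius_vox, average_domain = average_domain))
}

#' Seed-based Fisher-z connectivity map
#'
#' The seed time course is the mean over the seed block's voxels; the map is
#' the Fisher z of the Pearson correlation between the seed and every
#' in-mask voxel.
#'
#' @param b A preprocessed [bold_series()].
#' @param s A [seed_spec()]; the block must lie inside the mask.
#' @return A [connectivity_map()] of kind `"seed"`.
#' @export
seed_connectivity <- function(b, s) {
  stopifnot(inherits(b, "bold_series"), inherits(s, "seed_spec"))
  dims <- dim(b$mask)
  sv <- seed_voxels(s, dims)
  lin <- sv[, 1] + dims[1] * (sv[, 2] - 1) + dims[1] * dims[2] * (sv[, 3] - 1)
  if (!all(b$mask[lin])) stop("seed block not fully inside the mask")
  d <- dim(b$data)
  flat <- matrix(b$data, prod(d[1:3]), d[4])
  seed_tc <- colMeans(flat[lin, , drop = FALSE])
  if (stats::sd(seed_tc) == 0) stop("seed time course has zero variance")
  sstd <- (seed_tc - mean(seed_tc)) / sqrt(sum((seed_tc - mean(seed_tc))^2))
  Z <- standardize_cols(mask_matrix(b))
  r <- as.vector(crossprod(Z, sstd))
  vals <- fisher_z(r)
  vals[is.na(r)] <- NaN
  map <- array(NaN, dims)
  map[b$mask] <- vals
  connectivity_map(map, "seed", b$mask, b$subject,
                   list(seed = s$label, center = s$center, extent = s$extent))
}

#' Mean connectivity over a volume of interest
#'
#' Average of a connectivity map over the in-mask voxels of a VOI, ignoring
#' `NaN` (the ignored fraction is logged).
#'
#' @param m A [connectivity_map()].
#' @param voi_mask Logical 3D array.
#' @return Scalar mean connectivity.
#' @export
voi_score <- function(m, voi_mask) {
  stopifnot(inherits(m, "connectivity_map"),
            identical(dim(voi_mask), dim(m$mask)))
  sel <- voi_mask & m$mask
  if (!any(sel)) stop("VOI does not intersect the map mask")
  v <- m$map[sel]
  nan_frac <- mean(is.nan(v))
  if (nan_frac > 0) msg("voi_score: ignoring %.1f%% NaN voxels", 100 * nan_frac)
  if (all(is.nan(v))) stop("all VOI voxels are NaN")
  mean(v[!is.nan(v)])
}
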