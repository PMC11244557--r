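#' Specification for a synthetic rsfMRI cohort
#'
#' Defines a 2x2 sex-by-genotype cohort of 4D BOLD-like volumes with
#' spatially coherent networks and planted connectivity effects. Each network
#' is a set of voxels sharing a latent AR(1) signal; the within-network
#' pairwise correlation, on the Fisher-z scale, in cell (sex, genotype) is
#'
#'   z_cell = base_z + d_sex * I(M) + d_genotype * I(MUT) + d_interaction * I(M & MUT)
#'
#' so `d_interaction` is the extra coupling (in z units) applied to mutant
#' males only. The latent-signal loading that realizes a target z is
#' `w = noise_sd * sqrt(r / (1 - r))` with `r = tanh(z_cell)`.
#'
#' The defaults emulate the design of a typical mouse rsfMRI study: n = 10
#' animals per cell scanned at TR = 1 s for 1920 volumes, at a desk-scale
#' 16 x 16 x 8 phantom geometry.
#'
#' @param dims Integer length-3 grid dimensions in voxels.
#' @param n_timepoints Number of frames per subject.
#' @param tr_s Repetition time (s).
#' @param voxel_size_mm Voxel edge lengths (mm).
#' @param n_per_cell Subjects per design cell (>= 2).
#' @param ar1 AR(1) coefficient of latent signals and noise, |ar1| < 1.
#' @param networks Named list of integer matrices (voxels x 3) of voxel
#'   coordinates, one per network.
#' @param effects Data frame with columns `network`, `base_z`, `d_sex`,
#'   `d_genotype`, `d_interaction` (z-scale deltas; one row per network).
#' @param noise_sd SD of the voxelwise AR(1) noise.
#' @param nuisance_load Scale of the linear mixing of the 7 synthetic
#'   nuisance traces into every voxel (0 disables).
#' @param seed RNG seed; the simulation is bit-reproducible given the spec.
#' @return An object of class `fmri_sim_spec`.
#' @export
fmri_sim_spec <- function(dims = c(16L, 16L, 8L), n_timepoints = 1920L,
                          tr_s = 1, voxel_size_mm = c(0.23, 0.23, 0.6),
                          n_per_cell = 10L, ar1 = 0.4,
                          networks = list(), effects = NULL,
                          noise_sd = 1, nuisance_load = 0.2, seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), n_timepoints >= 2L,
            tr_s > 0, n_per_cell >= 2L, abs(ar1) < 1, noise_sd > 0,
            nuisance_load >= 0)
  if (is.null(effects)) {
    nn <- length(networks)
    effects <- data.frame(network = if (nn) names(networks) else character(0),
                          base_z = rep(0.3, nn), d_sex = rep(0, nn),
                          d_genotype = rep(0, nn), d_interaction = rep(0, nn))
  }
  if (length(networks)) {
    if (is.null(names(networks)) || anyDuplicated(names(networks)))
      stop("networks must be uniquely named")
    if (!setequal(effects$network, names(networks)))
      stop("effects table must have one row per network")
    lin <- lapply(networks, function(vx) {
      vx <- as.matrix(vx)
      if (any(vx < 1) || any(vx > matrix(dims, nrow(vx), 3, byrow = TRUE)))
        stop("network voxels outside grid")
      vx[, 1] + dims[1] * (vx[, 2] - 1) + dims[1] * dims[2] * (vx[, 3] - 1)
    })
    # overlapping networks are contradictory unless their effect rows agree
    for (i in seq_along(lin)) for (j in seq_len(i - 1L)) {
      if (length(intersect(lin[[i]], lin[[j]]))) {
        ei <- effects[effects$network == names(networks)[i], -1]
        ej <- effects[effects$network == names(networks)[j], -1]
        if (!isTRUE(all.equal(unlist(ei), unlist(ej), check.attributes = FALSE)))
          stop("networks '", names(networks)[i], "' and '", names(networks)[j],
               "' overlap with contradictory effects")
      }
    }
  }
  structure(list(dims = dims, n_timepoints = as.integer(n_timepoints),
                 tr_s = tr_s, voxel_size_mm = voxel_size_mm,
                 n_per_cell = as.integer(n_per_cell), ar1 = ar1,
                 networks = networks, effects = effects, noise_sd = noise_sd,
                 nuisance_load = nuisance_load, seed = as.integer(seed)),
            class = "fmri_sim_spec")
}

# unit-variance AR(1) series (matrix: one column per series)
ar1_series <- function(n, k, phi, sd = 1) {
  e <- matrix(stats::rnorm(n * k), n, k)
  if (phi != 0) {
    x <- stats::filter(e, phi, method = "recursive")
    x <- matrix(as.numeric(x), n, k) * sqrt(1 - phi^2)
  } else x <- e
  x * sd
}

cell_table <- function(n_per_cell) {
  if (length(n_per_cell) == 1L) n_per_cell <- rep(n_per_cell, 4L)
  stopifnot(length(n_per_cell) == 4L)
  cells <- data.frame(sex = c("F", "M", "F", "M"),
                      genotype = c("WT", "WT", "MUT", "MUT"))
  cells[rep(seq_len(4L), n_per_cell), , drop = FALSE]
}

#' Simulate a synthetic rsfMRI cohort with planted connectivity effects
#'
#' Generates one 4D volume per subject: shared latent network signals
#' weighted by the subject's design cell, plus voxelwise AR(1) noise, plus a
#' linear mixture of 7 synthetic nuisance traces (6 motion + 1 ventricular).
#' Ground truth labels every voxel with its effect class.
#'
#' @param spec An [fmri_sim_spec()].
#' @return A list with elements `bold` (list of [bold_series()]), `nuisance`
#'   (list of [nuisance_set()]), `design` (data frame: subject, sex,
#'   genotype), and `truth` (list: `voxel_class` 3D character array with
#'   values `"null"` or `<network>:<effect-kind>`, `cell_z` per-network
#'   per-cell target z table, `networks` linear voxel indices).
#' @export
simulate_bold <- function(spec) {
  stopifnot(inherits(spec, "fmri_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  dims <- spec$dims; tt <- spec$n_timepoints
  nvox <- prod(dims)
  design <- cell_table(spec$n_per_cell)
  design$subject <- sprintf("sub%02d", seq_len(nrow(design)))
  design <- validate_design(design[, c("subject", "sex", "genotype")])

  net_lin <- lapply(spec$networks, function(vx) {
    vx <- as.matrix(vx)
    vx[, 1] + dims[1] * (vx[, 2] - 1) + dims[1] * dims[2] * (vx[, 3] - 1)
  })

  # target z per network x cell
  eff <- spec$effects
  cellz <- NULL
  if (nrow(eff)) {
    grid <- expand.grid(sex = c("F", "M"), genotype = c("WT", "MUT"),
                        network = eff$network, stringsAsFactors = FALSE)
    grid$z <- mapply(function(sx, gt, nw) {
      e <- eff[eff$network == nw, ]
      z <- e$base_z + e$d_sex * (sx == "M") + e$d_genotype * (gt == "MUT") +
        e$d_interaction * (sx == "M" & gt == "MUT")
      if (z < 0) stop("negative target z for network '", nw, "'")
      z
    }, grid$sex, grid$genotype, grid$network)
    cellz <- grid
  }

  bold <- vector("list", nrow(design))
  nuis <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    noise <- ar1_series(tt, nvox, spec$ar1, spec$noise_sd)
    dat <- noise
    if (length(net_lin)) {
      latents <- ar1_series(tt, length(net_lin), spec$ar1)
      for (k in seq_along(net_lin)) {
        z <- cellz$z[cellz$network == names(net_lin)[k] &
                       cellz$sex == as.character(design$sex[i]) &
                       cellz$genotype == as.character(design$genotype[i])]
        r <- tanh(z)
        w <- spec$noise_sd * sqrt(r / (1 - r))
        if (w > 0) dat[, net_lin[[k]]] <- dat[, net_lin[[k]]] + w * latents[, k]
      }
    }
    motion <- ar1_series(tt, 6L, 0.95, 0.5)
    vent <- ar1_series(tt, 1L, spec$ar1)[, 1]
    if (spec$nuisance_load > 0) {
      loadings <- matrix(stats::rnorm(7L * nvox, sd = spec$nuisance_load), 7L, nvox)
      dat <- dat + cbind(motion, vent) %*% loadings
    }
    arr <- array(0, c(dims, tt))
    arr[] <- t(dat)
    bold[[i]] <- bold_series(arr, voxel_size_mm = spec$voxel_size_mm,
                             tr_s = spec$tr_s, subject = design$subject[i])
    nuis[[i]] <- nuisance_set(motion, vent)
  }

  voxel_class <- array("null", dims)
  if (length(net_lin)) for (k in seq_along(net_lin)) {
    e <- eff[eff$network == names(net_lin)[k], ]
    kind <- if (e$d_interaction != 0) "interaction"
            else if (e$d_genotype != 0) "genotype"
            else if (e$d_sex != 0) "sex" else "network"
    voxel_class[net_lin[[k]]] <- paste0(names(net_lin)[k], ":", kind)
  }

  list(bold = bold, nuisance = nuis, design = design,
       truth = list(voxel_class = voxel_class, cell_z = cellz,
                    networks = net_lin))
}

# save/restore the global RNG stream so simulators don't perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cuboid network mask helper
#'
#' Voxel-coordinate matrix for an axis-aligned block, convenient for
#' declaring network masks in [fmri_sim_spec()].
#'
#' @param x,y,z Integer ranges (vectors) of voxel coordinates.
#' @return Integer matrix with columns x, y, z.
#' @export
block_mask <- function(x, y, z) {
  as.matrix(expand.grid(x = as.integer(x), y = as.integer(y),
                        z = as.integer(z)))
}
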