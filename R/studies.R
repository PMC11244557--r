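# Calibration and power studies run under fixed, package-defined conditions.
# These drivers tie the simulators to the inference machinery so that the
# same study can be run from the test suite, the acceptance script and the
# analysis scripts.

# shared phantom geometry for the fMRI studies: 16x16x8 grid, 120 frames,
# TR 1 s, n = 5 per cell, one 40-voxel network block with a 3x3x1 seed
# inside it
fmri_study_spec <- function(seed, d_interaction = 0, n_per_cell = 5L,
                            n_timepoints = 120L) {
  fmri_sim_spec(
    dims = c(16L, 16L, 8L), n_timepoints = n_timepoints, tr_s = 1,
    n_per_cell = n_per_cell, ar1 = 0.4,
    networks = list(A = block_mask(5:8, 5:9, 3:4)),
    effects = data.frame(network = "A", base_z = 0.3, d_sex = 0,
                         d_genotype = 0, d_interaction = d_interaction),
    noise_sd = 1, nuisance_load = 0.2, seed = seed)
}

# nuisance regression and spatial smoothing (0.6 mm FWHM at 0.23 mm
# in-plane voxels), then a seed map from a 3x3x1 block inside the network;
# smoothing matters here because cluster-extent inference presupposes
# spatially smooth fields
fmri_study_maps <- function(sim, fwhm_mm = 0.6) {
  lapply(seq_along(sim$bold), function(i) {
    b <- regress_nuisance(sim$bold[[i]], sim$nuisance[[i]])
    b <- smooth_gaussian(b, fwhm_mm)
    seed_connectivity(b, seed_spec(c(6L, 7L, 3L)))
  })
}

#' Familywise error calibration of cluster-extent correction
#'
#' Simulates null 2x2 cohorts (a shared 40-voxel network with identical
#' coupling in all cells, so the interaction is truly absent), maps
#' seed-based connectivity after nuisance regression, fits the voxelwise
#' factorial model and applies [cluster_fwer()] to the interaction
#' contrast. A dataset counts as a familywise false positive if any cluster
#' reaches corrected p < `alpha`.
#'
#' @param seeds Simulation seeds, one dataset per seed.
#' @param n_perm Permutations per dataset.
#' @param t_thresh Cluster-forming threshold.
#' @param alpha Nominal FWER level.
#' @return List: `rejected` (logical per dataset), `fwer` (the familywise
#'   false-positive rate).
#' @export
null_fwer_study <- function(seeds = 1:100, n_perm = 500L, t_thresh = 2.1,
                            alpha = 0.05) {
  rejected <- vapply(seeds, function(s) {
    sim <- simulate_bold(fmri_study_spec(seed = s, d_interaction = 0))
    maps <- fmri_study_maps(sim)
    st <- voxelwise_glm(maps, sim$design)
    cl <- cluster_fwer(st$interaction, maps, sim$design, t_thresh = t_thresh,
                       n_perm = n_perm, seed = s)
    nrow(cl$clusters) > 0 && any(cl$clusters$p_fwer < alpha)
  }, logical(1))
  list(rejected = rejected, fwer = mean(rejected))
}

#' Detection power for a planted sex-by-genotype connectivity interaction
#'
#' As [null_fwer_study()], but the network's coupling is raised by
#' `delta` z units in mutant males only. A dataset counts as a detection
#' when some cluster with corrected p < `alpha` overlaps the planted
#' network mask.
#'
#' @param seeds Simulation seeds.
#' @param delta Planted interaction effect (z units).
#' @param n_perm,t_thresh,alpha As in [null_fwer_study()].
#' @return List: `detected` (logical per dataset), `rate`.
#' @export
interaction_detection_study <- function(seeds = 1:50, delta = 0.4,
                                        n_perm = 500L, t_thresh = 2.1,
                                        alpha = 0.05) {
  detected <- vapply(seeds, function(s) {
    sim <- simulate_bold(fmri_study_spec(seed = s, d_interaction = delta))
    maps <- fmri_study_maps(sim)
    st <- voxelwise_glm(maps, sim$design)
    cl <- cluster_fwer(st$interaction, maps, sim$design, t_thresh = t_thresh,
                       n_perm = n_perm, seed = s)
    truth <- which(sim$truth$voxel_class != "null")
    hit <- FALSE
    for (k in seq_len(nrow(cl$clusters))) {
      if (cl$clusters$p_fwer[k] < alpha &&
          length(intersect(cl$voxels[[k]], truth))) hit <- TRUE
    }
    hit
  }, logical(1))
  list(detected = detected, rate = mean(detected))
}

# shared conditions for the transcriptomic studies: 2000 genes, n = 5 per
# cell; planted sets (if any) carry opposite-signed within-sex logFCs
counts_study_spec <- function(seed, lfc = 0, n_set = 50L, n_genes = 2000L,
                              artifact_strength = 0.5) {
  planted <- if (lfc != 0) {
    data.frame(name = c("plantMpFm", "plantMmFp"), size = n_set,
               male_lfc = c(lfc, -lfc), female_lfc = c(-lfc, lfc))
  } else NULL
  counts_sim_spec(n_genes = n_genes, n_per_cell = 5L,
                  planted_sets = planted,
                  artifact_frac = 0.3,
                  artifact_strength = artifact_strength, seed = seed)
}

# one pass of the DE pipeline under study conditions; returns the
# classified de_result joined with ground truth
run_de_once <- function(sim, min_reads = 100L, min_samples = 2L,
                        var_quantile = 0.15, n_sv = 2L, q_thresh = 0.05) {
  ds <- count_dataset(sim$counts, sim$genes, sim$design)
  ds <- filter_genes(ds, min_reads, min_samples, var_quantile)
  f <- tmm_factors(ds)
  lc <- logcpm(ds, f)
  X <- interaction_model_matrix(ds$design)
  w <- precision_weights(lc, X, effective_libsize(ds, f))
  sv <- estimate_svs(lc, X, n_sv)
  de <- fit_interaction(lc, w, ds$design, svs = sv)
  de <- classify_interaction(de, q_thresh)
  de$true_class <- sim$truth$class[match(de$gene_id, sim$truth$gene_id)]
  de
}

#' Null calibration of the interaction differential-expression test
#'
#' Runs the full DE pipeline (filter, TMM, log-CPM, precision weights, two
#' surrogate variables, weighted interaction fit) on null simulations with
#' no planted effects, recording the number of interaction genes at
#' q < `q_thresh` per run and, for the first run, the Kolmogorov-Smirnov
#' uniformity p value of the interaction p values.
#'
#' @param seeds Simulation seeds.
#' @param q_thresh FDR threshold.
#' @return List: `n_signif` per run, `frac_zero` (runs with zero calls),
#'   `ks_p` (uniformity of run 1's interaction p values).
#' @export
de_null_study <- function(seeds = 1:50, q_thresh = 0.05) {
  n_signif <- integer(length(seeds))
  ks_p <- NA_real_
  for (i in seq_along(seeds)) {
    sim <- simulate_counts(counts_study_spec(seed = seeds[i], lfc = 0,
                                             artifact_strength = 0))
    de <- run_de_once(sim, q_thresh = q_thresh)
    n_signif[i] <- sum(de$inter_q < q_thresh)
    if (i == 1L)
      ks_p <- stats::ks.test(de$inter_p, "punif")$p.value
  }
  list(n_signif = n_signif, frac_zero = mean(n_signif == 0L), ks_p = ks_p)
}

#' Recovery of planted M+F-/M-F+ gene classes
#'
#' Plants two 50-gene sets with opposite-signed within-sex log fold changes
#' of magnitude `lfc` and measures, over runs, the sensitivity (planted
#' genes assigned their true class) and the opposite-class confusion
#' (planted genes assigned the mirror class).
#'
#' @param seeds Simulation seeds.
#' @param lfc Within-sex log2 fold-change magnitude.
#' @param q_thresh FDR threshold for classification.
#' @return List: `sensitivity`, `confusion`, and the per-run counts
#'   (`n_planted`, `n_correct`, `n_opposite`).
#' @export
class_recovery_study <- function(seeds = 1:10, lfc = 1.5, q_thresh = 0.05) {
  n_planted <- n_correct <- n_opposite <- integer(length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_counts(counts_study_spec(seed = seeds[i], lfc = lfc))
    de <- run_de_once(sim, q_thresh = q_thresh)
    planted_ids <- sim$truth$gene_id[sim$truth$class %in% c("M+F-", "M-F+")]
    truth <- sim$truth$class[match(planted_ids, sim$truth$gene_id)]
    called <- de$class[match(planted_ids, de$gene_id)]
    called[is.na(called)] <- "filtered"   # dropped by filtering counts as a miss
    n_planted[i] <- length(planted_ids)
    n_correct[i] <- sum(called == truth)
    n_opposite[i] <- sum((truth == "M+F-" & called == "M-F+") |
                           (truth == "M-F+" & called == "M+F-"))
  }
  list(sensitivity = sum(n_correct) / sum(n_planted),
       confusion = sum(n_opposite) / sum(n_planted),
       n_planted = n_planted, n_correct = n_correct, n_opposite = n_opposite)
}

#' Surrogate-variable recovery of a planted artifact factor
#'
#' Simulates counts with a binary artifact factor balanced within design
#' cells (hence near-orthogonal to sex and genotype), loading on half the
#' genes with log2-scale strength 1, runs the pipeline through
#' [estimate_svs()], and reports the absolute correlation between the first
#' surrogate variable and the true factor.
#'
#' @param seed Simulation seed.
#' @param strength Artifact loading SD (log2 scale).
#' @param frac Fraction of genes loading on the artifact.
#' @return List: `r` (|correlation| of sv1 with the artifact), `sv` matrix.
#' @export
sv_recovery_study <- function(seed = 1L, strength = 1, frac = 0.5) {
  spec <- counts_sim_spec(n_genes = 2000L, n_per_cell = 5L,
                          artifact_frac = frac,
                          artifact_strength = strength,
                          artifact_samples = "balanced", seed = seed)
  sim <- simulate_counts(spec)
  ds <- count_dataset(sim$counts, sim$genes, sim$design)
  ds <- filter_genes(ds)
  f <- tmm_factors(ds)
  lc <- logcpm(ds, f)
  X <- interaction_model_matrix(ds$design)
  sv <- estimate_svs(lc, X, 2L)
  list(r = abs(stats::cor(sv[, 1], sim$artifact)), sv = sv)
}
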