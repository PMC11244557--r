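#' Specification for a synthetic RNA-seq count experiment
#'
#' Negative-binomial counts for a 2x2 sex-by-genotype design with planted
#' within-sex log2 fold changes, library-size variation, a gene-wise
#' RIN-like covariate effect, and a structured artifact factor recoverable
#' as a surrogate variable. Counts follow NB(mu, phi) with variance
#' mu + phi * mu^2; gene-wise dispersions are log-normal.
#'
#' The default cohort matches a typical bulk-tissue factorial study:
#' n = 4, 4, 5, 5 per cell (F-WT, M-WT, F-MUT, M-MUT).
#'
#' @param n_genes Number of genes.
#' @param n_per_cell Subjects per cell; scalar or length-4 vector in cell
#'   order F-WT, M-WT, F-MUT, M-MUT.
#' @param baseline_meanlog,baseline_sdlog Parameters of the baseline log2-CPM
#'   normal draw (before normalization to 1e6 total CPM).
#' @param baseline_log2cpm Optional explicit per-gene baseline log2-CPM
#'   vector (overrides the draw; `-Inf` marks an unexpressed gene).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   gene-wise NB dispersion phi.
#' @param libsize_range Length-2 range of library sizes (total counts).
#' @param libsizes Optional explicit per-sample library sizes (overrides
#'   `libsize_range`).
#' @param planted_sets Data frame with columns `name`, `size`, `male_lfc`,
#'   `female_lfc` and optionally `chrom`: disjoint gene sets given
#'   mutant-vs-wildtype log2 fold changes within each sex (and optionally
#'   pinned to one chromosome).
#' @param artifact_frac Fraction of genes loading on the artifact factor.
#' @param artifact_strength SD (log2 scale) of nonzero artifact loadings.
#' @param artifact_samples `"balanced"` (affected samples split evenly
#'   within each design cell, keeping the factor near-orthogonal to the
#'   design) or `"random"`.
#' @param rin_sd SD of the gene-wise log2-per-RIN-unit slope.
#' @param x_frac Fraction of genes assigned to the X chromosome.
#' @param homolog_frac Fraction of genes given a human homolog symbol.
#' @param seed RNG seed.
#' @return An object of class `counts_sim_spec`.
#' @export
counts_sim_spec <- function(n_genes = 12000L, n_per_cell = c(4L, 4L, 5L, 5L),
                            baseline_meanlog = 4, baseline_sdlog = 2,
                            baseline_log2cpm = NULL,
                            dispersion_meanlog = log(0.1),
                            dispersion_sdlog = 0.5,
                            libsize_range = c(1e7, 5e7),
                            libsizes = NULL,
                            planted_sets = NULL,
                            artifact_frac = 0.3, artifact_strength = 0,
                            artifact_samples = c("balanced", "random"),
                            rin_sd = 0.02, x_frac = 0.05,
                            homolog_frac = 0.85, seed = 1L) {
  stopifnot(n_genes >= 1, all(n_per_cell >= 2), dispersion_sdlog >= 0,
            length(libsize_range) == 2L, all(libsize_range > 0),
            artifact_frac >= 0, artifact_frac <= 1, artifact_strength >= 0,
            rin_sd >= 0, x_frac >= 0, x_frac <= 1)
  artifact_samples <- match.arg(artifact_samples)
  if (is.null(planted_sets))
    planted_sets <- data.frame(name = character(0), size = integer(0),
                               male_lfc = numeric(0), female_lfc = numeric(0))
  if (anyDuplicated(planted_sets$name)) stop("planted set names must be unique")
  if (sum(planted_sets$size) > n_genes) stop("planted sets exceed n_genes")
  if (!is.null(baseline_log2cpm) && length(baseline_log2cpm) != n_genes)
    stop("baseline_log2cpm must have length n_genes")
  structure(list(n_genes = as.integer(n_genes), n_per_cell = n_per_cell,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 baseline_log2cpm = baseline_log2cpm,
                 dispersion_meanlog = dispersion_meanlog,
                 dispersion_sdlog = dispersion_sdlog,
                 libsize_range = libsize_range, libsizes = libsizes,
                 planted_sets = planted_sets,
                 artifact_frac = artifact_frac,
                 artifact_strength = artifact_strength,
                 artifact_samples = artifact_samples, rin_sd = rin_sd,
                 x_frac = x_frac, homolog_frac = homolog_frac,
                 seed = as.integer(seed)),
            class = "counts_sim_spec")
}

truth_class <- function(male_lfc, female_lfc) {
  ifelse(male_lfc > 0 & female_lfc < 0, "M+F-",
    ifelse(male_lfc < 0 & female_lfc > 0, "M-F+",
      ifelse(male_lfc != 0 & female_lfc != 0, "concordant", "null")))
}

#' Simulate a gene-by-sample NB count matrix with planted interactions
#'
#' @param spec A [counts_sim_spec()].
#' @return A list with `counts` (integer gene x sample matrix), `genes`
#'   (data frame: gene_id, chrom, human_homolog), `design` (data frame:
#'   subject, sex, genotype, RIN), `truth` (data frame: gene_id, class,
#'   male_lfc, female_lfc, artifact_loading) and `artifact` (0/1 per
#'   sample).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "counts_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  ng <- spec$n_genes
  design <- cell_table(spec$n_per_cell)
  design$subject <- sprintf("s%02d", seq_len(nrow(design)))
  design$RIN <- round(stats::runif(nrow(design), 6.8, 10), 2)
  design <- validate_design(design[, c("subject", "sex", "genotype", "RIN")],
                            require_covariates = "RIN")
  ns <- nrow(design)

  gene_id <- sprintf("gene%05d", seq_len(ng))
  chrom <- sample(c(paste0("chr", 1:19), "chrX"), ng, replace = TRUE,
                  prob = c(rep((1 - spec$x_frac) / 19, 19), spec$x_frac))
  homolog <- ifelse(stats::runif(ng) < spec$homolog_frac, toupper(gene_id), "")

  if (is.null(spec$baseline_log2cpm)) {
    base_l2 <- stats::rnorm(ng, spec$baseline_meanlog, spec$baseline_sdlog)
  } else base_l2 <- spec$baseline_log2cpm
  cpm0 <- 2^base_l2
  cpm0[!is.finite(cpm0)] <- 0
  cpm0 <- cpm0 / sum(cpm0) * 1e6
  phi <- stats::rlnorm(ng, spec$dispersion_meanlog, spec$dispersion_sdlog)

  # assign planted sets to disjoint random genes (optionally on one chromosome)
  male_lfc <- female_lfc <- numeric(ng)
  set_of <- rep(NA_character_, ng)
  ps <- spec$planted_sets
  taken <- logical(ng)
  for (k in seq_len(nrow(ps))) {
    # planted effects go into expressed genes (>= 1 CPM), the standard floor
    pool <- which(!taken & cpm0 >= 1)
    if (!is.null(ps$chrom) && !is.na(ps$chrom[k]))
      pool <- intersect(pool, which(chrom == ps$chrom[k]))
    if (length(pool) < ps$size[k])
      stop("not enough eligible genes for planted set '", ps$name[k], "'")
    idx <- sample(pool, ps$size[k])
    if (any(cpm0[idx] == 0))
      stop("planted fold change on a gene with zero baseline")
    taken[idx] <- TRUE
    male_lfc[idx] <- ps$male_lfc[k]
    female_lfc[idx] <- ps$female_lfc[k]
    set_of[idx] <- ps$name[k]
  }

  # artifact factor: 0/1 per sample, gene loadings on a random subset
  artifact <- rep(0L, ns)
  if (spec$artifact_samples == "balanced") {
    cell <- interaction(design$sex, design$genotype)
    for (cl in levels(cell)) {
      idx <- which(cell == cl)
      artifact[sample(idx, floor(length(idx) / 2))] <- 1L
    }
  } else artifact[sample(ns, floor(ns / 2))] <- 1L
  loading <- numeric(ng)
  if (spec$artifact_strength > 0 && spec$artifact_frac > 0) {
    hit <- sample(ng, round(spec$artifact_frac * ng))
    loading[hit] <- stats::rnorm(length(hit), 0, spec$artifact_strength)
  }

  rin_slope <- if (spec$rin_sd > 0) stats::rnorm(ng, 0, spec$rin_sd) else numeric(ng)
  libsize <- if (!is.null(spec$libsizes)) {
    if (length(spec$libsizes) != ns) stop("libsizes must have one entry per sample")
    as.numeric(spec$libsizes)
  } else stats::runif(ns, spec$libsize_range[1], spec$libsize_range[2])

  codes <- effect_codes(design)
  is_m <- codes$sex == 1
  is_mut <- codes$genotype == 1
  lfc_mat <- outer(male_lfc, as.numeric(is_m & is_mut)) +
    outer(female_lfc, as.numeric(!is_m & is_mut))
  l2mu <- log2(cpm0) + lfc_mat +
    outer(loading, as.numeric(artifact)) +
    outer(rin_slope, design$RIN - mean(design$RIN))
  mu <- sweep(2^l2mu, 2L, libsize / 1e6, "*")
  mu[cpm0 == 0, ] <- 0

  counts <- matrix(stats::rnbinom(ng * ns, mu = as.vector(mu),
                                  size = rep(1 / phi, ns)), ng, ns)
  dimnames(counts) <- list(gene_id, design$subject)

  list(counts = counts,
       genes = data.frame(gene_id = gene_id, chrom = chrom,
                          human_homolog = homolog),
       design = design,
       truth = data.frame(gene_id = gene_id,
                          class = truth_class(male_lfc, female_lfc),
                          set = set_of, male_lfc = male_lfc,
                          female_lfc = female_lfc,
                          artifact_loading = loading),
       artifact = artifact)
}
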