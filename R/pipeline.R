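# recognized configuration keys, checked before any compute
.config_keys <- list(
  top = c("pipeline", "out_dir", "seed", "inputs", "params"),
  imaging_inputs = c("bold", "nuisance", "design", "mask"),
  imaging_params = c("n_drop", "fwhm_mm", "band", "map", "radius_vox",
                     "seed_center", "seed_extent", "contrast", "t_thresh",
                     "n_perm", "connectivity", "average_domain"),
  rnaseq_inputs = c("counts", "design", "genes", "gmt", "homologs"),
  rnaseq_params = c("min_reads", "min_samples", "var_quantile", "n_sv",
                    "q_thresh", "covariates", "haldane"))

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or an equivalent nested list. Unknown keys are
#' rejected before any computation; defaults are filled in.
#'
#' @param config YAML path or list with keys `pipeline` (`"imaging"` or
#'   `"rnaseq"`), `out_dir`, `seed`, `inputs`, `params`.
#' @return The validated config list with defaults applied.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  check_keys(config, .config_keys$top, "top level")
  if (is.null(config$pipeline) ||
      !config$pipeline %in% c("imaging", "rnaseq"))
    stop("config$pipeline must be 'imaging' or 'rnaseq'")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  config$seed <- as.integer(config$seed %||% 1L)
  kind <- config$pipeline
  check_keys(config$inputs, .config_keys[[paste0(kind, "_inputs")]],
             paste0(kind, " inputs"))
  check_keys(config$params, .config_keys[[paste0(kind, "_params")]],
             paste0(kind, " params"))
  defaults <- if (kind == "imaging") {
    list(n_drop = 50L, fwhm_mm = 0.6, band = c(0.01, 0.1), map = "global",
         radius_vox = 6, contrast = "interaction", t_thresh = 2.1,
         n_perm = 1000L, connectivity = 6L, average_domain = "z")
  } else {
    list(min_reads = 100L, min_samples = 2L, var_quantile = 0.15,
         n_sv = 2L, q_thresh = 0.05, covariates = "RIN", haldane = TRUE)
  }
  for (k in names(defaults))
    if (is.null(config$params[[k]])) config$params[[k]] <- defaults[[k]]
  config
}

provenance_block <- function(config, extra = list()) {
  c(list(package = "dimorph",
         version = as.character(utils::packageVersion("dimorph")),
         timestamp = format(Sys.time(), tz = "UTC"),
         config_hash = rlang::hash(config[c("pipeline", "inputs", "params",
                                            "seed")]),
         seed = config$seed,
         params = config$params),
    extra)
}

#' Run the imaging pipeline from a configuration
#'
#' Stage order: trim, nuisance regression, smoothing, band-pass filtering,
#' connectivity mapping (global, local or seed), voxelwise factorial GLM,
#' cluster-extent FWER correction. Writes per-contrast t maps (NIfTI), the
#' cluster table (TSV) and a provenance manifest (JSON) to `out_dir`.
#' Re-running with the same config and inputs reproduces identical tables.
#'
#' @param config YAML path or list (see [load_config()]).
#' @return Invisibly, a list with the stat maps, cluster result and output
#'   paths.
#' @export
run_imaging_pipeline <- function(config) {
  config <- load_config(config)
  if (config$pipeline != "imaging") stop("not an imaging config")
  p <- config$params
  inp <- config$inputs
  for (k in c("bold", "nuisance", "design"))
    if (is.null(inp[[k]])) stop("imaging stage requires input: ", k)
  design <- read_design(inp$design)
  if (length(inp$bold) != nrow(design) ||
      length(inp$nuisance) != nrow(design))
    stop("need one bold and one nuisance file per design row")
  mask <- if (!is.null(inp$mask)) read_nifti_map(inp$mask)$map > 0 else NULL

  maps <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    b <- read_nifti_bold(inp$bold[i], mask = mask,
                         subject = design$subject[i])
    nu <- read_nuisance(inp$nuisance[i])
    b <- preprocess_bold(b, nu, n_drop = p$n_drop, fwhm_mm = p$fwhm_mm,
                         band = p$band)
    maps[[i]] <- switch(p$map,
      global = global_connectivity(b, average_domain = p$average_domain),
      local = local_connectivity(b, radius_vox = p$radius_vox,
                                 average_domain = p$average_domain),
      seed = seed_connectivity(b, seed_spec(p$seed_center,
                                            p$seed_extent %||% c(3L, 3L, 1L))),
      stop("unknown map kind: ", p$map))
  }
  stats <- voxelwise_glm(maps, design)
  clus <- cluster_fwer(stats[[p$contrast]], maps, design,
                       t_thresh = p$t_thresh, n_perm = p$n_perm,
                       seed = config$seed, connectivity = p$connectivity)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  vox_mm <- b$voxel_size_mm
  paths <- character(0)
  for (con in names(stats)) {
    f <- file.path(config$out_dir, paste0("tmap_", con, ".nii"))
    write_nifti_map(stats[[con]], f, vox_mm)
    paths <- c(paths, f)
  }
  clus_path <- file.path(config$out_dir, "clusters.tsv")
  write_tsv(clus$clusters, clus_path)
  manifest <- provenance_block(config, list(
    stage_order = c("trim", "regress_nuisance", "smooth", "bandpass",
                    paste0("connectivity_", p$map), "voxelwise_glm",
                    "cluster_fwer"),
    n_subjects = nrow(design),
    n_voxels_analyzed = sum(stats[[1]]$analyzed),
    n_voxels_excluded = sum(maps[[1]]$mask) - sum(stats[[1]]$analyzed)))
  man_path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(stats = stats, clusters = clus,
                 paths = c(paths, clus_path, man_path)))
}

#' Run the transcriptomics pipeline from a configuration
#'
#' Stage order: gene filtering, TMM normalization, log-CPM, precision
#' weights, surrogate variables, weighted interaction fit, M+F-/M-F+
#' classification, then (when a GMT collection is supplied) hypergeometric
#' enrichment of the classes and per-chromosome disproportionality. Writes
#' the DE table, enrichment tables and a provenance manifest to `out_dir`.
#'
#' @param config YAML path or list (see [load_config()]).
#' @return Invisibly, a list with the `de_result`, enrichment tables and
#'   output paths.
#' @export
run_rnaseq_pipeline <- function(config) {
  config <- load_config(config)
  if (config$pipeline != "rnaseq") stop("not an rnaseq config")
  p <- config$params
  inp <- config$inputs
  for (k in c("counts", "design", "genes"))
    if (is.null(inp[[k]])) stop("rnaseq stage requires input: ", k)
  counts <- read_counts(inp$counts)
  design <- read_design(inp$design, require_covariates = p$covariates)
  genes <- read_gene_meta(inp$genes)
  ds <- count_dataset(counts, genes, design)

  ds <- filter_genes(ds, p$min_reads, p$min_samples, p$var_quantile)
  f <- tmm_factors(ds)
  lc <- logcpm(ds, f)
  X <- interaction_model_matrix(ds$design, p$covariates)
  w <- precision_weights(lc, X, effective_libsize(ds, f))
  sv <- estimate_svs(lc, X, p$n_sv)
  de <- fit_interaction(lc, w, ds$design, p$covariates, sv)
  de <- classify_interaction(de, p$q_thresh)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  de_path <- file.path(config$out_dir, "de_results.tsv")
  write_tsv(as.data.frame(de), de_path)
  paths <- de_path

  background <- gene_set(de$gene_id, "background", "mouse")
  classes <- list()
  for (cl in c("M+F-", "M-F+")) {
    ids <- de$gene_id[de$class == cl]
    if (length(ids)) classes[[cl]] <- gene_set(ids, cl, "mouse")
  }

  enr <- chrom <- NULL
  if (length(classes)) {
    chrom_meta <- ds$genes[, c("gene_id", "chrom")]
    chrom <- do.call(rbind, lapply(names(classes), function(cl) {
      out <- chromosome_enrich(classes[[cl]], chrom_meta, background,
                               p$haldane)
      out$class <- cl
      out
    }))
    chrom_path <- file.path(config$out_dir, "chromosome_enrichment.tsv")
    write_tsv(chrom, chrom_path)
    paths <- c(paths, chrom_path)

    if (!is.null(inp$gmt)) {
      lists <- read_gmt(inp$gmt)
      queries <- classes
      bg <- background
      if (!is.null(inp$homologs)) {
        hm <- read_homolog_map(inp$homologs)
        queries <- lapply(classes, map_homologs, table = hm)
        bg <- map_homologs(background, hm)
      }
      enr <- enrich_classes(queries, lists, bg, p$haldane)
      enr_path <- file.path(config$out_dir, "enrichment.tsv")
      write_tsv(enr, enr_path)
      paths <- c(paths, enr_path)
    }
  }

  manifest <- provenance_block(config, list(
    stage_order = c("filter_genes", "tmm", "logcpm", "precision_weights",
                    "estimate_svs", "fit_interaction",
                    "classify_interaction", "enrichment"),
    n_genes_input = nrow(counts), n_genes_retained = nrow(ds$counts),
    class_counts = as.list(table(de$class))))
  man_path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(de = de, chromosome = chrom, enrichment = enr,
                 paths = c(paths, man_path)))
}

#' Run a configured pipeline
#'
#' Dispatches to [run_imaging_pipeline()] or [run_rnaseq_pipeline()] based
#' on `config$pipeline`.
#'
#' @param config YAML path or list (see [load_config()]).
#' @return See the stage runners.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  switch(config$pipeline,
         imaging = run_imaging_pipeline(config),
         rnaseq = run_rnaseq_pipeline(config))
}
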