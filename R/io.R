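#' Read a 4D NIfTI volume as a BOLD series
#'
#' Voxel size (mm) and TR (s) are taken from the header `pixdim`.
#'
#' @param path NIfTI-1 file (3D volumes are rejected here; see
#'   [read_nifti_map()]).
#' @param mask Optional logical 3D array; default all voxels.
#' @param subject Subject label; default the file name.
#' @return A [bold_series()].
#' @export
read_nifti_bold <- function(path, mask = NULL, subject = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 4L) stop("expected a 4D NIfTI volume, got ", nd, "D: ", path)
  pd <- RNifti::pixdim(img)
  bold_series(array(as.numeric(img), dim(img)), mask = mask,
              voxel_size_mm = pd[1:3], tr_s = pd[4],
              subject = subject %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Write a BOLD series as 4D NIfTI (float32 storage)
#'
#' @param b A [bold_series()].
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_nifti_bold <- function(b, path) {
  stopifnot(inherits(b, "bold_series"))
  dat <- structure(b$data, pixdim = c(b$voxel_size_mm, b$tr_s))
  RNifti::writeNifti(RNifti::asNifti(dat, datatype = "float"), path)
  invisible(path)
}

#' Read / write a 3D scalar map as NIfTI
#'
#' @param path NIfTI file.
#' @return `read_nifti_map`: list with `map` (3D array) and
#'   `voxel_size_mm`.
#' @export
read_nifti_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(img)), "D: ", path)
  list(map = array(as.numeric(img), dim(img)),
       voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname read_nifti_map
#' @param map 3D numeric array (or [connectivity_map()] / `stat_map`).
#' @param voxel_size_mm Voxel edge lengths.
#' @export
write_nifti_map <- function(map, path, voxel_size_mm = c(1, 1, 1)) {
  if (inherits(map, "connectivity_map")) map <- map$map
  if (inherits(map, "stat_map")) map <- map$map
  stopifnot(length(dim(map)) == 3L)
  dat <- structure(map, pixdim = voxel_size_mm)
  RNifti::writeNifti(RNifti::asNifti(dat, datatype = "float"), path)
  invisible(path)
}

#' Read / write a nuisance regressor TSV
#'
#' Columns `tx, ty, tz, rx, ry, rz, vent`, one row per frame.
#'
#' @param path TSV file.
#' @return A [nuisance_set()].
#' @export
read_nuisance <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("tx", "ty", "tz", "rx", "ry", "rz", "vent")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("nuisance file missing columns: ",
                         paste(miss, collapse = ", "))
  nuisance_set(as.matrix(d[, need[1:6]]), d$vent)
}

#' @rdname read_nuisance
#' @param nu A [nuisance_set()].
#' @export
write_nuisance <- function(nu, path) {
  d <- data.frame(nu$motion, vent = nu$ventricular)
  utils::write.table(format(d, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample counts TSV
#'
#' First column is the gene ID; remaining columns are integer counts with
#' the header row giving sample IDs. Duplicate gene IDs are an error.
#'
#' @param path TSV file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0))
    stop("counts must be nonnegative numbers: ", path)
  rownames(m) <- ids
  m
}

#' Read a subject design TSV
#'
#' Requires columns `subject`, `sex` (M/F), `genotype` (WT/MUT); numeric
#' covariate columns are carried through. Offending rows are reported with
#' line numbers.
#'
#' @param path TSV file.
#' @param require_covariates Covariates that must be present and numeric.
#' @return Validated design data frame (see [validate_design()]).
#' @export
read_design <- function(path, require_covariates = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c(subject = "character"))
  bad <- which(!(d$sex %in% c("M", "F")) | !(d$genotype %in% c("WT", "MUT")))
  if (length(bad))
    stop("invalid sex/genotype levels in ", path, " at line(s): ",
         paste(bad + 1L, collapse = ", "))
  validate_design(d, require_covariates)
}

#' Read a gene metadata TSV
#'
#' Columns `gene_id`, `chrom`, `human_homolog` (blank for no homolog).
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_gene_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, na.strings = NULL)
  need <- c("gene_id", "chrom")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("gene metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(d$human_homolog)) d$human_homolog <- ""
  d$human_homolog[is.na(d$human_homolog)] <- ""
  d
}

#' Read / write GMT gene-set collections
#'
#' GMT format: one set per line, tab-separated `name`, `description`,
#' members. Malformed lines are reported with their line number.
#'
#' @param path GMT file.
#' @param namespace Namespace tag applied to every set.
#' @return Named list of [gene_set()]s.
#' @export
read_gmt <- function(path, namespace = "human") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf < 3L)
  if (length(bad))
    stop("GMT line(s) with fewer than 3 fields in ", path, ": line ",
         paste(bad, collapse = ", "))
  sets <- fgsea::gmtPathways(path)
  lapply(stats::setNames(names(sets), names(sets)),
         function(nm) gene_set(sets[[nm]], nm, namespace))
}

#' @rdname read_gmt
#' @param sets Named list of [gene_set()]s (or character vectors).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    ids <- if (inherits(sets[[nm]], "gene_set")) sets[[nm]]$ids else sets[[nm]]
    paste(c(nm, nm, ids), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a mouse-to-human homolog mapping TSV
#'
#' Columns `mouse_id`, `human_id`.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_homolog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("mouse_id", "human_id") %in% names(d)))
    stop("homolog map needs columns mouse_id, human_id: ", path)
  if (nrow(d) == 0L) stop("empty homolog mapping table: ", path)
  d
}

# deterministic TSV writer (fixed significant digits, no quoting)
write_tsv <- function(d, path, digits = 10) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) formatC(x, digits = digits,
                                               format = "g"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a counts matrix as TSV
#'
#' @param counts Integer gene x sample matrix.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
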