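#' Assemble a counts dataset
#'
#' Bundles a gene-by-sample integer count matrix with gene metadata and a
#' sample design table, validating that they agree.
#'
#' @param counts Integer gene x sample matrix with row and column names.
#' @param genes Data frame with at least `gene_id` (matching rownames) and
#'   optionally `chrom`, `human_homolog`.
#' @param design Design table (`subject`, `sex`, `genotype`, covariates)
#'   whose subjects match the count columns.
#' @return An object of class `count_dataset`.
#' @export
count_dataset <- function(counts, genes, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  design <- validate_design(design)
  if (!setequal(colnames(counts), design$subject))
    stop("samples in counts and design differ: ",
         paste(union(setdiff(colnames(counts), design$subject),
                     setdiff(design$subject, colnames(counts))), collapse = ", "))
  design <- design[match(colnames(counts), design$subject), , drop = FALSE]
  if (!all(rownames(counts) %in% genes$gene_id))
    stop("gene metadata missing for some count rows")
  genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
  structure(list(counts = counts, genes = genes, design = design),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("<count_dataset> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Low-read and low-variance gene filtering
#'
#' Removes genes with fewer than `min_reads` reads in `min_samples` or more
#' samples, then drops the lowest-variance fraction `var_quantile` of the
#' remaining genes (variance computed on log-CPM). Ties in variance are
#' broken by keeping the lexicographically lowest gene IDs.
#'
#' @param x A [count_dataset()].
#' @param min_reads,min_samples Read filter: drop genes with
#'   `count < min_reads` in `>= min_samples` samples (defaults 100 and 2).
#' @param var_quantile Fraction of lowest-variance genes to drop
#'   (default 0.15).
#' @return The filtered `count_dataset`.
#' @export
filter_genes <- function(x, min_reads = 100L, min_samples = 2L,
                         var_quantile = 0.15) {
  stopifnot(inherits(x, "count_dataset"), min_reads >= 0, min_samples >= 0,
            var_quantile >= 0, var_quantile < 1)
  low <- rowSums(x$counts < min_reads) >= min_samples
  keep <- !low
  if (!any(keep)) stop("all genes removed by the read filter")
  cts <- x$counts[keep, , drop = FALSE]
  if (var_quantile > 0) {
    lc <- logcpm(cts, rep(1, ncol(cts)))
    v <- apply(lc, 1L, stats::var)
    n_drop <- floor(var_quantile * nrow(cts))
    if (n_drop >= nrow(cts)) stop("variance filter would remove all genes")
    ord <- order(v, rownames(cts))  # ties: drop the higher gene IDs last
    cts <- cts[sort(ord[seq.int(n_drop + 1L, nrow(cts))]), , drop = FALSE]
  }
  msg("filter_genes: retained %d of %d genes", nrow(cts), nrow(x$counts))
  count_dataset(cts, x$genes, x$design)
}

#' TMM normalization factors
#'
#' Classic trimmed-mean-of-M-values scale factors: M/A values against a
#' reference sample (the one whose upper-quartile CPM is closest to the
#' mean upper quartile), doubly trimmed (30% on M, 5% on A), with a
#' precision-weighted mean of the surviving M values; factors are rescaled
#' to geometric mean 1. Computed with `edgeR::calcNormFactors`.
#'
#' @param x A [count_dataset()] or counts matrix.
#' @param ref Optional reference column index; default automatic.
#' @return Named per-sample scale factors.
#' @export
tmm_factors <- function(x, ref = NULL) {
  cts <- if (inherits(x, "count_dataset")) x$counts else as.matrix(x)
  if (ncol(cts) < 2L) stop("need at least 2 samples")
  if (any(colSums(cts) == 0)) stop("all-zero sample column")
  f <- edgeR::calcNormFactors(cts, method = "TMM", refColumn = ref)
  if (any(!is.finite(f)))
    stop("TMM failed: a sample shares no expressed gene with the reference")
  stats::setNames(f, colnames(cts))
}

#' Normalized log2 counts per million
#'
#' `log2((count + 0.5) / (libsize * factor + 1) * 1e6)`, the standard
#' offset convention for downstream linear modeling.
#'
#' @param x A [count_dataset()] or counts matrix.
#' @param factors Per-sample normalization factors (e.g. [tmm_factors()]).
#' @return Gene-by-sample matrix of log2-CPM values.
#' @export
logcpm <- function(x, factors) {
  cts <- if (inherits(x, "count_dataset")) x$counts else as.matrix(x)
  stopifnot(length(factors) == ncol(cts), all(factors > 0))
  eff <- colSums(cts) * factors
  log2(sweep(cts + 0.5, 2L, eff + 1, "/") * 1e6)
}

# effective (TMM-scaled) library sizes
effective_libsize <- function(x, factors) {
  cts <- if (inherits(x, "count_dataset")) x$counts else as.matrix(x)
  colSums(cts) * factors
}

#' Observation-level precision weights from the mean-variance trend
#'
#' Fits a gene-wise linear model to the log-CPM matrix, smooths the
#' sqrt-residual-SD against average log2 count with lowess, predicts each
#' observation's SD from the trend at its fitted value, and returns
#' `predicted_sqrt_sd^-4` (i.e. inverse predicted variance) as its weight —
#' strictly positive and nonincreasing in predicted variance.
#'
#' @param lcpm Gene-by-sample log2-CPM matrix (>= 10 genes).
#' @param design_matrix Sample-by-coefficient model matrix (known
#'   covariates included).
#' @param lib_size Effective library sizes (see [effective_libsize()]).
#' @param span Lowess span (default 0.5).
#' @return Gene-by-sample matrix of positive weights.
#' @export
precision_weights <- function(lcpm, design_matrix, lib_size, span = 0.5) {
  lcpm <- as.matrix(lcpm)
  if (nrow(lcpm) < 10L)
    stop("mean-variance trend unidentifiable with fewer than 10 genes")
  X <- as.matrix(design_matrix)
  stopifnot(nrow(X) == ncol(lcpm), length(lib_size) == ncol(lcpm))
  fit <- stats::lm.fit(X, t(lcpm))
  df <- ncol(lcpm) - fit$rank
  if (df < 1L) stop("saturated design: no residual degrees of freedom")
  sdev <- sqrt(colSums(as.matrix(fit$residuals)^2) / df)
  sx <- rowMeans(lcpm) + mean(log2(lib_size + 1)) - log2(1e6)
  sy <- sqrt(sdev)
  lo <- stats::lowess(sx, sy, f = span)
  fitted_lcpm <- t(as.matrix(fit$fitted.values))
  fitted_lcount <- sweep(fitted_lcpm, 2L, log2(lib_size + 1) - log2(1e6), "+")
  pred <- stats::approx(lo$x, lo$y, xout = fitted_lcount, rule = 2,
                        ties = "ordered")$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(pred^-4, nrow(lcpm), ncol(lcpm))
  dimnames(w) <- dimnames(lcpm)
  w
}

#' Surrogate variables from the residual expression matrix
#'
#' Residualizes the log-CPM matrix on the known design (sex, genotype,
#' interaction, covariates) and returns the top `n_sv` sample-side singular
#' vectors of the residual matrix as orthonormal surrogate variables —
#' latent covariates capturing structured technical artifact left in the
#' error term.
#'
#' @param lcpm Gene-by-sample log2-CPM matrix.
#' @param design_matrix Sample-by-coefficient model matrix of known
#'   variables.
#' @param n_sv Number of surrogate variables (default 2); must satisfy
#'   `n_sv < n_samples - rank(design_matrix)`.
#' @return Sample-by-`n_sv` matrix with orthonormal columns (sv1, sv2, ...).
#' @export
estimate_svs <- function(lcpm, design_matrix, n_sv = 2L) {
  lcpm <- as.matrix(lcpm)
  X <- as.matrix(design_matrix)
  rk <- qr(X)$rank
  if (n_sv < 1L || n_sv >= ncol(lcpm) - rk)
    stop("n_sv must be in [1, n_samples - rank(design) - 1] = [1, ",
         ncol(lcpm) - rk - 1L, "]")
  fit <- stats::lm.fit(X, t(lcpm))
  R <- as.matrix(fit$residuals)  # samples x genes
  sv <- svd(R, nu = n_sv, nv = 0)$u
  colnames(sv) <- paste0("sv", seq_len(n_sv))
  sv
}

# model matrix for logcpm ~ genotype * sex + covariates + svs, effect coded
interaction_model_matrix <- function(design, covariates = "RIN", svs = NULL) {
  design <- validate_design(design, require_covariates = covariates)
  codes <- effect_codes(design)
  X <- cbind(intercept = 1, genotype = codes$genotype, sex = codes$sex,
             `genotype:sex` = codes$genotype * codes$sex)
  for (cv in covariates) {
    X <- cbind(X, design[[cv]] - mean(design[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  if (!is.null(svs)) X <- cbind(X, as.matrix(svs))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("model matrix is rank deficient; offending columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]], collapse = ", "))
  X
}

#' Precision-weighted factorial differential-expression fit
#'
#' Per-gene weighted least squares of log-CPM on
#' `genotype * sex + covariates + surrogate variables` with +/-1 effect
#' coding (WT/F = -1, MUT/M = +1). Reports, per gene, the within-male and
#' within-female mutant-vs-wildtype contrasts, the interaction coefficient
#' (half the difference of the two simple effects), two-sided p values from
#' the t distribution at the residual degrees of freedom, and
#' Benjamini-Hochberg q values over the interaction p values. No empirical
#' Bayes variance moderation is applied; the ordinary WLS t is used.
#'
#' @param lcpm Gene-by-sample log2-CPM matrix.
#' @param weights Gene-by-sample positive weights (e.g.
#'   [precision_weights()]); `NULL` for unweighted OLS.
#' @param design Design table with `sex`, `genotype` and the covariates.
#' @param covariates Covariate column names (default `"RIN"`).
#' @param svs Optional sample-by-k surrogate-variable matrix.
#' @return A `de_result` data frame: one row per gene with columns
#'   `gene_id`, `mean_lcpm`, `male_est/t/p`, `female_est/t/p`,
#'   `inter_est/t/p/q`, `class` (set by [classify_interaction()]).
#' @export
fit_interaction <- function(lcpm, weights = NULL, design,
                            covariates = "RIN", svs = NULL) {
  lcpm <- as.matrix(lcpm)
  X <- interaction_model_matrix(design, covariates, svs)
  n <- nrow(X); pcoef <- ncol(X)
  stopifnot(ncol(lcpm) == n)
  if (is.null(weights)) weights <- matrix(1, nrow(lcpm), n)
  weights <- as.matrix(weights)
  stopifnot(identical(dim(weights), dim(lcpm)), all(weights > 0))
  df <- n - pcoef
  if (df < 1L) stop("no residual degrees of freedom")

  # contrasts on (intercept, genotype, sex, genotype:sex, ...):
  # MUT-WT within males = 2*b_g + 2*b_gs; within females = 2*b_g - 2*b_gs
  cons <- rbind(male = c(0, 2, 0, 2, rep(0, pcoef - 4L)),
                female = c(0, 2, 0, -2, rep(0, pcoef - 4L)),
                inter = c(0, 0, 0, 1, rep(0, pcoef - 4L)))

  ng <- nrow(lcpm)
  est <- matrix(NA_real_, ng, 3L, dimnames = list(NULL, rownames(cons)))
  tst <- est
  for (g in seq_len(ng)) {
    w <- weights[g, ]
    sw <- sqrt(w)
    Xw <- X * sw
    yw <- lcpm[g, ] * sw
    qx <- qr(Xw)
    beta <- qr.coef(qx, yw)
    rss <- sum(qr.resid(qx, yw)^2)
    s2 <- rss / df
    XtXi <- chol2inv(qr.R(qx))
    ce <- cons %*% beta
    cv <- rowSums((cons %*% XtXi) * cons) * s2
    est[g, ] <- ce
    tst[g, ] <- ifelse(cv > 0, ce / sqrt(cv),
                       ifelse(ce == 0, 0, sign(ce) * T_CLIP))
  }
  tst <- pmin(pmax(tst, -T_CLIP), T_CLIP)
  pv <- 2 * stats::pt(-abs(tst), df)
  out <- data.frame(
    gene_id = rownames(lcpm) %||% sprintf("gene%d", seq_len(ng)),
    mean_lcpm = rowMeans(lcpm),
    male_est = est[, "male"], male_t = tst[, "male"], male_p = pv[, "male"],
    female_est = est[, "female"], female_t = tst[, "female"],
    female_p = pv[, "female"],
    inter_est = est[, "inter"], inter_t = tst[, "inter"],
    inter_p = pv[, "inter"],
    inter_q = bh_fdr(pv[, "inter"]),
    class = NA_character_,
    row.names = NULL)
  attr(out, "df") <- df
  class(out) <- c("de_result", "data.frame")
  out
}

#' Classify interaction genes by within-sex effect directions
#'
#' Genes whose interaction q value passes `q_thresh` are labelled by the
#' signs of their simple effects: mutant-down in males and mutant-up in
#' females is `M-F+`, the reverse is `M+F-`, same-signed effects are
#' `concordant`, anything else (including all genes above the q threshold)
#' is `NS`.
#'
#' @param d A `de_result` from [fit_interaction()].
#' @param q_thresh FDR threshold (default 0.05).
#' @return The `de_result` with the `class` column filled in.
#' @export
classify_interaction <- function(d, q_thresh = 0.05) {
  stopifnot(inherits(d, "de_result"))
  sig <- d$inter_q < q_thresh
  cls <- rep("NS", nrow(d))
  cls[sig & d$male_est > 0 & d$female_est < 0] <- "M+F-"
  cls[sig & d$male_est < 0 & d$female_est > 0] <- "M-F+"
  cls[sig & sign(d$male_est) == sign(d$female_est) & d$male_est != 0] <- "concordant"
  d$class <- cls
  attr(d, "q_thresh") <- q_thresh
  d
}
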