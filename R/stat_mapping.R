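# |t| ceiling reported when a voxel has zero residual variance
T_CLIP <- 1e6

# stack per-subject maps into subjects x voxels over the common mask;
# voxels with any-subject NaN are excluded from analysis
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 2L, all(vapply(maps, inherits, TRUE, "connectivity_map")))
  mask <- maps[[1]]$mask
  for (m in maps) if (!identical(dim(m$mask), dim(mask)) || !identical(m$mask, mask))
    stop("all maps must share one mask")
  Y <- t(vapply(maps, function(m) m$map[mask], numeric(sum(mask))))
  ok <- colSums(!is.finite(Y)) == 0L
  list(Y = Y[, ok, drop = FALSE], mask = mask, ok = ok)
}

# design matrix with +/-1 effect coding (F/WT = -1, M/MUT = +1)
factorial_design_matrix <- function(design) {
  design <- validate_design(design)
  codes <- effect_codes(design)
  cbind(intercept = 1, sex = codes$sex, genotype = codes$genotype,
        interaction = codes$sex * codes$genotype)
}

# per-voxel OLS t statistics for every column of X; Y is subjects x voxels
glm_tstats <- function(X, Y, Y2 = colSums(Y^2)) {
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  XtY <- crossprod(X, Y)
  B <- XtXi %*% XtY
  df <- nrow(X) - ncol(X)
  rss <- pmax(Y2 - colSums(B * XtY), 0)
  sigma2 <- rss / df
  se <- sqrt(outer(diag(XtXi), sigma2))
  tt <- B / se
  tt[se == 0] <- sign(B[se == 0]) * T_CLIP
  tt[is.na(tt)] <- 0
  tt <- pmin(pmax(tt, -T_CLIP), T_CLIP)
  list(t = tt, beta = B, df = df)
}

#' Voxelwise 2x2 factorial linear model
#'
#' Fits, at every analyzed voxel, an OLS model of the connectivity value on
#' an intercept, sex, genotype and their product, with +/-1 effect coding
#' (F/WT = -1, M/MUT = +1), and returns one t map per contrast. With this
#' coding a positive interaction t means the genotype effect is larger
#' (more positive) in males than in females. Voxels where any subject is
#' `NaN` are excluded; zero-residual voxels report |t| clipped at `1e6`.
#'
#' @param maps List of [connectivity_map()]s, one per subject, sharing one mask.
#' @param design Design table with `subject`, `sex`, `genotype` matching the
#'   map order.
#' @return A named list of `stat_map` objects (`sex`, `genotype`,
#'   `interaction`), each with fields `map` (3D t values, `NaN` where not
#'   analyzed), `df`, `contrast`, and `analyzed` (logical 3D).
#' @export
voxelwise_glm <- function(maps, design) {
  design <- validate_design(design)
  if (length(maps) != nrow(design)) stop("one map per design row required")
  tab <- table(design$sex, design$genotype)
  if (any(tab < 2L))
    stop("interaction model refused: every sex x genotype cell needs >= 2 subjects; ",
         "cell counts: ", paste(tab, collapse = ", "))
  st <- stack_maps(maps)
  X <- factorial_design_matrix(design)
  fit <- glm_tstats(X, st$Y)
  analyzed <- st$mask
  analyzed[st$mask] <- st$ok
  out <- lapply(c(sex = "sex", genotype = "genotype", interaction = "interaction"),
                function(con) {
    m3 <- array(NaN, dim(st$mask))
    m3[analyzed] <- fit$t[con, ]
    structure(list(map = m3, df = fit$df, contrast = con, analyzed = analyzed),
              class = "stat_map")
  })
  out
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$map[x$analyzed]
  cat(sprintf("<stat_map> %s: df=%d, %d voxels, max|t|=%.2f\n",
              x$contrast, x$df, length(v), max(abs(v))))
  invisible(x)
}

# neighbor offsets for 6/18/26 connectivity
conn_offsets <- function(connectivity = 6L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  n2 <- rowSums(g^2)
  lim <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3,
                stop("connectivity must be 6, 18 or 26"))
  g[n2 > 0 & n2 <= lim, , drop = FALSE]
}

# label connected components among `which_vox` (linear indices into dims);
# returns a list of integer vectors (one per component)
label_clusters <- function(which_vox, dims, connectivity = 6L) {
  if (!length(which_vox)) return(list())
  offs <- conn_offsets(connectivity)
  shift <- offs[, 1] + dims[1] * offs[, 2] + dims[1] * dims[2] * offs[, 3]
  coord <- arrayInd(which_vox, dims)
  inset <- integer(prod(dims))
  inset[which_vox] <- seq_along(which_vox)
  labels <- integer(length(which_vox))
  comps <- list()
  for (s in seq_along(which_vox)) {
    if (labels[s]) next
    lab <- length(comps) + 1L
    queue <- s
    labels[s] <- lab
    members <- integer(0)
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      members <- c(members, cur)
      for (o in seq_len(nrow(offs))) {
        nc <- coord[cur, , drop = FALSE] +
          matrix(offs[o, ], length(cur), 3, byrow = TRUE)
        ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
          nc[, 2] >= 1 & nc[, 2] <= dims[2] &
          nc[, 3] >= 1 & nc[, 3] <= dims[3]
        if (!any(ok)) next
        nb <- inset[which_vox[cur[ok]] + shift[o]]
        nb <- nb[nb > 0L]
        nb <- nb[labels[nb] == 0L]
        if (length(nb)) {
          nb <- unique(nb)
          labels[nb] <- lab
          queue <- c(queue, nb)
        }
      }
    }
    comps[[lab]] <- which_vox[members]
  }
  comps
}

# half set of neighbor offsets (one per unordered pair direction)
half_offsets <- function(connectivity) {
  g <- conn_offsets(connectivity)
  g[g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0), , drop = FALSE]
}

# largest connected-component size among `vox` (sorted linear indices) via
# union-find over neighbor pairs; fast path for the permutation null
largest_component <- function(vox, dims, connectivity = 6L) {
  n <- length(vox)
  if (n <= 1L) return(n)
  offs <- half_offsets(connectivity)
  x <- (vox - 1L) %% dims[1] + 1L
  rest <- (vox - 1L) %/% dims[1]
  y <- rest %% dims[2] + 1L
  z <- rest %/% dims[2] + 1L
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    ok <- x + d[1] >= 1L & x + d[1] <= dims[1] &
      y + d[2] >= 1L & y + d[2] <= dims[2] &
      z + d[3] >= 1L & z + d[3] <= dims[3]
    if (!any(ok)) next
    shift <- d[1] + dims[1] * d[2] + dims[1] * dims[2] * d[3]
    j <- match(vox[ok] + shift, vox)
    hit <- which(!is.na(j))
    if (!length(hit)) next
    ii <- which(ok)[hit]; jj <- j[hit]
    for (k in seq_along(ii)) {
      ri <- find(ii[k]); rj <- find(jj[k])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  max(tabulate(roots))
}

# max component size among supra-threshold voxels (pos/neg handled separately)
max_cluster_extent <- function(tvals, lin_idx, t_thresh, dims, connectivity) {
  ext <- 0L
  for (sgn in c(1, -1)) {
    vox <- lin_idx[sgn * tvals > t_thresh]
    if (length(vox) > ext)
      ext <- max(ext, largest_component(vox, dims, connectivity))
  }
  ext
}

# exchangeability-respecting permutations: shuffle the tested factor within
# strata of the other factor (Freedman-Lane-style restricted permutation)
permute_design <- function(design, contrast) {
  d <- design
  if (contrast %in% c("interaction", "genotype")) {
    for (sx in levels(d$sex)) {
      idx <- which(d$sex == sx)
      d$genotype[idx] <- d$genotype[sample(idx)]
    }
  } else if (contrast == "sex") {
    for (gt in levels(d$genotype)) {
      idx <- which(d$genotype == gt)
      d$sex[idx] <- d$sex[sample(idx)]
    }
  } else stop("unknown contrast: ", contrast)
  d
}

#' Cluster-extent familywise error correction by restricted permutation
#'
#' Forms clusters of supra-threshold voxels (`|t| > t_thresh`, positive and
#' negative tails separately, face/6-neighbor connectivity by default) on an
#' observed t map, and corrects their extents against the permutation null
#' distribution of the maximum cluster extent. Permutations respect
#' exchangeability: the tested factor is shuffled within strata of the other
#' factor (for the interaction and genotype contrasts, genotype is permuted
#' within sex; for sex, within genotype). Corrected
#' p = (1 + #\{perm max >= extent\}) / (1 + n_perm).
#'
#' @param tmap A `stat_map` from [voxelwise_glm()].
#' @param maps,design The subject maps and design used to build `tmap`.
#' @param t_thresh Cluster-forming threshold on |t| (default 2.1).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed making the permutation stream reproducible.
#' @param connectivity Voxel neighborhood: 6 (faces, default), 18 or 26.
#' @return An object of class `cluster_result`: data frame `clusters`
#'   (cluster id, sign, extent, peak |t|, corrected p) with voxel lists in
#'   `attr(, "voxels")`, plus the null max-extent distribution and the
#'   parameters used.
#' @export
cluster_fwer <- function(tmap, maps, design, t_thresh = 2.1, n_perm = 1000L,
                         seed = 1L, connectivity = 6L) {
  stopifnot(inherits(tmap, "stat_map"))
  if (t_thresh <= 0) stop("t_thresh must be positive")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  design <- validate_design(design)
  st <- stack_maps(maps)
  dims <- dim(st$mask)
  lin_idx <- which(st$mask)[st$ok]
  Y <- st$Y
  Y2 <- colSums(Y^2)
  con <- tmap$contrast

  # observed clusters, positive and negative tails separately
  tv <- tmap$map[st$mask][st$ok]
  clusters <- list()
  for (sgn in c(1, -1)) {
    vox <- lin_idx[sgn * tv > t_thresh]
    for (comp in label_clusters(vox, dims, connectivity)) {
      clusters[[length(clusters) + 1L]] <-
        list(sign = sgn, voxels = comp, extent = length(comp),
             peak_t = max(abs(tmap$map[comp])))
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    Xp <- factorial_design_matrix(permute_design(design, con))
    tp <- glm_tstats(Xp, Y, Y2)$t[con, ]
    null_max[p] <- max_cluster_extent(tp, lin_idx, t_thresh, dims, connectivity)
  }

  if (length(clusters)) {
    tab <- data.frame(
      cluster = seq_along(clusters),
      sign = vapply(clusters, `[[`, 0, "sign"),
      extent = vapply(clusters, `[[`, 0L, "extent"),
      peak_t = vapply(clusters, `[[`, 0, "peak_t"))
    tab$p_fwer <- vapply(tab$extent,
                         function(e) (1 + sum(null_max >= e)) / (1 + n_perm), 0)
    tab <- tab[order(tab$p_fwer, -tab$extent), , drop = FALSE]
    tab$cluster <- seq_len(nrow(tab))
    voxlist <- lapply(clusters, `[[`, "voxels")[as.integer(rownames(tab))]
  } else {
    tab <- data.frame(cluster = integer(0), sign = numeric(0),
                      extent = integer(0), peak_t = numeric(0),
                      p_fwer = numeric(0))
    voxlist <- list()
  }
  rownames(tab) <- NULL
  structure(list(clusters = tab, voxels = voxlist, null_max = null_max,
                 contrast = con, t_thresh = t_thresh, n_perm = n_perm,
                 seed = seed, connectivity = connectivity),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s: |t| > %g, %d permutations\n",
              x$contrast, x$t_thresh, x$n_perm))
  print(x$clusters)
  invisible(x)
}

#' Two-sample pooled-variance t test on ROI scores
#'
#' @param scores_g1,scores_g2 Numeric vectors (each length >= 2).
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
roi_ttest <- function(scores_g1, scores_g2) {
  if (length(scores_g1) < 2L || length(scores_g2) < 2L)
    stop("each group needs >= 2 observations")
  if (stats::var(scores_g1) == 0 && stats::var(scores_g2) == 0)
    stop("zero pooled variance")
  ht <- stats::t.test(scores_g1, scores_g2, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Two-way factorial ANOVA with optional Tukey post hoc tests
#'
#' Type-II sums of squares for sex, genotype and their interaction (equal to
#' Type-I/III under balance), with Tukey HSD pairwise comparisons of the
#' four cell means on request.
#'
#' @param values Numeric response, one per design row.
#' @param design Design table (`sex`, `genotype`).
#' @param tukey Also compute Tukey HSD over the four cells?
#' @return List with `F` and `p` (named vectors: sex, genotype,
#'   interaction), `df`, and optionally `tukey` (the `TukeyHSD` table).
#' @export
factorial_anova <- function(values, design, tukey = FALSE) {
  design <- validate_design(design)
  if (length(values) != nrow(design)) stop("one value per design row required")
  if (any(table(design$sex, design$genotype) < 1L))
    stop("every sex x genotype cell needs at least one observation")
  dat <- data.frame(y = values, sex = design$sex, genotype = design$genotype)
  fit <- stats::lm(y ~ sex * genotype, data = dat)
  rows <- c(sex = "sex", genotype = "genotype", interaction = "sex:genotype")
  rss <- sum(stats::residuals(fit)^2)
  tot <- sum((values - mean(values))^2)
  if (rss <= 1e-12 * max(tot, 1)) {
    # zero residual variance: car::Anova refuses; fall back to the
    # sequential decomposition (equal under balance) with the policy
    # F = 0 for zero-SS effects, clipped-max otherwise
    a1 <- suppressWarnings(stats::anova(fit))
    ss <- stats::setNames(a1[rows, "Sum Sq"], names(rows))
    tol <- 1e-10 * max(tot, 1)
    Fv <- ifelse(ss <= tol, 0, T_CLIP)
    pv <- ifelse(ss <= tol, 1, 0)
    a2 <- a1
  } else {
    a2 <- car::Anova(fit, type = 2)
    Fv <- stats::setNames(a2[rows, "F value"], names(rows))
    pv <- stats::setNames(a2[rows, "Pr(>F)"], names(rows))
  }
  out <- list(F = Fv, p = pv,
              df = c(effect = 1, residual = a2["Residuals", "Df"]))
  if (tukey) {
    dat$cell <- interaction(dat$sex, dat$genotype, sep = ":")
    out$tukey <- stats::TukeyHSD(stats::aov(y ~ cell, data = dat))$cell
  }
  out
}
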