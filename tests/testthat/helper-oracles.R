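# Independent reference implementations used as oracles. These deliberately
# use naive double loops / direct formulas so they share no code path with
# the package.

Z_CLIP <- atanh(1 - 1e-7)

clip_z <- function(r) atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))

# brute-force global degree centrality: double loop over voxel pairs
brute_global <- function(tc) {
  V <- ncol(tc)
  out <- numeric(V)
  for (i in seq_len(V)) {
    zs <- c()
    for (j in seq_len(V)) {
      if (i == j) next
      zs <- c(zs, clip_z(stats::cor(tc[, i], tc[, j])))
    }
    out[i] <- mean(zs)
  }
  out
}

# brute-force local connectivity over coordinates within `radius`
brute_local <- function(tc, coords, radius) {
  V <- ncol(tc)
  out <- rep(NaN, V)
  for (i in seq_len(V)) {
    zs <- c()
    for (j in seq_len(V)) {
      if (i == j) next
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius)
        zs <- c(zs, clip_z(stats::cor(tc[, i], tc[, j])))
    }
    if (length(zs)) out[i] <- mean(zs)
  }
  out
}

# brute-force seed map from an explicit seed time course
brute_seed <- function(tc, seed_tc) {
  vapply(seq_len(ncol(tc)), function(i) clip_z(stats::cor(seed_tc, tc[, i])),
         numeric(1))
}

# independent TMM: reference sample by upper-quartile rule, doubly trimmed
# (30% of M, 5% of A) precision-weighted mean of M values, geometric mean 1
brute_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)),
               function(j) stats::quantile(counts[, j] / lib[j], 0.75), 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j] / lib[j]
    rf <- counts[, ref] / lib[ref]
    keep <- obs > 0 & rf > 0
    M <- log2(obs[keep] / rf[keep])
    if (!length(M) || max(abs(M)) < 1e-6) return(1)  # pure depth difference
    A <- 0.5 * log2(obs[keep] * rf[keep])
    # delta-method variance of M; the trimmed mean is precision-weighted
    v <- (lib[j] - counts[keep, j]) / (lib[j] * counts[keep, j]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    sel <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
  }, 0)
  f / exp(mean(log(f)))
}

# hypergeometric upper tail by explicit enumeration over overlap counts
enum_hyper_p <- function(N, K, n, a) {
  ks <- a:min(K, n)
  ks <- ks[n - ks <= N - K]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# two-way ANOVA by explicit sums-of-squares decomposition (balanced)
brute_anova <- function(y, f1, f2) {
  gm <- mean(y)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  mc <- tapply(y, interaction(f1, f2), mean)
  n_cell <- table(f1, f2)[1, 1]
  ss1 <- sum(table(f1) * (m1 - gm)^2)
  ss2 <- sum(table(f2) * (m2 - gm)^2)
  sscells <- n_cell * sum((mc - gm)^2)
  ss12 <- sscells - ss1 - ss2
  sse <- sum((y - ave(y, interaction(f1, f2)))^2)
  dfe <- length(y) - 4
  list(F1 = (ss1 / 1) / (sse / dfe), F2 = (ss2 / 1) / (sse / dfe),
       F12 = (ss12 / 1) / (sse / dfe), dfe = dfe)
}

# interaction t from the explicit balanced cell-means contrast:
# t = (m11 - m10 - m01 + m00) / sqrt(s2_pooled * sum(1/n_cell)) (quarter scale
# matches the effect-coded coefficient; t is identical)
brute_interaction_t <- function(y, sex, genotype) {
  cells <- split(y, interaction(sex, genotype))
  m <- vapply(cells, mean, 0)
  v <- vapply(cells, function(x) sum((x - mean(x))^2), 0)
  n <- vapply(cells, length, 0L)
  s2 <- sum(v) / (length(y) - 4)
  est <- m["M.MUT"] - m["F.MUT"] - m["M.WT"] + m["F.WT"]
  unname(est / sqrt(s2 * sum(1 / n)))
}

# small helper: a ready-made toy 2x2 design
toy_design <- function(n_per_cell = 3, rin = FALSE) {
  d <- data.frame(
    subject = sprintf("t%02d", seq_len(4 * n_per_cell)),
    sex = rep(c("F", "M", "F", "M"), each = n_per_cell),
    genotype = rep(c("WT", "WT", "MUT", "MUT"), each = n_per_cell))
  if (rin) d$RIN <- seq(7, 9, length.out = nrow(d))
  d
}

# wrap a time-course matrix (t x V) as a bold_series on a flat grid
tc_as_bold <- function(tc, dims = NULL, tr_s = 1) {
  V <- ncol(tc)
  if (is.null(dims)) dims <- c(V, 1L, 1L)
  bold_series(array(t(tc), c(dims, nrow(tc))), tr_s = tr_s)
}
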