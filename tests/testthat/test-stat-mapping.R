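make_maps <- function(values_mat, dims = c(2L, 2L, 1L)) {
  # values_mat: subjects x voxels
  lapply(seq_len(nrow(values_mat)), function(i) {
    connectivity_map(array(values_mat[i, ], dims), "seed",
                     array(TRUE, dims), sprintf("s%02d", i))
  })
}

test_that("constant maps give zero t everywhere", {
  d <- toy_design(3)
  maps <- make_maps(matrix(5, 12, 4))
  st <- voxelwise_glm(maps, d)
  expect_true(all(st$sex$map == 0))
  expect_true(all(st$interaction$map == 0))
  expect_equal(st$interaction$df, 8)
})

test_that("a pure noiseless interaction pattern reports the clipped max t", {
  d <- toy_design(3)
  v <- ifelse(d$sex == "M" & d$genotype == "MUT", 1, 0)
  st <- voxelwise_glm(make_maps(matrix(v, 12, 4)), d)
  expect_true(all(st$interaction$map == 1e6))
})

test_that("voxelwise t equals the explicit cell-means oracle", {
  set.seed(20)
  d <- toy_design(5)
  means <- ifelse(d$sex == "M", 0.3, 0) + ifelse(d$genotype == "MUT", 0.2, 0) +
    ifelse(d$sex == "M" & d$genotype == "MUT", 0.4, 0)
  Y <- matrix(rnorm(20 * 200), 20) + means
  st <- voxelwise_glm(make_maps(Y, dims = c(10L, 10L, 2L)), d)
  t_oracle <- apply(Y, 2, brute_interaction_t, sex = d$sex,
                    genotype = d$genotype)
  expect_lt(max(abs(st$interaction$map[st$interaction$analyzed] - t_oracle)),
            1e-8)
  # squared interaction t equals the two-way ANOVA F (balanced design)
  for (j in c(1, 50, 200)) {
    a <- factorial_anova(Y[, j], d)
    expect_equal(st$interaction$map[st$interaction$analyzed][j]^2,
                 unname(a$F["interaction"]), tolerance = 1e-8)
  }
})

test_that("NaN voxels are excluded and empty cells are refused", {
  d <- toy_design(2)
  Y <- matrix(rnorm(8 * 4), 8)
  Y[3, 2] <- NaN
  st <- voxelwise_glm(make_maps(Y), d)
  expect_true(is.nan(st$interaction$map[2, 1, 1]))
  expect_equal(sum(st$interaction$analyzed), 3L)
  bad <- d; bad$genotype <- "WT"
  expect_error(voxelwise_glm(make_maps(Y), bad), "cell")
})

test_that("cluster correction behaves at the edges and is monotone", {
  set.seed(21)
  d <- toy_design(3)
  dims <- c(6L, 6L, 2L)
  Y <- matrix(rnorm(12 * prod(dims), sd = 0.1), 12)
  maps <- make_maps(Y, dims)
  st <- voxelwise_glm(maps, d)
  # an absurd threshold yields no clusters
  clh <- cluster_fwer(st$interaction, maps, d, t_thresh = 50, n_perm = 100,
                      seed = 3)
  expect_equal(nrow(clh$clusters), 0L)
  cl <- cluster_fwer(st$interaction, maps, d, t_thresh = 1.5, n_perm = 120,
                     seed = 3)
  if (nrow(cl$clusters)) {
    expect_true(all(cl$clusters$p_fwer >= 1 / 121))
    expect_true(all(cl$clusters$p_fwer <= 1))
    # corrected p nonincreasing in extent
    ord <- order(cl$clusters$extent)
    expect_true(all(diff(cl$clusters$p_fwer[ord]) <= 0))
  }
  expect_error(cluster_fwer(st$interaction, maps, d, t_thresh = 0), "positive")
  expect_error(cluster_fwer(st$interaction, maps, d, n_perm = 10), "100")
  # determinism: same seed, same result
  cl2 <- cluster_fwer(st$interaction, maps, d, t_thresh = 1.5, n_perm = 120,
                      seed = 3)
  expect_identical(cl$clusters, cl2$clusters)
  expect_identical(cl$null_max, cl2$null_max)
})

test_that("restricted permutations preserve cell counts", {
  d <- toy_design(4)
  set.seed(22)
  for (i in 1:20) {
    p <- dimorph:::permute_design(d, "interaction")
    expect_identical(table(p$sex, p$genotype), table(d$sex, d$genotype))
    expect_identical(p$sex, d$sex)  # sex untouched for genotype shuffles
    p2 <- dimorph:::permute_design(d, "sex")
    expect_identical(p2$genotype, d$genotype)
  }
})

test_that("cluster labelling agrees between BFS and union-find", {
  dims <- c(9L, 7L, 5L)
  set.seed(23)
  for (conn in c(6L, 18L, 26L)) {
    for (i in 1:10) {
      vox <- sort(sample(prod(dims), 60))
      comps <- dimorph:::label_clusters(vox, dims, conn)
      expect_setequal(unlist(comps), vox)
      expect_equal(max(lengths(comps)),
                   dimorph:::largest_component(vox, dims, conn))
    }
  }
  # face connectivity does not bridge diagonal neighbors
  two_diag <- c(1L, 9L + 2L)  # (1,1,1) and (2,2,1)
  expect_length(dimorph:::label_clusters(two_diag, dims, 6L), 2L)
  expect_length(dimorph:::label_clusters(two_diag, dims, 18L), 1L)
})

test_that("pooled t test matches its closed form and symmetries", {
  r <- roi_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  rs <- roi_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)
  ident <- roi_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(roi_ttest(c(1, 1), c(1, 1)), "variance")
  expect_error(roi_ttest(1, c(1, 2)), ">= 2")
})

test_that("two-way ANOVA matches brute-force sums of squares", {
  d <- toy_design(2)
  # noiseless toy: one cell elevated, residual SS = 0, every effect SS > 0
  # -> all F values at the clipped ceiling (the brute decomposition has
  # sse = 0, F = Inf)
  y0 <- c(0, 0, 0, 0, 0, 0, 1, 1)
  a0 <- factorial_anova(y0, d, tukey = TRUE)
  o0 <- brute_anova(y0, d$sex, d$genotype)
  expect_true(all(o0$F12 == Inf, o0$F1 == Inf))
  expect_equal(unname(a0$F), rep(1e6, 3))
  expect_equal(unname(a0$p), rep(0, 3))
  expect_equal(nrow(a0$tukey), 6L)
  # noisy balanced toy: F values equal the explicit SS decomposition
  set.seed(24)
  y <- c(0, 0.2, 0.1, 0, 0.05, 0, 1, 1.4) + rnorm(8, sd = 0.1)
  a <- factorial_anova(y, d)
  o <- brute_anova(y, d$sex, d$genotype)
  expect_equal(unname(a$F["sex"]), o$F1, tolerance = 1e-10)
  expect_equal(unname(a$F["genotype"]), o$F2, tolerance = 1e-10)
  expect_equal(unname(a$F["interaction"]), o$F12, tolerance = 1e-10)
  # scale invariance of F
  a2 <- factorial_anova(2 * y, d)
  expect_equal(a$F, a2$F, tolerance = 1e-10)
  # additive cell means with zero noise: no interaction
  add <- ifelse(d$sex == "M", 1, 0) + ifelse(d$genotype == "MUT", 2, 0)
  a3 <- factorial_anova(add, d)
  expect_equal(unname(a3$F["interaction"]), 0)
})
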