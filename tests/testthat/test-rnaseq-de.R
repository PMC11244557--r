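toy_dataset <- function(counts, n_per_cell = NULL) {
  ns <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ns))
  stopifnot(ns %% 4 == 0)
  d <- toy_design(ns / 4, rin = TRUE)
  d$subject <- colnames(counts)
  count_dataset(counts, data.frame(gene_id = rownames(counts),
                                   chrom = "chr1", human_homolog = ""), d)
}

test_that("read filter drops low-count genes; thresholds are as documented", {
  counts <- rbind(a = rep(1000L, 8), b = rep(0L, 8),
                  c = c(rep(1000L, 7), 5L), d = c(rep(1000L, 6), 5L, 5L))
  ds <- toy_dataset(counts)
  kept <- suppressMessages(filter_genes(ds, min_reads = 100, min_samples = 2,
                                        var_quantile = 0))
  # b fails everywhere; d fails in exactly 2 samples; c fails in only 1
  expect_setequal(rownames(kept$counts), c("a", "c"))
  expect_error(suppressMessages(
    filter_genes(ds, min_reads = 1e7, min_samples = 1, var_quantile = 0)),
    "all genes")
  expect_equal(formals(filter_genes)$min_reads, 100L)
  expect_equal(formals(filter_genes)$min_samples, 2L)
  expect_equal(formals(filter_genes)$var_quantile, 0.15)
})

test_that("variance filter drops the exact quantile with stable tie-break", {
  set.seed(30)
  # 100 genes with identical counts up to a column permutation -> identical
  # log-CPM variance; the tie-break keeps the lexicographically first 85
  base <- rpois(8, 500) + 200L
  counts <- t(vapply(1:100, function(i) base, integer(8)))
  rownames(counts) <- sprintf("g%03d", 1:100)
  ds <- toy_dataset(counts)
  kept <- suppressMessages(filter_genes(ds, min_reads = 0, min_samples = 9,
                                        var_quantile = 0.15))
  expect_equal(nrow(kept$counts), 85L)
  expect_identical(rownames(kept$counts), sprintf("g%03d", 16:100))
})

test_that("TMM factors: identity, pure depth, and the brute-force oracle", {
  m <- matrix(c(100L, 200L, 300L, 50L, 400L), 5, 3)
  m[, 2] <- m[, 1]; m[, 3] <- m[, 1]
  expect_equal(unname(tmm_factors(m)), c(1, 1, 1))
  m2 <- cbind(s1 = c(100L, 200L, 300L, 50L, 400L),
              s2 = 2L * c(100L, 200L, 300L, 50L, 400L))
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
  set.seed(31)
  for (i in 1:10) {
    toy <- matrix(rpois(15, lambda = sample(c(50, 200, 1000), 15,
                                            replace = TRUE)) + 1L, 5, 3)
    expect_equal(unname(tmm_factors(toy)), unname(brute_tmm(toy)),
                 tolerance = 1e-6)
  }
  expect_error(tmm_factors(matrix(1L, 3, 1)), "2 samples")
  expect_error(tmm_factors(cbind(c(1L, 2L), c(0L, 0L))), "all-zero")
})

test_that("log-CPM follows the offset convention exactly", {
  cts <- matrix(0L, 1, 1, dimnames = list("g1", "s1"))
  # libsize counted from the matrix itself is 0 here, so build explicitly
  cts2 <- rbind(g1 = c(0L), g2 = c(1000000L))
  colnames(cts2) <- "s1"
  lc <- logcpm(cts2, factors = 1)
  expect_equal(lc["g1", 1], log2(0.5 / 1000001 * 1e6), tolerance = 1e-9)
  expect_equal(lc["g1", 1], -1.0000014, tolerance = 1e-4)
  # doubling all counts of every gene leaves CPM invariant (~)
  set.seed(32)
  cts3 <- matrix(rpois(40, 800) + 100L, 10, 4)
  l1 <- logcpm(cts3, rep(1, 4))
  l2 <- logcpm(2L * cts3, rep(1, 4))
  expect_lt(max(abs(l2 - l1)), 2e-3)
  # equal counts and libsizes give constant rows
  cts4 <- matrix(rep(c(100L, 900L), each = 3), 2, 3, byrow = TRUE)
  lr <- logcpm(cts4, rep(1, 3))
  expect_equal(unname(apply(lr, 1, var)), c(0, 0))
})

test_that("precision weights are positive and track the variance trend", {
  set.seed(33)
  d <- toy_design(5, rin = TRUE)
  X <- dimorph:::interaction_model_matrix(d)
  ns <- nrow(d)
  # homoskedastic: variance unrelated to mean -> near-flat weights
  lcpm <- matrix(rnorm(400 * ns, mean = rep(runif(400, 2, 10), ns), sd = 0.5),
                 400, ns)
  w <- precision_weights(lcpm, X, rep(2e6, ns))
  expect_true(all(w > 0))
  expect_lt(sd(w) / mean(w), 0.2)
  # planted decreasing mean-variance trend: weights track true precision
  for (s in 1:3) {
    set.seed(s)
    mu <- runif(500, 2, 12)
    sdv <- 1.5 - 0.1 * mu
    lcpm2 <- matrix(rnorm(500 * ns, mean = rep(mu, ns), sd = rep(sdv, ns)),
                    500, ns)
    w2 <- precision_weights(lcpm2, X, rep(2e6, ns))
    expect_gt(cor(rowMeans(w2), 1 / sdv^2, method = "spearman"), 0.8)
  }
  expect_error(precision_weights(lcpm[1:5, ], X, rep(2e6, ns)), "10 genes")
})

test_that("precision weights agree with limma voom on NB data", {
  sim <- simulate_counts(counts_sim_spec(n_genes = 600, n_per_cell = 5,
                                         seed = 34))
  ds <- suppressMessages(filter_genes(
    count_dataset(sim$counts, sim$genes, sim$design)))
  f <- tmm_factors(ds)
  lc <- logcpm(ds, f)
  X <- dimorph:::interaction_model_matrix(ds$design)
  w <- precision_weights(lc, X, dimorph:::effective_libsize(ds, f))
  v <- limma::voom(ds$counts, X, lib.size = dimorph:::effective_libsize(ds, f))
  expect_gt(cor(as.vector(w), as.vector(v$weights)), 0.95)
  expect_lt(max(abs(lc - v$E)), 1e-10)
})

test_that("surrogate variables are orthonormal and bounded by the design", {
  set.seed(35)
  d <- toy_design(5, rin = TRUE)
  X <- dimorph:::interaction_model_matrix(d)
  lcpm <- matrix(rnorm(300 * 20), 300, 20)
  sv <- estimate_svs(lcpm, X, 2)
  expect_equal(crossprod(sv), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(estimate_svs(lcpm, X, 15), "n_sv")
})

test_that("a planted balanced artifact is recovered by sv1", {
  r <- suppressMessages(sv_recovery_study(seed = 1))
  expect_gt(r$r, 0.9)
})

test_that("weighted fit reduces to OLS under equal weights and matches limma", {
  sim <- simulate_counts(counts_sim_spec(n_genes = 120, n_per_cell = 4,
                                         seed = 36))
  ds <- count_dataset(sim$counts, sim$genes, sim$design)
  f <- tmm_factors(ds)
  lc <- logcpm(ds, f)
  de_w1 <- fit_interaction(lc, matrix(1, nrow(lc), ncol(lc)), ds$design)
  de_null <- fit_interaction(lc, NULL, ds$design)
  expect_equal(de_w1$inter_est, de_null$inter_est, tolerance = 1e-10)
  expect_equal(de_w1$inter_t, de_null$inter_t, tolerance = 1e-10)
  # independent route: limma lmFit with ordinary (unmoderated) t
  X <- dimorph:::interaction_model_matrix(ds$design)
  fit <- limma::lmFit(lc, X)
  t_limma <- (fit$coefficients / (fit$stdev.unscaled * fit$sigma))[, "genotype:sex"]
  expect_equal(unname(de_null$inter_t), unname(t_limma), tolerance = 1e-8)
  expect_equal(unname(de_null$inter_est),
               unname(fit$coefficients[, "genotype:sex"]), tolerance = 1e-10)
})

test_that("pure interaction patterns produce the documented contrasts", {
  d <- toy_design(3, rin = TRUE)
  d$RIN <- rep(c(7, 8, 9), 4)        # identical within-cell covariate
  dlt <- 1
  y <- ifelse(d$genotype == "MUT" & d$sex == "M", dlt,
              ifelse(d$genotype == "MUT" & d$sex == "F", -dlt, 0))
  lcpm <- matrix(rep(y, each = 20), 20, 12, byrow = FALSE)
  rownames(lcpm) <- sprintf("g%02d", 1:20)
  de <- fit_interaction(lcpm, NULL, d, covariates = "RIN")
  expect_equal(de$male_est, rep(dlt, 20), tolerance = 1e-10)
  expect_equal(de$female_est, rep(-dlt, 20), tolerance = 1e-10)
  expect_equal(abs(de$inter_t), rep(1e6, 20))
})

test_that("sample order does not affect the fitted results", {
  sim <- simulate_counts(counts_sim_spec(n_genes = 150, n_per_cell = 3,
                                         seed = 37))
  ds <- count_dataset(sim$counts, sim$genes, sim$design)
  f <- tmm_factors(ds)
  lc <- logcpm(ds, f)
  de1 <- fit_interaction(lc, NULL, ds$design)
  set.seed(38)
  perm <- sample(ncol(lc))
  de2 <- fit_interaction(lc[, perm], NULL, ds$design[perm, ])
  expect_equal(de1$inter_t, de2$inter_t, tolerance = 1e-10)
  expect_equal(de1$male_est, de2$male_est, tolerance = 1e-10)
})

test_that("class labels follow the simple-effect sign rules", {
  d <- structure(data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    male_est = c(-1, 0.5, 1, -1), female_est = c(1, 0.1, -1, 1),
    inter_q = c(0.001, 0.01, 0.2, 0.04)),
    class = c("de_result", "data.frame"))
  out <- classify_interaction(d, 0.05)
  expect_equal(out$class, c("M-F+", "concordant", "NS", "M-F+"))
  # the class invariant: non-NS implies q below threshold
  expect_true(all(out$inter_q[out$class != "NS"] < 0.05))
})

test_that("duplicate genes and design mismatches are rejected", {
  cts <- matrix(1L, 2, 4, dimnames = list(c("g1", "g1"),
                                          sprintf("s%02d", 1:4)))
  d <- toy_design(1, rin = TRUE)
  d$subject <- sprintf("s%02d", 1:4)
  expect_error(count_dataset(cts, data.frame(gene_id = "g1"), d), "duplicate")
  cts2 <- matrix(1L, 2, 4, dimnames = list(c("g1", "g2"),
                                           sprintf("x%02d", 1:4)))
  expect_error(count_dataset(cts2,
                             data.frame(gene_id = c("g1", "g2")), d),
               "differ")
})
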