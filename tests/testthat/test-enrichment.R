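bg20 <- gene_set(sprintf("g%02d", 1:20), "bg")

test_that("homolog mapping translates, drops and deduplicates", {
  tab <- data.frame(mouse_id = c("a", "b", "c"),
                    human_id = c("A", "B", "C"))
  gs <- gene_set(c("a", "b", "c"), "s")
  expect_setequal(map_homologs(gs, tab)$ids, c("A", "B", "C"))
  # identity table
  id_tab <- data.frame(mouse_id = c("a", "b"), human_id = c("a", "b"))
  expect_setequal(map_homologs(gene_set(c("a", "b"), "s"), id_tab)$ids,
                  c("a", "b"))
  # 3 genes, 2 mapped -> size 2 and a log line
  expect_message(
    out <- map_homologs(gene_set(c("a", "b", "zzz"), "s"), tab),
    "1 of 3")
  expect_length(out$ids, 2L)
  # many-to-one collapses
  m2o <- data.frame(mouse_id = c("a", "b"), human_id = c("X", "X"))
  expect_equal(map_homologs(gene_set(c("a", "b"), "s"), m2o)$ids, "X")
  expect_error(map_homologs(gs, tab[0, ]), "empty")
})

test_that("the worked hypergeometric example matches its enumeration", {
  q <- gene_set(sprintf("g%02d", 1:8), "q")
  l <- gene_set(sprintf("g%02d", c(1:4, 15)), "l")
  r <- hypergeom_enrich(q, l, bg20)
  expect_equal(r$overlap, 4L)
  manual <- sum(choose(5, 4:5) * choose(15, 8 - (4:5))) / choose(20, 8)
  expect_equal(r$p, manual, tolerance = 1e-12)
  expect_equal(r$p, enum_hyper_p(20, 5, 8, 4), tolerance = 1e-12)
})

test_that("hypergeometric p equals exact enumeration across configurations", {
  for (N in c(10L, 17L, 30L)) {
    bg <- gene_set(sprintf("x%02d", 1:N), "bg")
    for (K in c(1L, N %/% 3, N %/% 2, N - 1L)) {
      for (n in c(1L, N %/% 4, N %/% 2, N)) {
        for (a in unique(c(0L, 1L, min(K, n) %/% 2, min(K, n)))) {
          if (a > min(K, n) || n - a > N - K) next
          # construct sets realizing exactly this overlap
          qids <- c(sprintf("x%02d", seq_len(a)),
                    sprintf("x%02d", K + seq_len(n - a)))
          lids <- sprintf("x%02d", seq_len(K))
          if (!length(qids)) next
          r <- hypergeom_enrich(gene_set(qids, "q"), gene_set(lids, "l"), bg)
          expect_equal(r$p, enum_hyper_p(N, K, n, a), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("zero overlap and degenerate tables follow the stated policies", {
  q <- gene_set(sprintf("g%02d", 10:14), "q")
  l <- gene_set(sprintf("g%02d", 1:5), "l")
  r0 <- hypergeom_enrich(q, l, bg20, haldane = FALSE)
  expect_equal(r0$p, 1)          # P[X >= 0] = 1
  expect_equal(r0$odds_ratio, 0)
  rh <- hypergeom_enrich(q, l, bg20, haldane = TRUE)
  expect_gt(rh$odds_ratio, 0)    # +0.5 correction keeps OR finite, positive
  # query = list = background
  rall <- hypergeom_enrich(bg20, bg20, bg20)
  expect_equal(rall$p, 1)
  expect_true(is.finite(rall$odds_ratio))
  expect_error(hypergeom_enrich(gene_set("nope", "q"), l, bg20),
               "not in background")
})

test_that("enrichment is label-symmetric and monotone in the overlap", {
  q <- gene_set(sprintf("g%02d", 1:8), "q")
  l <- gene_set(sprintf("g%02d", c(1:4, 15:17)), "l")
  a <- hypergeom_enrich(q, l, bg20)
  b <- hypergeom_enrich(l, q, bg20)
  expect_equal(a$overlap, b$overlap)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$odds_ratio, b$odds_ratio, tolerance = 1e-12)
  # p strictly decreases as the overlap grows (N, |list|, |query| fixed)
  ps <- vapply(0:5, function(a) {
    qids <- c(sprintf("g%02d", seq_len(a)),
              if (a < 8) sprintf("g%02d", 10 + seq_len(8 - a)))
    hypergeom_enrich(gene_set(qids, "q"), gene_set(sprintf("g%02d", 1:5), "l"),
                     bg20)$p
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("chromosome disproportionality flags an all-X class", {
  chroms <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       chrom = rep(c("chr1", "chr2", "chr3", "chrX"), each = 5))
  cls <- gene_set(sprintf("g%02d", 16:19), "cls")  # 4 of 5 chrX genes
  out <- chromosome_enrich(cls, chroms, bg20)
  x <- out[out$chrom == "chrX", ]
  expect_equal(x$overlap, 4L)
  expect_equal(x$percent, 80)
  expect_equal(x$p, min(out$p))
  expect_equal(x$odds_ratio, max(out$odds_ratio))
  # percentage arithmetic: 3 of 10 -> 30%
  chroms2 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                        chrom = rep(c("chrA", "chrB"), each = 10))
  out2 <- chromosome_enrich(gene_set(sprintf("g%02d", 1:3), "c"), chroms2,
                            bg20)
  expect_equal(out2$percent[out2$chrom == "chrA"], 30)
  expect_error(chromosome_enrich(cls, chroms[1:10, ], bg20), "without")
})

test_that("random class assignment rarely yields q-significant chromosomes", {
  set.seed(40)
  N <- 400
  ids <- sprintf("r%03d", seq_len(N))
  bg <- gene_set(ids, "bg")
  chroms <- data.frame(gene_id = ids,
                       chrom = sample(paste0("chr", 1:20), N, replace = TRUE))
  hits <- vapply(1:100, function(i) {
    cls <- gene_set(sample(ids, 40), "cls")
    any(chromosome_enrich(cls, chroms, bg)$q < 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("BH q values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # order-preserving: q nondecreasing along increasing p
  p <- c(0.04, 0.001, 0.03)
  expect_true(all(diff(bh_fdr(p)[order(p)]) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("class-by-list families share one BH correction", {
  qs <- list(A = gene_set(sprintf("g%02d", 1:5), "A"),
             B = gene_set(sprintf("g%02d", 6:10), "B"))
  ls <- list(L1 = gene_set(sprintf("g%02d", 1:6), "L1"),
             L2 = gene_set(sprintf("g%02d", 11:16), "L2"))
  out <- enrich_classes(qs, ls, bg20)
  expect_equal(nrow(out), 4L)
  expect_equal(out$q, bh_fdr(out$p))
})
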