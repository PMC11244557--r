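#!/usr/bin/env Rscript
# Inspect the enrichment stage outputs: hypergeometric odds ratios of the
# recovered M+F- / M-F+ classes against the planted gene lists (after
# mouse->human homolog mapping, background = post-filter universe) and the
# per-chromosome disproportionality of each class (the M-F+ set was
# planted on chrX). Reads results/rnaseq_de/.

de_dir <- "results/rnaseq_de"
stopifnot(dir.exists(de_dir))

enr <- read.delim(file.path(de_dir, "enrichment.tsv"))
cat("class x gene-list enrichment (hypergeometric OR, BH q):\n")
print(enr[order(enr$p), c("query_name", "list_name", "overlap",
                          "odds_ratio", "p", "q")], digits = 3)

chrom <- read.delim(file.path(de_dir, "chromosome_enrichment.tsv"))
cat("\ntop chromosome disproportionality rows:\n")
print(head(chrom[order(chrom$p), ], 6), digits = 3)
sig <- chrom[chrom$q < 0.05, ]
if (nrow(sig))
  cat(sprintf("\nchromosomes passing q < 0.05: %s\n",
              paste(sprintf("%s (%s, OR %.1f)", sig$chrom, sig$class,
                            sig$odds_ratio), collapse = ", ")))
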