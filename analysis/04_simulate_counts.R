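#!/usr/bin/env Rscript
# Simulate the transcriptomic cohort: NB counts for 12000 genes over the
# study's 4/4/5/5 sex-by-genotype design, with two 50-gene planted sets of
# opposite-signed within-sex fold changes (the M+F- / M-F+ phenomenon, the
# M-F+ set pinned to chrX to exercise chromosome disproportionality), a
# balanced technical artifact factor, and a RIN-like covariate. Writes
# counts/design/gene TSVs, gene lists (GMT) and a homolog map under
# results/rnaseq_cohort/.

suppressMessages(library(dimorph))
out_dir <- "results/rnaseq_cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- counts_sim_spec(
  n_genes = 12000L, n_per_cell = c(4L, 4L, 5L, 5L),
  planted_sets = data.frame(
    name = c("plantMpFm", "plantMmFp"), size = 50L,
    male_lfc = c(1.5, -1.5), female_lfc = c(-1.5, 1.5),
    chrom = c(NA, "chrX")),
  artifact_frac = 0.3, artifact_strength = 0.5,
  x_frac = 0.05, seed = 1L)
sim <- simulate_counts(spec)

write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
write.table(sim$design, file.path(out_dir, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$genes, file.path(out_dir, "genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# gene lists in the human namespace + mouse->human homolog map
hm <- data.frame(mouse_id = sim$genes$gene_id,
                 human_id = toupper(sim$genes$gene_id))
hm <- hm[sim$genes$human_homolog != "", ]
write.table(hm, file.path(out_dir, "homologs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
set.seed(2)
write_gmt(list(
  planted_MpFm = toupper(sim$truth$gene_id[sim$truth$set %in% "plantMpFm"]),
  planted_MmFp = toupper(sim$truth$gene_id[sim$truth$set %in% "plantMmFp"]),
  random_200 = toupper(sample(sim$genes$gene_id, 200))),
  file.path(out_dir, "lists.gmt"))

cat(sprintf("wrote %d genes x %d samples to %s\n", nrow(sim$counts),
            ncol(sim$counts), out_dir))
print(table(sim$truth$class))
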