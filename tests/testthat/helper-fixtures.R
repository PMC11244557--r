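# fixture builders shared across test files

write_rnaseq_inputs <- function(td, seed = 61) {
  spec <- counts_sim_spec(n_genes = 400, n_per_cell = 3,
                          planted_sets = data.frame(
                            name = c("a", "b"), size = c(15, 15),
                            male_lfc = c(2, -2), female_lfc = c(-2, 2)),
                          seed = seed)
  sim <- simulate_counts(spec)
  write_counts(sim$counts, file.path(td, "counts.tsv"))
  utils::write.table(sim$design, file.path(td, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes, file.path(td, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(list(planted = toupper(
    sim$truth$gene_id[sim$truth$class != "null"])),
    file.path(td, "lists.gmt"))
  hm <- data.frame(mouse_id = sim$genes$gene_id,
                   human_id = toupper(sim$genes$gene_id))
  utils::write.table(hm[sim$genes$human_homolog != "", ],
                     file.path(td, "homologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(pipeline = "rnaseq", out_dir = file.path(td, "out"), seed = 1,
       inputs = list(counts = file.path(td, "counts.tsv"),
                     design = file.path(td, "design.tsv"),
                     genes = file.path(td, "genes.tsv"),
                     gmt = file.path(td, "lists.gmt"),
                     homologs = file.path(td, "homologs.tsv")),
       params = list(min_reads = 5L))
}
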