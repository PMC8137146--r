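#!/usr/bin/env Rscript

# Stage 2: transcription read-through at transcription end sites.
#
# For every expressed, non-neighbouring gene, contrasts mean coverage over
# the first 1 kb downstream of the TES against the gene body in each
# condition (read-through index) and reports the per-gene log2 change on
# depletion. Genes planted with termination failure should rise to the top
# of the ranking with deltas near log2(0.4/0.05) = 3.

library(rtquant)

data_dir <- "scratch/synthetic"
dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(seed = 42L)
params <- analysis_params()

chrom_lengths <- read_chrom_sizes(file.path(data_dir, "chrom.sizes"))
genes <- read_annotation(file.path(data_dir, "annotation.gtf"), "gtf")
cov_ctrl <- read_bedgraph(file.path(data_dir, "control.rep1.plus.bedgraph"),
                          file.path(data_dir, "control.rep1.minus.bedgraph"),
                          chrom_lengths)
cov_dep <- read_bedgraph(file.path(data_dir, "depleted.rep1.plus.bedgraph"),
                         file.path(data_dir, "depleted.rep1.minus.bedgraph"),
                         chrom_lengths)

# expression filter from the read emitter (control condition)
ann <- make_annotation(spec)
reads <- simulate_reads(spec, ann)
tpm <- compute_tpm(count_exonic_all(reads, genes), exonic_length(genes))
expr <- filter_expressed(data.frame(gene_id = genes$gene_id, tpm = tpm),
                         params)
write.table(expr, "results/expression.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rt <- readthrough_table(cov_ctrl, cov_dep, genes, params,
                        tpm = setNames(expr$tpm, expr$gene_id))
write.table(rt, "results/readthrough.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim(file.path(data_dir, "truth", "genes.tsv"))
m <- merge(rt, truth[, c("gene_id", "rt_affected")], by = "gene_id")
cat(sprintf("read-through table: %d genes after filters\n", nrow(rt)))
cat(sprintf("  mean delta (planted): %.3f; (background): %.3f\n",
            mean(m$delta_log2[m$rt_affected]),
            mean(m$delta_log2[!m$rt_affected])))
top <- rt$gene_id[seq_len(min(10, nrow(rt)))]
cat(sprintf("  planted genes in top 10 by delta: %d\n",
            sum(top %in% truth$gene_id[truth$rt_affected])))
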