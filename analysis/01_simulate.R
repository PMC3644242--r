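#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 173 transcripts with the
# family/completeness structure of the published Hevea AP2/ERF inventory
# (25 AP2, 141 ERF, 4 RAV, 3 Soloist; 142 genes with a complete domain),
# a per-tissue read-membership table over the five 454 libraries, and
# twelve planted miRNA/target pairs (half cleavage-type, half
# translation-type).

suppressPackageStartupMessages(library(ap2erf))

outdir <- "results/cohort"
cfg <- cohort_config(seed = 1L)
cohort <- generate_cohort(cfg)
membership <- generate_read_membership(cohort, total_reads = 6318L,
                                       seed = 2L)
pairs <- generate_mirna_pairs(cohort, n_sites = 12L, seed = 3L)

dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
write_cohort(cohort, outdir, membership)
writeLines(paste0(">", names(pairs$mirnas), "\n", unname(pairs$mirnas)),
           file.path(outdir, "mirnas.fasta"))
write.table(pairs$sites, file.path(outdir, "mirna_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", length(cohort$transcripts), "transcripts:\n")
print(table(cohort$genes$family))
full <- unique(cohort$domains$gene[cohort$domains$kind == "AP2" &
                                     cohort$domains$completeness %in%
                                     c("full", "short")])
cat(length(full), "genes carry a complete AP2 domain;",
    sum(membership$read_count), "reads over",
    length(unique(membership$library)), "tissue libraries;",
    nrow(pairs$sites), "miRNA sites planted.\n")
cat("Outputs in", outdir, "\n")
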