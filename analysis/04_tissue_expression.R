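#!/usr/bin/env Rscript
# Stage 4 — read distribution across tissue libraries and qPCR ratios.
#
# Computes per-tissue shares of AP2/ERF reads from the published
# per-library counts, recomputes the margins of the published ERF
# group x tissue table, aggregates the synthetic read membership by
# recovered group, and illustrates the efficiency-corrected qPCR ratio.

suppressPackageStartupMessages(library(ap2erf))

indir <- "results/cohort"
phy <- "results/phylogeny"
outdir <- "results/tissues"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

# published per-library AP2/ERF read counts -> shares
counts <- hevea_tissue_read_counts()
shares <- tissue_percentages(counts)
shares_df <- data.frame(library = names(counts), reads = as.numeric(counts),
                        share_pct = as.numeric(shares))
write.table(shares_df, file.path(outdir, "tissue_shares_published.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Published read shares (%):\n")
print(shares_df)

# published ERF group x tissue cells -> recomputed margins
t8 <- hevea_erf_group_reads()
rm8 <- as.matrix(t8[, -1]); rownames(rm8) <- t8$group
tab8 <- aggregate_by_group(rm8, data.frame(gene = t8$group,
                                           group = t8$group))
write.table(data.frame(group = rownames(tab8), tab8, check.names = FALSE),
            file.path(outdir, "group_tissue_published.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nRecomputed margins: Group I total", tab8["I", "Total"],
    "| bark total", tab8["Total", "bark"],
    "| grand total", tab8["Total", "Total"], "\n")

# synthetic membership aggregated by recovered ERF group
membership <- read.delim(file.path(indir, "read_membership.tsv"))
groups <- read.delim(file.path(phy, "erf_groups.tsv"))
rm_syn <- count_reads(membership)
tab_syn <- aggregate_by_group(rm_syn[rownames(rm_syn) %in% groups$gene, ,
                                     drop = FALSE],
                              groups[, c("gene", "group")])
write.table(data.frame(group = rownames(tab_syn), tab_syn,
                       check.names = FALSE),
            file.path(outdir, "group_tissue_synthetic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nSynthetic cohort: ", tab_syn["Total", "Total"],
    "ERF reads aggregated over", nrow(tab_syn) - 1, "groups.\n")

# qPCR normalized ratios for a worked example
ex <- data.frame(sample = c("latex", "bark", "leaf"),
                 cp_target = c(24.1, 27.3, 29.0),
                 cp_ref = c(25.6, 25.9, 26.2))
ex$ratio <- qpcr_ratio(ex$cp_target, ex$cp_ref)
write.table(ex, file.path(outdir, "qpcr_example.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nqPCR normalized ratios (E = 2):\n")
print(ex)
cat("Outputs in", outdir, "\n")
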