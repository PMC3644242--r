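#!/usr/bin/env Rscript
# Stage 3 — anchor domains, build the NJ tree, assign ERF groups, and
# discover diagnostic residues.
#
# Anchors each gene's first complete AP2 domain to the AtERF1 numbering
# (positions 145-202 plus the 167i insertion slot), curates a conserved
# block, builds the neighbour-joining tree rooted on the AP2+RAV split,
# assigns ERF groups by placement against a labelled reference panel with
# marker signatures as secondary evidence, maps groups onto the Sakuma
# nomenclature, and recovers per-group diagnostic residues and the ten
# universal residues.

suppressPackageStartupMessages(library(ap2erf))

indir <- "results/cohort"
cls <- "results/classification"
outdir <- "results/phylogeny"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

tx <- Biostrings::readDNAStringSet(file.path(indir, "transcripts.fasta"))
transcripts <- setNames(as.character(tx), names(tx))
rc <- run_classification(transcripts, reference_seed = 1001L)

write.table(rc$groups, file.path(outdir, "erf_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rc$calls, file.path(outdir, "named_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sak <- tabulate_sakuma(rc$summary)
write.table(sak, file.path(outdir, "table_sakuma.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# display tree over all complete domains, rooted on the AP2+RAV branch
full_ids <- rc$calls$gene[rc$calls$completeness %in%
                            c("two-full", "full+partial", "one-full")]
full_ids <- intersect(full_ids, rownames(rc$numbered))
block <- extract_block(rc$numbered[full_ids, , drop = FALSE])
tree <- nj_tree(pdistance_matrix(block))
tree <- root_on_ap2_rav(tree, setNames(rc$calls$family, rc$calls$gene))
ape::write.tree(tree, file.path(outdir, "nj_tree.nwk"))

# diagnostic residues on the recovered full-domain panel
panel_ids <- rc$calls$gene[rc$calls$completeness %in%
                             c("two-full", "full+partial", "one-full") &
                             rc$calls$family != "SOLOIST"]
panel_ids <- intersect(panel_ids, rownames(rc$numbered))
labels <- ifelse(rc$calls$family[match(panel_ids, rc$calls$gene)] == "ERF",
                 rc$groups$group[match(panel_ids, rc$groups$gene)],
                 rc$calls$family[match(panel_ids, rc$calls$gene)])
keep <- !is.na(labels)
cons <- column_conservation(rc$numbered[panel_ids[keep], , drop = FALSE],
                            labels[keep])
markers <- find_group_markers(cons)
write.table(markers, file.path(outdir, "group_markers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
erf_sel <- labels[keep] %in% c("I", "II", "III", "IV", "V", "VI", "VI-L",
                               "VII", "VIII", "IX", "X")
universal <- find_universal_residues(
  column_conservation(rc$numbered[panel_ids[keep][erf_sel], , drop = FALSE],
                      labels[keep][erf_sel]), 100)
write.table(universal, file.path(outdir, "universal_residues.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("ERF group sizes (full-domain members):\n")
print(rc$summary$erf_groups)
cat("Sakuma correspondence:\n")
print(sak)
cat("Universal residues:",
    paste0(universal$residue, universal$position, collapse = ", "), "\n")
cat(nrow(markers), "diagnostic-residue rows;",
    "tree with", length(tree$tip.label), "leaves in",
    file.path(outdir, "nj_tree.nwk"), "\n")
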