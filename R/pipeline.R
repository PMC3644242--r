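# End-to-end orchestration: simulate -> scan -> classify -> group ->
# markers -> tissues -> mirna, with a read-length prefilter and a
# plain-text run manifest. Stages communicate through files, so deleting a
# stage's outputs and re-running regenerates that stage and its
# descendants only.

#' Length/complexity read prefilter
#'
#' Keeps reads of at least `min_len` nt whose dinucleotide Shannon entropy
#' reaches `entropy_floor` bits; short or low-complexity reads are
#' discarded with a reason.
#'
#' @param reads named character vector of read sequences, or a path to a
#'   FASTA/FASTQ file.
#' @param min_len minimum read length (nt).
#' @param entropy_floor minimum dinucleotide entropy (bits).
#' @return list: `kept` (named character vector), `discarded` (data.frame
#'   id, reason).
#' @export
filter_reads <- function(reads, min_len = 120L, entropy_floor = 1.0) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    x <- Biostrings::readDNAStringSet(reads, format = fmt)
    reads <- stats::setNames(as.character(x), names(x))
  }
  keep <- logical(length(reads))
  reason <- character(length(reads))
  for (i in seq_along(reads)) {
    s <- toupper(reads[[i]])
    if (nchar(s) < min_len) {
      reason[i] <- "short"
    } else if (dinucleotide_entropy(s) < entropy_floor) {
      reason[i] <- "low_complexity"
    } else keep[i] <- TRUE
  }
  list(kept = reads[keep],
       discarded = data.frame(id = names(reads)[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE))
}

dinucleotide_entropy <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2L) return(0)
  di <- paste0(ch[-length(ch)], ch[-1L])
  p <- table(di) / length(di)
  -sum(p * log2(p))
}

# ---- classification of a scanned cohort ------------------------------------

#' Classify scanned hits into family calls
#'
#' Applies the architecture rules per contig, using the nearest-family
#' homology hint for single-domain genes (the published rationale for
#' single-domain AP2-family members).
#'
#' @param hits output of [scan_transcripts()].
#' @param contigs contig ids to classify (defaults to those with hits).
#' @param model model used for anchoring hint domains.
#' @return data.frame: gene, family, completeness, homology_override,
#'   n_ap2, n_b3.
#' @export
classify_hits <- function(hits, contigs = unique(hits$contig),
                          model = ap2_model()) {
  out <- list()
  for (id in contigs) {
    h <- hits[hits$contig == id, , drop = FALSE]
    ap2h <- h[h$kind == "AP2", , drop = FALSE]
    hint <- NULL
    if (nrow(ap2h) == 1L && ap2h$completeness[1] != "short" &&
        nrow(h[h$kind == "B3", ]) == 0L) {
      numbered <- try(anchor_align(ap2h$aa[1], model), silent = TRUE)
      if (!inherits(numbered, "try-error"))
        hint <- homology_family_hint(numbered)
    }
    cl <- classify_family(h, hint)
    out[[length(out) + 1L]] <- data.frame(
      gene = id, family = cl$family, completeness = cl$completeness,
      homology_override = cl$homology_override,
      n_ap2 = nrow(ap2h), n_b3 = sum(h$kind == "B3"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# pick the alignment domain per gene: first (5'-most) AP2 repeat
# preferentially, second repeat when the first is absent/unusable
select_alignment_domain <- function(hits_gene) {
  ap2 <- hits_gene[hits_gene$kind == "AP2", , drop = FALSE]
  if (!nrow(ap2)) return(NULL)
  ap2 <- ap2[order(ap2$nt_start), , drop = FALSE]
  full <- ap2[ap2$completeness %in% c("full", "short"), , drop = FALSE]
  if (nrow(full)) full[1, ] else ap2[1, ]
}

#' Run the full classification workflow on a set of transcripts
#'
#' Scan, classify, anchor, and assign ERF groups against a labelled
#' reference panel; produces the family and group inventories the
#' published tables report.
#'
#' @param transcripts named character vector of DNA sequences.
#' @param reference_seed seed for the generated ERF reference panel.
#' @param min_orf_aa minimum peptide candidate length for translation.
#' @return list: hits, calls (named family calls), groups (ERF group
#'   assignments for full-domain ERFs), numbered (anchored residue matrix
#'   of full/short domains, one per gene), summary (named counts: total,
#'   full_domain, per family, DREB/ERF bands).
#' @export
run_classification <- function(transcripts, reference_seed = 100L,
                               min_orf_aa = 50L) {
  model <- ap2_model()
  hits <- scan_transcripts(transcripts, ap2 = model, min_orf_aa = min_orf_aa)
  calls <- classify_hits(hits, model = model)

  # anchored domain per gene (R1 preferred)
  numbered <- list()
  for (id in calls$gene) {
    sel <- select_alignment_domain(hits[hits$contig == id, , drop = FALSE])
    if (is.null(sel)) next
    nb <- try(anchor_align(sel$aa, model), silent = TRUE)
    if (!inherits(nb, "try-error")) numbered[[id]] <- unclass(nb)
  }
  nmat <- do.call(rbind, numbered)

  # ERF group assignment for full-domain ERF genes
  erf_full <- calls$gene[calls$family == "ERF" &
                           calls$completeness == "one-full"]
  erf_full <- intersect(erf_full, rownames(nmat))
  groups <- NULL
  if (length(erf_full) >= 1L) {
    panel <- generate_reference_panel(seed = reference_seed)
    groups <- assign_group(nmat[erf_full, , drop = FALSE],
                           panel$residues, panel$labels)
  }
  calls <- assign_names(calls, groups)

  summary <- summarize_inventory(calls, groups)
  list(hits = hits, calls = calls, groups = groups, numbered = nmat,
       summary = summary)
}

summarize_inventory <- function(calls, groups) {
  full_classes <- c("two-full", "full+partial", "one-full")
  is_full <- calls$completeness %in% full_classes |
    calls$family == "SOLOIST"
  group_counts <- stats::setNames(integer(length(ERF_GROUPS)), ERF_GROUPS)
  dreb <- erfb <- vil <- 0L
  if (!is.null(groups)) {
    tab <- table(groups$group)
    group_counts[names(tab)] <- as.integer(tab)
    dreb <- sum(group_counts[DREB_GROUPS])
    vil <- group_counts[["VI-L"]]
    erfb <- sum(group_counts) - dreb - vil
  }
  list(
    total = sum(calls$family != "UNCLASSIFIED"),
    full_domain = sum(is_full & calls$family != "UNCLASSIFIED"),
    families = c(AP2 = sum(calls$family == "AP2"),
                 ERF = sum(calls$family == "ERF"),
                 RAV = sum(calls$family == "RAV"),
                 SOLOIST = sum(calls$family == "SOLOIST")),
    families_full = c(AP2 = sum(calls$family == "AP2" & is_full),
                      ERF = sum(calls$family == "ERF" & is_full),
                      RAV = sum(calls$family == "RAV" & is_full),
                      SOLOIST = sum(calls$family == "SOLOIST")),
    erf_groups = group_counts,
    sakuma = c(AP2 = sum(calls$family == "AP2" & is_full),
               DREB = dreb, ERF_B = erfb, VI_L = vil,
               RAV = sum(calls$family == "RAV" & is_full),
               SOLOIST = sum(calls$family == "SOLOIST")))
}

#' Nakano-to-Sakuma summary of a classified cohort
#'
#' The correspondence-table layout over complete-domain genes: AP2, DREB
#' (groups I-IV), ERF B-groups (V-X), VI-L within B-6, RAV, Soloist and the
#' total.
#'
#' @param summary the `summary` element of [run_classification()].
#' @return data.frame mirroring the published correspondence layout.
#' @export
tabulate_sakuma <- function(summary) {
  s <- summary$sakuma
  data.frame(
    family = c("AP2 family", "ERF", "ERF", "ERF", "RAV", "SOLOIST",
               "Total"),
    nakano_group = c("-", "I to IV", "V to X", "VI-L & Xb-L", "-", "-", ""),
    sakuma_subfamily = c("AP2", "DREB", "ERF", "ERF", "RAV", "SOLOIST", ""),
    sakuma_subgroup = c("-", "A-1 to A-6", "B-1 to B-6", "B-6", "-", "-",
                        ""),
    n_genes = c(s[["AP2"]], s[["DREB"]], s[["ERF_B"]], s[["VI_L"]],
                s[["RAV"]], s[["SOLOIST"]], sum(s)),
    stringsAsFactors = FALSE)
}

# ---- staged pipeline --------------------------------------------------------

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fnv_digest <- function(text) {
  h <- 5381
  for (b in utf8ToInt(paste(text, collapse = "\n")))
    h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run every pipeline stage into an output directory
#'
#' simulate -> scan -> classify -> group -> markers -> tissues -> mirna ->
#' summaries, writing TSV/FASTA outputs per stage and a plain-text
#' manifest. A stage whose outputs already exist is skipped unless an
#' upstream stage re-ran or `force` is set; outputs are byte-identical for
#' a fixed seed (except the manifest timestamp).
#'
#' @param config a [cohort_config()]; its seed drives every stage.
#' @param outdir output directory.
#' @param force re-run all stages.
#' @param quiet suppress stage messages.
#' @return invisibly, the manifest as a named character vector.
#' @export
run_all <- function(config = cohort_config(), outdir, force = FALSE,
                    quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg) if (!quiet)
    message("[", stage, "] ", msg)
  p <- function(...) file.path(outdir, ...)
  ran <- FALSE
  counts <- c()

  need <- function(files) force || ran || !all(file.exists(files))

  # -- simulate
  sim_files <- p(c("transcripts.fasta", "genes_truth.tsv",
                   "domains_truth.tsv", "read_membership.tsv",
                   "mirnas.fasta", "mirna_truth.tsv", "config.txt"))
  if (need(sim_files)) {
    say("simulate", "generating cohort")
    cohort <- generate_cohort(config)
    membership <- generate_read_membership(cohort, seed = config$seed + 1L)
    write_cohort(cohort, outdir, membership)
    pairs <- generate_mirna_pairs(cohort, seed = config$seed + 2L)
    writeLines(paste0(">", names(pairs$mirnas), "\n",
                      unname(pairs$mirnas)), p("mirnas.fasta"))
    write_tsv(pairs$sites, p("mirna_truth.tsv"))
    ran <- TRUE
  } else say("simulate", "outputs present, skipped")
  transcripts <- {
    x <- Biostrings::readDNAStringSet(p("transcripts.fasta"))
    stats::setNames(as.character(x), names(x))
  }
  counts["transcripts"] <- length(transcripts)

  # -- scan
  if (need(p("hits.tsv"))) {
    say("scan", "scanning six-frame translations for AP2/B3 domains")
    hits <- scan_transcripts(transcripts)
    write_tsv(hits, p("hits.tsv"))
    ran <- TRUE
  } else say("scan", "outputs present, skipped")
  hits <- utils::read.delim(p("hits.tsv"), stringsAsFactors = FALSE)
  counts["domain_hits"] <- nrow(hits)

  # -- classify
  if (need(p("calls.tsv"))) {
    say("classify", "applying domain-architecture family rules")
    calls <- classify_hits(hits)
    write_tsv(calls, p("calls.tsv"))
    ran <- TRUE
  } else say("classify", "outputs present, skipped")
  calls <- utils::read.delim(p("calls.tsv"), stringsAsFactors = FALSE)
  counts["classified"] <- sum(calls$family != "UNCLASSIFIED")

  # -- anchor + group
  if (need(p(c("groups.tsv", "named_calls.tsv", "tree.nwk")))) {
    say("group", "anchoring domains and assigning ERF groups by NJ placement")
    model <- ap2_model()
    numbered <- list()
    for (id in calls$gene) {
      sel <- select_alignment_domain(hits[hits$contig == id, , drop = FALSE])
      if (is.null(sel)) next
      nb <- try(anchor_align(sel$aa, model), silent = TRUE)
      if (!inherits(nb, "try-error")) numbered[[id]] <- unclass(nb)
    }
    nmat <- do.call(rbind, numbered)
    utils::write.table(
      data.frame(gene = rownames(nmat), nmat, check.names = FALSE),
      p("numbered_domains.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "-")
    erf_full <- calls$gene[calls$family == "ERF" &
                             calls$completeness == "one-full"]
    erf_full <- intersect(erf_full, rownames(nmat))
    panel <- generate_reference_panel(seed = config$seed + 3L)
    groups <- assign_group(nmat[erf_full, , drop = FALSE],
                           panel$residues, panel$labels)
    write_tsv(groups, p("groups.tsv"))
    named <- assign_names(calls, groups)
    write_tsv(named, p("named_calls.tsv"))
    full_ids <- rownames(nmat)[rownames(nmat) %in%
                                 calls$gene[calls$completeness %in%
                                              c("two-full", "full+partial",
                                                "one-full")]]
    if (length(full_ids) >= 4L) {
      block <- extract_block(nmat[full_ids, , drop = FALSE])
      d <- pdistance_matrix(block)
      tree <- nj_tree(d)
      fams <- stats::setNames(calls$family, calls$gene)
      tree <- root_on_ap2_rav(tree, fams)
      ape::write.tree(tree, p("tree.nwk"))
    } else writeLines(";", p("tree.nwk"))
    ran <- TRUE
  } else say("group", "outputs present, skipped")
  groups <- utils::read.delim(p("groups.tsv"), stringsAsFactors = FALSE)
  named <- utils::read.delim(p("named_calls.tsv"), stringsAsFactors = FALSE)
  counts["erf_grouped"] <- nrow(groups)

  # -- markers
  if (need(p(c("markers.tsv", "universal_residues.tsv")))) {
    say("markers", "computing per-group conservation and diagnostic residues")
    nmat <- read_numbered(p("numbered_domains.tsv"))
    panel_ids <- calls$gene[calls$completeness %in%
                              c("two-full", "full+partial", "one-full") &
                              calls$family != "SOLOIST"]
    panel_ids <- intersect(panel_ids, rownames(nmat))
    labels <- ifelse(calls$family[match(panel_ids, calls$gene)] == "ERF",
                     groups$group[match(panel_ids, groups$gene)],
                     calls$family[match(panel_ids, calls$gene)])
    ok <- !is.na(labels)
    cons <- column_conservation(nmat[panel_ids[ok], , drop = FALSE],
                                labels[ok])
    write_tsv(find_group_markers(cons), p("markers.tsv"))
    erf_ids <- panel_ids[ok][labels[ok] %in% ERF_GROUPS]
    cons_erf <- column_conservation(nmat[erf_ids, , drop = FALSE],
                                    labels[ok][labels[ok] %in% ERF_GROUPS])
    write_tsv(find_universal_residues(cons_erf),
              p("universal_residues.tsv"))
    ran <- TRUE
  } else say("markers", "outputs present, skipped")
  counts["markers"] <- nrow(utils::read.delim(p("markers.tsv")))

  # -- tissues
  if (need(p(c("group_tissue_table.tsv", "tissue_shares.tsv")))) {
    say("tissues", "aggregating read distribution by group and tissue")
    membership <- utils::read.delim(p("read_membership.tsv"),
                                    stringsAsFactors = FALSE)
    rm <- count_reads(membership)
    shares <- tissue_percentages(colSums(rm))
    write_tsv(data.frame(library = names(shares), reads = colSums(rm),
                         share_pct = as.numeric(shares)),
              p("tissue_shares.tsv"))
    assn <- data.frame(gene = groups$gene, group = groups$group,
                       stringsAsFactors = FALSE)
    grp_table <- aggregate_by_group(rm[rownames(rm) %in% assn$gene, ,
                                       drop = FALSE], assn)
    utils::write.table(data.frame(group = rownames(grp_table), grp_table,
                                  check.names = FALSE),
                       p("group_tissue_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ran <- TRUE
  } else say("tissues", "outputs present, skipped")

  # -- mirna
  if (need(p("mirna_hits.tsv"))) {
    say("mirna", "scanning miRNAs against transcripts")
    mir <- Biostrings::readRNAStringSet(p("mirnas.fasta"))
    mirnas <- stats::setNames(as.character(mir), names(mir))
    genes_truth <- utils::read.delim(p("genes_truth.tsv"),
                                     stringsAsFactors = FALSE)
    ann <- build_site_annotations(genes_truth, hits)
    mh <- scan_target_set(mirnas, transcripts, annotations = ann)
    if (nrow(mh)) {
      # 1-based inclusive positions for the report
      mh$mir_position <- paste0(mh$tx_start + 1L, "-", mh$tx_end)
    }
    write_tsv(mh, p("mirna_hits.tsv"))
    ran <- TRUE
  } else say("mirna", "outputs present, skipped")
  counts["mirna_hits"] <- nrow(utils::read.delim(p("mirna_hits.tsv")))

  # -- summaries + manifest
  say("summary", "writing inventory tables and manifest")
  summary <- summarize_inventory(named, groups)
  write_tsv(tabulate_families(named), p("table_families.tsv"))
  write_tsv(data.frame(group = names(summary$erf_groups),
                       n_genes = as.integer(summary$erf_groups)),
            p("table_erf_groups.tsv"))
  write_tsv(tabulate_sakuma(summary), p("table_sakuma.tsv"))
  manifest <- c(
    tool = paste0("ap2erf ", as.character(utils::packageVersion("ap2erf"))),
    seed = as.character(config$seed),
    config_digest = fnv_digest(readLines(p("config.txt"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outdir = normalizePath(outdir),
    vapply(names(counts), function(k) as.character(counts[[k]]),
           character(1)))
  writeLines(paste0(names(manifest), "=", manifest), p("manifest.txt"))
  invisible(manifest)
}

read_numbered <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "-")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

build_site_annotations <- function(genes_truth, hits) {
  ann <- data.frame(gene = genes_truth$gene,
                    cds_start = genes_truth$cds_start,
                    cds_end = genes_truth$cds_end,
                    ap2_start = NA_integer_, ap2_end = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ann))) {
    h <- hits[hits$contig == ann$gene[k] & hits$kind == "AP2", ,
              drop = FALSE]
    if (nrow(h)) {
      h <- h[order(h$nt_start), , drop = FALSE]
      ann$ap2_start[k] <- h$nt_start[1]
      ann$ap2_end[k] <- h$nt_end[1]
    }
  }
  ann
}
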