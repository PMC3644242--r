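# Synthetic cohort generator.
#
# Generates labelled transcript cohorts with the family/completeness
# structure of the Hevea AP2/ERF inventory: double-AP2-domain AP2-family
# genes, single-domain ERFs in eleven groups, RAV genes with one AP2 and one
# B3 domain, and Soloists with a short AP2 domain missing six residues.
# Every diagnostic feature downstream stages test for is planted
# deterministically; all remaining domain positions carry substitution
# noise.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort configuration
#'
#' Defaults reproduce the published Hevea inventory: 25 AP2-family genes
#' (9 with two full domains, 4 full+partial, 2 two-partial, 7 one-full,
#' 3 one-partial), 141 ERF genes (115 full-domain split over eleven groups,
#' 26 partial), 4 RAV and 3 Soloist genes (173 genes, 142 of them carrying a
#' complete AP2 domain counting the short Soloist domain). Tissue weights
#' follow the published read shares over the five 454 libraries.
#'
#' @param ap2_two_full,ap2_full_partial,ap2_two_partial,ap2_one_full,ap2_one_partial
#'   AP2-family completeness class counts.
#' @param erf_groups named integer vector of full-domain ERF genes per group.
#' @param erf_partial number of partial-domain ERF genes.
#' @param rav,soloist family counts.
#' @param tissues named numeric vector of tissue read-share weights (sum 1).
#' @param utr_range 5'/3' UTR length range (nt).
#' @param flank_aa_range coding-flank length range on each side of a domain
#'   (amino acids).
#' @param noise per-position substitution probability at non-diagnostic
#'   domain positions.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(ap2_two_full = 9L, ap2_full_partial = 4L,
                          ap2_two_partial = 2L, ap2_one_full = 7L,
                          ap2_one_partial = 3L,
                          erf_groups = c(I = 12L, II = 7L, III = 11L,
                                         IV = 3L, V = 5L, VI = 5L,
                                         `VI-L` = 6L, VII = 23L,
                                         VIII = 15L, IX = 19L, X = 9L),
                          erf_partial = 26L, rav = 4L, soloist = 3L,
                          tissues = c(root = 0.298, bark = 0.222,
                                      latex = 0.212, embryogenic = 0.164,
                                      leaf = 0.104),
                          utr_range = c(50L, 300L),
                          flank_aa_range = c(30L, 80L),
                          noise = 0.05, seed = 1L) {
  cfg <- list(ap2_two_full = ap2_two_full, ap2_full_partial = ap2_full_partial,
              ap2_two_partial = ap2_two_partial, ap2_one_full = ap2_one_full,
              ap2_one_partial = ap2_one_partial, erf_groups = erf_groups,
              erf_partial = erf_partial, rav = rav, soloist = soloist,
              tissues = tissues, utr_range = utr_range,
              flank_aa_range = flank_aa_range, noise = noise,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  counts <- c(cfg$ap2_two_full, cfg$ap2_full_partial, cfg$ap2_two_partial,
              cfg$ap2_one_full, cfg$ap2_one_partial, cfg$erf_groups,
              cfg$erf_partial, cfg$rav, cfg$soloist)
  if (any(counts < 0)) stop("configuration error: negative count in ",
                            "family/completeness fields")
  if (!all(names(cfg$erf_groups) %in% ERF_GROUPS))
    stop("configuration error: erf_groups has unknown group label")
  if (length(cfg$tissues) && abs(sum(cfg$tissues) - 1) > 1e-9)
    stop("configuration error: tissues weights must sum to 1")
  if (any(cfg$tissues < 0))
    stop("configuration error: tissues weights must be non-negative")
  invisible(cfg)
}

# ---- residue-level sampling -------------------------------------------------

# Positions held noise-free for a family/group (names into the 59-slot
# numbered layout).
fixed_positions <- function(family, group = NULL) {
  fixed <- character(0)
  if (family == "ERF") {
    fixed <- c(names(UNIVERSAL_RESIDUES), as.character(SUBFAMILY_POSITIONS),
               names(GROUP_MARKERS[[group]]))
    if (group == "IX") fixed <- c(fixed, "167i")
    if (group == "VI-L") fixed <- c(fixed, as.character(KREYD_POSITIONS),
                                    "196")
  } else if (family %in% c("AP2", "SOLOIST")) {
    fixed <- c(names(UNIVERSAL_RESIDUES), as.character(SUBFAMILY_POSITIONS),
               names(AP2_FAMILY_VARIANTS))
  } else if (family == "RAV") {
    fixed <- c(names(UNIVERSAL_RESIDUES), as.character(SUBFAMILY_POSITIONS))
  }
  unique(fixed)
}

# Sample one domain's residues: consensus + substitution noise outside the
# fixed diagnostic positions.
sample_domain <- function(family, group = NULL, noise = 0.05,
                          insertion_residue = NULL) {
  if (is.null(insertion_residue))
    insertion_residue <- sample(AA_ALPHABET, 1L)
  res <- group_consensus(family, group, insertion_residue)
  fixed <- fixed_positions(family, group)
  mut <- which(!is.na(res) & !(names(res) %in% fixed) &
                 stats::runif(length(res)) < noise)
  for (i in mut) {
    alt <- setdiff(AA_ALPHABET, res[i])
    res[i] <- alt[sample.int(length(alt), 1L)]
  }
  res
}

# Deterministic per-gene modifications guaranteeing marker-safe
# conservation levels at any seed:
#  - every group drift position reverts to the scaffold in enough members
#    to stay below 90% within-group conservation;
#  - every AP2-family variant position reverts in three full-domain
#    members (85% panel conservation), and exactly two full-domain members
#    carry A150 against T150 for the rest.
plan_modifications <- function(plan, config) {
  mods <- stats::setNames(vector("list", nrow(plan)), plan$gene)
  add_revert <- function(gene, pos) {
    mods[[gene]]$revert <<- unique(c(mods[[gene]]$revert, pos))
  }
  drift_quota <- function(n) floor(n * 0.15) + 1L
  for (grp in unique(plan$group[plan$family == "ERF"])) {
    if (is.na(grp)) next
    full <- plan$gene[plan$family == "ERF" & plan$group == grp &
                        plan$class == "full"]
    n <- length(full)
    if (!n) next
    m <- drift_quota(n)
    drift <- names(group_drift(grp))
    for (t in seq_along(drift)) {
      dev <- unique(((t - 1L) * m + 0:(m - 1L)) %% n) + 1L
      for (s in dev) add_revert(full[s], drift[t])
    }
  }
  ravs <- plan$gene[plan$family == "RAV"]
  if (length(ravs)) {
    m <- drift_quota(length(ravs))
    drift <- names(group_drift("RAV"))
    for (t in seq_along(drift)) {
      dev <- unique(((t - 1L) * m + 0:(m - 1L)) %% length(ravs)) + 1L
      for (s in dev) add_revert(ravs[s], drift[t])
    }
  }
  full_ap2 <- plan$gene[plan$family == "AP2" &
                          plan$class %in% c("two_full", "full_partial",
                                            "one_full")]
  vars <- names(AP2_FAMILY_VARIANTS)
  if (length(full_ap2)) {
    for (j in seq_along(vars)) {
      dev <- unique(((j - 1L) * 3L + 0:2) %% length(full_ap2)) + 1L
      for (s in dev) add_revert(full_ap2[s], vars[j])
    }
    for (g in plan$gene[plan$family == "AP2"])
      mods[[g]]$res150 <- "T"
    for (g in full_ap2[seq_len(min(2L, length(full_ap2)))])
      mods[[g]]$res150 <- "A"
  }
  mods
}

apply_modifications <- function(res, mod) {
  if (is.null(mod)) return(res)
  if (!is.null(mod$revert)) {
    rp <- mod$revert[!is.na(res[mod$revert])]
    res[rp] <- AP2_SCAFFOLD[rp]
  }
  if (!is.null(mod$res150) && !is.na(res["150"])) res["150"] <- mod$res150
  res
}

# Truncate a numbered domain: keep `keep` core columns from the N or C side.
truncate_domain <- function(res, side, keep) {
  core <- setdiff(names(res), "167i")
  present <- core[!is.na(res[core])]
  if (side == "N") drop <- present[seq_len(length(present) - keep)]
  else drop <- present[(keep + 1L):length(present)]
  res[drop] <- NA_character_
  if (!is.na(res["167i"])) {
    # insertion slot only meaningful when both flanks survive
    if (is.na(res["167"]) || is.na(res["168"])) res["167i"] <- NA_character_
  }
  res
}

domain_string <- function(res) paste(res[!is.na(res)], collapse = "")

# ---- protein / transcript assembly -----------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein, codons) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cc <- codons[[a]]
    cc[sample.int(length(cc), 1L)]
  }, character(1)), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                               collapse = "")

#' Generate a labelled synthetic cohort
#'
#' Builds one transcript per configured gene: an in-frame coding region
#' embedding the planted AP2 (and, for RAV, B3) domains, flanked by UTRs.
#' Partial domains are truncated at a transcript end, as expected for
#' incompletely assembled contigs. Deterministic for a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @return list with elements `transcripts` (named character vector of DNA
#'   sequences, ids `synth_<family>_<n>`), `genes` (truth data.frame: gene,
#'   family, group, subgroup, completeness class, CDS interval, UTR
#'   presence), `domains` (truth data.frame, one row per planted domain with
#'   transcript/protein coordinates, model span and completeness), and
#'   `domain_residues` (matrix of numbered residues, one row per planted
#'   domain, columns [numbered_positions()]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  noise <- config$noise
  codons <- codon_table()

  gene_plan <- build_gene_plan(config)
  mods <- plan_modifications(gene_plan, config)
  n <- nrow(gene_plan)
  if (n == 0L) {
    return(list(transcripts = stats::setNames(character(0), character(0)),
                genes = gene_plan,
                domains = empty_domain_truth(),
                domain_residues = matrix(character(0), 0, 59,
                                         dimnames = list(NULL,
                                                         numbered_positions())),
                config = config))
  }

  # Stage 1: sample residues for every planted domain.
  dom_rows <- list()
  for (i in seq_len(n)) {
    g <- gene_plan[i, ]
    nd <- if (g$family == "AP2" &&
              g$class %in% c("two_full", "full_partial", "two_partial")) 2L
          else 1L
    for (r in seq_len(nd)) {
      res <- sample_domain(g$family,
                           if (g$family %in% c("ERF", "RAV")) g$group else
                             NULL, noise)
      res <- apply_modifications(res, mods[[g$gene]])
      dom_rows[[length(dom_rows) + 1L]] <-
        list(gene = g$gene, family = g$family, group = g$group,
             rep = r, res = res)
    }
  }

  # Guard: no non-universal core position may be 100% conserved with one
  # residue in every ERF group among full-domain ERF domains (keeps the
  # universal-residue set exactly the planted ten at any seed).
  dom_rows <- enforce_nonuniversal(dom_rows, gene_plan)

  # Stage 2: truncate partial domains, assemble proteins and transcripts.
  transcripts <- character(n)
  genes_out <- gene_plan
  genes_out$cds_start <- NA_integer_
  genes_out$cds_end <- NA_integer_
  genes_out$utr5 <- FALSE
  genes_out$utr3 <- FALSE
  domains_out <- list()
  residues_out <- list()

  dom_by_gene <- split(seq_along(dom_rows),
                       vapply(dom_rows, `[[`, character(1), "gene"))

  for (i in seq_len(n)) {
    g <- gene_plan[i, ]
    idx <- dom_by_gene[[g$gene]]
    doms <- dom_rows[idx]
    built <- assemble_gene(g, doms, config, codons)
    transcripts[i] <- built$dna
    genes_out$cds_start[i] <- built$cds_start
    genes_out$cds_end[i] <- built$cds_end
    genes_out$utr5[i] <- built$utr5
    genes_out$utr3[i] <- built$utr3
    domains_out <- c(domains_out, built$domains)
    residues_out <- c(residues_out, built$residues)
  }
  names(transcripts) <- gene_plan$gene

  domains_df <- do.call(rbind, lapply(domains_out, as.data.frame,
                                      stringsAsFactors = FALSE))
  rownames(domains_df) <- NULL
  res_mat <- do.call(rbind, residues_out)
  colnames(res_mat) <- numbered_positions()
  rownames(res_mat) <- paste0(domains_df$gene, "_R", domains_df$rep)

  list(transcripts = transcripts, genes = genes_out, domains = domains_df,
       domain_residues = res_mat, config = config)
}

empty_domain_truth <- function() {
  data.frame(gene = character(0), family = character(0), group = character(0),
             rep = integer(0), kind = character(0), completeness = character(0),
             model_start = integer(0), model_end = integer(0),
             aa_start = integer(0), aa_len = integer(0),
             nt_start = integer(0), nt_end = integer(0),
             has_insertion = logical(0), stringsAsFactors = FALSE)
}

# One row per gene: id, family, group, subgroup letter, completeness class.
build_gene_plan <- function(config) {
  rows <- list()
  add <- function(family, class, group = NA_character_,
                  subgroup = NA_character_, fam_index, fam_total) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, class = class, group = group, subgroup = subgroup,
      fam_index = fam_index, fam_total = fam_total, stringsAsFactors = FALSE)
  }
  ap2_classes <- rep(c("two_full", "full_partial", "two_partial", "one_full",
                       "one_partial"),
                     c(config$ap2_two_full, config$ap2_full_partial,
                       config$ap2_two_partial, config$ap2_one_full,
                       config$ap2_one_partial))
  for (k in seq_along(ap2_classes))
    add("AP2", ap2_classes[k], fam_index = k, fam_total = length(ap2_classes))
  erf_k <- 0L
  for (grp in names(config$erf_groups)) {
    ng <- config$erf_groups[[grp]]
    if (ng == 0L) next
    letters_g <- if (grp == "VI-L") rep("", ng)
                 else rep(c("a", "b"), c(ceiling(ng / 2), floor(ng / 2)))
    for (j in seq_len(ng)) {
      erf_k <- erf_k + 1L
      add("ERF", "full", grp, letters_g[j], fam_index = erf_k, fam_total = 0L)
    }
  }
  if (config$erf_partial > 0L) {
    grps <- rep(names(config$erf_groups),
                length.out = config$erf_partial)
    sides <- rep(c("partial_N", "partial_C"),
                 length.out = config$erf_partial)
    for (j in seq_len(config$erf_partial)) {
      erf_k <- erf_k + 1L
      add("ERF", sides[j], grps[j], "", fam_index = erf_k, fam_total = 0L)
    }
  }
  for (k in seq_len(config$rav))
    add("RAV", "full", fam_index = k, fam_total = config$rav)
  for (k in seq_len(config$soloist))
    add("SOLOIST", "short", fam_index = k, fam_total = config$soloist)
  if (!length(rows))
    return(data.frame(gene = character(0), family = character(0),
                      class = character(0), group = character(0),
                      subgroup = character(0), fam_index = integer(0),
                      fam_total = integer(0), stringsAsFactors = FALSE))
  plan <- do.call(rbind, rows)
  idx <- stats::ave(seq_len(nrow(plan)), plan$family, FUN = seq_along)
  plan$gene <- paste0("synth_", tolower(plan$family), "_", idx)
  plan[, c("gene", "family", "class", "group", "subgroup", "fam_index",
           "fam_total")]
}

enforce_nonuniversal <- function(dom_rows, gene_plan) {
  is_erf_full <- vapply(dom_rows, function(d) {
    d$family == "ERF" &&
      gene_plan$class[match(d$gene, gene_plan$gene)] == "full"
  }, logical(1))
  if (!any(is_erf_full)) return(dom_rows)
  idx <- which(is_erf_full)
  grp <- vapply(dom_rows[idx], `[[`, character(1), "group")
  mat <- do.call(rbind, lapply(dom_rows[idx], `[[`, "res"))
  core <- ap2_positions()
  check <- setdiff(core, names(UNIVERSAL_RESIDUES))
  for (p in check) {
    col <- mat[, p]
    if (anyNA(col)) next
    if (length(unique(col)) == 1L) {
      groups_present <- unique(grp)
      per_group_same <- all(vapply(groups_present, function(gg)
        length(unique(col[grp == gg])) == 1L, logical(1)))
      if (per_group_same && length(groups_present) >= 2L) {
        # flip one copy in the largest group to the next alphabet residue
        big <- names(sort(table(grp), decreasing = TRUE))[1]
        tgt <- idx[grp == big][1]
        cur <- dom_rows[[tgt]]$res[p]
        alt <- setdiff(AA_ALPHABET, cur)[1]
        dom_rows[[tgt]]$res[p] <- alt
      }
    }
  }
  dom_rows
}

# Assemble one gene's protein(s) and transcript; returns truth rows.
assemble_gene <- function(g, doms, config, codons) {
  flank <- function() sample(config$flank_aa_range[1]:config$flank_aa_range[2],
                             1L)
  utr <- function() sample(config$utr_range[1]:config$utr_range[2], 1L)
  keep_n <- function() sample(20:40, 1L)

  res_list <- lapply(doms, `[[`, "res")
  cls <- g$class

  # decide truncations per class
  trunc <- list()
  if (g$family == "AP2") {
    trunc <- switch(cls,
      two_full    = list(NULL, NULL),
      full_partial = list(NULL, list(side = "C", keep = keep_n())),
      two_partial = list(list(side = "N", keep = keep_n()),
                         list(side = "C", keep = keep_n())),
      one_full    = list(NULL),
      one_partial = list(list(side = "C", keep = keep_n())))
    res_list <- res_list[seq_along(trunc)]
  } else if (g$family == "ERF" && cls != "full") {
    side <- if (cls == "partial_N") "N" else "C"
    trunc <- list(list(side = side, keep = keep_n()))
  } else {
    trunc <- rep(list(NULL), length(res_list))
  }
  for (j in seq_along(trunc)) if (!is.null(trunc[[j]]))
    res_list[[j]] <- truncate_domain(res_list[[j]], trunc[[j]]$side,
                                     trunc[[j]]$keep)

  completeness <- vapply(seq_along(res_list), function(j) {
    if (g$family == "SOLOIST") return("short")
    if (is.null(trunc[[j]])) "full"
    else if (trunc[[j]]$side == "N") "partial_N" else "partial_C"
  }, character(1))

  # layout: optional N flank, domains (+ linker), optional C flank
  open5 <- completeness[1] == "partial_N"             # transcript 5'-truncated
  open3 <- completeness[length(completeness)] == "partial_C"

  pieces <- character(0)     # protein pieces
  dom_aa_start <- integer(length(res_list))
  aa_len <- 0L
  if (!open5) {
    nf <- flank()
    pieces <- c(pieces, paste0("M", random_aa(nf - 1L)))
    aa_len <- nf
  }
  for (j in seq_along(res_list)) {
    if (j > 1L) {
      linker <- random_aa(25L)
      pieces <- c(pieces, linker)
      aa_len <- aa_len + 25L
    }
    s <- domain_string(res_list[[j]])
    dom_aa_start[j] <- aa_len + 1L
    pieces <- c(pieces, s)
    aa_len <- aa_len + nchar(s)
  }
  b3_aa_start <- NA_integer_
  if (g$family == "RAV") {
    linker <- random_aa(20L)
    pieces <- c(pieces, linker)
    aa_len <- aa_len + 20L
    b3 <- noisy_string(B3_CONSENSUS, config$noise)
    b3_aa_start <- aa_len + 1L
    pieces <- c(pieces, b3)
    aa_len <- aa_len + nchar(b3)
  }
  if (!open3) {
    cf <- flank()
    pieces <- c(pieces, random_aa(cf))
    aa_len <- aa_len + cf
  }
  protein <- paste(pieces, collapse = "")

  cds_nt <- reverse_translate(protein, codons)
  if (!open3) cds_nt <- paste0(cds_nt, "TAA")
  utr5 <- if (open5) "" else random_dna(utr())
  utr3 <- if (open3) "" else random_dna(utr())
  dna <- paste0(utr5, cds_nt, utr3)

  cds_start <- nchar(utr5)
  cds_end <- cds_start + nchar(cds_nt)

  domains <- list()
  residues <- list()
  for (j in seq_along(res_list)) {
    res <- res_list[[j]]
    present_core <- which(!is.na(res[setdiff(names(res), "167i")]))
    s <- domain_string(res)
    nt_start <- cds_start + 3L * (dom_aa_start[j] - 1L)
    kind_row <- list(
      gene = g$gene, family = g$family, group = g$group, rep = j,
      kind = "AP2", completeness = completeness[j],
      model_start = min(present_core), model_end = max(present_core),
      aa_start = dom_aa_start[j], aa_len = nchar(s),
      nt_start = nt_start, nt_end = nt_start + 3L * nchar(s),
      has_insertion = !is.na(res["167i"]))
    domains[[length(domains) + 1L]] <- kind_row
    residues[[length(residues) + 1L]] <- res
  }
  if (g$family == "RAV") {
    nt_start <- cds_start + 3L * (b3_aa_start - 1L)
    domains[[length(domains) + 1L]] <- list(
      gene = g$gene, family = g$family, group = g$group, rep = 2L,
      kind = "B3", completeness = "full",
      model_start = 1L, model_end = nchar(B3_CONSENSUS),
      aa_start = b3_aa_start, aa_len = nchar(B3_CONSENSUS),
      nt_start = nt_start, nt_end = nt_start + 3L * nchar(B3_CONSENSUS),
      has_insertion = FALSE)
    residues[[length(residues) + 1L]] <-
      stats::setNames(rep(NA_character_, 59L), numbered_positions())
  }

  list(dna = dna, cds_start = cds_start, cds_end = cds_end,
       utr5 = !open5, utr3 = !open3, domains = domains, residues = residues)
}

noisy_string <- function(s, noise) {
  aa <- strsplit(s, "")[[1]]
  mut <- which(stats::runif(length(aa)) < noise)
  for (i in mut) aa[i] <- sample(setdiff(AA_ALPHABET, aa[i]), 1L)
  paste(aa, collapse = "")
}

# ---- read membership --------------------------------------------------------

#' Generate a synthetic read-membership table
#'
#' Allocates `total_reads` reads multinomially over genes x tissues: each
#' gene receives a log-normal expression weight and each tissue the share
#' configured in the cohort, mirroring per-library read counting from an
#' assembly.
#'
#' @param cohort output of [generate_cohort()] (or any list with a `genes`
#'   data.frame and `config`).
#' @param total_reads total read count to distribute.
#' @param seed RNG seed.
#' @param tissues optional named weight vector overriding the cohort config.
#' @return data.frame with columns contig_id, library, read_count (all
#'   gene x tissue cells).
#' @export
generate_read_membership <- function(cohort, total_reads = 6318L,
                                     seed = 1L, tissues = NULL) {
  if (total_reads < 0) stop("total_reads must be >= 0")
  w <- if (is.null(tissues)) cohort$config$tissues else tissues
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("unknown tissue label: tissue weights must be named")
  genes <- cohort$genes$gene
  grid <- expand.grid(contig_id = genes, library = names(w),
                      stringsAsFactors = FALSE)
  if (!nrow(grid) || total_reads == 0L) {
    grid$read_count <- integer(nrow(grid))
    return(grid)
  }
  with_seed(seed, {
    gw <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
    p <- as.vector(outer(gw / sum(gw), w / sum(w)))
    grid$read_count <- as.integer(stats::rmultinom(1L, total_reads, p))
  })
  grid
}

# ---- miRNA pair planting ----------------------------------------------------

#' Plant miRNA/target pairs on a cohort
#'
#' Each planted site takes the reverse complement of an existing transcript
#' window as the miRNA, then perturbs the miRNA side only: cleavage-type
#' sites get one G:U wobble outside positions 9-11 (positions 9-11 stay
#' Watson-Crick); translation-type sites get a non-pairing base opposite
#' miRNA position 9. Sites are placed in UTRs or CDS regions outside the
#' AP2 domain so planting never disturbs domain recovery. All planted sites
#' satisfy the default acceptance thresholds of the target scanner.
#'
#' @param cohort output of [generate_cohort()].
#' @param n_sites number of sites to plant (half cleavage, half translation).
#' @param seed RNG seed.
#' @param site_length planted site length (nt).
#' @return list with `mirnas` (named character vector, RNA alphabet) and
#'   `sites` (truth data.frame: mirna_id, gene, tx_start, tx_end (0-based
#'   half-open), mode, region).
#' @export
generate_mirna_pairs <- function(cohort, n_sites = 12L, seed = 1L,
                                 site_length = 21L) {
  sites_empty <- data.frame(mirna_id = character(0), gene = character(0),
                            tx_start = integer(0), tx_end = integer(0),
                            mode = character(0), region = character(0),
                            stringsAsFactors = FALSE)
  if (n_sites == 0L)
    return(list(mirnas = stats::setNames(character(0), character(0)),
                sites = sites_empty))
  genes <- cohort$genes
  eligible <- genes[genes$utr5 & genes$utr3, , drop = FALSE]
  if (nrow(eligible) < n_sites)
    stop("n_sites exceeds the number of eligible (untruncated) transcripts")
  with_seed(seed, {
    pick <- eligible$gene[sample.int(nrow(eligible), n_sites)]
    regions <- rep(c("5'UTR", "CDS-before-AP2", "CDS-after-AP2", "3'UTR"),
                   length.out = n_sites)
    modes <- rep(c("cleavage", "translation"), length.out = n_sites)
    mirnas <- character(0)
    rows <- list()
    for (k in seq_len(n_sites)) {
      gid <- pick[k]
      gi <- genes[genes$gene == gid, ]
      dom <- cohort$domains[cohort$domains$gene == gid &
                              cohort$domains$kind == "AP2", ][1, ]
      tx <- cohort$transcripts[[gid]]
      L <- nchar(tx)
      win <- site_window(regions[k], gi, dom, L, site_length)
      if (is.null(win)) {
        warning("transcript ", gid, " too short for a planted site; skipped")
        next
      }
      start <- win[1]  # 0-based
      target <- substr(tx, start + 1L, start + site_length)
      mir <- perturb_mirna(rc_rna(target), target, modes[k])
      mid <- paste0("synth_miR_", k)
      mirnas[mid] <- mir
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mid, gene = gid, tx_start = start,
        tx_end = start + site_length, mode = modes[k], region = regions[k],
        stringsAsFactors = FALSE)
    }
    sites <- if (length(rows)) do.call(rbind, rows) else sites_empty
    list(mirnas = mirnas, sites = sites)
  })
}

# choose a 0-based window start inside the requested region
site_window <- function(region, gi, dom, L, len) {
  rng <- switch(region,
    "5'UTR" = c(0L, gi$cds_start),
    "3'UTR" = c(gi$cds_end, L),
    "CDS-before-AP2" = c(gi$cds_start, dom$nt_start),
    "CDS-after-AP2" = c(dom$nt_end, gi$cds_end))
  if (rng[2] - rng[1] < len) return(NULL)
  start <- rng[1] + sample.int(rng[2] - rng[1] - len + 1L, 1L) - 1L
  c(start, start + len)
}

rc_rna <- function(dna) {
  comp <- chartr("ACGTU", "UGCAA", dna)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Perturb the miRNA (5'->3'); miRNA position p faces target base
# target[len - p + 1]. Positions 10-11 always stay Watson-Crick.
perturb_mirna <- function(mir, target, mode) {
  m <- strsplit(mir, "")[[1]]
  t <- strsplit(chartr("T", "U", target), "")[[1]]
  len <- length(m)
  facing <- function(p) t[len - p + 1L]
  if (mode == "cleavage") {
    # one G:U wobble at the first eligible position outside 9-11
    for (p in setdiff(3:(len - 2L), 9:11)) {
      tb <- facing(p)
      if (tb == "G") { m[p] <- "U"; break }
      if (tb == "U") { m[p] <- "G"; break }
    }
  } else {
    tb <- facing(9L)
    m[9L] <- switch(tb, A = "C", C = "A", G = "A", U = "C")
  }
  paste(m, collapse = "")
}

# ---- reference panels -------------------------------------------------------

#' Generate a labelled ERF reference panel
#'
#' Independent domain draws for each ERF group, used as the labelled
#' references for tree-based group assignment (the role the Arabidopsis
#' panel plays for real data). Subgroup letters are attached round-robin so
#' they can be carried (never inferred) onto queries.
#'
#' @param n_per_group domains per group.
#' @param seed RNG seed.
#' @param noise substitution noise outside diagnostic positions.
#' @return list with `residues` (matrix, rows = references, columns
#'   [numbered_positions()]) and `labels` (data.frame: id, group, subgroup).
#' @export
generate_reference_panel <- function(n_per_group = 3L, seed = 100L,
                                     noise = 0.05) {
  with_seed(seed, {
    rows <- list()
    labs <- list()
    for (grp in ERF_GROUPS) {
      letters_g <- if (grp == "VI-L") rep("", n_per_group)
                   else rep(c("a", "b", "c"), length.out = n_per_group)
      for (j in seq_len(n_per_group)) {
        id <- paste0("ref_", gsub("-", "", grp), "_", j)
        rows[[id]] <- sample_domain("ERF", grp, noise)
        labs[[length(labs) + 1L]] <- data.frame(
          id = id, group = grp, subgroup = letters_g[j],
          stringsAsFactors = FALSE)
      }
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- numbered_positions()
    list(residues = mat, labels = do.call(rbind, labs))
  })
}

# ---- output -----------------------------------------------------------------

#' Write a cohort to disk
#'
#' Transcripts as FASTA, gene and domain truth and read membership as TSV,
#' and the configuration as plain key=value text.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param membership optional read-membership data.frame to write alongside.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, membership = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "transcripts.fasta")
  seqs <- Biostrings::DNAStringSet(cohort$transcripts)
  Biostrings::writeXStringSet(seqs, fa)
  files <- fa
  tsv <- function(x, name) {
    f <- file.path(dir, name)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(files, tsv(cohort$genes, "genes_truth.tsv"),
             tsv(cohort$domains, "domains_truth.tsv"))
  if (!is.null(membership))
    files <- c(files, tsv(membership, "read_membership.tsv"))
  cfgf <- file.path(dir, "config.txt")
  cfg <- cohort$config
  flat <- c(
    vapply(c("ap2_two_full", "ap2_full_partial", "ap2_two_partial",
             "ap2_one_full", "ap2_one_partial", "erf_partial", "rav",
             "soloist", "noise", "seed"),
           function(k) paste0(k, "=", cfg[[k]]), character(1)),
    paste0("erf_groups=", paste(names(cfg$erf_groups), cfg$erf_groups,
                                sep = ":", collapse = ",")),
    paste0("tissues=", paste(names(cfg$tissues), cfg$tissues,
                             sep = ":", collapse = ",")))
  writeLines(flat, cfgf)
  invisible(c(files, cfgf))
}
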