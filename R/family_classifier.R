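# Domain-architecture family classification: AP2 / ERF / RAV / Soloist.

#' Classify one gene from its domain hits
#'
#' Architecture rules: two AP2 domains give AP2; one AP2 plus a B3 domain
#' gives RAV; a short AP2 domain (full span, four or more internal
#' deletions) gives SOLOIST; a single full or partial AP2 domain gives ERF
#' unless a homology hint says the gene sits closer to the AP2 family (the
#' published rationale for single-domain AP2-family members); no hits give
#' UNCLASSIFIED.
#'
#' @param hits data.frame of hits for one gene (columns kind, completeness
#'   at minimum).
#' @param homology_hint optional "AP2" or "ERF" from [homology_family_hint()].
#' @return list: family, completeness summary, override flag.
#' @export
classify_family <- function(hits, homology_hint = NULL) {
  if (!is.null(hits$contig) && length(unique(hits$contig)) > 1L)
    stop("hits from mixed genes; classify one gene at a time")
  ap2 <- hits[hits$kind == "AP2", , drop = FALSE]
  b3 <- hits[hits$kind == "B3", , drop = FALSE]
  n_ap2 <- nrow(ap2)
  override <- FALSE
  if (n_ap2 == 0L) {
    family <- "UNCLASSIFIED"
  } else if (n_ap2 >= 2L) {
    family <- "AP2"
  } else if (nrow(b3) >= 1L) {
    family <- "RAV"
  } else if (ap2$completeness[1] == "short") {
    family <- "SOLOIST"
  } else if (!is.null(homology_hint) && identical(homology_hint, "AP2")) {
    family <- "AP2"
    override <- TRUE
  } else {
    family <- "ERF"
  }
  list(family = family,
       completeness = completeness_summary(family, ap2),
       homology_override = override)
}

completeness_summary <- function(family, ap2) {
  if (!nrow(ap2)) return("none")
  cls <- ap2$completeness
  is_full <- cls == "full" | cls == "short"
  if (nrow(ap2) >= 2L) {
    if (all(is_full)) "two-full"
    else if (any(is_full)) "full+partial"
    else "two-partial"
  } else {
    if (is_full[1]) "one-full" else "one-partial"
  }
}

#' Nearest-family homology hint for a single-domain gene
#'
#' Scores the domain residues against the AP2-family and ERF consensus
#' profiles at the family-informative positions (position 150 plus the
#' AP2-family variant positions) and returns the closer family. Used to
#' implement the homology override for single-domain AP2-family members.
#'
#' @param numbered named residue vector from [anchor_align()] (or a row of
#'   generator truth).
#' @return "AP2" or "ERF".
#' @export
homology_family_hint <- function(numbered) {
  info_pos <- c("150", names(AP2_FAMILY_VARIANTS))
  ap2_res <- c(`150` = "T", AP2_FAMILY_VARIANTS)
  erf_res <- c(`150` = "R", AP2_SCAFFOLD[names(AP2_FAMILY_VARIANTS)])
  obs <- numbered[info_pos]
  present <- !is.na(obs)
  ap2_match <- sum(present & (obs == ap2_res |
                                (info_pos == "150" & obs %in% "A")))
  erf_match <- sum(present & obs == erf_res)
  # strict majority among the informative positions the (possibly partial)
  # domain actually covers, with at least two concordant residues
  if (ap2_match >= 2L && ap2_match > erf_match) "AP2" else "ERF"
}

#' Assign published-style gene names
#'
#' `Hb<family>-<n>` for AP2 and RAV, `HbSoloist<n>` for soloists, and
#' `HbERF-<group><subgroup letter><n>` for ERF members (e.g. HbERF-VIIa12).
#' Numbering is stable under the input order, counted within each family
#' (within group+subgroup for ERF).
#'
#' @param calls data.frame with columns gene, family.
#' @param groups optional data.frame (gene, group, subgroup) for ERF
#'   members.
#' @return `calls` with a `name` column added.
#' @export
assign_names <- function(calls, groups = NULL) {
  key <- character(nrow(calls))
  label <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    fam <- calls$family[i]
    if (fam == "ERF") {
      grp <- sub <- ""
      if (!is.null(groups)) {
        j <- match(calls$gene[i], groups$gene)
        if (!is.na(j)) {
          grp <- groups$group[j]
          sub <- if (is.na(groups$subgroup[j])) "" else groups$subgroup[j]
        }
      }
      key[i] <- paste0("ERF:", grp, sub)
      label[i] <- paste0("HbERF-", grp, sub)
    } else if (fam == "SOLOIST") {
      key[i] <- "SOLOIST"
      label[i] <- "HbSoloist"
    } else if (fam == "UNCLASSIFIED") {
      key[i] <- "UNCLASSIFIED"
      label[i] <- "unclassified"
    } else {
      key[i] <- fam
      label[i] <- paste0("Hb", fam, "-")
    }
  }
  idx <- stats::ave(seq_len(nrow(calls)), key, FUN = seq_along)
  calls$name <- paste0(label, idx)
  calls
}

#' Family-by-completeness summary table
#'
#' Mirrors the published classification summary layout: per family, the
#' domain-architecture completeness classes with family totals and a grand
#' total.
#'
#' @param calls data.frame with columns family, completeness.
#' @return data.frame: family, conserved_domain (completeness class), count,
#'   with per-family "Total" rows and a final TOTAL row.
#' @export
tabulate_families <- function(calls) {
  layout <- list(
    AP2 = c("two-full", "full+partial", "two-partial", "one-full",
            "one-partial"),
    ERF = c("one-full", "one-partial"),
    RAV = c("one-full"),
    SOLOIST = c("one-full"))
  rows <- list()
  for (fam in names(layout)) {
    sub <- calls[calls$family == fam, , drop = FALSE]
    for (cls in layout[[fam]])
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, conserved_domain = cls,
        count = sum(sub$completeness == cls), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, conserved_domain = "Total", count = nrow(sub),
      stringsAsFactors = FALSE)
  }
  n_uncl <- sum(calls$family == "UNCLASSIFIED")
  if (n_uncl > 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      family = "UNCLASSIFIED", conserved_domain = "", count = n_uncl,
      stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    family = "TOTAL", conserved_domain = "", count = nrow(calls),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
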