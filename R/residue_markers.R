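# Per-group conservation, diagnostic-residue discovery, motif scans,
# DREB/ERF subfamily calls and Nakano-to-Sakuma nomenclature mapping.

#' Per-group, per-position residue frequencies
#'
#' @param residues residue matrix (rows = domains, columns = position
#'   labels, NA = gap).
#' @param groups group label per row.
#' @return list: `freq` (data.frame group, position, residue, freq summing
#'   to 1 over non-gap residues per group x position) and `gaps`
#'   (data.frame group, position, gap_fraction, n).
#' @export
column_conservation <- function(residues, groups) {
  stopifnot(nrow(residues) == length(groups))
  freq_rows <- list()
  gap_rows <- list()
  for (g in unique(groups)) {
    sub <- residues[groups == g, , drop = FALSE]
    for (p in colnames(sub)) {
      col <- sub[, p]
      n <- length(col)
      nong <- col[!is.na(col)]
      gap_rows[[length(gap_rows) + 1L]] <- data.frame(
        group = g, position = p, gap_fraction = 1 - length(nong) / n,
        n = n, stringsAsFactors = FALSE)
      if (!length(nong)) next
      tab <- table(nong)
      freq_rows[[length(freq_rows) + 1L]] <- data.frame(
        group = g, position = p, residue = names(tab),
        freq = as.numeric(tab) / length(nong), stringsAsFactors = FALSE)
    }
  }
  list(freq = do.call(rbind, freq_rows), gaps = do.call(rbind, gap_rows))
}

#' Universally conserved residues
#'
#' Positions where one residue reaches `min_conservation` percent in every
#' group of the table.
#'
#' @param conservation output of [column_conservation()].
#' @param min_conservation percent threshold.
#' @return data.frame: position, residue.
#' @export
find_universal_residues <- function(conservation, min_conservation = 100) {
  freq <- conservation$freq
  groups <- unique(freq$group)
  if (min_conservation <= 0) {
    # every residue trivially reaches a zero threshold in every group
    pos <- unique(freq$position)
    modal <- vapply(pos, function(p) {
      sub <- freq[freq$position == p, ]
      sub$residue[which.max(sub$freq)]
    }, character(1))
    return(data.frame(position = pos, residue = modal,
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  out <- list()
  for (p in unique(freq$position)) {
    sub <- freq[freq$position == p & freq$freq * 100 >= min_conservation, ]
    for (r in unique(sub$residue)) {
      if (length(unique(sub$group[sub$residue == r])) == length(groups))
        out[[length(out) + 1L]] <- data.frame(position = p, residue = r,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(position = character(0), residue = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Discover group-diagnostic residues
#'
#' A residue is a group marker when its within-group conservation reaches
#' `within_min` percent while at most `max_shared_groups` other groups carry
#' it above `outside_max` percent (0 shared groups is the strict
#' group-specific case; the default 1 admits the published markers that two
#' groups share, such as the group VIII pair borrowed from groups V and VI).
#' At a position with a reported marker, additional residues above
#' `secondary_min` percent that pass the same exclusivity test are reported
#' too (the published T150/A150-style split). Groups whose domains occupy
#' the "167i" insertion slot in at least `within_min` percent of members,
#' against at most `outside_max` percent elsewhere, are reported as
#' "+X167"-type markers (position "167i", residue "X").
#'
#' @param conservation output of [column_conservation()].
#' @param within_min,outside_max,secondary_min percent thresholds.
#' @param max_shared_groups how many other groups may exceed `outside_max`.
#' @return data.frame (MarkerTable): group, position, residue,
#'   conservation_pct.
#' @export
find_group_markers <- function(conservation, within_min = 90,
                               outside_max = 10, max_shared_groups = 1L,
                               secondary_min = 5) {
  freq <- conservation$freq
  gaps <- conservation$gaps
  groups <- unique(freq$group)
  out <- list()
  exclusivity_ok <- function(g, p, r) {
    others <- freq[freq$position == p & freq$residue == r &
                     freq$group != g & freq$freq * 100 > outside_max, ]
    # a residue absent from a group's rows is at frequency 0 there
    nrow(others) <= max_shared_groups
  }
  core_positions <- setdiff(unique(freq$position), "167i")
  for (g in groups) {
    for (p in core_positions) {
      rows <- freq[freq$group == g & freq$position == p, , drop = FALSE]
      if (!nrow(rows)) next
      primary <- rows[rows$freq * 100 >= within_min, , drop = FALSE]
      primary <- primary[vapply(primary$residue, exclusivity_ok,
                                logical(1), g = g, p = p), , drop = FALSE]
      if (!nrow(primary)) next
      secondary <- rows[rows$freq * 100 >= secondary_min &
                          rows$freq * 100 < within_min, , drop = FALSE]
      secondary <- secondary[vapply(secondary$residue, exclusivity_ok,
                                    logical(1), g = g, p = p), ,
                             drop = FALSE]
      rep_rows <- rbind(primary, secondary)
      out[[length(out) + 1L]] <- data.frame(
        group = g, position = p, residue = rep_rows$residue,
        conservation_pct = round(rep_rows$freq * 100, 1),
        stringsAsFactors = FALSE)
    }
    # +X167 insertion-occupancy rule
    occ <- gaps[gaps$position == "167i", , drop = FALSE]
    if (nrow(occ)) {
      own <- 1 - occ$gap_fraction[occ$group == g]
      others <- 1 - occ$gap_fraction[occ$group != g]
      if (length(own) && own * 100 >= within_min &&
          all(others * 100 <= outside_max))
        out[[length(out) + 1L]] <- data.frame(
          group = g, position = "167i", residue = "X",
          conservation_pct = round(own * 100, 1), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), position = character(0),
                      residue = character(0), conservation_pct = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(match(res$group, c("AP2", ERF_GROUPS, "RAV")),
                   res$position, -res$conservation_pct), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' DREB/ERF subfamily call from positions 158 and 163
#'
#' V158 with E163 gives DREB; A158 with D163 gives ERF; anything else is
#' UNRESOLVED and falls back to tree placement.
#'
#' @param numbered a `numbered_domain` (or named residue vector).
#' @return "DREB", "ERF" or "UNRESOLVED".
#' @export
subfamily_call <- function(numbered) {
  r158 <- numbered[["158"]]
  r163 <- numbered[["163"]]
  if (!is.na(r158) && !is.na(r163)) {
    if (r158 == "V" && r163 == "E") return("DREB")
    if (r158 == "A" && r163 == "D") return("ERF")
  }
  "UNRESOLVED"
}

EAR_PATTERN <- "[LF]DLN[LF].P"

#' Scan a peptide for conserved AP2/ERF motifs
#'
#' Literal scans for the YRG, WLG and RAYD elements, the VI-L-specific
#' KREYD motif, and the EAR repression motif as the pattern (L/F)DLN(L/F)xP.
#'
#' @param aa peptide sequence.
#' @return data.frame: motif, present, position (1-based first occurrence
#'   or NA).
#' @export
scan_motifs <- function(aa) {
  pats <- c(YRG = "YRG", WLG = "WLG", RAYD = "RAYD", KREYD = "KREYD",
            EAR = EAR_PATTERN)
  pos <- vapply(pats, function(p) {
    m <- regexpr(p, aa)
    if (m[1] == -1L) NA_integer_ else as.integer(m[1])
  }, integer(1))
  data.frame(motif = names(pats), present = !is.na(pos), position = pos,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map Nakano families/groups to the Sakuma nomenclature
#'
#' @param family "AP2", "ERF", "RAV" or "SOLOIST".
#' @param group ERF group ("I".."X", "VI-L", "Xb-L"); ignored otherwise.
#' @return list: subfamily, subgroup band (NA where Sakuma has none).
#' @export
map_nomenclature <- function(family, group = NA) {
  if (family %in% c("AP2", "RAV", "SOLOIST"))
    return(list(subfamily = family, subgroup = NA_character_))
  if (family != "ERF") stop("unknown family: ", family)
  if (is.na(group)) stop("ERF member needs a group")
  if (group %in% DREB_GROUPS)
    list(subfamily = "DREB", subgroup = "A-1 to A-6")
  else if (group %in% c("V", "VI", "VII", "VIII", "IX", "X"))
    list(subfamily = "ERF", subgroup = "B-1 to B-6")
  else if (group %in% c("VI-L", "Xb-L"))
    list(subfamily = "ERF", subgroup = "B-6")
  else stop("unknown ERF group: ", group)
}
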