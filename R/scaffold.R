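# AP2 domain scaffold and diagnostic-residue constants.
#
# The AP2 DNA-binding domain is modelled as 58 core positions numbered
# 145..202 after the AtERF1 three-dimensional structure, with an optional
# insertion slot ("167i") between positions 167 and 168 that is occupied in
# ERF group IX (giving that group its 59-residue domain). Internally, model
# column m corresponds to structural position m + 144.

#' @useDynLib ap2erf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

AP2_MODEL_LENGTH <- 58L
AP2_POSITION_OFFSET <- 144L
AP2_INSERTION_AFTER <- 167L   # structural position preceding the "167i" slot

ERF_GROUPS <- c("I", "II", "III", "IV", "V", "VI", "VI-L", "VII", "VIII",
                "IX", "X")

# Ten residues totally conserved in every ERF group.
UNIVERSAL_RESIDUES <- c(
  `148` = "G", `150` = "R", `152` = "R", `155` = "G", `160` = "E",
  `161` = "I", `172` = "W", `173` = "L", `174` = "G", `182` = "A"
)

# DREB/ERF subfamily diagnostics: V158+E163 for groups I-IV (DREB, Sakuma
# A-groups), A158+D163 for groups V-X and VI-L (ERF, B-groups).
SUBFAMILY_POSITIONS <- c(158L, 163L)
DREB_DIAGNOSTIC <- c(`158` = "V", `163` = "E")
ERFB_DIAGNOSTIC <- c(`158` = "A", `163` = "D")
DREB_GROUPS <- c("I", "II", "III", "IV")

# Per-group diagnostic residues at AtERF1-anchored positions. Group IX is
# diagnosed by occupancy of the 167i insertion slot rather than a residue.
GROUP_MARKERS <- list(
  "I"    = c(`168` = "R"),
  "II"   = c(`175` = "S", `176` = "Y"),
  "III"  = c(`181` = "M"),
  "IV"   = c(`168` = "G"),
  "V"    = c(`168` = "K"),
  "VI"   = c(`153` = "P"),
  "VI-L" = c(`189` = "K", `196` = "M"),
  "VII"  = c(`149` = "I", `168` = "G", `169` = "V"),
  "VIII" = c(`153` = "P", `168` = "K"),
  "IX"   = character(0),      # +X167 insertion rule
  "X"    = c(`168` = "A")
)

# Family-level diagnostics at position 150 (ERF carries the universal R150).
FAMILY_150 <- list(AP2 = c("T", "A"), RAV = "V")

# Six residues missing from the Soloist short domain (contiguous block
# containing R152; the six identities beyond R152 are a modelling choice).
SOLOIST_DELETED_POSITIONS <- 149:154

# Scaffold consensus for the 58 core positions (positions 145..202).
# Carries the YRG (146-148), WLG (172-174) and RAYD (181-184) elements and
# an (R)EYD run at 190-193 that the VI-L-specific K189 completes to the
# literal KREYD motif.
AP2_SCAFFOLD <- c(
  `145` = "S", `146` = "Y", `147` = "R", `148` = "G", `149` = "K",
  `150` = "R", `151` = "V", `152` = "R", `153` = "S", `154` = "W",
  `155` = "G", `156` = "K", `157` = "W", `158` = "A", `159` = "S",
  `160` = "E", `161` = "I", `162` = "R", `163` = "D", `164` = "P",
  `165` = "N", `166` = "R", `167` = "G", `168` = "N", `169` = "E",
  `170` = "T", `171` = "R", `172` = "W", `173` = "L", `174` = "G",
  `175` = "A", `176` = "F", `177` = "D", `178` = "T", `179` = "A",
  `180` = "H", `181` = "R", `182` = "A", `183` = "Y", `184` = "D",
  `185` = "R", `186` = "A", `187` = "A", `188` = "L", `189` = "Q",
  `190` = "R", `191` = "E", `192` = "Y", `193` = "D", `194` = "R",
  `195` = "A", `196` = "L", `197` = "T", `198` = "N", `199` = "F",
  `200` = "G", `201` = "L", `202` = "I"
)

# KREYD block: fixed (noise-free) in VI-L so the literal motif is present in
# every member; noisy elsewhere so none of R190..D193 is universally
# conserved at 100%.
KREYD_POSITIONS <- 189:193

# AP2-family scaffold variants: positions where the AP2 (double-domain)
# family consensus differs from the ERF scaffold. Used by the
# nearest-family homology override for single-domain AP2 members. Each
# family gene deviates from these at most once (round-robin), keeping their
# within-family conservation below typical marker thresholds.
AP2_FAMILY_VARIANTS <- c(
  `157` = "F", `165` = "K", `178` = "S", `186` = "G", `195` = "S",
  `199` = "Y"
)

# Group "drift": each ERF group (and the RAV family) carries its own
# consensus at eight additional non-diagnostic positions, mirroring the
# broad inter-group divergence of real AP2 domains. Drift positions are
# conserved well below marker thresholds (a deterministic share of each
# group's members reverts to the scaffold), so they separate groups in the
# tree without ever entering the diagnostic-residue table.
DRIFT_POOL <- c("145", "151", "154", "156", "159", "162", "164", "166",
                "170", "171", "177", "179", "180", "183", "184", "185",
                "187", "188", "194", "197", "198", "200", "201", "202")

#' Drift consensus of one ERF group (or RAV)
#'
#' @param group ERF group label or "RAV".
#' @return named character vector of eight position -> residue entries.
#' @keywords internal
group_drift <- function(group) {
  gi <- if (identical(group, "RAV")) 12L else match(group, ERF_GROUPS)
  if (is.na(gi)) return(character(0))
  idx <- ((gi - 1L) * 5L + (0:7) * 3L) %% length(DRIFT_POOL) + 1L
  pos <- DRIFT_POOL[idx]
  res <- vapply(seq_along(pos), function(k) {
    r <- AA_ALPHABET[((gi * 7L + k * 3L) %% 20L) + 1L]
    if (r == AP2_SCAFFOLD[[pos[k]]])
      r <- AA_ALPHABET[((gi * 7L + k * 3L + 1L) %% 20L) + 1L]
    r
  }, character(1))
  stats::setNames(res, pos)
}

# Synthetic B3 DNA-binding domain consensus (50 residues). The B3 domain of
# RAV-family proteins is only used architecturally (present/absent), so a
# fixed synthetic consensus is sufficient.
B3_CONSENSUS <- paste0(
  "RESDVLVFKELVNSDLTFGLRVNWSEKF",
  "VTDHDLKEGDLVSFYREGDGEL"
)

#' Structural position labels of the AP2 domain model
#'
#' @return Character vector of the 58 core position labels ("145".."202").
#' @keywords internal
ap2_positions <- function() names(AP2_SCAFFOLD)

#' Column labels of a numbered AP2 domain (core positions plus "167i")
#'
#' @return Character vector of length 59: "145".."167", "167i", "168".."202".
#' @export
numbered_positions <- function() {
  pos <- ap2_positions()
  idx <- match(as.character(AP2_INSERTION_AFTER), pos)
  c(pos[seq_len(idx)], "167i", pos[(idx + 1L):length(pos)])
}

#' Group-consensus AP2 domain residues
#'
#' Returns the noise-free consensus of the AP2 domain for one family or ERF
#' group: the scaffold with the universal residues, subfamily diagnostics
#' (V158/E163 for groups I-IV, A158/D163 for V-X and VI-L), the group
#' diagnostic residues of the marker table, the VI-L KREYD block and, for
#' group IX, an occupied 167i insertion slot.
#'
#' @param family "ERF", "AP2", "RAV" or "SOLOIST".
#' @param group ERF group label ("I".."X", "VI-L"); ignored otherwise.
#' @param insertion_residue residue planted in the 167i slot for group IX.
#' @return Named character vector over [numbered_positions()]; unoccupied
#'   slots and soloist-deleted positions are `NA`.
#' @export
group_consensus <- function(family = "ERF", group = NULL,
                            insertion_residue = "S") {
  res <- AP2_SCAFFOLD
  if (family == "ERF") {
    diag <- if (!is.null(group) && group %in% DREB_GROUPS) DREB_DIAGNOSTIC
            else ERFB_DIAGNOSTIC
    res[names(diag)] <- diag
    if (!is.null(group)) {
      drift <- group_drift(group)
      if (length(drift)) res[names(drift)] <- drift
      mk <- GROUP_MARKERS[[group]]
      if (length(mk)) res[names(mk)] <- mk
    }
  } else if (family %in% c("AP2", "SOLOIST")) {
    res[names(AP2_FAMILY_VARIANTS)] <- AP2_FAMILY_VARIANTS
    res["150"] <- "T"
    res[names(DREB_DIAGNOSTIC)] <- DREB_DIAGNOSTIC
  } else if (family == "RAV") {
    drift <- group_drift("RAV")
    res[names(drift)] <- drift
    res["150"] <- "V"
    res[names(DREB_DIAGNOSTIC)] <- DREB_DIAGNOSTIC
  } else {
    stop("unknown family: ", family)
  }
  out <- stats::setNames(rep(NA_character_, 59L), numbered_positions())
  out[names(res)] <- res
  if (family == "ERF" && identical(group, "IX")) out["167i"] <- insertion_residue
  if (family == "SOLOIST")
    out[as.character(SOLOIST_DELETED_POSITIONS)] <- NA_character_
  out
}

#' Reference table of group-diagnostic residues
#'
#' The diagnostic-residue table the generator plants and marker discovery is
#' expected to recover: one row per (group, position, residue) with the
#' family rows T150/A150 (AP2) and V150 (RAV), the per-group ERF rows, and
#' the group IX "+X167" insertion rule (residue recorded as "X").
#'
#' @return data.frame with columns group, position, residue.
#' @export
ap2_marker_reference <- function() {
  rows <- list(
    c("AP2", "150", "T"), c("AP2", "150", "A")
  )
  for (g in ERF_GROUPS) {
    if (g == "IX") {
      rows[[length(rows) + 1L]] <- c("IX", "167i", "X")
    } else {
      mk <- GROUP_MARKERS[[g]]
      for (i in seq_along(mk))
        rows[[length(rows) + 1L]] <- c(g, names(mk)[i], unname(mk[i]))
    }
  }
  rows[[length(rows) + 1L]] <- c("RAV", "150", "V")
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("group", "position", "residue")
  out[order(match(out$group, c("AP2", ERF_GROUPS, "RAV")), out$position), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
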