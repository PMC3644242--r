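# Read-distribution summaries across tissue libraries and qPCR relative
# abundance.

#' Build a contig x library read-count matrix
#'
#' Accepts rows of either (contig, library, count) or (contig, read,
#' library) layout; the latter is aggregated by counting reads.
#'
#' @param records data.frame; layout detected from the third column
#'   (numeric = counts).
#' @param libraries optional vector of allowed library names; unknown
#'   labels are rejected.
#' @return integer matrix, rows = contigs, columns = libraries.
#' @export
count_reads <- function(records, libraries = NULL) {
  if (!nrow(records)) {
    return(matrix(integer(0), 0, length(libraries),
                  dimnames = list(NULL, libraries)))
  }
  third_numeric <- is.numeric(records[[3]])
  if (third_numeric) {
    contig <- as.character(records[[1]])
    lib <- as.character(records[[2]])
    cnt <- records[[3]]
    if (any(cnt < 0)) stop("negative read count")
    if (any(cnt != floor(cnt))) stop("read counts must be integers")
  } else {
    contig <- as.character(records[[1]])
    lib <- as.character(records[[3]])
    cnt <- rep(1L, nrow(records))
  }
  if (!is.null(libraries) && any(!(lib %in% libraries)))
    stop("unknown library label: ",
         paste(unique(setdiff(lib, libraries)), collapse = ", "))
  libs <- if (is.null(libraries)) sort(unique(lib)) else libraries
  m <- matrix(0L, length(unique(contig)), length(libs),
              dimnames = list(unique(contig), libs))
  for (k in seq_along(contig))
    m[contig[k], lib[k]] <- m[contig[k], lib[k]] + as.integer(cnt[k])
  m
}

#' Aggregate a read matrix by group with margins
#'
#' @param rm contig x library count matrix.
#' @param assignments data.frame (gene/contig id in column 1, group label
#'   in column 2); contigs without an assignment are pooled under
#'   "unassigned".
#' @return matrix group x library with a "Total" margin row and column.
#' @export
aggregate_by_group <- function(rm, assignments) {
  grp <- assignments[[2]][match(rownames(rm), assignments[[1]])]
  grp[is.na(grp)] <- "unassigned"
  agg <- rowsum(rm, grp)
  agg <- agg[order(match(rownames(agg),
                         c(paste0("Group ", ERF_GROUPS), ERF_GROUPS))), ,
             drop = FALSE]
  out <- rbind(agg, Total = colSums(agg))
  cbind(Total = rowSums(out), out)
}

#' Per-tissue read shares
#'
#' Percentages of the total, rounded half-up to one decimal.
#'
#' @param counts named numeric vector of per-tissue read counts.
#' @return named numeric vector of shares (percent).
#' @export
tissue_percentages <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("total read count must be positive")
  round_half_up(100 * counts / total, 1L)
}

round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' qPCR normalized expression ratio
#'
#' Efficiency-corrected relative abundance of a target against a reference
#' gene: `E_target^(-Cp_target) / E_ref^(-Cp_ref)`. With both amplification
#' efficiencies at the default 2.0 this reduces to the published
#' `2^-(Cp_target - Cp_reference)` form.
#'
#' @param cp_target,cp_ref crossing-point cycles (0-60).
#' @param e_target,e_ref amplification factors per cycle, in (1, 2.2].
#' @return normalized ratio (dimensionless).
#' @export
qpcr_ratio <- function(cp_target, cp_ref, e_target = 2, e_ref = 2) {
  if (any(cp_target <= 0 | cp_target >= 60) ||
      any(cp_ref <= 0 | cp_ref >= 60))
    stop("Cp values must lie in (0, 60)")
  if (any(e_target <= 1 | e_target > 2.2) || any(e_ref <= 1 | e_ref > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  e_target^(-cp_target) / e_ref^(-cp_ref)
}

#' Published per-tissue AP2/ERF read counts (five 454 libraries)
#'
#' The printed per-library totals of reads from AP2/ERF contigs, used as
#' fixed input for the tissue-share computation.
#'
#' @return named numeric vector.
#' @export
hevea_tissue_read_counts <- function() {
  c(root = 1883, bark = 1403, latex = 1341, embryogenic = 1037, leaf = 654)
}

#' Published ERF group x tissue read-count table
#'
#' The printed 11 x 5 read-count cells (ERF groups by tissue library),
#' without margins; margins are recomputed by [aggregate_by_group()].
#'
#' @return data.frame: group, bark, embryo, latex, leaf, root.
#' @export
hevea_erf_group_reads <- function() {
  f <- system.file("extdata", "erf_group_reads.tsv", package = "ap2erf",
                   mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
}
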