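# AtERF1-anchored numbering, conserved-block curation, neighbour-joining
# and reference-based ERF group assignment.

#' Anchor a domain sequence to the AtERF1 numbering
#'
#' Global alignment of an extracted domain against the 58-position model
#' (plus the 167i insertion slot): each matched model column receives the
#' aligned residue, labelled by structural position 145..202 or "167i".
#'
#' @param aa domain amino-acid sequence (length 20-70).
#' @param model a `position_model`, default [ap2_model()].
#' @return named character vector over [numbered_positions()] (`NA` at
#'   unoccupied positions), class `numbered_domain`.
#' @export
anchor_align <- function(aa, model = ap2_model()) {
  if (nchar(aa) < 20L || nchar(aa) > 70L)
    stop("domain sequence length out of range 20-70")
  codes <- aa_codes(aa)
  al <- profile_align_cpp(codes, model$scores, model$del_open, model$del_ext,
                          model$ins_open, model$ins_ext, 2L)
  h <- path_to_hit(al$path_i, al$path_j, al$score, model)
  if (is.null(h) || (h$model_end - h$model_start + 1L) < model$min_span ||
      h$score < model$threshold * span_max_score(model, h$model_start,
                                                 h$model_end))
    stop("not an AP2 domain: alignment score below model threshold")
  out <- stats::setNames(rep(NA_character_, ncol(model$scores)),
                         numbered_positions())
  chars <- strsplit(aa, "")[[1]]
  matched <- al$path_i > 0L & al$path_j > 0L
  out[al$path_j[matched]] <- chars[al$path_i[matched]]
  class(out) <- "numbered_domain"
  out
}

#' Number of occupied positions of a numbered domain
#' @param numbered output of [anchor_align()].
#' @export
occupied_positions <- function(numbered) sum(!is.na(numbered))

#' Extract a conserved alignment block
#'
#' Columns are conserved when at least half the rows are non-gap and the
#' modal residue frequency among non-gap rows reaches
#' `conservation_threshold`; maximal runs of at least `min_block`
#' consecutive conserved columns are retained (the Gblocks-style curation
#' step of the published workflow).
#'
#' @param msa residue matrix, rows = sequences, columns labelled by
#'   position (NA = gap).
#' @param conservation_threshold modal-frequency threshold.
#' @param min_block minimum run length (columns).
#' @return list (class `curated_block`): `residues` (matrix over the
#'   selected columns), `positions` (their labels).
#' @export
extract_block <- function(msa, conservation_threshold = 0.5,
                          min_block = 10L) {
  if (nrow(msa) < 4L) stop("need at least 4 sequences")
  conserved <- vapply(seq_len(ncol(msa)), function(j) {
    col <- msa[, j]
    nong <- col[!is.na(col)]
    if (length(nong) < nrow(msa) / 2) return(FALSE)
    max(table(nong)) / length(nong) >= conservation_threshold
  }, logical(1))
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- logical(ncol(msa))
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] >= min_block)
      keep[starts[k]:ends[k]] <- TRUE
  if (!any(keep))
    stop("no conserved block of at least ", min_block,
         " columns; consider lowering the conservation threshold")
  structure(list(residues = msa[, keep, drop = FALSE],
                 positions = colnames(msa)[keep]),
            class = "curated_block")
}

#' Pairwise p-distance matrix of a curated block
#'
#' d(i,j) is the fraction of differing residues among columns where both
#' rows are non-gap.
#'
#' @param block a `curated_block` (or plain residue matrix).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(block) {
  m <- if (inherits(block, "curated_block")) block$residues else block
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok))
        stop("no comparable columns between rows ", i, " and ", j)
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration with a deterministic tie-break (smallest row
#' index, then smallest column index) and negative branch-length estimates
#' clamped to zero (recorded in the `negative_clamped` attribute).
#'
#' @param d symmetric distance matrix with zero diagonal and row names.
#' @return unrooted `phylo` tree (trifurcating root node).
#' @export
nj_tree <- function(d) {
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  sub <- labels                 # newick fragment per active node
  D <- d
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (length(sub) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    # deterministic tie-break: smallest row index, then smallest column
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- bl(li); lj <- bl(lj)
    newsub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], li, sub[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    sub <- c(sub[-c(i, j)], newsub)
  }
  l1 <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[1], l1, sub[2], l2,
                 sub[3], l3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_clamped") <- clamped
  tree
}

# all clades (tip-label sets on each side of every edge) of a phylo tree
tree_clades <- function(tree) {
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  clades <- lapply(parts, function(p) tips[p])
  compl <- lapply(clades, function(cl) setdiff(tips, cl))
  c(clades, compl[lengths(compl) > 0L])
}

# marker-signature match: the most specific group whose full diagnostic
# signature (band residues at 158/163, group markers, 167i occupancy for
# IX) is carried by the numbered domain
signature_group <- function(numbered) {
  best <- NULL; best_size <- -1L; n_best <- 0L
  for (g in ERF_GROUPS) {
    band <- if (g %in% DREB_GROUPS) DREB_DIAGNOSTIC else ERFB_DIAGNOSTIC
    need <- c(band, GROUP_MARKERS[[g]])
    ok <- all(!is.na(numbered[names(need)]) &
                numbered[names(need)] == need)
    if (g == "IX") ok <- ok && !is.na(numbered["167i"])
    if (g != "IX" && ok) ok <- is.na(numbered["167i"])
    if (ok) {
      size <- length(need) + (g == "IX")
      if (size > best_size) { best <- g; best_size <- size; n_best <- 1L }
      else if (size == best_size) n_best <- n_best + 1L
    }
  }
  if (is.null(best) || n_best > 1L) NULL else best
}

#' Assign ERF groups by tree placement against labelled references
#'
#' Builds one joint neighbour-joining tree of the queries and the reference
#' panel on the curated block; each query takes the majority group label of
#' its smallest enclosing reference-containing clade. Planted diagnostic
#' residues provide secondary evidence: when a query's unique marker
#' signature contradicts the tree placement, the signature wins and the
#' `method` field records it. Subgroup letters are carried from the
#' references of the assigned group (never inferred).
#'
#' @param query_residues residue matrix of query domains (rows named by
#'   gene, columns [numbered_positions()]).
#' @param ref_residues,ref_labels reference panel from
#'   [generate_reference_panel()] (or any labelled panel).
#' @param conservation_threshold,min_block block-curation parameters.
#' @return data.frame: gene, group, subgroup, method
#'   ("tree", "markers", "tree+markers").
#' @export
assign_group <- function(query_residues, ref_residues, ref_labels,
                         conservation_threshold = 0.5, min_block = 10L) {
  if (is.null(dim(query_residues)))
    query_residues <- matrix(query_residues, nrow = 1,
                             dimnames = list("query",
                                             names(query_residues)))
  missing_groups <- setdiff(ERF_GROUPS, ref_labels$group)
  if (length(missing_groups))
    warning("references missing group(s): ",
            paste(missing_groups, collapse = ", "))
  all_res <- rbind(query_residues, ref_residues)
  block <- extract_block(all_res, conservation_threshold, min_block)
  d <- pdistance_matrix(block)
  tree <- nj_tree(d)
  clades <- tree_clades(tree)
  ref_ids <- ref_labels$id
  out <- list()
  for (q in rownames(query_residues)) {
    holding <- clades[vapply(clades, function(cl) q %in% cl, logical(1))]
    sizes <- lengths(holding)
    with_ref <- vapply(holding, function(cl)
      length(intersect(cl, ref_ids)) > 0L, logical(1))
    cand <- holding[with_ref]
    cand <- cand[order(lengths(cand))]
    tree_grp <- NA_character_
    clade_refs <- character(0)
    if (length(cand)) {
      clade_refs <- intersect(cand[[1]], ref_ids)
      labs <- ref_labels$group[match(clade_refs, ref_labels$id)]
      tab <- sort(table(labs), decreasing = TRUE)
      tree_grp <- names(tab)[1]
    }
    sig_grp <- signature_group(query_residues[q, ])
    if (!is.null(sig_grp) && !is.na(tree_grp) && sig_grp == tree_grp) {
      grp <- tree_grp; method <- "tree+markers"
    } else if (!is.null(sig_grp)) {
      grp <- sig_grp
      method <- if (is.na(tree_grp)) "markers" else "markers"
    } else {
      grp <- tree_grp; method <- "tree"
    }
    sub <- NA_character_
    if (!is.na(grp)) {
      grp_refs <- clade_refs[ref_labels$group[match(clade_refs,
                                                    ref_labels$id)] == grp]
      pool <- if (length(grp_refs)) grp_refs
              else ref_labels$id[ref_labels$group == grp]
      if (length(pool)) {
        subs <- ref_labels$subgroup[match(pool, ref_labels$id)]
        tab <- sort(table(subs), decreasing = TRUE)
        sub <- names(tab)[1]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = q, group = grp, subgroup = sub, method = method,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Root a tree for display on the AP2+RAV split
#'
#' Roots on the branch separating the AP2 and RAV families from the rest
#' when such a branch exists (display convention of the published tree).
#'
#' @param tree a `phylo`.
#' @param families named character vector mapping tip label to family.
#' @return rooted `phylo` (unchanged if no clean split exists).
#' @export
root_on_ap2_rav <- function(tree, families) {
  ar <- names(families)[families %in% c("AP2", "RAV")]
  ar <- intersect(ar, tree$tip.label)
  if (!length(ar) || length(ar) == length(tree$tip.label)) return(tree)
  if (ape::is.monophyletic(tree, ar))
    ape::root(tree, outgroup = ar, resolve.root = TRUE)
  else tree
}
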