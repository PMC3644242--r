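# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(cohort_config())
  .fixtures$cohort
}

default_classification <- function() {
  if (is.null(.fixtures$classification))
    .fixtures$classification <-
      run_classification(default_cohort()$transcripts,
                         reference_seed = 101L)
  .fixtures$classification
}

# truth-labelled full-domain residue panel (first full repeat per gene,
# soloists excluded), as used for diagnostic-residue discovery
truth_marker_panel <- function() {
  if (!is.null(.fixtures$panel)) return(.fixtures$panel)
  co <- default_cohort()
  dom <- co$domains[co$domains$kind == "AP2" &
                      co$domains$completeness == "full", ]
  dom <- dom[order(dom$gene, dom$rep), ]
  dom <- dom[!duplicated(dom$gene), ]
  mat <- co$domain_residues[paste0(dom$gene, "_R", dom$rep), , drop = FALSE]
  rownames(mat) <- dom$gene
  fam <- co$genes$family[match(dom$gene, co$genes$gene)]
  grp <- co$genes$group[match(dom$gene, co$genes$gene)]
  .fixtures$panel <- list(residues = mat,
                          labels = ifelse(fam == "ERF", grp, fam))
  .fixtures$panel
}

# deterministic domain -> transcript embedding for small scan tests
embed_domain <- function(aa, utr5 = 60L, utr3 = 60L, flank = 30L,
                         seed = 42L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    codons <- ap2erf:::codon_table()
    prot <- paste0("M", ap2erf:::random_aa(flank - 1L), aa,
                   ap2erf:::random_aa(flank))
    paste0(ap2erf:::random_dna(utr5),
           ap2erf:::reverse_translate(prot, codons), "TAA",
           ap2erf:::random_dna(utr3))
  })
}

consensus_string <- function(family = "ERF", group = "I") {
  ap2erf:::domain_string(group_consensus(family, group))
}

# brute-force least-squares topology oracle over all unrooted topologies
ls_topology_oracle <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  pairs <- t(utils::combn(n, 2))
  best <- NULL; best_ss <- Inf
  for (ti in seq_along(tops)) {
    tr <- tops[[ti]]     # [[ reattaches the shared tip labels
    # a pair's path crosses an edge iff the edge's tip split separates it
    desc <- function(node) {
      if (node <= n) return(node)
      kids <- tr$edge[tr$edge[, 1] == node, 2]
      unlist(lapply(kids, desc))
    }
    splits <- lapply(tr$edge[, 2], desc)
    A <- vapply(splits, function(sp)
      as.numeric(xor(pairs[, 1] %in% sp, pairs[, 2] %in% sp)),
      numeric(nrow(pairs)))
    dv <- d[pairs]
    fit <- qr.solve(A, dv)
    ss <- sum((A %*% fit - dv)^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- tr }
  }
  best
}

random_additive_distance <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# topology equality via canonical non-trivial bipartitions (independent of
# edge ordering and rooting conventions)
tree_splits <- function(tr) {
  n <- length(tr$tip.label)
  desc <- function(node) {
    if (node <= n) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  sp <- lapply(tr$edge[, 2][tr$edge[, 2] > n], desc)
  anchor <- sort(tr$tip.label)[1]      # same anchor for any tip ordering
  canon <- vapply(sp, function(s) {
    other <- setdiff(tr$tip.label, s)
    side <- if (anchor %in% s) s else other
    paste(sort(side), collapse = "|")
  }, character(1))
  sort(unique(canon[vapply(sp, function(s)
    length(s) >= 2 && length(s) <= n - 2, logical(1))]))
}

same_topology <- function(t1, t2) {
  identical(tree_splits(t1), tree_splits(t2))
}
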