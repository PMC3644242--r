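test_that("anchoring numbers domains against the AtERF1 coordinates", {
  ix <- anchor_align(consensus_string("ERF", "IX"))
  expect_equal(occupied_positions(ix), 59)
  expect_false(is.na(ix["167i"]))
  g1 <- anchor_align(consensus_string("ERF", "I"))
  expect_equal(occupied_positions(g1), 58)
  expect_true(is.na(g1["167i"]))
  # scaffold maps onto itself with no gaps
  scaf <- anchor_align(paste(ap2erf:::AP2_SCAFFOLD, collapse = ""))
  expect_identical(unname(scaf[names(ap2erf:::AP2_SCAFFOLD)]),
                   unname(ap2erf:::AP2_SCAFFOLD))
  # idempotence: re-anchoring the occupied residues changes nothing
  again <- anchor_align(paste(g1[!is.na(g1)], collapse = ""))
  expect_identical(unclass(again), unclass(g1))
  expect_error(anchor_align(ap2erf:::random_aa(58L)), "not an AP2 domain")
})

test_that("block curation keeps maximal conserved runs", {
  rows <- t(replicate(6, group_consensus("ERF", "I")))
  colnames(rows) <- numbered_positions()
  b <- extract_block(rows, 0.5, 10L)
  expect_equal(ncol(b$residues), 58)   # insertion slot dropped as gappy

  # one hypervariable column splits the 58 into runs of 12 and 45: with a
  # planted variable column at position 13 the curated block keeps 57
  vari <- rows
  vari[, 13] <- ap2erf:::AA_ALPHABET[seq_len(nrow(vari))]
  b57 <- extract_block(vari, 0.9, 10L)
  expect_equal(ncol(b57$residues), 57)

  alt <- rows
  alt[, seq(1, 59, by = 2)] <- matrix(
    ap2erf:::AA_ALPHABET[(seq_len(6 * 30) %% 20) + 1], nrow = 6)
  expect_error(extract_block(alt, 0.9, 10L), "conserved block")
})

test_that("p-distance equals a brute-force column recount", {
  m <- matrix(c("A", "C", "D", "E", "F",
                "A", "C", "D", "E", "F",
                "A", "A", "A", "E", "F"), nrow = 3, byrow = TRUE)
  rownames(m) <- c("x", "y", "z")
  d <- pdistance_matrix(m)
  expect_equal(d["x", "y"], 0)
  expect_equal(d["x", "z"], 2 / 5)
  set.seed(31)
  r <- matrix(sample(ap2erf:::AA_ALPHABET, 20 * 30, replace = TRUE), 20)
  r[sample(length(r), 40)] <- NA
  rownames(r) <- paste0("s", 1:20)
  dr <- pdistance_matrix(r)
  for (i in 1:19) for (j in (i + 1):20) {
    ok <- !is.na(r[i, ]) & !is.na(r[j, ])
    expect_equal(dr[i, j], sum(r[i, ok] != r[j, ok]) / sum(ok))
  }
  expect_error(pdistance_matrix(rbind(a = c("A", NA), b = c(NA, "C"))),
               "comparable")
})

test_that("neighbour-joining satisfies the closed-form and additive contracts", {
  # three taxa: unique star with three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), sort(c(1, 2, 3)))

  # additive four-taxon case favouring ((A,B),(C,D))
  d4 <- matrix(c(0, 2, 7, 7,
                 2, 0, 7, 7,
                 7, 7, 0, 2,
                 7, 7, 2, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(d4)
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(same_topology(t4, ref))

  # a duplicate taxon is placed as its twin's sister
  d5 <- d4
  d5 <- rbind(cbind(d5, A2 = d5[, "A"]), A2 = c(d5["A", ], 0))
  t5 <- nj_tree(d5)
  expect_true(ape::is.monophyletic(t5, c("A", "A2")))

  bad <- d4; bad[1, 2] <- 3
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ recovers the generating topology on additive matrices (oracle check)", {
  for (s in 1:30) {
    n <- if (s %% 2 == 0) 4L else 5L
    gen <- random_additive_distance(n, seed = 1000 + s)
    nj <- nj_tree(gen$d)
    oracle <- ls_topology_oracle(gen$d)
    expect_true(same_topology(nj, oracle), label = paste("trial", s))
    expect_true(same_topology(nj, gen$tree), label = paste("gen", s))
  }
  # and on larger additive matrices the generating topology comes back
  for (s in 1:5) {
    gen <- random_additive_distance(8L, seed = 2000 + s)
    expect_true(same_topology(nj_tree(gen$d), gen$tree))
  }
})

test_that("reference-based group assignment recovers truth and ignores reference order", {
  panel <- generate_reference_panel(seed = 300L)
  qs <- c("I", "VII", "IX", "VI-L")
  qmat <- do.call(rbind, lapply(seq_along(qs), function(k)
    ap2erf:::with_seed(400L + k,
                       ap2erf:::sample_domain("ERF", qs[k], 0.05))))
  rownames(qmat) <- paste0("q", seq_along(qs))
  colnames(qmat) <- numbered_positions()
  g <- assign_group(qmat, panel$residues, panel$labels)
  expect_identical(g$group, qs)

  # query identical to a reference gets that reference's group
  q1 <- panel$residues["ref_VII_1", , drop = FALSE]
  rownames(q1) <- "probe"
  g1 <- assign_group(q1, panel$residues, panel$labels)
  expect_identical(g1$group, "VII")

  # invariance under reference reordering
  ord <- rev(seq_len(nrow(panel$residues)))
  g2 <- assign_group(qmat, panel$residues[ord, ],
                     panel$labels[ord, ])
  expect_identical(g2$group, g$group)

  # missing groups warn but assignment proceeds
  keep <- panel$labels$group != "III"
  expect_warning(
    g3 <- assign_group(qmat, panel$residues[keep, ],
                       panel$labels[keep, , drop = FALSE]),
    "missing group")
  expect_identical(g3$group, qs)
})

test_that("ERF group recovery is complete on the default cohort", {
  co <- default_cohort()
  rc <- default_classification()
  g <- merge(rc$groups, co$genes[, c("gene", "group")], by = "gene",
             suffixes = c(".pred", ".true"))
  expect_equal(nrow(g), 115)
  expect_identical(g$group.pred, g$group.true)
})
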