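test_that("column conservation matches brute-force tallies", {
  one <- matrix(c("A", "C", "D"), 1, dimnames = list("s1", c("p1", "p2",
                                                             "p3")))
  cc <- column_conservation(one, "G1")
  expect_true(all(cc$freq$freq == 1))

  two <- rbind(s1 = c("A", "C"), s2 = c("A", "D"))
  colnames(two) <- c("p1", "p2")
  cc2 <- column_conservation(two, c("G1", "G1"))
  expect_equal(sort(cc2$freq$freq[cc2$freq$position == "p2"]), c(0.5, 0.5))
  expect_equal(cc2$freq$freq[cc2$freq$position == "p1"], 1)

  set.seed(8)
  m <- matrix(sample(c(ap2erf:::AA_ALPHABET[1:4], NA), 20 * 6,
                     replace = TRUE), 20)
  colnames(m) <- paste0("p", 1:6)
  grp <- rep(c("G1", "G2"), each = 10)
  cc3 <- column_conservation(m, grp)
  for (r in seq_len(nrow(cc3$freq))) {
    row <- cc3$freq[r, ]
    col <- m[grp == row$group, row$position]
    col <- col[!is.na(col)]
    expect_equal(row$freq, sum(col == row$residue) / length(col))
  }
  # frequencies sum to 1 per group x position over non-gap residues
  sums <- tapply(cc3$freq$freq, paste(cc3$freq$group, cc3$freq$position),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("universal residues are exactly the ten planted positions", {
  panel <- truth_marker_panel()
  erf <- panel$labels %in% ap2erf:::ERF_GROUPS
  cons <- column_conservation(panel$residues[erf, , drop = FALSE],
                              panel$labels[erf])
  u <- find_universal_residues(cons, 100)
  expect_setequal(paste(u$position, u$residue),
                  paste(names(ap2erf:::UNIVERSAL_RESIDUES),
                        ap2erf:::UNIVERSAL_RESIDUES))
  # threshold 0 admits every position
  u0 <- find_universal_residues(cons, 0)
  expect_true(all(ap2erf:::ap2_positions() %in% u0$position))
  # a single mutated copy of G148 removes 148 at the 100% threshold
  mut <- panel$residues[erf, , drop = FALSE]
  mut[1, "148"] <- "A"
  u1 <- find_universal_residues(column_conservation(mut,
                                                    panel$labels[erf]), 100)
  expect_false("148" %in% u1$position)
})

test_that("marker discovery reproduces the shipped diagnostic table exactly", {
  panel <- truth_marker_panel()
  cons <- column_conservation(panel$residues, panel$labels)
  mk <- find_group_markers(cons)
  ref <- ap2_marker_reference()
  expect_identical(sort(paste(mk$group, mk$position, mk$residue)),
                   sort(paste(ref$group, ref$position, ref$residue)))
  # invariant under row reordering and under duplicating a sequence
  ord <- rev(seq_len(nrow(panel$residues)))
  mk2 <- find_group_markers(column_conservation(panel$residues[ord, ],
                                                panel$labels[ord]))
  expect_identical(mk2, mk)
  dup <- rbind(panel$residues, panel$residues[5, , drop = FALSE])
  mk3 <- find_group_markers(column_conservation(dup, c(panel$labels,
                                                       panel$labels[5])))
  expect_identical(sort(paste(mk3$group, mk3$position, mk3$residue)),
                   sort(paste(mk$group, mk$position, mk$residue)))
})

test_that("a single group reports its conserved positions; a discordant member drops a 100% marker", {
  panel <- truth_marker_panel()
  g2 <- panel$residues[panel$labels == "II", , drop = FALSE]
  cons1 <- column_conservation(g2, rep("II", nrow(g2)))
  mk1 <- find_group_markers(cons1)
  expect_true(all(c("175", "176") %in%
                    mk1$position[mk1$group == "II"]))
  # with one member discordant at S175, a 100% threshold drops that marker
  g2m <- g2; g2m[1, "175"] <- "G"
  mkm <- find_group_markers(column_conservation(g2m, rep("II", nrow(g2m))),
                            within_min = 100)
  expect_false("175" %in% mkm$position)
  expect_true("176" %in% mkm$position)
})

test_that("subfamily calls follow the 158/163 rule", {
  d <- group_consensus("ERF", "I")
  expect_identical(subfamily_call(d), "DREB")
  expect_identical(subfamily_call(group_consensus("ERF", "VIII")), "ERF")
  d["163"] <- "D"
  expect_identical(subfamily_call(d), "UNRESOLVED")
  # agreement with the Sakuma banding on every full-domain synthetic ERF
  co <- default_cohort()
  erf <- co$genes[co$genes$family == "ERF" & co$genes$class == "full", ]
  for (k in seq_len(nrow(erf))) {
    res <- co$domain_residues[paste0(erf$gene[k], "_R1"), ]
    band <- map_nomenclature("ERF", erf$group[k])$subfamily
    expect_identical(subfamily_call(res), band, label = erf$gene[k])
  }
})

test_that("motif scans find the conserved elements where planted", {
  scaf <- paste(ap2erf:::AP2_SCAFFOLD, collapse = "")
  m <- scan_motifs(scaf)
  expect_true(all(m$present[m$motif %in% c("YRG", "WLG", "RAYD")]))
  expect_false(m$present[m$motif == "KREYD"])
  vil <- scan_motifs(consensus_string("ERF", "VI-L"))
  expect_true(vil$present[vil$motif == "KREYD"])
  g1 <- scan_motifs(consensus_string("ERF", "I"))
  expect_false(g1$present[g1$motif == "KREYD"])
  none <- scan_motifs("AAAA")
  expect_false(any(none$present))
  ear <- scan_motifs("GGLDLNLAPGG")
  expect_true(ear$present[ear$motif == "EAR"])
  expect_equal(ear$position[ear$motif == "EAR"], 3)
})

test_that("Nakano groups map onto the Sakuma nomenclature", {
  expect_identical(map_nomenclature("ERF", "II")$subfamily, "DREB")
  expect_identical(map_nomenclature("ERF", "VI-L"),
                   list(subfamily = "ERF", subgroup = "B-6"))
  expect_identical(map_nomenclature("RAV")$subfamily, "RAV")
  expect_identical(map_nomenclature("ERF", "IX")$subgroup, "B-1 to B-6")
  expect_error(map_nomenclature("ERF", "XIV"), "unknown")
  expect_error(map_nomenclature("ERF"), "group")
})
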