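test_that("a perfect complement scores penalty zero and cleavage", {
  site <- "UACGUACGUACGUACGUACGU"
  tx <- paste0(strrep("A", 30), site, strrep("C", 30))
  mir <- ap2erf:::rc_rna(site)
  h <- scan_targets(mir, tx)
  expect_equal(nrow(h), 1)
  expect_equal(h$penalty, 0)
  expect_equal(c(h$tx_start, h$tx_end), c(30, 51))
  expect_identical(h$inhibition, "cleavage")
  # T/U alphabet equivalence on both inputs
  h2 <- scan_targets(chartr("U", "T", mir), chartr("U", "T", tx))
  expect_equal(h2$penalty, h$penalty)
  expect_equal(h2$tx_start, h$tx_start)
  expect_error(scan_targets("ACGUACGUACGUACGUX", tx), "non-RNA")
})

test_that("the published fragment pair scores 2.5 with three wobbles and passes every filter", {
  mir <- "GUGCGUUUCACGUCGG"
  frag <- "UUGCCGUGAAACGCAU"
  tx <- paste0(strrep("A", 12), frag, strrep("A", 12))
  h <- scan_targets(mir, tx)
  expect_equal(nrow(h), 1)
  expect_equal(h$penalty, 2.5)
  expect_equal(h$length, 16)
  expect_identical(h$mir_fragment, mir)
  expect_identical(h$target_fragment, frag)
  expect_lte(h$energy, -20)
  expect_identical(h$inhibition, "cleavage")
})

test_that("a non-pairing base opposite a protected position rejects the site", {
  site <- "UACGUACGUACGUACGUACGU"   # 21 nt
  tx0 <- paste0(strrep("A", 30), site, strrep("C", 30))
  mir <- strsplit(ap2erf:::rc_rna(site), "")[[1]]
  # break pairing at miRNA position 10 (A<->C gives no pair, no wobble)
  t10 <- site[[1]]
  facing <- substr(site, 21 - 10 + 1, 21 - 10 + 1)
  mir[10] <- switch(facing, A = "C", C = "A", G = "A", U = "C")
  expect_equal(nrow(scan_targets(paste(mir, collapse = ""), tx0)), 0)
  # the same perturbation at position 5 only adds penalty 1
  mir2 <- strsplit(ap2erf:::rc_rna(site), "")[[1]]
  facing5 <- substr(site, 21 - 5 + 1, 21 - 5 + 1)
  mir2[5] <- switch(facing5, A = "C", C = "A", G = "A", U = "C")
  h <- scan_targets(paste(mir2, collapse = ""), tx0)
  expect_equal(h$penalty, 1)
})

test_that("penalty grows monotonically as mismatches accumulate", {
  site <- "GCGCAUAUGCGCAUAUGCGCA"
  tx <- paste0(strrep("U", 25), site, strrep("U", 25))
  mir <- strsplit(ap2erf:::rc_rna(site), "")[[1]]
  prev <- -1
  for (nmut in 0:2) {
    m <- mir
    for (p in seq_len(nmut)) {
      facing <- substr(site, 21 - (2 * p + 1) + 1, 21 - (2 * p + 1) + 1)
      m[2 * p + 1] <- switch(facing, A = "C", C = "A", G = "A", U = "C")
    }
    h <- scan_targets(paste(m, collapse = ""), tx)
    expect_equal(nrow(h), 1)
    expect_gt(h$penalty, prev)
    prev <- h$penalty
  }
})

test_that("the per-pair duplex energy model is additive", {
  expect_equal(duplex_energy("GGGGGGGGGG", "CCCCCCCCCC"), -30)
  expect_equal(duplex_energy("AAAA", "GGGG"), 0)
  expect_equal(duplex_energy("GUGCGUUUCACGUCGG", "UUGCCGUGAAACGCAU"), -34)
  expect_lte(duplex_energy("GUGCGUUUCACGUCGG", "UUGCCGUGAAACGCAU"), -20)
  expect_equal(duplex_energy("AU", "AU"), -4)   # two A:U pairs
  expect_equal(duplex_energy("GU", "GU"), -2)   # two G:U wobbles
  expect_error(duplex_energy("AUG", "AU"), "equal length")
})

test_that("inhibition calls depend on Watson-Crick pairing at positions 9-11", {
  site <- "UACGUACGUACGUACGUACGU"
  tx <- paste0(strrep("A", 30), site, strrep("C", 30))
  mir <- strsplit(ap2erf:::rc_rna(site), "")[[1]]
  # non-pair at position 9 -> translation
  f9 <- substr(site, 21 - 9 + 1, 21 - 9 + 1)
  m9 <- mir; m9[9] <- switch(f9, A = "C", C = "A", G = "A", U = "C")
  h9 <- scan_targets(paste(m9, collapse = ""), tx)
  expect_identical(h9$inhibition, "translation")
  # wobble at position 10, Watson-Crick elsewhere -> translation
  f10 <- substr(site, 21 - 10 + 1, 21 - 10 + 1)
  m10 <- mir
  m10[10] <- switch(f10, G = "U", U = "G", NA)
  if (!is.na(m10[10])) {
    h10 <- scan_targets(paste(m10, collapse = ""), tx)
    expect_identical(h10$inhibition, "translation")
    expect_identical(call_inhibition(h10[1, ]), "translation")
  }
  h0 <- scan_targets(paste(mir, collapse = ""), tx)
  expect_identical(call_inhibition(h0[1, ]), "cleavage")
})

test_that("site regions follow the midpoint rule", {
  # transcript: 0-99 UTR5, 100-399 CDS (AP2 at 200-300), 400-500 UTR3
  cds <- c(100, 400); ap2 <- c(200, 300)
  expect_identical(annotate_site(10, 31, cds, ap2, 500), "5'UTR")
  expect_identical(annotate_site(120, 141, cds, ap2, 500), "CDS-before-AP2")
  expect_identical(annotate_site(240, 261, cds, ap2, 500), "CDS-inside-AP2")
  expect_identical(annotate_site(320, 341, cds, ap2, 500), "CDS-after-AP2")
  expect_identical(annotate_site(420, 441, cds, ap2, 500), "3'UTR")
  # straddling sites take the region of their midpoint
  expect_identical(annotate_site(95, 116, cds, ap2, 500), "CDS-before-AP2")
  expect_error(annotate_site(490, 511, cds, ap2, 500), "outside")
})
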