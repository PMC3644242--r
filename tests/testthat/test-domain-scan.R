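test_that("six-frame translation finds stop-free stretches with forward coordinates", {
  r <- six_frame_translate("ATGAAATAA", min_orf_aa = 2L)
  mk <- r[r$aa == "MK", ]
  expect_equal(nrow(mk), 1)
  expect_equal(mk$frame, 0)
  expect_identical(mk$strand, "+")
  expect_equal(c(mk$nt_start, mk$nt_end), c(0, 6))
  expect_equal(nrow(six_frame_translate("", 1L)), 0)
  expect_error(six_frame_translate("ACGTQACGT"), "offset 4")
})

test_that("translating a reverse complement flips strands but not peptides", {
  set.seed(21)
  for (rep in 1:5) {
    dna <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
    a <- six_frame_translate(dna, min_orf_aa = 20L)
    b <- six_frame_translate(rc, min_orf_aa = 20L)
    expect_setequal(a$aa, b$aa)
    # each forward peptide appears on the opposite strand of the rc, at the
    # mirrored forward-strand interval
    for (k in seq_len(nrow(a))) {
      m <- b[b$aa == a$aa[k] & b$strand != a$strand[k], ]
      expect_true(any(m$nt_start == 400 - a$nt_end[k] &
                        m$nt_end == 400 - a$nt_start[k]))
    }
  }
})

test_that("model building follows the log-odds contract", {
  aln <- c("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
  m <- build_model(aln, min_span = 5L)
  for (j in 1:20) {
    col <- m$scores[, j]
    expect_equal(names(which.max(col)), substr(aln[1], j, j))
  }
  # a column holding all 20 residues equally scores ~0 for each
  aln20 <- vapply(ap2erf:::AA_ALPHABET, function(a)
    paste0(a, "AC"), character(1))
  m20 <- build_model(aln20)
  expect_true(all(abs(m20$scores[, 1]) < 1e-9))
  expect_error(build_model(c("ACD", "AC")), "ragged")
})

test_that("the model separates planted domains from random peptides (AUC 1)", {
  m <- ap2_model()
  set.seed(99)
  pos <- replicate(100, {
    g <- sample(ap2erf:::ERF_GROUPS, 1)
    aa <- ap2erf:::domain_string(ap2erf:::sample_domain("ERF", g, 0.05))
    max(scan_ap2(aa, m)$score, -Inf)
  })
  neg <- replicate(100, {
    aa <- ap2erf:::random_aa(58L)
    h <- scan_ap2(aa, m)
    if (nrow(h)) max(h$score) else {
      al <- ap2erf:::profile_align_cpp(ap2erf:::aa_codes(aa), m$scores,
                                       m$del_open, m$del_ext, m$ins_open,
                                       m$ins_ext, 0L)
      al$score
    }
  })
  expect_true(min(pos) > max(neg))   # AUC exactly 1
})

test_that("scan completeness calls recover generator truth", {
  full <- consensus_string("ERF", "I")
  h <- scan_ap2(full)
  expect_equal(nrow(h), 1)
  expect_identical(h$completeness, "full")
  expect_equal(c(h$model_start, h$model_end), c(1, 58))

  trunc <- substr(full, 11, 58)          # 10 residues lost on the N side
  ht <- scan_ap2(trunc)
  expect_identical(ht$completeness, "partial_N")
  expect_equal(ht$model_start, 11)

  expect_equal(nrow(scan_ap2(ap2erf:::random_aa(80L))), 0)

  sol <- consensus_string("SOLOIST")
  hs <- scan_ap2(sol)
  expect_identical(hs$completeness, "short")
  expect_gte(hs$n_internal_del, 4)

  ix <- consensus_string("ERF", "IX")
  hi <- scan_ap2(ix)
  expect_identical(hi$completeness, "full")
  expect_true(hi$has_insertion)
})

test_that("B3 detection distinguishes RAV from ERF peptides and keeps hits disjoint", {
  co <- default_cohort()
  rav <- co$genes$gene[co$genes$family == "RAV"][1]
  h <- scan_transcripts(co$transcripts[rav])
  expect_equal(sum(h$kind == "AP2"), 1)
  expect_equal(sum(h$kind == "B3"), 1)

  erf <- co$genes$gene[co$genes$family == "ERF" & co$genes$class == "full"][1]
  he <- scan_transcripts(co$transcripts[erf])
  expect_equal(sum(he$kind == "B3"), 0)
  expect_equal(nrow(detect_b3("")), 0)

  # two-domain AP2 gene: hits never overlap on the transcript
  ap2 <- co$genes$gene[co$genes$family == "AP2" &
                         co$genes$class == "two_full"][1]
  ha <- scan_transcripts(co$transcripts[ap2])
  ha <- ha[order(ha$nt_start), ]
  expect_equal(nrow(ha), 2)
  expect_lte(ha$nt_end[1], ha$nt_start[2])
})

test_that("on the clean cohort, scanned completeness agrees with truth for every gene", {
  co <- default_cohort()
  rc <- default_classification()
  hits <- rc$hits[rc$hits$kind == "AP2", ]
  truth <- co$domains[co$domains$kind == "AP2", ]
  for (id in unique(truth$gene)) {
    got <- sort(hits$completeness[hits$contig == id])
    want <- sort(truth$completeness[truth$gene == id])
    expect_identical(got, want, label = id)
  }
})
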