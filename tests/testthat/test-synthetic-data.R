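test_that("an all-zero configuration yields empty collections", {
  cfg <- cohort_config(ap2_two_full = 0L, ap2_full_partial = 0L,
                       ap2_two_partial = 0L, ap2_one_full = 0L,
                       ap2_one_partial = 0L,
                       erf_groups = c(I = 0L), erf_partial = 0L,
                       rav = 0L, soloist = 0L)
  co <- generate_cohort(cfg)
  expect_length(co$transcripts, 0)
  expect_equal(nrow(co$genes), 0)
  expect_equal(nrow(co$domains), 0)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(rav = -1L), "negative count")
  expect_error(cohort_config(erf_groups = c(bogus = 3L)), "erf_groups")
  expect_error(cohort_config(tissues = c(root = 0.7, bark = 0.2)),
               "tissues")
})

test_that("the default cohort reproduces the published inventory", {
  co <- default_cohort()
  expect_equal(nrow(co$genes), 173)
  expect_equal(as.vector(table(co$genes$family)[c("AP2", "ERF", "RAV",
                                                  "SOLOIST")]),
               c(25, 141, 4, 3))
  # genes with at least one complete domain (soloist short domains count)
  full <- unique(co$domains$gene[co$domains$kind == "AP2" &
                                   co$domains$completeness %in%
                                   c("full", "short")])
  expect_length(full, 142)
  # per-group tallies of full-domain ERFs match the configured counts
  erf_full <- co$genes[co$genes$family == "ERF" & co$genes$class == "full", ]
  expect_equal(as.vector(table(erf_full$group)[names(cohort_config()$erf_groups)]),
               as.vector(cohort_config()$erf_groups))
})

test_that("generation is byte-identical for a fixed seed", {
  co1 <- generate_cohort(cohort_config(seed = 7L))
  co2 <- generate_cohort(cohort_config(seed = 7L))
  expect_identical(co1$transcripts, co2$transcripts)
  expect_identical(co1$domain_residues, co2$domain_residues)
  co3 <- generate_cohort(cohort_config(seed = 8L))
  expect_false(identical(co1$transcripts, co3$transcripts))
})

test_that("every full ERF domain carries its group's diagnostic residues", {
  co <- default_cohort()
  erf <- co$genes[co$genes$family == "ERF" & co$genes$class == "full", ]
  for (k in seq_len(nrow(erf))) {
    res <- co$domain_residues[paste0(erf$gene[k], "_R1"), ]
    grp <- erf$group[k]
    mk <- ap2erf:::GROUP_MARKERS[[grp]]
    if (length(mk))
      expect_identical(unname(res[names(mk)]), unname(mk),
                       label = paste(erf$gene[k], grp))
    if (grp == "IX") expect_false(is.na(res["167i"]))
    band <- if (grp %in% ap2erf:::DREB_GROUPS) ap2erf:::DREB_DIAGNOSTIC
            else ap2erf:::ERFB_DIAGNOSTIC
    expect_identical(unname(res[names(band)]), unname(band))
  }
  # soloists: 52-residue domain missing the block containing position 152
  sol <- co$domain_residues[paste0(co$genes$gene[co$genes$family ==
                                                   "SOLOIST"], "_R1"), ]
  expect_true(all(is.na(sol[, "152"])))
  expect_true(all(rowSums(!is.na(sol)) == 52))
})

test_that("read membership follows the multinomial allocation", {
  co <- default_cohort()
  m0 <- generate_read_membership(co, total_reads = 0L)
  expect_true(all(m0$read_count == 0))
  m1 <- generate_read_membership(co, total_reads = 500L, seed = 3L,
                                 tissues = c(latex = 1))
  expect_equal(sum(m1$read_count), 500)
  expect_true(all(m1$library == "latex"))
  # per-tissue totals within 3 binomial standard errors of expectation
  m <- generate_read_membership(co, total_reads = 10000L, seed = 4L)
  per <- tapply(m$read_count, m$library, sum)
  w <- cohort_config()$tissues[names(per)]
  se <- sqrt(10000 * w * (1 - w))
  expect_true(all(abs(per - 10000 * w) <= 3 * se))
  expect_error(generate_read_membership(co, 10L,
                                        tissues = stats::setNames(1, "")),
               "tissue")
})

test_that("planted miRNA sites satisfy the scanner's acceptance thresholds", {
  co <- default_cohort()
  expect_equal(nrow(generate_mirna_pairs(co, n_sites = 0L)$sites), 0)
  mp <- generate_mirna_pairs(co, n_sites = 8L, seed = 11L)
  expect_equal(nrow(mp$sites), 8)
  expect_equal(sum(mp$sites$mode == "cleavage"), 4)
  for (k in seq_len(nrow(mp$sites))) {
    s <- mp$sites[k, ]
    h <- scan_targets(mp$mirnas[[s$mirna_id]],
                      co$transcripts[[s$gene]],
                      mirna_id = s$mirna_id, transcript_id = s$gene)
    expect_equal(nrow(h), 1, label = s$mirna_id)
    expect_equal(h$tx_start, s$tx_start)
    expect_equal(h$tx_end, s$tx_end)
    expect_identical(h$inhibition, s$mode)
  }
})
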