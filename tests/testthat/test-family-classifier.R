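mkhits <- function(...) {
  rows <- list(...)
  if (!length(rows))
    return(data.frame(kind = character(0), completeness = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(rows, function(r)
    data.frame(kind = r[[1]], completeness = r[[2]],
               stringsAsFactors = FALSE)))
}

test_that("domain-architecture rules assign families", {
  expect_identical(classify_family(mkhits(list("AP2", "full"),
                                          list("AP2", "full")))$family,
                   "AP2")
  expect_identical(classify_family(mkhits(list("AP2", "full"),
                                          list("B3", "full")))$family,
                   "RAV")
  expect_identical(classify_family(mkhits())$family, "UNCLASSIFIED")
  expect_identical(classify_family(mkhits(list("AP2", "short")))$family,
                   "SOLOIST")
  expect_identical(classify_family(mkhits(list("AP2", "full")))$family,
                   "ERF")
  expect_identical(classify_family(mkhits(list("AP2", "partial_N")))$family,
                   "ERF")
  ov <- classify_family(mkhits(list("AP2", "full")), homology_hint = "AP2")
  expect_identical(ov$family, "AP2")
  expect_true(ov$homology_override)
  bad <- mkhits(list("AP2", "full"), list("AP2", "full"))
  bad$contig <- c("g1", "g2")
  expect_error(classify_family(bad), "mixed")
})

test_that("the homology hint separates AP2-family from ERF single domains", {
  ap2 <- group_consensus("AP2")
  erf <- group_consensus("ERF", "V")
  expect_identical(homology_family_hint(ap2), "AP2")
  expect_identical(homology_family_hint(erf), "ERF")
  # partial AP2-family domain covering only the N-side informative sites
  part <- ap2
  part[as.character(175:202)] <- NA
  expect_identical(homology_family_hint(part), "AP2")
})

test_that("gene names follow the published pattern", {
  calls <- data.frame(
    gene = c(paste0("e", 1:12), "s1", "s2", "s3", paste0("a", 1:6)),
    family = c(rep("ERF", 12), rep("SOLOIST", 3), rep("AP2", 6)),
    stringsAsFactors = FALSE)
  groups <- data.frame(gene = paste0("e", 1:12), group = "VII",
                       subgroup = "a", stringsAsFactors = FALSE)
  named <- assign_names(calls, groups)
  expect_identical(named$name[12], "HbERF-VIIa12")
  expect_identical(named$name[15], "HbSoloist3")
  expect_identical(named$name[21], "HbAP2-6")
})

test_that("family tables conserve totals and mirror the published layout", {
  rc <- default_classification()
  tab <- tabulate_families(rc$calls)
  expect_equal(tab$count[tab$family == "TOTAL"], 173)
  expect_equal(tab$count[tab$family == "AP2" &
                           tab$conserved_domain == "Total"], 25)
  expect_equal(tab$count[tab$family == "ERF" &
                           tab$conserved_domain == "Total"], 141)
  # grand total equals the number of calls for any input
  sub <- rc$calls[sample(seq_len(nrow(rc$calls)), 40), ]
  t2 <- tabulate_families(sub)
  expect_equal(t2$count[t2$family == "TOTAL"], 40)
  # permutation invariance
  perm <- rc$calls[rev(seq_len(nrow(rc$calls))), ]
  expect_equal(tabulate_families(perm)$count, tab$count)
  t0 <- tabulate_families(rc$calls[0, ])
  expect_true(all(t0$count == 0))
})

test_that("classification recovers generator truth exactly on the default cohort", {
  co <- default_cohort()
  rc <- default_classification()
  m <- merge(rc$calls, co$genes[, c("gene", "family")], by = "gene",
             suffixes = c(".pred", ".true"))
  expect_equal(nrow(m), 173)
  expect_identical(m$family.pred, m$family.true)
})
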