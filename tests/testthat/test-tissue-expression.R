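test_that("read counting aggregates recognized layouts", {
  expect_equal(nrow(count_reads(data.frame())), 0)
  rec <- data.frame(contig = c("c1", "c1", "c1"),
                    library = c("latex", "latex", "latex"),
                    count = c(2, 3, 4))
  m <- count_reads(rec)
  expect_equal(m["c1", "latex"], 9L)
  # contig/read/library layout counts rows
  rr <- data.frame(contig = c("c1", "c1", "c2"),
                   read = c("r1", "r2", "r3"),
                   library = c("bark", "bark", "leaf"))
  m2 <- count_reads(rr)
  expect_equal(m2["c1", "bark"], 2L)
  expect_equal(m2["c2", "leaf"], 1L)
  expect_error(count_reads(data.frame(c = "c1", l = "x", n = -1)),
               "negative")
  expect_error(count_reads(rec, libraries = c("bark")), "unknown library")
  # synthetic membership reshapes losslessly
  co <- default_cohort()
  mem <- generate_read_membership(co, 5000L, seed = 9L)
  m3 <- count_reads(mem)
  expect_equal(sum(m3), 5000)
  expect_equal(unname(m3["synth_erf_1", "latex"]),
               mem$read_count[mem$contig_id == "synth_erf_1" &
                                mem$library == "latex"])
})

test_that("group aggregation reproduces the published margins", {
  t8 <- hevea_erf_group_reads()
  rm <- as.matrix(t8[, -1])
  rownames(rm) <- t8$group
  tab <- aggregate_by_group(rm, data.frame(gene = t8$group,
                                           group = t8$group))
  expect_equal(unname(tab["I", "Total"]), 829)
  expect_equal(unname(tab["Total", "bark"]), 1316)
  expect_equal(unname(tab["Total", "Total"]), 5889)
  # margins are cell sums
  inner <- tab[setdiff(rownames(tab), "Total"),
               setdiff(colnames(tab), "Total")]
  expect_equal(unname(rowSums(inner)),
               unname(tab[setdiff(rownames(tab), "Total"), "Total"]))
  # permutation of contig order changes nothing
  ord <- sample(nrow(rm))
  tab2 <- aggregate_by_group(rm[ord, ], data.frame(gene = t8$group,
                                                   group = t8$group))
  expect_equal(tab2, tab)
  zero <- aggregate_by_group(rm * 0L, data.frame(gene = t8$group,
                                                 group = t8$group))
  expect_true(all(zero == 0))
})

test_that("tissue shares reproduce the published percentages", {
  counts <- hevea_tissue_read_counts()
  p <- tissue_percentages(counts)
  expect_equal(unname(p[c("root", "bark", "latex", "embryogenic", "leaf")]),
               c(29.8, 22.2, 21.2, 16.4, 10.4))
  expect_lte(abs(sum(p) - 100), 0.3)
  expect_equal(unname(tissue_percentages(c(latex = 42))), 100.0)
  expect_error(tissue_percentages(c(a = 0, b = 0)), "positive")
  # scale invariance under randomized inputs
  set.seed(14)
  for (rep in 1:25) {
    x <- stats::setNames(sample(1:5000, 5), letters[1:5])
    k <- sample(c(2, 3, 7, 10), 1)
    expect_equal(tissue_percentages(x * k), tissue_percentages(x))
  }
})

test_that("qPCR ratios follow the efficiency-corrected closed form", {
  expect_equal(qpcr_ratio(20, 20), 1.0)
  expect_equal(qpcr_ratio(21, 20), 0.5)
  expect_equal(qpcr_ratio(18, 20), 4.0)
  expect_equal(qpcr_ratio(20, 20, e_target = 1.9, e_ref = 2.1),
               1.9^-20 / 2.1^-20)
  # monotonicity: decreasing in Cp_target, increasing in Cp_ref
  set.seed(15)
  for (rep in 1:20) {
    cpt <- runif(1, 10, 40); cpr <- runif(1, 10, 40)
    expect_lt(qpcr_ratio(cpt + 0.5, cpr), qpcr_ratio(cpt, cpr))
    expect_gt(qpcr_ratio(cpt, cpr + 0.5), qpcr_ratio(cpt, cpr))
  }
  expect_error(qpcr_ratio(0, 20), "Cp")
  expect_error(qpcr_ratio(20, 20, e_target = 2.5), "efficienc")
})
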