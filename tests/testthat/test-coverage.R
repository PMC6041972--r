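test_that("merged interval length unions overlaps per chromosome", {
  expect_equal(merged_length(c(0, 5), c(10, 15)), 15)
  expect_equal(merged_length(c(0, 20), c(10, 30)), 20)
  expect_equal(merged_length(numeric(), numeric()), 0)
  # same bounds on different chromosomes do not merge
  expect_equal(merged_length(c(0, 0), c(10, 10), c("1", "2")), 20)
  # random intervals against the grid-rasterization oracle
  set.seed(31)
  for (rep in 1:10) {
    start <- round(runif(5, 0, 50), 2)
    end <- start + round(runif(5, 0.5, 20), 2)
    expect_equal(merged_length(start, end),
                 grid_merged_length(start, end), tolerance = 0.02)
  }
  # merged <= raw sum, equality iff disjoint
  expect_lt(merged_length(c(0, 5), c(10, 15)), 25)
  expect_equal(merged_length(c(0, 20), c(10, 30)), sum(c(10, 10)))
})

test_that("meta-QTL coverage is a raw CI sum honoring a printed width column", {
  mq <- data.frame(ci95_start = c(0, 5), ci95_end = c(10, 15))
  expect_equal(mqtl_coverage(mq), 20)
  mq$ci95_width <- c(11, 11)
  expect_equal(mqtl_coverage(mq), 22)
  expect_equal(mqtl_coverage(mq[0, ]), 0)
})

test_that("coverage and reduction percentages follow their formulas", {
  expect_equal(coverage_percent(7980.637), 100)
  expect_equal(coverage_percent(0), 0)
  expect_equal(coverage_percent(50, 200), 25)
  expect_equal(reduction_percent(100, 25), 75)
  expect_equal(reduction_percent(7, 7), 0)
  expect_error(reduction_percent(0, 0), "> 0")
  # reduction in [0, 100] whenever mqtl_cov <= qtl_cov
  set.seed(13)
  q <- runif(20, 1, 100)
  m <- q * runif(20)
  expect_true(all(reduction_percent(q, m) >= 0 &
                    reduction_percent(q, m) <= 100))
})

test_that("coverage report combines merged QTL and raw meta-QTL sums", {
  prj <- data.frame(tissue_class = "leaf", chromosome = "1",
                    ref_ci_start = c(0, 5, 30), ref_ci_end = c(10, 15, 40),
                    projection_status = c("projected", "projected",
                                          "discarded_negative"))
  mq <- data.frame(tissue_class = "leaf", ci95_start = c(2, 6),
                   ci95_end = c(8, 12))
  rep <- coverage_report(prj, mq, map_length_cM = 100)
  expect_equal(rep$qtl_coverage_cM, 15)  # merged, discarded row excluded
  expect_equal(rep$mqtl_coverage_cM, 12) # raw sum
  expect_equal(rep$qtl_pct, 15)
  expect_equal(rep$reduction_pct, (15 - 12) / 15 * 100)
})

test_that("physical anchoring walks outward past unanchored markers", {
  ref <- toy_map(c("m1", "m2", "m3", "m4", "m5"), c(0, 25, 50, 75, 100),
                 map_id = "ref")
  anch <- data.frame(marker = c("m1", "m3", "m4"), chromosome = "1",
                     position_bp = c(1e6, 5e6, 8e6))
  mq <- list(chromosome = "1", ci95_start = 30, ci95_end = 70)
  # flanks m2 (unanchored, walk to m1) and m4 (anchored)
  got <- anchor_physical(mq, ref, anch)
  expect_equal(got$start_bp, 1e6)
  expect_equal(got$end_bp, 8e6)
  expect_false(got$open_start || got$open_end)

  # right side exhausts the chromosome without an anchor
  anch2 <- anch[anch$marker != "m4", ]
  mq2 <- list(chromosome = "1", ci95_start = 30, ci95_end = 90)
  got2 <- anchor_physical(mq2, ref, anch2)
  expect_true(got2$open_end)
  expect_true(is.na(got2$end_bp))

  # widening the CI never narrows the physical interval
  wide <- anchor_physical(list(chromosome = "1", ci95_start = 20,
                               ci95_end = 72), ref, anch)
  expect_lte(wide$start_bp, got$start_bp)
  expect_gte(wide$end_bp, got$end_bp)
  # widening past the last anchored marker opens the interval instead
  past <- anchor_physical(list(chromosome = "1", ci95_start = 20,
                               ci95_end = 90), ref,
                          anch[anch$marker != "m4", ])
  expect_true(past$open_end)
})

test_that("physical coverage sums closed intervals and names open ones", {
  expect_equal(physical_coverage(0, 2066432718), 100)
  expect_equal(physical_coverage(c(0, 100), c(50, 150), genome_bp = 1000),
               10)
  expect_error(physical_coverage(c(0, NA), c(10, 20), ids = c("A", "B")),
               "B")
})

test_that("cross-tissue overlap regions require two tissue classes", {
  mq <- data.frame(
    mqtl_id = c("LIR5", "SIR6", "SIR7", "SIR8", "KIR1", "LIR9", "SIR9"),
    tissue_class = c("leaf", "stem", "stem", "stem", "kernel", "leaf",
                     "stem"),
    chromosome = c("2", "2", "4", "4", "5", "5", "5"),
    ci95_start = c(81.21, 78.03, 10, 15, 0, 8, 16),
    ci95_end = c(124.35, 102.14, 20, 25, 10, 18, 26),
    stringsAsFactors = FALSE)
  regions <- cross_tissue_overlaps(mq)
  # chr2: leaf+stem overlap
  chr2 <- regions[regions$chromosome == "2", ]
  expect_equal(nrow(chr2), 1)
  expect_equal(chr2$tissue_classes, "leaf,stem")
  expect_equal(chr2$span_start, 78.03)
  expect_equal(chr2$span_end, 124.35)
  # chr4: two stem MQTL overlap but one tissue only -> no region
  expect_false("4" %in% regions$chromosome)
  # chr5: kernel-leaf-stem chain where ends do not touch -> one region,
  # all three classes
  chr5 <- regions[regions$chromosome == "5", ]
  expect_equal(chr5$n_mqtl, 3)
  expect_true(chr5$all_tissues)
  # permutation invariance
  perm <- cross_tissue_overlaps(mq[sample(nrow(mq)), ])
  expect_equal(perm, regions)
})
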