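test_that("LOD from LRS follows the 1/4.6 scaling", {
  expect_equal(lod_from_lrs(4.6), 1)
  expect_equal(lod_from_lrs(0), 0)
  expect_equal(lod_from_lrs(23), 23 / 4.6)
  expect_error(lod_from_lrs(-1), ">= 0")
})

test_that("R2 from LOD matches the closed form and its inverse", {
  expect_equal(r2_from_lod(0, 100), 0)
  expect_equal(r2_from_lod(1, 2), 0.9)
  expect_equal(r2_from_lod(3, 300), 1 - 10^(-0.02))
  expect_error(r2_from_lod(2, 1), ">= 2")
  # strictly increasing in lod, decreasing in n; inverse identity
  lods <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(r2_from_lod(lods, 150)) > 0))
  ns <- seq(50, 500, by = 50)
  expect_true(all(diff(r2_from_lod(3, ns)) < 0))
  for (lod in c(0.5, 2, 7)) {
    r2 <- r2_from_lod(lod, 180)
    expect_equal(-(180 / 2) * log10(1 - r2), lod, tolerance = 1e-9)
  }
})

test_that("95% CI width uses the population-type k constant", {
  expect_equal(ci95_width(530, 1, "F2"), 1)
  expect_equal(ci95_width(163, 0.10, "RIL"), 10)
  expect_equal(ci95_width(171, 0.044, "F3"), 530 / (171 * 0.044))
  expect_error(ci95_width(100, 0, "F2"), "infinite")
  expect_error(ci95_width(100, 0.1, "BC1"), "population type")
  # strictly decreasing in n and r2; scale invariance n*r2
  expect_true(all(diff(ci95_width(seq(50, 400, 50), 0.1, "RIL")) < 0))
  expect_true(all(diff(ci95_width(200, seq(0.05, 0.4, 0.05), "RIL")) < 0))
  expect_equal(ci95_width(100, 0.2, "RIL"), ci95_width(200, 0.1, "RIL"))
})

test_that("standardization fills statistics in precedence order", {
  q <- toy_qtl(lrs = 23, lod = NA, r2 = NA)
  std <- standardize_qtl(q)
  expect_equal(std$lod, 5)
  expect_equal(std$r2, r2_from_lod(5, 200))
  expect_equal(std$lod_source, "from_lrs")
  expect_equal(std$r2_source, "from_lod")

  # reported r2 takes precedence and is untouched
  q2 <- toy_qtl(lod = 3, r2 = 0.044, population_size = 171,
                population_type = "F3")
  std2 <- standardize_qtl(q2)
  expect_equal(std2$r2, 0.044)
  expect_equal(std2$r2_source, "reported")
  expect_equal(std2$ci95_width, ci95_width(171, 0.044, "F3"))
  expect_equal(std2$ci95_end - std2$ci95_start, std2$ci95_width)
  expect_equal((std2$ci95_start + std2$ci95_end) / 2, std2$position_cM)

  expect_error(standardize_qtl(toy_qtl(lod = NA, lrs = NA, r2 = NA)),
               "cannot standardize")
})

test_that("standardization is idempotent on already-standardized records", {
  std <- standardize_qtl(toy_qtl(r2 = 0.12))
  again <- standardize_qtl(std[names(toy_qtl())])
  expect_equal(again$r2, std$r2)
  expect_equal(again$ci95_width, std$ci95_width)
})

test_that("de-duplication keeps the highest-R2 record per overlap group", {
  mk <- function(id, start, end, r2, trait = "t", study = "s1") {
    q <- toy_qtl(id, study_id = study, trait = trait, r2 = r2,
                 position_cM = (start + end) / 2,
                 ci_start_cM = start, ci_end_cM = end)
    std <- standardize_qtl(q)
    # pin standardized CI to the stated interval for the overlap test
    std$ci95_start <- start
    std$ci95_end <- end
    std$ci95_width <- end - start
    std
  }
  two <- rbind(mk("a", 10, 30, 0.05), mk("b", 25, 45, 0.12))
  expect_equal(dedupe_overlapping(two)$qtl_id, "b")

  disjoint <- rbind(mk("a", 0, 10, 0.05), mk("b", 20, 30, 0.12))
  expect_setequal(dedupe_overlapping(disjoint)$qtl_id, c("a", "b"))

  # chained A~B, B~C, A not overlapping C: one connected component
  chain <- rbind(mk("A", 10, 30, 0.03), mk("B", 25, 45, 0.10),
                 mk("C", 40, 60, 0.07))
  expect_equal(dedupe_overlapping(chain)$qtl_id, "B")

  # different traits are separate groups
  mixed <- rbind(mk("a", 10, 30, 0.05, trait = "t1"),
                 mk("b", 20, 40, 0.12, trait = "t2"))
  expect_equal(nrow(dedupe_overlapping(mixed)), 2)
})

test_that("de-duplication is idempotent, deterministic, and never empties", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    start <- runif(n, 0, 50)
    qs <- do.call(rbind, lapply(seq_len(n), function(i)
      toy_qtl(sprintf("q%d", i), position_cM = start[i] + 5,
              ci_start_cM = start[i], ci_end_cM = start[i] + 10,
              r2 = runif(1, 0.01, 0.4))))
    std <- standardize_qtl(qs)
    once <- dedupe_overlapping(std)
    expect_gte(nrow(once), 1)
    expect_lte(nrow(once), nrow(std))
    expect_identical(dedupe_overlapping(once), once)
  }
  # ties on r2 break to the narrower reported CI, then smaller id
  tie <- rbind(
    standardize_qtl(toy_qtl("wide", ci_start_cM = 30, ci_end_cM = 70,
                            r2 = 0.2)),
    standardize_qtl(toy_qtl("slim", ci_start_cM = 45, ci_end_cM = 55,
                            r2 = 0.2)))
  expect_equal(dedupe_overlapping(tie)$qtl_id, "slim")
})
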