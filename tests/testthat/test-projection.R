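test_that("shared markers are found and inverted markers removed", {
  comp <- toy_map(c("a", "b", "c"), c(0, 10, 20), map_id = "comp")
  ref <- toy_map(c("a", "b", "c"), c(0, 20, 40), map_id = "ref")
  a <- shared_markers(comp, ref, "1")
  expect_equal(a$status, "ok")
  expect_equal(nrow(a$pairs), 3)
  expect_equal(a$global_ratio, 2)

  # reference order a, c, b: one of b/c dropped, 2 retained
  ref_inv <- toy_map(c("a", "c", "b"), c(0, 20, 40), map_id = "ref")
  a2 <- shared_markers(comp, ref_inv, "1")
  expect_equal(a2$status, "ok")
  expect_equal(nrow(a2$pairs), 2)
  expect_true(all(diff(a2$pairs$ref_pos) > 0))
  expect_true(all(diff(a2$pairs$comp_pos) > 0))

  disjoint <- toy_map(c("x", "y"), c(0, 10), map_id = "other")
  expect_equal(shared_markers(disjoint, ref, "1")$status, "no_anchors")
})

test_that("positions interpolate inside anchors and extrapolate outside", {
  a <- manual_anchor_set(c(0, 10), c(0, 20))
  expect_equal(project_position(5, a), 10)
  expect_equal(project_position(12, a), 24)   # 20 + 2 * global ratio 2
  expect_equal(project_position(-1, a), -2)
  piece <- manual_anchor_set(c(0, 10, 20), c(0, 15, 40))
  expect_equal(project_position(15, piece), 27.5)
  expect_error(project_position(5, shared_markers(
    toy_map("x", 1, map_id = "a"), toy_map("y", 1, map_id = "b"), "1")),
    "fewer than 2")
})

test_that("QTL projection rescales CIs and discards negatives", {
  identity_comp <- toy_map(c("a", "b"), c(0, 100), map_id = "comp")
  identity_ref <- toy_map(c("a", "b"), c(0, 100), map_id = "ref")
  std <- standardize_qtl(toy_qtl(position_cM = 5, r2 = 163 / (200 * 6)))
  std$ci95_start <- 2; std$ci95_end <- 8; std$ci95_width <- 6
  prj <- project_qtl(std, identity_comp, identity_ref)
  expect_equal(prj$projection_status, "projected")
  expect_equal(prj$ref_position, 5)
  expect_equal(c(prj$ref_ci_start, prj$ref_ci_end), c(2, 8))

  # piecewise anchors {(0,0),(10,15),(20,40)}: q at 15 CI [10,20]
  comp <- toy_map(c("a", "b", "c"), c(0, 10, 20), map_id = "comp")
  ref <- toy_map(c("a", "b", "c"), c(0, 15, 40), map_id = "ref")
  std2 <- std
  std2$position_cM <- 15; std2$ci95_start <- 10; std2$ci95_end <- 20
  prj2 <- project_qtl(std2, comp, ref)
  expect_equal(prj2$ref_position, 27.5)
  expect_equal(c(prj2$ref_ci_start, prj2$ref_ci_end), c(15, 40))

  # CI start projecting below zero discards the record
  ref_shift <- toy_map(c("a", "b"), c(0, 30), map_id = "ref")
  comp_shift <- toy_map(c("a", "b"), c(10, 20), map_id = "comp")
  std3 <- std
  std3$position_cM <- 11; std3$ci95_start <- 9; std3$ci95_end <- 13
  prj3 <- project_qtl(std3, comp_shift, ref_shift)
  expect_equal(prj3$projection_status, "discarded_negative")

  # unanchorable chromosome flagged, not errored
  std4 <- std
  std4$chromosome <- "9"
  prj4 <- project_qtl(std4, identity_comp, identity_ref)
  expect_equal(prj4$projection_status, "no_anchors")
})

test_that("consensus construction preserves the reference and inserts markers", {
  ref <- toy_map(c("a", "c", "e"), c(0, 20, 40), map_id = "ref")
  expect_equal(build_consensus(ref)$consensus$position, ref$position)

  subset_comp <- toy_map(c("a", "c"), c(0, 10), map_id = "sub")
  cons <- build_consensus(ref, list(subset_comp))$consensus
  expect_equal(nrow(cons), 3)
  expect_equal(cons$position, ref$position)

  # component adds b (midway a-c) and d (midway c-e) on a 2x condensed scale
  comp <- toy_map(c("a", "b", "c", "d", "e"), c(0, 5, 10, 15, 20),
                  map_id = "comp")
  cons2 <- build_consensus(ref, list(comp))$consensus
  expect_equal(nrow(cons2), 5)
  expect_equal(cons2$position[cons2$marker == "b"], 10)
  expect_equal(cons2$position[cons2$marker == "d"], 30)
  expect_equal(cons2$position[cons2$marker %in% c("a", "c", "e")],
               ref$position)

  # duplicate submission of the same component changes nothing
  cons3 <- build_consensus(ref, list(comp, comp))$consensus
  expect_equal(cons3, cons2)

  # unanchorable component skipped with a warning
  stranger <- toy_map(c("x", "y"), c(0, 10), map_id = "stranger")
  expect_warning(build_consensus(ref, list(stranger)), "skipped")
})

test_that("projection is identity, monotone, and invertible on random maps", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    ref_pos <- sort(runif(n, 0, 150))
    comp_pos <- ref_pos[1] + c(0, cumsum(diff(ref_pos) *
                                           exp(rnorm(n - 1, 0, 0.2))))
    nm <- sprintf("m%02d", seq_len(n))
    ref <- toy_map(nm, ref_pos, map_id = "ref")
    comp <- toy_map(nm, comp_pos, map_id = "comp")

    self <- shared_markers(ref, ref, "1")
    probe <- runif(5, -10, 160)
    expect_equal(project_position(probe, self), probe, tolerance = 1e-9)

    fwd <- shared_markers(comp, ref, "1")
    xs <- sort(runif(20, -10, max(comp_pos) + 10))
    ys <- project_position(xs, fwd)
    expect_true(all(diff(ys) >= -1e-12))

    # round trip for anchor-interval-interior points
    bwd <- shared_markers(ref, comp, "1")
    interior <- runif(10, min(comp_pos), max(comp_pos))
    expect_equal(project_position(project_position(interior, fwd), bwd),
                 interior, tolerance = 1e-6)
  }
})

test_that("multi-study projection routes QTL to the right component map", {
  maps <- list(toy_map(c("a", "b"), c(0, 10), map_id = "s1"),
               toy_map(c("a", "b"), c(0, 50), map_id = "s2"))
  ref <- toy_map(c("a", "b"), c(0, 100), map_id = "ref")
  std <- standardize_qtl(rbind(
    toy_qtl("q1", study_id = "s1", position_cM = 5, r2 = 0.5),
    toy_qtl("q2", study_id = "s2", position_cM = 5, r2 = 0.5)))
  prj <- project_dataset(std, maps, ref)
  expect_equal(prj$ref_position[prj$qtl_id == "q1"], 50)
  expect_equal(prj$ref_position[prj$qtl_id == "q2"], 10)
  expect_error(project_dataset(standardize_qtl(toy_qtl(study_id = "s9")),
                               maps, ref), "no component map")
})
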