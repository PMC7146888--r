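one_qtl <- function(pos, chromosome = 1) {
  tibble::tibble(qtl_id = "q", trait = "GW", chromosome = chromosome,
                 position_cM = pos, study_id = "s", population_id = "p")
}

test_that("common flank search brackets, extrapolates and fails as specified", {
  src <- make_map(c("A", "B", "C"), c(10, 20, 30), map_id = "src")
  ref <- make_map(c("A", "B", "C"), c(10, 20, 30), map_id = "ref")
  fl <- find_common_flanks(15, src, ref, 1)
  expect_equal(c(fl$left, fl$right), c("A", "B"))
  expect_false(fl$extrapolated)

  fl <- find_common_flanks(5, src, ref, 1)
  expect_equal(c(fl$left, fl$right), c("A", "B"))
  expect_true(fl$extrapolated)

  ref1 <- make_map("A", 10, map_id = "ref1")
  expect_error(find_common_flanks(15, src, ref1, 1), "unprojectable")
})

test_that("projection between identical maps is the identity", {
  map <- ref_map_10()
  p <- project_qtl(one_qtl(12.3), ci_width = 4, map, map)
  expect_equal(p$status, "projected")
  expect_equal(p$ref_position, 12.3, tolerance = 1e-9)
  expect_equal(p$ci_width, 4.0, tolerance = 1e-9)
  expect_equal(p$sd, 4 / (2 * qnorm(0.975)), tolerance = 1e-9)
})

test_that("peak and CI endpoints interpolate on their own flank pairs", {
  # hand-computed: source A@10 B@20, reference A@100 B@140, scale factor 4
  src <- make_map(c("A", "B"), c(10, 20), map_id = "src")
  ref <- make_map(c("A", "B"), c(100, 140), map_id = "ref")
  p <- project_qtl(one_qtl(15), ci_width = 6, src, ref)
  expect_equal(p$ref_position, 120.0)
  expect_equal(p$ci_width, 24.0)  # endpoints 12 -> 108 and 18 -> 132

  # a peak exactly at a common marker maps to that marker's reference position
  p <- project_qtl(one_qtl(10), ci_width = 0.5, src, ref)
  expect_equal(p$ref_position, 100.0)
})

test_that("inverted marker order between maps fails as an order conflict", {
  src <- make_map(c("A", "B", "C"), c(10, 20, 30), map_id = "src")
  ref <- make_map(c("B", "A", "C"), c(10, 20, 30), map_id = "ref")
  p <- project_qtl(one_qtl(15), ci_width = 2, src, ref)
  expect_equal(p$status, "failed")
  expect_match(p$reason, "order conflict")
})

test_that("far extrapolation fails, near extrapolation is flagged", {
  src <- make_map(c("A", "B"), c(50, 60), map_id = "src")
  ref <- make_map(c("A", "B"), c(50, 60), map_id = "ref")
  near <- project_qtl(one_qtl(45), ci_width = 2, src, ref)
  expect_equal(near$status, "projected")
  expect_true(near$extrapolated)
  far <- project_qtl(one_qtl(20), ci_width = 2, src, ref)
  expect_equal(far$status, "failed")
})

test_that("degenerate projected intervals are floored at 0.1 cM", {
  # all mass in one reference segment collapsed to near-zero width
  src <- make_map(c("A", "B"), c(10, 20), map_id = "src")
  ref <- make_map(c("A", "B"), c(100, 100.001), map_id = "ref")
  p <- project_qtl(one_qtl(15), ci_width = 4, src, ref)
  expect_equal(p$ci_width, 0.1)
  expect_gt(p$sd, 0)
})

test_that("SNP flank substitution picks the nearest bp marker, lower on ties", {
  ref <- make_map(c("M1", "M2"), c(10, 20), bp = c(4.9e6, 5.3e6), map_id = "r")
  expect_equal(substitute_snp_flanks(5.0e6, 1, ref), "M1")
  expect_equal(substitute_snp_flanks(5.1e6, 1, ref), "M1")  # equidistant tie
  expect_equal(substitute_snp_flanks(5.3e6, 1, ref), "M2")  # exact hit
  no_bp <- make_map(c("M1", "M2"), c(10, 20), map_id = "r2")
  expect_error(substitute_snp_flanks(5e6, 1, no_bp), "bp-annotated")
})

test_that("projection is monotone and invertible on random shared maps", {
  for (seed in 1:20) {
    set.seed(seed)
    n_mark <- sample(5:12, 1)
    markers <- sprintf("MM%02d", seq_len(n_mark))
    src <- make_map(markers, sort(runif(n_mark, 0, 100)), map_id = "src")
    ref <- make_map(markers, sort(runif(n_mark, 0, 150)), map_id = "ref")
    lo <- min(src$cM) + 0.5
    hi <- max(src$cM) - 0.5
    pos <- sort(runif(8, lo, hi))
    proj <- vapply(pos, function(p) {
      project_qtl(one_qtl(p), ci_width = 1, src, ref)$ref_position
    }, numeric(1))
    expect_true(all(diff(proj) >= -1e-9))
    # round trip source -> reference -> source recovers the peak
    back <- vapply(proj, function(p) {
      project_qtl(one_qtl(p), ci_width = 1, ref, src)$ref_position
    }, numeric(1))
    expect_equal(back, pos, tolerance = 1e-6)
  }
})

test_that("projection from a marker-subset map has exactly zero error", {
  cfg <- simulation_config(n_chromosomes = 2, markers_per_chromosome = 40,
                           traits = "GW", n_true_per_cell = 2,
                           min_separation = 30, n_studies = 6,
                           detection_probability = 1,
                           N_range = c(150, 300), r2_range = c(0.1, 0.3),
                           source_map_marker_fraction = 0.4, seed = 42)
  sim <- simulate_compendium(cfg)
  q <- add_ci(sim$qtls, sim$studies)
  proj <- project_qtls(q, sim$source_maps, sim$reference_map)
  ok <- proj$status == "projected"
  expect_true(any(ok))
  expect_lt(max(abs(proj$ref_position[ok] - q$position_cM[ok])), 1e-9)
})
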