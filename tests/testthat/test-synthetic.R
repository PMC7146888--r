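small_cfg <- function(...) {
  simulation_config(n_chromosomes = 1, markers_per_chromosome = 20,
                    traits = "GW", n_true_per_cell = 1, min_separation = 10,
                    n_studies = 6, detection_probability = 1,
                    N_range = c(200, 300), r2_range = c(0.15, 0.30),
                    source_map_marker_fraction = 0.5, ...)
}

test_that("the generator is deterministic given its seed", {
  s1 <- simulate_compendium(small_cfg(seed = 31))
  s2 <- simulate_compendium(small_cfg(seed = 31))
  expect_identical(s1$qtls, s2$qtls)
  expect_identical(s1$studies, s2$studies)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_compendium(small_cfg(seed = 32))
  expect_false(identical(s1$qtls$position_cM, s3$qtls$position_cM))
})

test_that("the zero-noise limit reproduces true positions exactly", {
  sim <- simulate_compendium(small_cfg(seed = 5, noise_scale = 0))
  truth_pos <- sim$truth$loci$position[
    match(sim$truth$assignments$locus_id, sim$truth$loci$locus_id)]
  expect_equal(sim$qtls$position_cM, truth_pos)
})

test_that("full detection of one locus by six studies yields six QTLs", {
  sim <- simulate_compendium(small_cfg(seed = 17))
  expect_equal(nrow(sim$truth$loci), 1)
  expect_equal(nrow(sim$qtls), 6)
  expect_equal(unique(sim$truth$assignments$locus_id), "L001")
  expect_setequal(sim$truth$assignments$study_id, sim$studies$study_id)
})

test_that("simulated peak scatter matches the CI-derived standard deviation", {
  # one design, fixed N and r2, so every QTL shares one true sd
  cfg <- simulation_config(
    n_chromosomes = 1, markers_per_chromosome = 10, traits = "GW",
    true_loci = tibble::tibble(trait = "GW", chromosome = 1, position = 74),
    n_studies = 10000, detection_probability = 1,
    population_type_probs = c(F2 = 1),
    N_range = c(200, 200), r2_range = c(0.2, 0.2),
    source_map_marker_fraction = 0.5, seed = 23)
  sim <- simulate_compendium(cfg)
  ci <- 530 / (200 * 0.2)
  expect_equal(sd(sim$qtls$position_cM - 74), ci / (2 * qnorm(0.975)),
               tolerance = 0.05)
})

test_that("design mix frequencies converge to their probabilities", {
  cfg <- simulation_config(n_chromosomes = 1, markers_per_chromosome = 10,
                           traits = "GW", n_true_per_cell = 1,
                           n_studies = 1000, detection_probability = 0.5,
                           source_map_marker_fraction = 0.5, seed = 41)
  sim <- simulate_compendium(cfg)
  freq <- table(factor(sim$studies$population_type,
                       levels = names(cfg$population_type_probs))) / 1000
  for (pt in names(cfg$population_type_probs)) {
    p <- cfg$population_type_probs[[pt]]
    half_width <- 3.5 * sqrt(p * (1 - p) / 1000)
    expect_lt(abs(freq[[pt]] - p), half_width)
  }
})

test_that("recovery scoring follows its matching conventions", {
  truth <- list(
    loci = tibble::tibble(locus_id = c("L1", "L2"), trait = "GW",
                          chromosome = 1, position = c(30, 80)),
    assignments = tibble::tibble(
      qtl_id = sprintf("q%d", 1:6),
      locus_id = rep(c("L1", "L2"), each = 3),
      study_id = sprintf("s%d", c(1, 2, 3, 1, 2, 3))))
  exact <- tibble::tibble(mqtl_id = c("MQTL-GW1", "MQTL-GW2"), trait = "GW",
                          chromosome = 1, position = c(30, 80))
  ev <- evaluate_recovery(truth, exact)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$k_accuracy, 1)

  none <- exact[0, ]
  ev0 <- evaluate_recovery(truth, none)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)          # undefined-by-convention
  expect_true(ev0$precision_undefined)

  far <- tibble::tibble(mqtl_id = "MQTL-GW1", trait = "GW", chromosome = 1,
                        position = 60)
  ev_far <- evaluate_recovery(truth, far, match_tolerance = 5)
  expect_equal(ev_far$n_matched, 0)
  expect_equal(ev_far$recall, 0)
  expect_equal(ev_far$precision, 0)
})

test_that("infeasible locus placement fails after bounded attempts", {
  cfg <- simulation_config(n_chromosomes = 1, chromosome_length = 50,
                           markers_per_chromosome = 10, traits = "GW",
                           n_true_per_cell = 4, min_separation = 40,
                           n_studies = 2, seed = 1)
  expect_error(simulate_compendium(cfg), "could not place")
})

test_that("emitted tables are consumable by the compendium reader", {
  sim <- simulate_compendium(small_cfg(seed = 53))
  qp <- tempfile(fileext = ".tsv")
  write_qtl_table(sim$qtls, sim$studies, qp)
  comp <- read_qtl_table(qp)
  expect_equal(nrow(comp$qtls), nrow(sim$qtls))
  expect_equal(nrow(comp$rejected), 0)
  mp <- tempfile(fileext = ".tsv")
  write_genetic_map(sim$reference_map, mp)
  map <- read_genetic_map(mp)
  expect_equal(map$marker, sim$reference_map$marker)
  expect_equal(map$cM, sim$reference_map$cM)
})
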