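fake_model <- function(K, n, loglik, x = rep(0, n), sd = rep(1, n)) {
  structure(list(K = K, means = rep(0, K), weights = rep(1 / K, K),
                 loglik = loglik, n = n,
                 assignments = rep(seq_len(K), length.out = n),
                 trace = loglik, converged = TRUE, x = x, sd = sd),
            class = "qtl_mixture")
}

test_that("single-component fits are inverse-variance weighted means", {
  m <- fit_mixture(c(10, 20), c(1, 1), K = 1, seed = 1)
  expect_equal(m$means, 15.0, tolerance = 1e-9)
  expect_equal(m$weights, 1)

  # unequal precisions pull the mean towards the precise observation
  m <- fit_mixture(c(10, 20), c(1, 100), K = 1, seed = 1)
  expect_equal(m$means, (10 / 1 + 20 / 1e4) / (1 + 1e-4), tolerance = 1e-9)

  sds <- c(0.5, 1, 2, 4)
  m <- fit_mixture(rep(42, 4), sds, K = 1, seed = 1)
  expect_equal(m$means, 42.0, tolerance = 1e-9)
  expect_equal(m$loglik, sum(dnorm(rep(42, 4), 42, sds, log = TRUE)),
               tolerance = 1e-9)
})

test_that("EM log-likelihood is nondecreasing and recovers two groups", {
  set.seed(5)
  x <- c(rnorm(5, 10, 1), rnorm(5, 60, 1))
  sd <- rep(1, 10)
  m <- fit_mixture(x, sd, K = 2, seed = 2)
  expect_true(all(diff(m$trace) >= -1e-8))
  expect_lt(abs(m$means[1] - 10), 1.0)
  expect_lt(abs(m$means[2] - 60), 1.0)
  # hard clustering matches the exhaustive best-assignment oracle
  expect_equal(lc_of_partition(x, sd, m$assignments),
               oracle_best_lc(x, sd, 2), tolerance = 1e-6)
  expect_error(fit_mixture(x, sd, K = 11, seed = 1), "K must satisfy")
})

test_that("information criteria evaluate their printed formulas", {
  ic <- information_criteria(fake_model(K = 1, n = 4, loglik = -10))
  expect_equal(ic[["AIC"]], 22)
  expect_equal(ic[["AIC3"]], 23)
  expect_equal(ic[["BIC"]], 20 + log(4))
  expect_equal(ic[["AICc"]], 22 + 2 * 1 * 2 / (4 - 1 - 1))

  # n = 5, K = 2 (p = 3): AICc = AIC + 24 / (5 - 3 - 1) = AIC + 24
  ic <- information_criteria(fake_model(K = 2, n = 5, loglik = -10))
  expect_equal(ic[["AICc"]] - ic[["AIC"]], 24)

  # AICc unavailable when n - p - 1 <= 0
  ic <- information_criteria(fake_model(K = 2, n = 4, loglik = -10))
  expect_true(is.na(ic[["AICc"]]))
})

test_that("AWE reduces to -2 lnL + 2p(3/2 + ln n) when K = 1", {
  set.seed(7)
  x <- rnorm(6, 30, 2)
  m <- fit_mixture(x, rep(2, 6), K = 1, seed = 1)
  ic <- information_criteria(m)
  expect_equal(ic[["AWE"]], -2 * m$loglik + 2 * (3 / 2 + log(6)),
               tolerance = 1e-9)
})

test_that("model selection takes the modal vote, ties favour parsimony", {
  expect_equal(qtlmeta:::modal_k(c(AIC = 2L, AICc = 2L, AIC3 = 2L,
                                   BIC = 2L, AWE = 3L)), 2L)
  expect_equal(qtlmeta:::modal_k(c(1L, 1L, 2L, 2L, 3L)), 1L)
  expect_equal(qtlmeta:::modal_k(c(NA, 2L, 2L, 3L, 3L)), 2L)
  expect_equal(qtlmeta:::modal_k(c(NA_integer_, NA_integer_), fallback = 4L), 4L)

  # end to end: clearly separated pair of clusters elects K = 2
  set.seed(11)
  x <- c(rnorm(6, 20, 1), rnorm(6, 80, 1))
  models <- lapply(1:4, function(k) fit_mixture(x, rep(1, 12), k, seed = k))
  sel <- select_model(models)
  expect_equal(sel$K, 2L)
  # n = 1 forces K = 1
  sel1 <- select_model(list(fit_mixture(5, 1, K = 1, seed = 1)))
  expect_equal(sel1$K, 1L)
})

test_that("consensus pooling follows the closed forms", {
  single <- consensus_mqtl(tibble::tibble(
    ref_position = 30, sd = 8 / (2 * qnorm(0.975)),
    qtl_id = "a", study_id = "s1", population_id = "p1"))
  expect_equal(single$position, 30.0)
  expect_equal(single$ci_width, 8.0, tolerance = 1e-9)

  pair <- consensus_mqtl(tibble::tibble(
    ref_position = c(10, 14), sd = c(2, 2),
    qtl_id = c("a", "b"), study_id = c("s1", "s2"),
    population_id = c("p1", "p2")))
  expect_equal(pair$position, 12.0)
  expect_equal(pair$ci_width, 5.5436, tolerance = 1e-4)  # 3.92 * 2 / sqrt(2)
  expect_equal(pair$n_studies, 2)

  dominated <- consensus_mqtl(tibble::tibble(
    ref_position = c(10, 20), sd = c(1, 100),
    qtl_id = c("a", "b"), study_id = c("s1", "s2"),
    population_id = c("p1", "p2")))
  expect_equal(dominated$position, 10.001, tolerance = 1e-3)
})

test_that("MQTL calling filters on study support and recovers clusters", {
  proj <- function(pos, study) tibble::tibble(
    qtl_id = sprintf("q%02d", seq_along(pos)), trait = "GW", chromosome = 1,
    ref_position = pos, ci_width = 3.92, sd = 1,
    study_id = study, population_id = study, status = "projected")

  # one tight cluster fed by three studies -> exactly one MQTL
  set.seed(3)
  p <- proj(rnorm(6, 40, 1), rep(c("s1", "s2", "s3"), 2))
  res <- call_mqtls(p, seed = 1)
  expect_equal(nrow(res$mqtls), 1)
  expect_equal(res$mqtls$n_studies, 3)

  # two QTLs from a single study -> candidate discarded, nothing emitted
  p <- proj(c(40, 41), c("s1", "s1"))
  res <- call_mqtls(p, seed = 1)
  expect_equal(nrow(res$mqtls), 0)
  expect_equal(nrow(res$discarded), 1)

  # two clusters 50 cM apart, 4 QTLs / 2 studies each
  set.seed(9)
  p <- proj(c(rnorm(4, 30, 1), rnorm(4, 80, 1)),
            rep(c("s1", "s2"), 4))
  res <- call_mqtls(p, seed = 1)
  expect_equal(nrow(res$mqtls), 2)
  expect_lt(abs(res$mqtls$position[1] - 30), 1)
  expect_lt(abs(res$mqtls$position[2] - 80), 1)
})

test_that("detected MQTLs are numbered by position within trait", {
  set.seed(21)
  mk <- function(trait, chr, center, studies) tibble::tibble(
    qtl_id = sprintf("%s%d_%d", trait, chr, seq_len(4)), trait = trait,
    chromosome = chr, ref_position = rnorm(4, center, 0.5), ci_width = 3.92,
    sd = 1, study_id = studies, population_id = studies, status = "projected")
  proj <- dplyr::bind_rows(
    mk("GW", 2, 60, c("s1", "s2", "s1", "s2")),
    mk("GW", 1, 25, c("s3", "s4", "s3", "s4")),
    mk("HD", 1, 90, c("s5", "s6", "s5", "s6")))
  res <- detect_mqtls(proj, seed = 2, reference_map = NULL)
  expect_equal(res$mqtls$mqtl_id, c("MQTL-GW1", "MQTL-GW2", "MQTL-HD1"))
  expect_equal(res$mqtls$chromosome, c(1, 2, 1))
  # audit carries per-K criterion values and the chosen K per stratum
  expect_true(all(c("K", "AIC", "AWE", "chosen_K", "trait") %in%
                    names(res$audit)))
})

test_that("every emitted consensus lies inside its members and tightens the CI", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(2:9, 1)
    members <- tibble::tibble(
      ref_position = runif(n, 0, 100),
      sd = runif(n, 0.3, 4),
      qtl_id = sprintf("q%d", seq_len(n)),
      study_id = sprintf("s%d", sample(1:4, n, replace = TRUE)),
      population_id = sprintf("p%d", seq_len(n)))
    cons <- consensus_mqtl(members)
    expect_gte(cons$position, min(members$ref_position))
    expect_lte(cons$position, max(members$ref_position))
    expect_lte(cons$ci_width, min(members$sd) * 2 * qnorm(0.975) + 1e-12)
  }
})
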