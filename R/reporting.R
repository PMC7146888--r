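#' Pearson correlation between per-chromosome QTL and MQTL densities
#'
#' @param qtl_counts,mqtl_counts Equal-length numeric vectors (length >= 3) of
#'   per-chromosome counts.
#' @return Pearson product-moment correlation, rounded to 2 decimals;
#'   `NA` with a warning when either vector has zero variance.
#' @export
density_correlation <- function(qtl_counts, mqtl_counts) {
  stopifnot(length(qtl_counts) == length(mqtl_counts),
            length(qtl_counts) >= 3)
  if (stats::sd(qtl_counts) == 0 || stats::sd(mqtl_counts) == 0) {
    warning("zero variance in a count vector; correlation undefined")
    return(NA_real_)
  }
  round(stats::cor(qtl_counts, mqtl_counts), 2)
}

#' Summarise an MQTL analysis
#'
#' Computes the summary statistics of a meta-QTL run: MQTL counts per trait
#' and per chromosome (with min/max/mean), mean MQTL CI, mean original
#' (projected) CI and the fold reduction between them, the projection rate,
#' study-support counts at thresholds 2 to 5, and the per-chromosome
#' QTL-vs-MQTL density correlation.
#'
#' @param mqtls MQTL tibble (needs `trait`, `chromosome`, `ci_width`,
#'   `n_studies`; [detect_mqtls()] output or a compatible summary table).
#' @param projected Optional projected-QTL tibble from [project_qtls()]; used
#'   for the projected count, the mean original CI and the fold reduction.
#' @param compiled_total Optional number of QTLs compiled before projection;
#'   used for the projection rate.
#' @param qtl_counts Optional per-chromosome QTL counts (named or ordered by
#'   chromosome) for the density correlation; defaults to counts derived from
#'   `projected`.
#' @param n_chromosomes Number of chromosomes the per-chromosome summary runs
#'   over (chromosomes without MQTLs count as zero).
#' @return An object of class `mqtl_summary` (a list) with fields
#'   `n_mqtls`, `per_trait`, `per_chromosome`, `chr_min`, `chr_max`,
#'   `chr_mean`, `mean_mqtl_ci`, `mean_original_ci`, `fold_reduction`,
#'   `n_projected`, `compiled_total`, `projection_rate` (integer percent),
#'   `study_support` (tibble: threshold, n, percent) and
#'   `density_correlation`.
#' @export
summarize_mqtls <- function(mqtls, projected = NULL, compiled_total = NULL,
                            qtl_counts = NULL, n_chromosomes = 12) {
  chr_levels <- seq_len(n_chromosomes)
  per_chr <- as.integer(table(factor(mqtls$chromosome, levels = chr_levels)))
  per_trait <- table(factor(mqtls$trait, levels = qtl_traits()))

  n_projected <- if (!is.null(projected))
    sum(projected$status == "projected") else NA_integer_
  mean_original_ci <- if (!is.null(projected)) {
    ok <- projected$status == "projected"
    mean(projected$ci_width[ok])
  } else NA_real_
  mean_mqtl_ci <- if (nrow(mqtls) > 0) mean(mqtls$ci_width) else NA_real_
  fold <- if (!is.na(mean_mqtl_ci) && !is.na(mean_original_ci))
    mean_original_ci / mean_mqtl_ci else NA_real_
  projection_rate <- if (!is.null(compiled_total) && !is.na(n_projected))
    round(100 * n_projected / compiled_total) else NA_real_

  support <- dplyr::bind_rows(lapply(2:5, function(th) {
    n <- sum(mqtls$n_studies >= th)
    tibble::tibble(threshold = th, n = n,
                   percent = if (nrow(mqtls) > 0) 100 * n / nrow(mqtls)
                             else NA_real_)
  }))

  if (is.null(qtl_counts) && !is.null(projected)) {
    ok <- projected$status == "projected"
    qtl_counts <- as.integer(table(factor(projected$chromosome[ok],
                                          levels = chr_levels)))
  }
  dens <- if (!is.null(qtl_counts) && length(qtl_counts) >= 3)
    density_correlation(as.numeric(qtl_counts), per_chr) else NA_real_

  structure(list(
    n_mqtls = nrow(mqtls),
    per_trait = as.integer(per_trait),
    trait_levels = qtl_traits(),
    per_chromosome = tibble::tibble(chromosome = chr_levels, n_mqtls = per_chr),
    chr_min = min(per_chr), chr_max = max(per_chr), chr_mean = mean(per_chr),
    mean_mqtl_ci = mean_mqtl_ci,
    mean_original_ci = mean_original_ci,
    fold_reduction = fold,
    n_projected = n_projected,
    compiled_total = compiled_total %||% NA_integer_,
    projection_rate = projection_rate,
    study_support = support,
    density_correlation = dens), class = "mqtl_summary")
}

#' @export
print.mqtl_summary <- function(x, ...) {
  cat("MQTL summary\n")
  cat("  MQTLs:", x$n_mqtls, " (",
      paste(sprintf("%s=%d", x$trait_levels, x$per_trait), collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  per chromosome: min %d, max %d, mean %.1f\n",
              x$chr_min, x$chr_max, x$chr_mean))
  if (!is.na(x$mean_mqtl_ci))
    cat(sprintf("  mean MQTL CI: %.2f cM\n", x$mean_mqtl_ci))
  if (!is.na(x$mean_original_ci))
    cat(sprintf("  mean original CI: %.2f cM (%.1f-fold reduction)\n",
                x$mean_original_ci, x$fold_reduction))
  if (!is.na(x$n_projected) && !is.na(x$compiled_total))
    cat(sprintf("  projected: %d of %d QTLs (%d%%)\n",
                x$n_projected, x$compiled_total, x$projection_rate))
  th3 <- x$study_support[x$study_support$threshold == 3, ]
  if (x$n_mqtls > 0)
    cat(sprintf("  >=3 independent studies: %d (%.1f%%)\n", th3$n, th3$percent))
  if (!is.na(x$density_correlation))
    cat(sprintf("  QTL/MQTL density correlation: r = %.2f\n",
                x$density_correlation))
  invisible(x)
}

#' Bundled rice MQTL summary table
#'
#' A transcribed summary of 114 published rice meta-QTLs for five yield
#' traits (grain yield, grain weight, heading date, plant height, tiller
#' number): consensus-map position and 95% CI, anchored genomic interval
#' (Mb), and member QTL / study / population / gene counts. Used as a
#' reference fixture for the reporting functions.
#'
#' @return Tibble with one row per MQTL; columns `mqtl_id`, `trait`,
#'   `chromosome`, `flank_left`, `flank_right`, `position` (cM), `ci_width`
#'   (cM), `start_mb`, `end_mb`, `n_qtls`, `n_studies`, `n_populations`,
#'   `n_genes`.
#' @export
rice_mqtl_summary <- function() {
  path <- system.file("extdata", "rice_mqtl_summary.tsv", package = "qtlmeta",
                      mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  tibble::tibble(
    mqtl_id = raw$mqtl_id, trait = raw$trait,
    chromosome = as.integer(raw$chromosome),
    flank_left = raw$flank_left, flank_right = raw$flank_right,
    position = as.numeric(raw$position_cm),
    ci_width = as.numeric(raw$ci_cm),
    start_mb = as.numeric(raw$start_mb), end_mb = as.numeric(raw$end_mb),
    n_qtls = as.integer(raw$n_qtls), n_studies = as.integer(raw$n_studies),
    n_populations = as.integer(raw$n_populations),
    n_genes = as.integer(raw$n_genes))
}

#' Bundled per-chromosome projected-QTL counts
#'
#' Per-chromosome counts of the 960 projected rice QTLs by trait, matching
#' the compendium summarised by [rice_mqtl_summary()].
#'
#' @return Tibble with `chromosome` and one count column per trait.
#' @export
rice_qtl_counts <- function() {
  path <- system.file("extdata", "rice_qtl_counts.tsv", package = "qtlmeta",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = "iiiiii", progress = FALSE,
                  show_col_types = FALSE)
}

#' Bundled rice QTL study metadata
#'
#' One row per mapping population of the transcribed rice compendium (122
#' populations from 101 publications): parents, design, population size,
#' marker count, map density and studied traits. SNP-based studies carry `NA`
#' marker counts and densities.
#'
#' @return Tibble with `study_id`, `reference_tag`, `population_id`,
#'   `parents`, `population_type`, `population_size`, `n_markers`,
#'   `map_density_cm`, `traits` (semicolon-separated codes).
#' @export
rice_qtl_studies <- function() {
  path <- system.file("extdata", "rice_qtl_studies.tsv", package = "qtlmeta",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    population_size = "i", n_markers = "i", map_density_cm = "d",
    .default = "c"), progress = FALSE, show_col_types = FALSE)
}
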