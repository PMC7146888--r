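#' 95% confidence interval of a QTL peak from population design
#'
#' Closed-form width of the 95% confidence interval of a QTL position, in cM,
#' as a function of mapping-population design, population size N and the
#' proportion of phenotypic variance explained (R-squared):
#' `CI = 530/(N * R2)` for backcross (BC) and F2 populations,
#' `CI = 287/(N * R2)` for doubled haploids (DH) and
#' `CI = 163/(N * R2)` for recombinant inbred lines (RIL).
#'
#' @param population_type Character vector of design codes
#'   (`"BC"`, `"DH"`, `"F2"`, `"RIL"`).
#' @param n Positive integer population sizes.
#' @param r2 Explained variance proportions in (0, 1]. Values in (1, 100] are
#'   treated as percentages and divided by 100, with a warning.
#' @return Numeric vector of CI widths in cM.
#' @examples
#' estimate_ci("F2", 106, 0.10)  # 50 cM
#' @export
estimate_ci <- function(population_type, n, r2) {
  k <- ci_numerators()[population_type]
  if (anyNA(k)) {
    stop("unknown population type: ",
         paste(unique(population_type[!population_type %in% names(ci_numerators())]),
               collapse = ", "))
  }
  if (any(n < 1)) stop("population size must be >= 1")
  pct <- !is.na(r2) & r2 > 1 & r2 <= 100
  if (any(pct)) {
    warning("r2 > 1 interpreted as percentage and divided by 100")
    r2[pct] <- r2[pct] / 100
  }
  if (any(is.na(r2) | r2 <= 0 | r2 > 1)) stop("r2 must lie in (0, 1]")
  unname(k / (n * r2))
}

#' Impute missing LOD and R-squared values
#'
#' Replaces missing LOD scores with 3.0 and missing explained-variance values
#' with 0.10 (the conventional significance floor and a 10% variance share),
#' flagging every imputation so it stays auditable downstream.
#'
#' @param lod,r2 Numeric vectors, possibly containing `NA`.
#' @return A tibble with columns `lod`, `r2`, `lod_imputed`, `r2_imputed`.
#' @export
impute_defaults <- function(lod, r2) {
  lod_imputed <- is.na(lod)
  r2_imputed <- is.na(r2)
  lod[lod_imputed] <- 3.0
  r2[r2_imputed] <- 0.10
  tibble::tibble(lod = lod, r2 = r2,
                 lod_imputed = lod_imputed, r2_imputed = r2_imputed)
}

#' Convert a 95% CI width to a standard deviation
#'
#' Assumes the QTL peak estimate is normally distributed, so a 95% interval
#' spans `2 * qnorm(0.975)` (about 3.92) standard deviations.
#'
#' @param ci_width Positive CI widths in cM.
#' @return Standard deviations in cM.
#' @export
ci_to_sd <- function(ci_width) {
  if (any(is.na(ci_width) | ci_width <= 0)) stop("ci_width must be positive")
  ci_width / ci_z()
}

#' Convert a standard deviation to a 95% CI width
#'
#' @param sd Positive standard deviations in cM.
#' @return CI widths in cM.
#' @export
sd_to_ci <- function(sd) {
  if (any(is.na(sd) | sd <= 0)) stop("sd must be positive")
  sd * ci_z()
}

#' Attach CI estimates to a QTL table
#'
#' Joins study design and size onto the QTL records, imputes missing LOD/R2,
#' and computes each QTL's 95% CI width and derived standard deviation.
#'
#' @param qtls,studies Tibbles from [read_qtl_table()].
#' @return `qtls` with added columns `lod`, `r2`, `lod_imputed`, `r2_imputed`,
#'   `ci_width` and `sd`.
#' @export
add_ci <- function(qtls, studies) {
  joined <- dplyr::left_join(
    qtls,
    studies[, c("study_id", "population_type", "population_size")],
    by = "study_id")
  if (anyNA(joined$population_type)) {
    stop("QTL(s) reference studies with unknown design: ",
         paste(unique(joined$qtl_id[is.na(joined$population_type)]), collapse = ", "))
  }
  imp <- impute_defaults(joined$lod, joined$r2)
  joined$lod <- imp$lod
  joined$r2 <- imp$r2
  joined$lod_imputed <- imp$lod_imputed
  joined$r2_imputed <- imp$r2_imputed
  joined$ci_width <- estimate_ci(joined$population_type,
                                 joined$population_size, joined$r2)
  joined$sd <- ci_to_sd(joined$ci_width)
  joined
}
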