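#' Consensus position and CI of one QTL cluster
#'
#' Pools the member QTLs of one mixture component by inverse-variance
#' weighting: the consensus position is
#' `sum(x_i / sd_i^2) / sum(1 / sd_i^2)`, its variance `1 / sum(1 / sd_i^2)`,
#' and the 95% CI width `2 * qnorm(0.975) * sqrt(variance)`. The pooled CI is
#' therefore never wider than the narrowest member CI.
#'
#' @param members Tibble of projected QTLs (columns `ref_position`, `sd`,
#'   `qtl_id`, `study_id`, `population_id`).
#' @return One-row tibble with `position`, `ci_width`, `n_qtls`, `n_studies`,
#'   `n_populations`, `member_qtl_ids` (semicolon-joined).
#' @export
consensus_mqtl <- function(members) {
  stopifnot(nrow(members) >= 1)
  prec <- 1 / members$sd^2
  position <- sum(members$ref_position * prec) / sum(prec)
  variance <- 1 / sum(prec)
  tibble::tibble(
    position = position,
    ci_width = ci_z() * sqrt(variance),
    n_qtls = nrow(members),
    n_studies = dplyr::n_distinct(members$study_id),
    n_populations = dplyr::n_distinct(members$population_id),
    member_qtl_ids = paste(members$qtl_id, collapse = ";"))
}

#' Call MQTLs on one trait x chromosome stratum
#'
#' Fits mixtures for K = 1..Kmax (Kmax = `min(n, kmax)`), selects K by the
#' five-criterion vote ([select_model()]), builds one consensus candidate per
#' component ([consensus_mqtl()]), and discards candidates supported by fewer
#' than `min_studies` distinct studies.
#'
#' @param projected Tibble of projected QTLs from a single trait and
#'   chromosome with `status == "projected"`.
#' @param seed Seed forwarded to [fit_mixture()].
#' @param kmax Upper bound for the number of components.
#' @param min_studies Minimum number of distinct supporting studies.
#' @return List with `mqtls` (tibble of surviving consensus candidates, ordered
#'   by position), `selection` (the [select_model()] result) and `discarded`
#'   (candidates removed by the study-support filter).
#' @export
call_mqtls <- function(projected, seed = 1, kmax = 10, min_studies = 2) {
  stopifnot(nrow(projected) >= 1)
  n <- nrow(projected)
  kc <- min(n, kmax)
  models <- lapply(seq_len(kc), function(k) {
    fit_mixture(projected$ref_position, projected$sd, K = k, seed = seed + k)
  })
  sel <- select_model(models)
  comp <- sel$model$assignments
  cands <- dplyr::bind_rows(lapply(sort(unique(comp)), function(k) {
    consensus_mqtl(projected[comp == k, ])
  }))
  cands <- cands[order(cands$position), ]
  keep <- cands$n_studies >= min_studies
  list(mqtls = cands[keep, ], selection = sel, discarded = cands[!keep, ])
}

## reference-map markers flanking a consensus CI: last marker at or below the
## lower bound and first marker at or above the upper bound (chromosome ends
## as fallback)
mqtl_flanks <- function(position, ci_width, chromosome, reference_map) {
  ref <- map_chromosome(reference_map, chromosome)
  lo <- position - ci_width / 2
  hi <- position + ci_width / 2
  below <- which(ref$cM <= lo)
  above <- which(ref$cM >= hi)
  left <- if (length(below)) max(below) else 1L
  right <- if (length(above)) min(above) else nrow(ref)
  c(ref$marker[left], ref$marker[right])
}

#' Detect meta-QTLs across a projected compendium
#'
#' Runs [call_mqtls()] independently on every trait x chromosome stratum of
#' the projected QTLs, then numbers the surviving consensus loci within each
#' trait by chromosome and position (`MQTL-<trait><serial>`). When a reference
#' map is supplied, each MQTL also gets the reference markers flanking its CI.
#'
#' @param projected Tibble from [project_qtls()]; failed rows are dropped.
#' @param seed Base seed; each stratum derives its own deterministic seed.
#' @param reference_map Optional `genetic_map` for flanking-marker lookup.
#' @param kmax,min_studies Passed to [call_mqtls()].
#' @return List with `mqtls` (tibble: `mqtl_id`, `trait`, `chromosome`,
#'   `position`, `ci_width`, `flank_left`, `flank_right`, `n_qtls`,
#'   `n_studies`, `n_populations`, `member_qtl_ids`) and `audit` (per-stratum
#'   model-selection table with criterion values and votes).
#' @export
detect_mqtls <- function(projected, seed = 1, reference_map = NULL,
                         kmax = 10, min_studies = 2) {
  projected <- projected[projected$status == "projected", ]
  strata <- dplyr::distinct(projected, .data$trait, .data$chromosome)
  strata <- strata[order(strata$trait, strata$chromosome), ]
  out <- list(); audits <- list()
  for (i in seq_len(nrow(strata))) {
    tr <- strata$trait[i]; ch <- strata$chromosome[i]
    sub <- projected[projected$trait == tr & projected$chromosome == ch, ]
    res <- call_mqtls(sub, seed = seed + 97 * i, kmax = kmax,
                      min_studies = min_studies)
    if (nrow(res$mqtls) > 0) {
      m <- res$mqtls
      m$trait <- tr; m$chromosome <- ch
      out[[length(out) + 1]] <- m
    }
    a <- res$selection$criteria
    a$trait <- tr; a$chromosome <- ch
    a$chosen_K <- res$selection$K
    audits[[length(audits) + 1]] <- a
  }
  audit <- dplyr::bind_rows(audits)
  if (length(out) == 0) {
    return(list(mqtls = tibble::tibble(
      mqtl_id = character(), trait = character(), chromosome = integer(),
      position = double(), ci_width = double(), flank_left = character(),
      flank_right = character(), n_qtls = integer(), n_studies = integer(),
      n_populations = integer(), member_qtl_ids = character()),
      audit = audit))
  }
  mqtls <- dplyr::bind_rows(out)
  mqtls <- mqtls[order(mqtls$trait, mqtls$chromosome, mqtls$position), ]
  mqtls <- dplyr::group_by(mqtls, .data$trait)
  mqtls <- dplyr::mutate(mqtls, mqtl_id = sprintf("MQTL-%s%d", .data$trait,
                                                  dplyr::row_number()))
  mqtls <- dplyr::ungroup(mqtls)
  if (!is.null(reference_map)) {
    fl <- t(mapply(mqtl_flanks, mqtls$position, mqtls$ci_width,
                   mqtls$chromosome, MoreArgs = list(reference_map = reference_map)))
    mqtls$flank_left <- fl[, 1]
    mqtls$flank_right <- fl[, 2]
  } else {
    mqtls$flank_left <- NA_character_
    mqtls$flank_right <- NA_character_
  }
  mqtls <- mqtls[, c("mqtl_id", "trait", "chromosome", "position", "ci_width",
                     "flank_left", "flank_right", "n_qtls", "n_studies",
                     "n_populations", "member_qtl_ids")]
  list(mqtls = mqtls, audit = audit)
}
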