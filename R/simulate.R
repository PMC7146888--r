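#' Configuration for a synthetic QTL compendium
#'
#' Collects the generator's parameters with defaults emulating a large rice
#' yield-trait compendium: 12 chromosomes of 147.65 cM carrying a dense
#' reference map (about 0.25 cM marker spacing), around a hundred studies
#' whose mapping populations mix the four designs (BC/DH/F2/RIL roughly
#' 33:13:27:40), population sizes between 77 and 1024, and per-QTL noise
#' scaled by the design-specific CI formulas.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in cM.
#' @param markers_per_chromosome Markers on the reference map per chromosome.
#' @param traits Trait codes simulated (subset of the five).
#' @param true_loci Either `NULL` (place `n_true_per_cell` loci per trait x
#'   chromosome at random with `min_separation`) or a tibble with `trait`,
#'   `chromosome`, `position` fixing the ground truth.
#' @param n_true_per_cell True loci per trait x chromosome when `true_loci`
#'   is `NULL`.
#' @param min_separation Minimum distance between true loci on one
#'   trait x chromosome, in cM.
#' @param n_studies Number of simulated studies (one population each).
#' @param population_type_probs Named sampling probabilities over
#'   `BC`, `DH`, `F2`, `RIL` (normalised internally).
#' @param N_range Integer range of population sizes.
#' @param r2_range Uniform bounds of the simulated explained variance.
#' @param detection_probability Probability that a given study detects a given
#'   true locus.
#' @param source_map_marker_fraction Fraction of reference markers retained in
#'   each study's source map (cM unchanged).
#' @param cm_jitter Optional sd of cM jitter applied to source-map marker
#'   positions, to study projection error in isolation (default 0: source
#'   maps are exact subsets).
#' @param extra_position_noise Additional peak noise sd in cM on top of the
#'   CI-derived noise.
#' @param noise_scale Multiplier on the CI-derived peak noise sd; 0 gives the
#'   zero-noise limit where every peak equals its true position.
#' @param seed Integer seed; the whole compendium is deterministic given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 12,
                              chromosome_length = 147.65,
                              markers_per_chromosome = 581,
                              traits = qtl_traits(),
                              true_loci = NULL,
                              n_true_per_cell = 2,
                              min_separation = 20,
                              n_studies = 101,
                              population_type_probs = c(BC = 33, DH = 13,
                                                        F2 = 27, RIL = 40),
                              N_range = c(77, 1024),
                              r2_range = c(0.05, 0.30),
                              detection_probability = 0.085,
                              source_map_marker_fraction = 0.15,
                              cm_jitter = 0,
                              extra_position_noise = 0,
                              noise_scale = 1,
                              seed = 1) {
  stopifnot(min_separation < chromosome_length,
            detection_probability > 0, detection_probability <= 1,
            all(names(population_type_probs) %in% population_types()),
            source_map_marker_fraction > 0, source_map_marker_fraction <= 1)
  probs <- population_type_probs / sum(population_type_probs)
  structure(list(
    n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
    markers_per_chromosome = markers_per_chromosome, traits = traits,
    true_loci = true_loci, n_true_per_cell = n_true_per_cell,
    min_separation = min_separation, n_studies = n_studies,
    population_type_probs = probs, N_range = N_range, r2_range = r2_range,
    detection_probability = detection_probability,
    source_map_marker_fraction = source_map_marker_fraction,
    cm_jitter = cm_jitter, extra_position_noise = extra_position_noise,
    noise_scale = noise_scale, seed = seed), class = "sim_config")
}

## rejection sampler for locus positions with a minimum pairwise separation
place_loci <- function(n, length_cm, min_sep, margin = 5) {
  if (n == 0) return(numeric(0))
  for (attempt in seq_len(1000)) {
    pos <- sort(stats::runif(n, margin, length_cm - margin))
    if (n == 1 || min(diff(pos)) >= min_sep) return(pos)
  }
  stop("could not place ", n, " loci with separation ", min_sep,
       " on a ", length_cm, " cM chromosome after 1000 attempts")
}

#' Simulate a multi-study QTL compendium with known ground truth
#'
#' Generates the statistical structure the meta-analysis assumes: true trait
#' loci on a dense reference map; studies with design, population size and R2
#' drawn from the configuration; each study detecting each true locus with
#' `detection_probability`, reporting a peak drawn from
#' `Normal(true position, noise_scale * CI / (2 * qnorm(0.975)))` (clamped to
#' the chromosome) where CI comes from the design-specific closed forms; and
#' per-study source maps that are random marker subsets of the reference map.
#' Phenotypes and genotypes are not simulated; QTL detections are drawn
#' directly.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List with `reference_map`, `source_maps` (named list, one per
#'   study), `studies`, `qtls` (compendium tibble as read by
#'   [read_qtl_table()]), and `truth` (list: `loci` tibble with `locus_id`,
#'   `trait`, `chromosome`, `position`; `assignments` tibble mapping each
#'   `qtl_id` to its generating `locus_id` and `study_id`).
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  ## reference map: uniform spacing, bp at 250 kb per cM
  ref <- dplyr::bind_rows(lapply(seq_len(config$n_chromosomes), function(ch) {
    cm <- seq(0, config$chromosome_length,
              length.out = config$markers_per_chromosome)
    tibble::tibble(chromosome = ch,
                   marker = sprintf("M%02d_%04d", ch, seq_along(cm)),
                   cM = cm, bp = round(cm * 250000) + 1)
  }))
  reference_map <- as_genetic_map(ref, map_id = "SIM_REF")

  ## ground-truth loci
  if (is.null(config$true_loci)) {
    loci <- dplyr::bind_rows(lapply(config$traits, function(tr) {
      dplyr::bind_rows(lapply(seq_len(config$n_chromosomes), function(ch) {
        pos <- place_loci(config$n_true_per_cell, config$chromosome_length,
                          config$min_separation)
        if (length(pos) == 0) return(NULL)
        tibble::tibble(trait = tr, chromosome = ch, position = pos)
      }))
    }))
  } else {
    loci <- tibble::as_tibble(config$true_loci)
  }
  loci$locus_id <- sprintf("L%03d", seq_len(nrow(loci)))

  ## studies: one population per simulated study
  types <- sample(names(config$population_type_probs), config$n_studies,
                  replace = TRUE, prob = config$population_type_probs)
  studies <- tibble::tibble(
    study_id = sprintf("SIM%03d", seq_len(config$n_studies)),
    population_id = sprintf("SIM%03d.P1", seq_len(config$n_studies)),
    reference_tag = sprintf("SimRef%03d", seq_len(config$n_studies)),
    population_type = types,
    population_size = config$N_range[1] - 1L +
      sample.int(config$N_range[2] - config$N_range[1] + 1L,
                 config$n_studies, replace = TRUE))

  ## per-study source maps: marker subsets of the reference (>= 2 per
  ## chromosome so every position stays projectable)
  source_maps <- lapply(seq_len(config$n_studies), function(s) {
    sub <- dplyr::bind_rows(lapply(seq_len(config$n_chromosomes), function(ch) {
      m <- ref[ref$chromosome == ch, ]
      k <- max(2L, round(config$source_map_marker_fraction * nrow(m)))
      picked <- sort(sample(nrow(m), k))
      out <- m[picked, ]
      if (config$cm_jitter > 0) {
        out$cM <- sort(pmax(0, out$cM + stats::rnorm(nrow(out), 0,
                                                     config$cm_jitter)))
      }
      out
    }))
    as_genetic_map(sub, map_id = sprintf("SIM_MAP%03d", s))
  })
  names(source_maps) <- vapply(source_maps, attr, character(1), "map_id")

  ## QTL detections
  qtl_rows <- list(); assign_rows <- list()
  for (s in seq_len(config$n_studies)) {
    detected <- stats::runif(nrow(loci)) < config$detection_probability
    for (j in which(detected)) {
      r2 <- stats::runif(1, config$r2_range[1], config$r2_range[2])
      ci <- estimate_ci(studies$population_type[s],
                        studies$population_size[s], r2)
      sd_eff <- config$noise_scale * ci / ci_z()
      peak <- loci$position[j] +
        (if (sd_eff > 0) stats::rnorm(1, 0, sd_eff) else 0) +
        (if (config$extra_position_noise > 0)
           stats::rnorm(1, 0, config$extra_position_noise) else 0)
      peak <- min(max(peak, 0), config$chromosome_length)
      qtl_id <- sprintf("Q%05d", length(qtl_rows) + 1)
      qtl_rows[[length(qtl_rows) + 1]] <- tibble::tibble(
        qtl_id = qtl_id,
        study_id = studies$study_id[s],
        population_id = studies$population_id[s],
        trait = loci$trait[j], chromosome = loci$chromosome[j],
        position_cM = peak,
        lod = round(stats::runif(1, 3, 12), 2), r2 = r2,
        flank_left = NA_character_, flank_right = NA_character_,
        map_id = names(source_maps)[s])
      assign_rows[[length(assign_rows) + 1]] <- tibble::tibble(
        qtl_id = qtl_id, locus_id = loci$locus_id[j],
        study_id = studies$study_id[s])
    }
  }
  qtls <- if (length(qtl_rows)) dplyr::bind_rows(qtl_rows) else
    tibble::tibble(qtl_id = character(), study_id = character(),
                   population_id = character(), trait = character(),
                   chromosome = integer(), position_cM = double(),
                   lod = double(), r2 = double(), flank_left = character(),
                   flank_right = character(), map_id = character())
  assignments <- if (length(assign_rows)) dplyr::bind_rows(assign_rows) else
    tibble::tibble(qtl_id = character(), locus_id = character(),
                   study_id = character())

  list(reference_map = reference_map, source_maps = source_maps,
       studies = studies, qtls = qtls,
       truth = list(loci = loci[, c("locus_id", "trait", "chromosome",
                                    "position")],
                    assignments = assignments),
       config = config)
}

#' Benchmark locus-number and position recovery of the full pipeline
#'
#' Runs seeded replicates of the complete analysis (simulate -> CI -> project
#' -> cluster) on single-chromosome compendia with known ground truth and
#' scores how often model selection recovers the true number of loci and how
#' accurately consensus positions land. Each replicate draws M true loci
#' (cycling over `m_values`) separated by at least `min_separation` cM, each
#' detected by all of `n_studies` studies; population sizes and explained
#' variances are drawn so that every per-QTL position noise sd stays at or
#' below about 2.8 cM under the design-specific CI formulas.
#'
#' @param n_replicates Number of simulated chromosomes.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param m_values True locus counts cycled over replicates.
#' @param min_separation Minimum true-locus separation in cM.
#' @param n_studies Studies per replicate (each detects every locus).
#' @param match_tolerance Matching tolerance passed to [evaluate_recovery()].
#' @return List with `k_accuracy` (fraction of replicates where the number of
#'   emitted MQTLs equals M), `rmse` (cM over all matched MQTL/locus pairs),
#'   `recall`, `n_replicates` and a per-replicate `details` tibble.
#' @export
recovery_benchmark <- function(n_replicates = 100, seed = 1,
                               m_values = c(1, 2, 3), min_separation = 15,
                               n_studies = 8, match_tolerance = 5) {
  details <- list()
  errors <- numeric(0)
  n_recoverable <- 0L
  n_matched <- 0L
  for (r in seq_len(n_replicates)) {
    m <- m_values[(r - 1) %% length(m_values) + 1]
    cfg <- simulation_config(
      n_chromosomes = 1, markers_per_chromosome = 100, traits = "GW",
      n_true_per_cell = m, min_separation = min_separation,
      n_studies = n_studies, detection_probability = 1,
      N_range = c(250, 450), r2_range = c(0.20, 0.35),
      source_map_marker_fraction = 0.5, seed = seed + r)
    sim <- simulate_compendium(cfg)
    q <- add_ci(sim$qtls, sim$studies)
    proj <- project_qtls(q, sim$source_maps, sim$reference_map)
    res <- detect_mqtls(proj, seed = seed + r)
    ev <- evaluate_recovery(sim$truth, res$mqtls,
                            match_tolerance = match_tolerance)
    errors <- c(errors, ev$matches$error)
    n_recoverable <- n_recoverable + ev$n_recoverable
    n_matched <- n_matched + ev$n_matched
    details[[r]] <- tibble::tibble(
      replicate = r, m_true = m, m_found = nrow(res$mqtls),
      k_correct = nrow(res$mqtls) == m, n_matched = ev$n_matched)
  }
  details <- dplyr::bind_rows(details)
  list(k_accuracy = mean(details$k_correct),
       rmse = if (length(errors)) sqrt(mean(errors^2)) else NA_real_,
       recall = if (n_recoverable > 0) n_matched / n_recoverable else NA_real_,
       n_replicates = n_replicates, details = details)
}

#' Score recovered MQTLs against simulation ground truth
#'
#' Matches MQTLs to true loci greedily by distance (nearest pair first) within
#' each trait x chromosome stratum, counting a match only within
#' `match_tolerance` cM. A true locus is *recoverable* when at least
#' `min_studies` distinct studies detected it (otherwise the study-support
#' filter removes it by design and it is not counted against recall).
#'
#' @param truth Truth list from [simulate_compendium()].
#' @param mqtls MQTL tibble from [detect_mqtls()].
#' @param match_tolerance Maximum matching distance in cM.
#' @param min_studies Study-support threshold defining recoverable loci.
#' @return List with `precision`, `recall`, `rmse` (cM over matched pairs),
#'   `k_accuracy` (fraction of strata with at least one recoverable locus
#'   where the number of MQTLs equals the number of recoverable loci),
#'   `n_matched`, `n_mqtls`, `n_recoverable`, `precision_undefined` (TRUE when
#'   no MQTL was emitted; precision is then reported as 1 by convention) and
#'   `matches` (tibble of matched pairs).
#' @export
evaluate_recovery <- function(truth, mqtls, match_tolerance = 5,
                              min_studies = 2) {
  support <- dplyr::summarise(
    dplyr::group_by(truth$assignments, .data$locus_id),
    n_studies = dplyr::n_distinct(.data$study_id), .groups = "drop")
  loci <- dplyr::left_join(truth$loci, support, by = "locus_id")
  loci$n_studies[is.na(loci$n_studies)] <- 0L
  recoverable <- loci[loci$n_studies >= min_studies, ]

  matches <- list()
  strata <- dplyr::distinct(recoverable, .data$trait, .data$chromosome)
  k_hits <- 0L
  for (i in seq_len(nrow(strata))) {
    tr <- strata$trait[i]; ch <- strata$chromosome[i]
    tl <- recoverable[recoverable$trait == tr & recoverable$chromosome == ch, ]
    mm <- mqtls[mqtls$trait == tr & mqtls$chromosome == ch, ]
    if (nrow(mm) == nrow(tl)) k_hits <- k_hits + 1L
    if (nrow(mm) == 0 || nrow(tl) == 0) next
    d <- abs(outer(mm$position, tl$position, "-"))
    while (TRUE) {
      best <- which(d == min(d), arr.ind = TRUE)[1, , drop = TRUE]
      if (!is.finite(d[best[1], best[2]]) || d[best[1], best[2]] > match_tolerance)
        break
      matches[[length(matches) + 1]] <- tibble::tibble(
        mqtl_id = mm$mqtl_id[best[1]], locus_id = tl$locus_id[best[2]],
        mqtl_position = mm$position[best[1]],
        true_position = tl$position[best[2]],
        error = mm$position[best[1]] - tl$position[best[2]])
      d[best[1], ] <- Inf
      d[, best[2]] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  matched <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(mqtl_id = character(), locus_id = character(),
                   mqtl_position = double(), true_position = double(),
                   error = double())
  n_mqtls <- nrow(mqtls)
  precision_undefined <- n_mqtls == 0
  list(
    precision = if (precision_undefined) 1 else nrow(matched) / n_mqtls,
    recall = if (nrow(recoverable) == 0) NA_real_
             else nrow(matched) / nrow(recoverable),
    rmse = if (nrow(matched) == 0) NA_real_ else sqrt(mean(matched$error^2)),
    k_accuracy = if (nrow(strata) == 0) NA_real_ else k_hits / nrow(strata),
    n_matched = nrow(matched), n_mqtls = n_mqtls,
    n_recoverable = nrow(recoverable),
    precision_undefined = precision_undefined,
    matches = matched)
}
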