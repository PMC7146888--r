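#' Find common flanking markers bracketing a position
#'
#' Identifies, among the markers shared by a source map and the reference map
#' on one chromosome, the nearest shared marker at-or-below and the nearest
#' shared marker above a source-map position. Positions outside the outermost
#' shared markers get the outermost pair, flagged as extrapolation.
#'
#' @param position Position in source-map cM.
#' @param source_map,reference_map `genetic_map` objects.
#' @param chromosome Chromosome identifier present in both maps.
#' @return A list with `left`, `right` (marker names), `src_left`, `src_right`,
#'   `ref_left`, `ref_right` (cM positions) and `extrapolated` (logical).
#' @export
find_common_flanks <- function(position, source_map, reference_map, chromosome) {
  src <- map_chromosome(source_map, chromosome)
  ref <- map_chromosome(reference_map, chromosome)
  common <- src[src$marker %in% ref$marker, ]
  if (nrow(common) < 2) {
    stop("unprojectable: fewer than 2 common markers on chromosome ", chromosome)
  }
  ref_cm <- ref$cM[match(common$marker, ref$marker)]
  extrapolated <- FALSE
  below <- which(common$cM <= position)
  above <- which(common$cM > position)
  if (length(below) == 0) {          # left of outermost common marker
    idx <- c(1L, 2L); extrapolated <- TRUE
  } else if (length(above) == 0) {   # right of outermost common marker
    idx <- c(nrow(common) - 1L, nrow(common)); extrapolated <- TRUE
  } else {
    idx <- c(max(below), min(above))
  }
  list(left = common$marker[idx[1]], right = common$marker[idx[2]],
       src_left = common$cM[idx[1]], src_right = common$cM[idx[2]],
       ref_left = ref_cm[idx[1]], ref_right = ref_cm[idx[2]],
       extrapolated = extrapolated)
}

## linear interpolation between one flank pair; degenerate source interval
## falls back to the reference midpoint
interpolate_position <- function(position, flanks) {
  if (flanks$src_left == flanks$src_right) {
    return(list(ref = (flanks$ref_left + flanks$ref_right) / 2, degenerate = TRUE))
  }
  scale <- (flanks$ref_right - flanks$ref_left) /
    (flanks$src_right - flanks$src_left)
  list(ref = flanks$ref_left + (position - flanks$src_left) * scale,
       degenerate = FALSE)
}

## cM distance from a position to the nearest common marker (0 inside the span)
extrapolation_distance <- function(position, common_cm) {
  max(0, min(common_cm) - position, position - max(common_cm))
}

#' Project one QTL onto the reference map
#'
#' Relocates a QTL peak and both ends of its confidence interval from the
#' source linkage map onto the reference map. Each of the three positions is
#' linearly interpolated between its own pair of flanking markers common to
#' the two maps (piecewise-linear projection), so a wide interval spanning
#' several map segments is not distorted by a single global scale. The
#' projected CI width is the distance between the projected endpoints, floored
#' at 0.1 cM; endpoints are clamped to the reference chromosome span.
#'
#' QTLs whose peak lies more than `max_extrapolation` cM beyond the outermost
#' common marker, or whose common markers appear in inverted order on the two
#' maps, are returned with `status = "failed"` and a reason; they are excluded
#' from clustering.
#'
#' @param qtl One-row tibble with at least `qtl_id`, `trait`, `chromosome`,
#'   `position_cM`, `study_id`, `population_id`.
#' @param ci_width 95% CI width on the source map, in cM.
#' @param source_map,reference_map `genetic_map` objects.
#' @param max_extrapolation Maximum tolerated extrapolation distance in cM.
#' @return One-row tibble with `qtl_id`, `trait`, `chromosome`, `ref_position`,
#'   `ci_width`, `sd`, `study_id`, `population_id`, `flank_left`,
#'   `flank_right`, `extrapolated`, `status`, `reason`.
#' @export
project_qtl <- function(qtl, ci_width, source_map, reference_map,
                        max_extrapolation = 10) {
  out <- tibble::tibble(
    qtl_id = qtl$qtl_id, trait = qtl$trait, chromosome = qtl$chromosome,
    ref_position = NA_real_, ci_width = NA_real_, sd = NA_real_,
    study_id = qtl$study_id, population_id = qtl$population_id,
    flank_left = NA_character_, flank_right = NA_character_,
    extrapolated = FALSE, status = "failed", reason = NA_character_)
  fail <- function(reason) { out$reason <- reason; out }

  res <- tryCatch({
    src <- map_chromosome(source_map, qtl$chromosome)
    ref <- map_chromosome(reference_map, qtl$chromosome)
    common <- src[src$marker %in% ref$marker, ]
    if (nrow(common) < 2) stop("unprojectable")
    ref_cm <- ref$cM[match(common$marker, ref$marker)]
    if (is.unsorted(ref_cm)) stop("order conflict")
    if (extrapolation_distance(qtl$position_cM, common$cM) > max_extrapolation) {
      stop("extrapolation beyond limit")
    }
    ref_len <- max(ref$cM)
    pts <- c(lower = qtl$position_cM - ci_width / 2,
             peak = qtl$position_cM,
             upper = qtl$position_cM + ci_width / 2)
    proj <- vapply(pts, function(p) {
      fl <- find_common_flanks(p, source_map, reference_map, qtl$chromosome)
      interpolate_position(p, fl)$ref
    }, numeric(1))
    proj <- pmin(pmax(proj, 0), ref_len)
    peak_flanks <- find_common_flanks(qtl$position_cM, source_map,
                                      reference_map, qtl$chromosome)
    out$ref_position <- unname(proj["peak"])
    out$ci_width <- max(unname(proj["upper"] - proj["lower"]), 0.1)
    out$sd <- out$ci_width / ci_z()
    out$flank_left <- peak_flanks$left
    out$flank_right <- peak_flanks$right
    out$extrapolated <- peak_flanks$extrapolated
    out$status <- "projected"
    out
  }, error = function(e) fail(conditionMessage(e)))
  res
}

#' Project a compendium of QTLs onto the reference map
#'
#' Applies [project_qtl()] to every row of a CI-annotated QTL table (see
#' [add_ci()]), looking up each QTL's source map by its `map_id`.
#'
#' @param qtls Tibble with columns required by [project_qtl()] plus `map_id`
#'   and `ci_width`.
#' @param maps Named list of source `genetic_map` objects.
#' @param reference_map The consensus reference `genetic_map`.
#' @param max_extrapolation Passed to [project_qtl()].
#' @return Tibble of projected QTLs, one row per input QTL, with a `status`
#'   column distinguishing `"projected"` from `"failed"` rows.
#' @export
project_qtls <- function(qtls, maps, reference_map, max_extrapolation = 10) {
  rows <- lapply(seq_len(nrow(qtls)), function(i) {
    q <- qtls[i, ]
    if (is.na(q$map_id) || !q$map_id %in% names(maps)) {
      r <- project_qtl(q, q$ci_width, reference_map, reference_map)
      r$status <- "failed"
      r$reason <- paste0("unknown map '", q$map_id, "'")
      r$ref_position <- NA_real_
      return(r)
    }
    project_qtl(q, q$ci_width, maps[[q$map_id]], reference_map,
                max_extrapolation = max_extrapolation)
  })
  dplyr::bind_rows(rows)
}

#' Substitute nearest reference markers for SNP-defined flanks
#'
#' For QTLs reported with physical (bp) flank positions from SNP-based maps,
#' returns for each flank the reference-map marker whose annotated bp position
#' is closest; equidistant ties resolve to the lower-bp marker.
#'
#' @param flank_bp Numeric vector of physical positions (bp).
#' @param chromosome Chromosome identifier.
#' @param reference_map A `genetic_map` whose chromosome has bp annotation for
#'   at least two markers.
#' @return Character vector of reference marker names, one per flank.
#' @export
substitute_snp_flanks <- function(flank_bp, chromosome, reference_map) {
  ref <- map_chromosome(reference_map, chromosome)
  ref <- ref[!is.na(ref$bp), ]
  if (nrow(ref) == 0) {
    stop("no bp-annotated markers on chromosome ", chromosome)
  }
  ref <- ref[order(ref$bp), ]
  vapply(flank_bp, function(b) {
    d <- abs(ref$bp - b)
    ref$marker[which.min(d)]  # which.min takes the first, i.e. lower-bp, tie
  }, character(1))
}
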