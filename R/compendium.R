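#' Read a QTL compendium table
#'
#' Reads a tab-separated compendium with one row per reported QTL and splits it
#' into validated QTL records and deduplicated study (population) records.
#' Rows that violate the data model are rejected, not silently carried: the
#' trait enumeration is closed (YLD, GW, HD, PH, TN) because downstream
#' clustering is stratified by trait.
#'
#' Expected columns (remappable through `col_map`): `qtl_id`, `study_id`,
#' `population_id`, `reference_tag`, `trait`, `chromosome`, `position_cM`,
#' `lod`, `r2`, `flank_left`, `flank_right`, `map_id`, `population_type`,
#' `population_size`. Empty strings are missing values. An `r2` given as a
#' percentage (value in (1, 100]) is divided by 100 with a warning, since
#' source tables mix conventions.
#'
#' @param path Path to a TSV file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(position_cM = "pos")`.
#' @return A list with elements `qtls` (tibble of accepted QTL records),
#'   `studies` (one row per population, deduplicated by `study_id`), and
#'   `rejected` (tibble with `row`, `qtl_id`, `reason`).
#' @seealso [validate_compendium()], [write_qtl_table()]
#' @export
read_qtl_table <- function(path, col_map = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  canonical <- c("qtl_id", "study_id", "population_id", "reference_tag",
                 "trait", "chromosome", "position_cM", "lod", "r2",
                 "flank_left", "flank_right", "map_id",
                 "population_type", "population_size")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (col_map[[nm]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[nm]]] <- nm
      }
    }
  }
  mandatory <- c("trait", "chromosome", "position_cM", "study_id",
                 "population_type", "population_size")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  for (nm in setdiff(canonical, names(raw))) raw[[nm]] <- NA_character_
  if (all(is.na(raw$qtl_id))) raw$qtl_id <- sprintf("QTL%04d", seq_len(nrow(raw)))

  pos <- suppressWarnings(as.numeric(raw$position_cM))
  chr <- suppressWarnings(as.integer(raw$chromosome))
  n_pop <- suppressWarnings(as.integer(raw$population_size))
  r2 <- suppressWarnings(as.numeric(raw$r2))
  pct <- !is.na(r2) & r2 > 1 & r2 <= 100
  if (any(pct)) {
    warning(sum(pct), " r2 value(s) > 1 interpreted as percentages and divided by 100")
    r2[pct] <- r2[pct] / 100
  }

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, msg) reason[is.na(reason) & bad] <<- msg
  flag(!(raw$trait %in% qtl_traits()), "unknown trait")
  flag(is.na(pos) | pos < 0, "non-numeric position")
  flag(is.na(chr) | chr < 1 | chr > 12, "chromosome outside 1-12")
  flag(!(raw$population_type %in% population_types()), "unknown population type")
  flag(is.na(n_pop) | n_pop < 1, "invalid population size")
  flag(!is.na(r2) & (r2 <= 0 | r2 > 1), "r2 outside (0, 1]")

  keep <- is.na(reason)
  qtls <- tibble::tibble(
    qtl_id = raw$qtl_id[keep],
    study_id = raw$study_id[keep],
    population_id = raw$population_id[keep],
    trait = raw$trait[keep],
    chromosome = chr[keep],
    position_cM = pos[keep],
    lod = suppressWarnings(as.numeric(raw$lod[keep])),
    r2 = r2[keep],
    flank_left = raw$flank_left[keep],
    flank_right = raw$flank_right[keep],
    map_id = raw$map_id[keep]
  )
  studies <- tibble::tibble(
    study_id = raw$study_id,
    population_id = raw$population_id,
    reference_tag = raw$reference_tag,
    population_type = raw$population_type,
    population_size = n_pop
  )[keep, ]
  studies <- dplyr::distinct(studies, .data$study_id, .keep_all = TRUE)
  rejected <- tibble::tibble(
    row = which(!keep),
    qtl_id = raw$qtl_id[!keep],
    reason = reason[!keep]
  )
  list(qtls = qtls, studies = studies, rejected = rejected)
}

#' Write a QTL compendium table
#'
#' Inverse of [read_qtl_table()]: serialises QTL and study records back to the
#' compendium TSV dialect, so that read -> write -> read is the identity.
#'
#' @param qtls,studies Tibbles as returned by [read_qtl_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qtl_table <- function(qtls, studies, path) {
  out <- dplyr::left_join(qtls, studies, by = "study_id",
                          suffix = c("", ".study"))
  if ("population_id.study" %in% names(out)) out$population_id.study <- NULL
  out <- out[, c("qtl_id", "study_id", "population_id", "reference_tag",
                 "trait", "chromosome", "position_cM", "lod", "r2",
                 "flank_left", "flank_right", "map_id",
                 "population_type", "population_size")]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' Reads a tab-separated linkage map with columns `chromosome`, `marker`, `cM`
#' and optionally `bp` (1-based physical position). Loci are ordered by cM
#' within each chromosome; markers sharing a cM position are allowed (dense
#' consensus maps co-locate markers) and keep their input order.
#'
#' @param path Path to the map TSV.
#' @param map_id Identifier stored as the `map_id` attribute; defaults to the
#'   file name without extension.
#' @return A tibble of class `genetic_map` with columns `chromosome`,
#'   `marker`, `cM` and `bp` (NA when absent).
#' @export
read_genetic_map <- function(path, map_id = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  need <- c("chromosome", "marker", "cM")
  if (!all(need %in% names(raw))) {
    stop("genetic map must have columns chromosome, marker, cM")
  }
  if (!"bp" %in% names(raw)) raw$bp <- NA_character_
  map <- tibble::tibble(
    chromosome = suppressWarnings(as.integer(raw$chromosome)),
    marker = raw$marker,
    cM = suppressWarnings(as.numeric(raw$cM)),
    bp = suppressWarnings(as.numeric(raw$bp))
  )
  bad <- is.na(map$chromosome) | is.na(map$cM)
  if (any(bad)) {
    warning(sum(bad), " map row(s) with missing chromosome or cM omitted")
    map <- map[!bad, ]
  }
  as_genetic_map(map, map_id = map_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a genetic map from a data frame
#'
#' Validates and orders marker loci built in code. Duplicate marker names are a
#' hard failure; equal-cM ties keep input order; bp order inconsistent with cM
#' order within a chromosome raises a warning.
#'
#' @param df Data frame with columns `chromosome`, `marker`, `cM` and
#'   optionally `bp`.
#' @param map_id Map identifier.
#' @return A `genetic_map` tibble.
#' @export
as_genetic_map <- function(df, map_id = "map") {
  df <- tibble::as_tibble(df)
  if (!"bp" %in% names(df)) df$bp <- NA_real_
  dup <- df$marker[duplicated(df$marker)]
  if (length(dup) > 0) {
    stop("duplicate marker name(s) in map '", map_id, "': ",
         paste(unique(dup), collapse = ", "))
  }
  ## stable sort keeps input order for co-locating markers
  df <- df[order(df$chromosome, df$cM), ]
  for (ch in unique(df$chromosome)) {
    sel <- df[df$chromosome == ch & !is.na(df$bp), ]
    if (nrow(sel) > 1 && is.unsorted(sel$bp)) {
      warning("bp order inconsistent with cM order on chromosome ", ch,
              " of map '", map_id, "'")
    }
  }
  structure(df, class = c("genetic_map", class(df)), map_id = map_id)
}

#' Write a genetic map to TSV
#'
#' @param map A `genetic_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map)[, c("chromosome", "marker", "cM", "bp")],
                   path, na = "", progress = FALSE)
  invisible(path)
}

map_chromosome <- function(map, chromosome) {
  sel <- map[map$chromosome == chromosome, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("chromosome ", chromosome, " absent from map '",
         attr(map, "map_id"), "'")
  }
  sel
}

chromosome_length <- function(map, chromosome) {
  max(map_chromosome(map, chromosome)$cM)
}

#' Validate a QTL compendium against its studies and maps
#'
#' Produces a report of inconsistencies before any analysis: QTLs referencing
#' unknown studies or maps, positions outside the span of their source
#' chromosome (errors), and cited flanking markers absent from the source map
#' (warnings; projection falls back to peak-based flanks).
#'
#' @param qtls,studies Tibbles from [read_qtl_table()].
#' @param maps Named list of `genetic_map` objects, keyed by `map_id`.
#' @return A tibble with columns `level` (`"error"`/`"warning"`), `qtl_id`
#'   and `issue`; zero rows when the compendium is fully consistent.
#' @export
validate_compendium <- function(qtls, studies, maps) {
  entries <- list()
  add <- function(level, qtl_id, issue) {
    entries[[length(entries) + 1]] <<- tibble::tibble(
      level = level, qtl_id = qtl_id, issue = issue)
  }
  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, ]
    if (!q$study_id %in% studies$study_id) {
      add("error", q$qtl_id, paste0("unknown study '", q$study_id, "'"))
    }
    if (is.na(q$map_id) || !q$map_id %in% names(maps)) {
      add("error", q$qtl_id, paste0("unknown map '", q$map_id, "'"))
      next
    }
    map <- maps[[q$map_id]]
    if (!q$chromosome %in% map$chromosome) {
      add("error", q$qtl_id,
          paste0("chromosome ", q$chromosome, " absent from map '", q$map_id, "'"))
      next
    }
    span <- chromosome_length(map, q$chromosome)
    if (q$position_cM > span) {
      add("error", q$qtl_id,
          sprintf("position out of span (%.2f cM > %.2f cM)", q$position_cM, span))
    }
    chrom_markers <- map_chromosome(map, q$chromosome)$marker
    for (fl in c(q$flank_left, q$flank_right)) {
      if (!is.na(fl) && !(fl %in% chrom_markers)) {
        add("warning", q$qtl_id,
            paste0("flanking marker '", fl, "' absent from source map"))
      }
    }
  }
  if (length(entries) == 0) {
    return(tibble::tibble(level = character(), qtl_id = character(),
                          issue = character()))
  }
  dplyr::bind_rows(entries)
}

#' Stop on compendium validation errors
#'
#' @param qtls,studies,maps As for [validate_compendium()].
#' @return The validation report, invisibly, if no error-level entries exist.
#' @export
assert_valid_compendium <- function(qtls, studies, maps) {
  report <- validate_compendium(qtls, studies, maps)
  if (any(report$level == "error")) {
    bad <- report[report$level == "error", ]
    stop("compendium has ", nrow(bad), " validation error(s); first: ",
         bad$qtl_id[1], ": ", bad$issue[1])
  }
  invisible(report)
}
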