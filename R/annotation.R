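#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 annotation and keeps features of type `"gene"` as a tibble
#' in 1-based closed coordinates (the GFF3 convention). Strand is ignored:
#' MQTL-to-gene assignment is purely positional.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `gene_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `annotation`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
  desc <- if (!is.null(gr$description)) gr$description
          else if (!is.null(gr$Name)) gr$Name else NA_character_
  tibble::tibble(
    gene_id = as.character(ids),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    annotation = as.character(desc))
}

#' Read a genomic feature track (BED)
#'
#' Imports a BED track (selective sweeps, GWAS SNPs, functional variants...).
#' BED is 0-based half-open on disk; the import converts to the package's
#' 1-based closed convention. Point features (SNPs) come out with
#' `start_bp == end_bp`.
#'
#' @param path Path to a BED file.
#' @param track_name Label stored in the `track` column; defaults to the file
#'   name.
#' @return Tibble with `track`, `feature_id`, `chromosome`, `start_bp`,
#'   `end_bp`.
#' @export
read_feature_track <- function(path, track_name = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  ids <- if (!is.null(gr$name)) as.character(gr$name)
         else sprintf("feature%04d", seq_along(gr))
  tibble::tibble(
    track = track_name %||% sub("\\.[^.]*$", "", basename(path)),
    feature_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr))
}

#' Anchor MQTLs to physical genome coordinates
#'
#' Converts each MQTL's CI flanking markers to base pairs using the reference
#' map's bp annotation. A flank marker lacking bp is replaced by the nearest
#' bp-annotated marker in cM on the same chromosome. The interval spans the
#' two flank bp positions (ordered), 1-based closed.
#'
#' @param mqtls Tibble from [detect_mqtls()] (needs `mqtl_id`, `chromosome`,
#'   `flank_left`, `flank_right`).
#' @param reference_map `genetic_map` with bp positions.
#' @return `mqtls` with added `start_bp` and `end_bp` columns.
#' @export
anchor_to_genome <- function(mqtls, reference_map) {
  flank_bp <- function(marker, chromosome) {
    ref <- map_chromosome(reference_map, chromosome)
    with_bp <- ref[!is.na(ref$bp), ]
    if (nrow(with_bp) == 0) {
      stop("no bp-annotated markers on chromosome ", chromosome)
    }
    idx <- match(marker, ref$marker)
    if (is.na(idx)) stop("marker '", marker, "' absent from reference map")
    if (!is.na(ref$bp[idx])) return(ref$bp[idx])
    with_bp$bp[which.min(abs(with_bp$cM - ref$cM[idx]))]
  }
  bounds <- t(mapply(function(l, r, ch) {
    b <- c(flank_bp(l, ch), flank_bp(r, ch))
    c(min(b), max(b))
  }, mqtls$flank_left, mqtls$flank_right, mqtls$chromosome,
  USE.NAMES = FALSE))
  mqtls$start_bp <- unname(bounds[, 1])
  mqtls$end_bp <- unname(bounds[, 2])
  mqtls
}

## overlap of 1-based closed intervals, via IRanges
overlap_hits <- function(q_start, q_end, s_start, s_end) {
  q <- IRanges::IRanges(start = q_start, end = q_end)
  s <- IRanges::IRanges(start = s_start, end = s_end)
  hits <- IRanges::findOverlaps(q, s)
  tibble::tibble(query = S4Vectors::queryHits(hits),
                 subject = S4Vectors::subjectHits(hits))
}

#' Genes overlapping a genomic interval
#'
#' Returns the genes sharing at least one base pair with a 1-based closed
#' interval (partial overlap counts, abutting at a single shared base counts),
#' sorted by start position.
#'
#' @param interval List or one-row data frame with `chromosome`, `start_bp`,
#'   `end_bp`.
#' @param genes Tibble from [read_gene_annotation()].
#' @return Tibble of overlapping genes.
#' @export
genes_in_interval <- function(interval, genes) {
  g <- genes[as.character(genes$chromosome) == as.character(interval$chromosome), ]
  if (nrow(g) == 0) return(g)
  hits <- overlap_hits(interval$start_bp, interval$end_bp, g$start_bp, g$end_bp)
  out <- g[hits$subject, ]
  out[order(out$start_bp), ]
}

#' Count genes in each anchored MQTL interval
#'
#' @param mqtls Tibble with `mqtl_id`, `chromosome`, `start_bp`, `end_bp`.
#' @param genes Tibble from [read_gene_annotation()].
#' @return `mqtls` with an added `n_genes` column.
#' @export
count_genes <- function(mqtls, genes) {
  mqtls$n_genes <- vapply(seq_len(nrow(mqtls)), function(i) {
    nrow(genes_in_interval(mqtls[i, ], genes))
  }, integer(1))
  mqtls
}

#' Co-locate MQTLs with a feature track
#'
#' An MQTL co-locates with a feature when their 1-based closed intervals share
#' at least one base pair; a point feature (SNP) inside the MQTL interval
#' counts.
#'
#' @param mqtls Anchored MQTL tibble (`mqtl_id`, `chromosome`, `start_bp`,
#'   `end_bp`).
#' @param track Tibble from [read_feature_track()].
#' @return Tibble with one row per (MQTL, feature) overlap: `mqtl_id`,
#'   `track`, `feature_id`, feature coordinates.
#' @export
colocate_features <- function(mqtls, track) {
  rows <- list()
  for (ch in unique(mqtls$chromosome)) {
    m <- mqtls[mqtls$chromosome == ch, ]
    f <- track[as.character(track$chromosome) == as.character(ch), ]
    if (nrow(f) == 0) next
    hits <- overlap_hits(m$start_bp, m$end_bp, f$start_bp, f$end_bp)
    if (nrow(hits) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      mqtl_id = m$mqtl_id[hits$query],
      track = f$track[hits$subject],
      feature_id = f$feature_id[hits$subject],
      chromosome = ch,
      feature_start_bp = f$start_bp[hits$subject],
      feature_end_bp = f$end_bp[hits$subject])
  }
  if (length(rows) == 0) {
    return(tibble::tibble(mqtl_id = character(), track = character(),
                          feature_id = character(), chromosome = character(),
                          feature_start_bp = double(), feature_end_bp = double()))
  }
  dplyr::bind_rows(rows)
}
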