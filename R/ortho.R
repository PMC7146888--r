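#' Read a two-column ortholog pair table
#'
#' @param path TSV with columns `gene_a` and `gene_b` (or two unnamed
#'   columns).
#' @return Tibble with `gene_a`, `gene_b`.
#' @export
read_ortholog_pairs <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(raw))) {
    names(raw)[1:2] <- c("gene_a", "gene_b")
  }
  out <- tibble::tibble(gene_a = raw$gene_a, gene_b = raw$gene_b)
  if (any(is.na(out$gene_a) | is.na(out$gene_b) |
            out$gene_a == "" | out$gene_b == "")) {
    stop("ortholog pairs must have non-empty gene ids on both sides")
  }
  out
}

## gene -> MQTL interval membership (>= 1 bp overlap), per species
genes_to_mqtls <- function(mqtls, genes) {
  rows <- list()
  for (ch in unique(mqtls$chromosome)) {
    m <- mqtls[mqtls$chromosome == ch, ]
    g <- genes[as.character(genes$chromosome) == as.character(ch), ]
    if (nrow(g) == 0) next
    hits <- overlap_hits(m$start_bp, m$end_bp, g$start_bp, g$end_bp)
    if (nrow(hits) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      mqtl_id = m$mqtl_id[hits$query], gene_id = g$gene_id[hits$subject])
  }
  if (length(rows) == 0) {
    return(tibble::tibble(mqtl_id = character(), gene_id = character()))
  }
  dplyr::bind_rows(rows)
}

#' Detect ortho-MQTLs between two species
#'
#' An ortho-MQTL is a pair of same-trait MQTLs, one per species, whose
#' anchored genomic intervals are linked by at least `min_links` orthologous
#' gene pairs (gene_a inside the species-A interval, gene_b inside the
#' species-B interval). Only well-supported species-A MQTLs, those with
#' `n_studies >= min_studies`, are considered; one MQTL may participate in
#' several ortho-MQTLs (no 1-to-1 forcing).
#'
#' @param mqtls_a,mqtls_b Anchored MQTL tibbles (columns `mqtl_id`, `trait`,
#'   `chromosome`, `start_bp`, `end_bp`; `mqtls_a` additionally `n_studies`).
#' @param orthologs Tibble with `gene_a` (species A ids), `gene_b`
#'   (species B ids).
#' @param genes_a,genes_b Gene coordinate tibbles per species
#'   (`gene_id`, `chromosome`, `start_bp`, `end_bp`).
#' @param min_studies Minimum study support on the species-A side.
#' @param min_links Minimum number of linking ortholog pairs.
#' @param trait_map Optional named character vector translating species-A
#'   trait codes to species-B codes; default is the identity.
#' @return Tibble with one row per ortho-MQTL: `mqtl_a`, `mqtl_b`, `trait`,
#'   `n_links`, `linking_pairs` (semicolon-joined `gene_a:gene_b`).
#' @export
find_ortho_mqtls <- function(mqtls_a, mqtls_b, orthologs, genes_a, genes_b,
                             min_studies = 3, min_links = 1,
                             trait_map = NULL) {
  stopifnot(min_links >= 1)
  a <- mqtls_a[mqtls_a$n_studies >= min_studies, ]
  empty <- tibble::tibble(mqtl_a = character(), mqtl_b = character(),
                          trait = character(), n_links = integer(),
                          linking_pairs = character())
  if (nrow(a) == 0 || nrow(mqtls_b) == 0 || nrow(orthologs) == 0) return(empty)

  map_a <- genes_to_mqtls(a, genes_a)
  map_b <- genes_to_mqtls(mqtls_b, genes_b)
  if (nrow(map_a) == 0 || nrow(map_b) == 0) return(empty)

  links <- dplyr::inner_join(orthologs, map_a, by = c(gene_a = "gene_id"))
  names(links)[names(links) == "mqtl_id"] <- "mqtl_a"
  links <- dplyr::inner_join(links, map_b, by = c(gene_b = "gene_id"))
  names(links)[names(links) == "mqtl_id"] <- "mqtl_b"
  if (nrow(links) == 0) return(empty)

  trait_a <- a$trait[match(links$mqtl_a, a$mqtl_id)]
  trait_b <- mqtls_b$trait[match(links$mqtl_b, mqtls_b$mqtl_id)]
  if (!is.null(trait_map)) {
    mapped <- unname(trait_map[trait_a])
    trait_a <- ifelse(is.na(mapped), trait_a, mapped)
  }
  links <- links[trait_a == trait_b, ]
  links$trait <- trait_a[trait_a == trait_b]
  if (nrow(links) == 0) return(empty)

  links$pair <- paste0(links$gene_a, ":", links$gene_b)
  out <- dplyr::summarise(
    dplyr::group_by(links, .data$mqtl_a, .data$mqtl_b, .data$trait),
    n_links = dplyr::n(),
    linking_pairs = paste(sort(.data$pair), collapse = ";"),
    .groups = "drop")
  out <- out[out$n_links >= min_links, ]
  out[order(out$mqtl_a, out$mqtl_b), ]
}
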