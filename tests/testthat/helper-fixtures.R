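# In-code fixtures shared across the suite: tiny genetic maps, a compendium
# TSV writer, and the exhaustive hard-assignment oracle used to cross-check
# the EM clustering.

make_map <- function(markers, cM, chromosome = 1, bp = NA_real_, map_id = "m") {
  as_genetic_map(
    tibble::tibble(chromosome = chromosome, marker = markers, cM = cM, bp = bp),
    map_id = map_id)
}

# reference map used by several projection tests: one chromosome, 0-100 cM
ref_map_10 <- function() {
  make_map(sprintf("MK%02d", 1:11), seq(0, 100, by = 10),
           bp = seq(0, 100, by = 10) * 2.5e5 + 1, map_id = "ref")
}

write_compendium_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("qtl_id", "study_id", "population_id", "reference_tag",
                    "trait", "chromosome", "position_cM", "lod", "r2",
                    "flank_left", "flank_right", "map_id",
                    "population_type", "population_size"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

# a well-formed 3-row compendium on the ref_map_10() map
compendium_rows_ok <- c(
  "q1\ts1\tp1\tref1\tGW\t1\t15\t4.2\t0.12\tMK02\tMK03\tref\tF2\t200",
  "q2\ts2\tp2\tref2\tGW\t1\t18\t\t0.20\t\t\tref\tRIL\t150",
  "q3\ts2\tp2\tref2\tHD\t1\t55\t3.1\t\tMK06\tMK07\tref\tRIL\t150")

# classification log-likelihood of one hard partition: component means are
# inverse-variance weighted member means, weights are occupancy fractions
lc_of_partition <- function(x, sd, z) {
  ks <- sort(unique(z))
  mu <- vapply(ks, function(k) {
    i <- z == k
    sum(x[i] / sd[i]^2) / sum(1 / sd[i]^2)
  }, numeric(1))
  w <- vapply(ks, function(k) mean(z == k), numeric(1))
  idx <- match(z, ks)
  sum(log(w[idx]) + dnorm(x, mu[idx], sd, log = TRUE))
}

# exhaustive oracle: best classification log-likelihood over all hard
# assignments of n observations to K non-empty components (n small)
oracle_best_lc <- function(x, sd, K) {
  n <- length(x)
  stopifnot(K^n <= 1e6)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf
  for (i in seq_len(nrow(grid))) {
    z <- grid[i, ]
    if (length(unique(z)) < K) next
    best <- max(best, lc_of_partition(x, sd, z))
  }
  best
}

# tiny GFF3 gene annotation written to disk (1-based closed coordinates)
write_gff3 <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chromosome, genes$start_bp, genes$end_bp,
                     genes$gene_id))
  writeLines(lines, path)
  path
}

# BED track on disk (0-based half-open); point features get end = start + 1
write_bed <- function(features, path = tempfile(fileext = ".bed")) {
  lines <- sprintf("%s\t%d\t%d\t%s", features$chromosome,
                   features$start_bp - 1L, features$end_bp, features$feature_id)
  writeLines(lines, path)
  path
}
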