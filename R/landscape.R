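#' A significance stratum on the -log10(p) axis
#'
#' A half-open interval `[lo, hi)` of -log10(p) values selecting a
#' "sectional view" of the landscape: adjacent strata partition the axis
#' exactly, and `hi = Inf` keeps the top of the landscape. The published
#' sectional view "-log10(p) > 100" corresponds to `stratum(100)`.
#'
#' @param lo Lower bound (inclusive), non-negative.
#' @param hi Upper bound (exclusive), may be `Inf`.
#' @return A `stratum` object.
#' @export
stratum <- function(lo = 0, hi = Inf) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || is.na(lo) || is.na(hi))
    stop("stratum: 'lo' and 'hi' must be single numbers", call. = FALSE)
  if (lo < 0) stop("stratum: 'lo' must be >= 0", call. = FALSE)
  if (lo >= hi) stop("stratum: need lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "stratum")
}

#' @export
print.stratum <- function(x, ...) {
  cat("<stratum> [", x$lo, ", ", x$hi, ")\n", sep = "")
  invisible(x)
}

#' Restrict a landscape table to a significance stratum
#'
#' Keeps the records with `lo <= neglog10p < hi`. Disjoint strata
#' covering the axis therefore partition the table.
#'
#' @param table A `landscape_table`.
#' @param strat A [stratum()].
#' @return A `landscape_table` subset (phenotype axis preserved).
#' @export
sectional_filter <- function(table, strat) {
  stopifnot(inherits(strat, "stratum"))
  keep <- table$neglog10p >= strat$lo & table$neglog10p < strat$hi
  out <- table[keep]
  data.table::setattr(out, "phenotypes", phenotypes(table))
  data.table::setattr(out, "meta", attr(table, "meta"))
  if (!inherits(out, "landscape_table"))
    data.table::setattr(out, "class", c("landscape_table", class(out)))
  out[]
}

# deterministic peak pick within groups: max neglog10p, ties -> smaller
# pos, then lexicographically smaller snp_id
peak_order <- function(dt) {
  data.table::setorderv(dt, c("neglog10p", "pos", "snp_id"),
                        order = c(-1L, 1L, 1L))
  dt
}

#' Entire-genome peaks: the per-chromosome maximum for each phenotype
#'
#' For the whole-genome view only the maximum -log10(p) per chromosome
#' and phenotype (within the selected stratum) is plotted; no minimum
#' significance floor is applied at this level. Ties are broken by
#' smaller position, then lexicographically smaller SNP id, so outputs
#' are deterministic.
#'
#' @param table A `landscape_table`.
#' @param strat A [stratum()]; default keeps everything.
#' @return A data.table with one row per (chrom, phenotype) having at
#'   least one in-stratum record, carrying the full peak record.
#' @export
genome_peaks <- function(table, strat = stratum()) {
  if (nrow(table) == 0L)
    stop("genome_peaks: empty landscape table", call. = FALSE)
  sub <- sectional_filter(table, strat)
  if (nrow(sub) == 0L)
    return(structure(sub[0L],
                     phenotypes = phenotypes(table), view = "genome"))
  sub <- peak_order(data.table::as.data.table(sub))
  out <- sub[!duplicated(sub, by = c("chrom", "phenotype"))]
  data.table::setorderv(out, c("chrom", "pos"))
  data.table::setattr(out, "phenotypes", phenotypes(table))
  data.table::setattr(out, "view", "genome")
  out[]
}

#' Single-chromosome per-segment peak grid
#'
#' Builds the surface plotted in the single-chromosome view: for every
#' (segment, phenotype) cell the in-stratum record with maximal
#' -log10(p), with a segment retained only if at least one phenotype
#' peaks above `threshold_min` there (strict `>`, default 6). Cells of a
#' retained segment are kept even when below the floor -- the floor
#' governs segment retention only, so the highest peak per phenotype is
#' always shown inside a retained segment.
#'
#' @param table A `landscape_table`.
#' @param chrom Chromosome 1-22.
#' @param scheme A `segment_scheme` (default 1 Mb fixed bins).
#' @param strat A [stratum()].
#' @param threshold_min Minimum significant threshold for segment
#'   retention, on the -log10(p) scale (default 6).
#' @return A `bin_peak_grid`: list with `chrom`, `scheme`, `stratum`,
#'   `threshold_min`, `cells` (data.table of peak records with a
#'   `segment` column), `segments` (retained ids in genomic order),
#'   `phenotypes`, and `n_gap` (records skipped for falling in
#'   blocks-mode gaps).
#' @export
chromosome_peaks <- function(table, chrom, scheme = fixed_bins(),
                             strat = stratum(), threshold_min = 6) {
  chrom <- as.integer(chrom)
  if (is.na(chrom) || chrom < 1L || chrom > 22L)
    stop("chromosome_peaks: 'chrom' must be in 1..22", call. = FALSE)
  sub <- data.table::as.data.table(sectional_filter(table, strat))
  keep <- sub$chrom == chrom  # precomputed: 'chrom' is also a column name
  sub <- sub[keep]
  sub$segment <- assign_segment(scheme, sub$chrom, sub$pos)
  n_gap <- sum(is.na(sub$segment))
  sub <- sub[!is.na(sub$segment)]
  if (nrow(sub) > 0L) {
    sub <- peak_order(sub)
    cells <- sub[!duplicated(sub, by = c("segment", "phenotype"))]
    seg_max <- cells[, list(mx = max(neglog10p)), by = "segment"]
    retained <- sort(seg_max$segment[seg_max$mx > threshold_min])
    cells <- cells[cells$segment %in% retained]
    data.table::setorderv(cells, c("segment", "phenotype"))
  } else {
    cells <- sub
    retained <- integer(0)
  }
  data.table::setattr(cells, "phenotypes", NULL)
  data.table::setattr(cells, "meta", NULL)
  if (length(retained) == 0L)
    message("chromosome_peaks: no segment on chromosome ", chrom,
            " exceeds threshold ", threshold_min, " in the stratum")
  structure(list(chrom = chrom, scheme = scheme, stratum = strat,
                 threshold_min = threshold_min, cells = cells,
                 segments = as.integer(retained),
                 phenotypes = phenotypes(table), n_gap = n_gap),
            class = "bin_peak_grid")
}

#' Retained segment ids of a peak grid, in genomic order
#' @param grid A `bin_peak_grid`.
#' @return Integer vector (possibly empty).
#' @export
retained_segments <- function(grid) {
  stopifnot(inherits(grid, "bin_peak_grid"))
  grid$segments
}

#' @export
print.bin_peak_grid <- function(x, ...) {
  cat("<bin_peak_grid> chr", x$chrom, ": ", length(x$segments),
      " retained segment(s) x ", length(x$phenotypes), " phenotype(s), ",
      nrow(x$cells), " non-empty cell(s); threshold_min=", x$threshold_min,
      ", stratum [", x$stratum$lo, ",", x$stratum$hi, ")\n", sep = "")
  invisible(x)
}

#' Export a peak grid as TSV
#' @param grid A `bin_peak_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "bin_peak_grid"))
  cols <- c("segment", "phenotype", "snp_id", "chrom", "pos", "neglog10p",
            "effect")
  data.table::fwrite(grid$cells[, cols, with = FALSE], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}
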