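#' Select a genomic region for export
#'
#' A region is either one segment of a segmentation scheme or an
#' explicit 1-based closed base-pair range on a chromosome.
#'
#' @param chrom Chromosome 1-22.
#' @param segment Segment id (requires `scheme`).
#' @param scheme A `segment_scheme` resolving the segment id.
#' @param start,end Explicit range bounds (1-based closed), used when
#'   `segment` is `NULL`.
#' @return A `region_selection` with resolved `start`/`end`.
#' @export
region_selection <- function(chrom, segment = NULL, scheme = fixed_bins(),
                             start = NULL, end = NULL) {
  chrom <- as.integer(chrom)
  if (is.na(chrom) || chrom < 1L || chrom > 22L)
    stop("region_selection: 'chrom' must be in 1..22", call. = FALSE)
  if (!is.null(segment)) {
    b <- segment_bounds(scheme, chrom, segment)
    start <- b$start[1L]
    end <- b$end[1L]
  }
  if (is.null(start) || is.null(end))
    stop("region_selection: give either 'segment' or 'start'/'end'",
         call. = FALSE)
  if (start > end)
    stop("region_selection: need start <= end", call. = FALSE)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), segment = segment),
            class = "region_selection")
}

#' Export regional summary statistics for colocalization follow-up
#'
#' Writes the summary statistics of a selected region across all
#' phenotypes as one wide-format TSV: one row per SNP present in at
#' least one phenotype, columns `snp_id, chrom, pos, allele1, allele2`,
#' then per-phenotype triplets `<ph>.beta, <ph>.se, <ph>.neglog10p`.
#' Multi-trait colocalization tools consume aligned per-trait
#' effect/se vectors, which this layout provides directly; SNPs missing
#' in some phenotype are kept with blank cells and the consumer decides
#' on complete-case filtering. The layout is documented in `#`-prefixed
#' header lines of the file.
#'
#' @param table A `landscape_table`.
#' @param sel A [region_selection()].
#' @param path Output TSV path.
#' @return Invisibly, a named integer vector of per-phenotype record
#'   counts inside the region.
#' @export
export_region <- function(table, sel, path) {
  stopifnot(inherits(sel, "region_selection"))
  ph <- phenotypes(table)
  sub <- data.table::as.data.table(table)
  sub <- sub[sub$chrom == sel$chrom & sub$pos >= sel$start &
               sub$pos <= sel$end]
  if (nrow(sub) == 0L)
    stop("export_region: no records in selection chr", sel$chrom, ":",
         format(sel$start, scientific = FALSE), "-",
         format(sel$end, scientific = FALSE), call. = FALSE)
  counts <- vapply(ph, function(p) sum(sub$phenotype == p), 0L)
  key <- unique(sub[, c("snp_id", "chrom", "pos", "allele1", "allele2"),
                    with = FALSE], by = c("snp_id", "chrom", "pos"))
  data.table::setorderv(key, c("pos", "snp_id"))
  wide <- key
  for (p in ph) {
    sp <- sub[sub$phenotype == p]
    m <- match(paste(key$snp_id, key$pos), paste(sp$snp_id, sp$pos))
    wide[[paste0(p, ".beta")]] <- sp$effect[m]
    wide[[paste0(p, ".se")]] <- sp$se[m]
    wide[[paste0(p, ".neglog10p")]] <- sp$neglog10p[m]
  }
  hdr <- c(
    paste0("# regional summary statistics, chr", sel$chrom, ":",
           format(sel$start, scientific = FALSE), "-",
           format(sel$end, scientific = FALSE),
           if (!is.null(sel$segment)) paste0(" (segment ", sel$segment, ")")),
    "# one row per SNP present in >= 1 phenotype; per-phenotype columns",
    "# <phenotype>.beta, <phenotype>.se, <phenotype>.neglog10p; blank =",
    "# SNP absent from that phenotype's summary file (no imputation)")
  writeLines(hdr, path)
  suppressWarnings(
    data.table::fwrite(wide, path, sep = "\t", quote = FALSE, na = "",
                       append = TRUE, col.names = TRUE))
  invisible(counts)
}

#' Re-import an exported region in long format
#'
#' Reads a file written by [export_region()] back into a long-format
#' data.table; no values are lost in the round trip.
#'
#' @param path Path to an exported region TSV.
#' @return data.table with columns `phenotype, snp_id, chrom, pos,
#'   allele1, allele2, effect, se, neglog10p`.
#' @export
read_region <- function(path) {
  wide <- data.table::fread(path, sep = "\t", header = TRUE, skip = "snp_id",
                            na.strings = "", showProgress = FALSE)
  trip <- grep("\\.neglog10p$", names(wide), value = TRUE)
  ph <- sub("\\.neglog10p$", "", trip)
  out <- lapply(ph, function(p) {
    dt <- wide[, c("snp_id", "chrom", "pos", "allele1", "allele2"),
               with = FALSE]
    dt$phenotype <- p
    dt$effect <- wide[[paste0(p, ".beta")]]
    dt$se <- wide[[paste0(p, ".se")]]
    dt$neglog10p <- wide[[paste0(p, ".neglog10p")]]
    dt[!is.na(dt$neglog10p)]
  })
  data.table::rbindlist(out)
}
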