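#' Load gene intervals for SNP-to-gene mapping
#'
#' Reads a 4-column gene interval file (BED: chrom, start, end, symbol;
#' 0-based half-open) and builds a per-chromosome interval index for
#' windowed point queries. Coordinates are converted to the internal
#' 1-based closed convention; non-autosomal entries are skipped with a
#' count; identical duplicate lines are collapsed. Overlapping gene
#' intervals are legitimate and all hits are reported by queries.
#'
#' @param path Path to a 4+ column BED/TSV file.
#' @return A `gene_interval_map`: list with `genes` (data.table chrom,
#'   start, end, symbol) and `n_skipped`.
#' @export
load_gene_intervals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("load_gene_intervals: empty file '", path, "'", call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  short <- vapply(fields, length, 0L) < 4L
  if (any(short))
    stop("load_gene_intervals: line ", which(short)[1L],
         " lacks a symbol column (need chrom, start, end, symbol)",
         call. = FALSE)
  chrom <- normalize_chrom(vapply(fields, `[[`, "", 1L))
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  symbol <- vapply(fields, `[[`, "", 4L)
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0
  if (any(bad))
    stop("load_gene_intervals: malformed coordinates on line ",
         which(bad)[1L], call. = FALSE)
  keep <- !is.na(chrom)
  n_skipped <- sum(!keep)
  genes <- data.table::data.table(chrom = chrom[keep],
                                  start = start0[keep] + 1,  # BED -> 1-based
                                  end = end0[keep],
                                  symbol = symbol[keep])
  genes <- unique(genes)
  if (nrow(genes) == 0L)
    stop("load_gene_intervals: no autosomal gene intervals in '", path, "'",
         call. = FALSE)
  data.table::setorderv(genes, c("chrom", "start", "end", "symbol"))
  structure(list(genes = genes, n_skipped = n_skipped),
            class = "gene_interval_map")
}

#' @export
print.gene_interval_map <- function(x, ...) {
  cat("<gene_interval_map> ", nrow(x$genes), " interval(s) on ",
      length(unique(x$genes$chrom)), " chromosome(s); ", x$n_skipped,
      " non-autosomal line(s) skipped\n", sep = "")
  invisible(x)
}

#' Map a SNP position to gene symbols within a window
#'
#' Returns every gene whose interval, expanded by `window_bp` on both
#' sides, contains the query position. The default 100 kb window matches
#' common practice for assigning intergenic association signals to
#' nearby genes. Results are ordered by distance from the position to
#' the *unexpanded* interval (0 inside the gene), ties alphabetical.
#'
#' @param map A `gene_interval_map`.
#' @param chrom Chromosome.
#' @param pos 1-based position.
#' @param window_bp Window in bp added to both interval ends
#'   (default 100,000).
#' @return Character vector of gene symbols (possibly empty).
#' @export
map_snp_to_genes <- function(map, chrom, pos, window_bp = 100000) {
  stopifnot(inherits(map, "gene_interval_map"))
  if (window_bp < 0)
    stop("map_snp_to_genes: 'window_bp' must be >= 0", call. = FALSE)
  keep <- map$genes$chrom == as.integer(chrom)
  g <- map$genes[keep]
  if (nrow(g) == 0L) return(character(0))
  q <- IRanges::IRanges(start = as.integer(pos), width = 1L)
  subj <- IRanges::IRanges(start = pmax(1, g$start - window_bp),
                           end = g$end + window_bp)
  hits <- IRanges::findOverlaps(q, subj)
  idx <- S4Vectors::subjectHits(hits)
  if (length(idx) == 0L) return(character(0))
  dist <- pmax(0, pmax(g$start[idx] - pos, pos - g$end[idx]))
  g$symbol[idx][order(dist, g$symbol[idx])]
}

#' Gene-view heatmap matrix: genes shared across phenotypes
#'
#' The graded -log10(p) heatmap can visually conceal a significant
#' association sitting next to a much stronger one, because the colour
#' scale is dominated by the top peak. The gene view counters this with
#' a binary matrix: rows are genes found in a group of segments, columns
#' are phenotypes, and a cell is 1 when that phenotype has at least one
#' SNP above `threshold` mapping to the gene (within `window_bp`) --
#' rendered with uniform brightness regardless of how far above the
#' threshold the signal is.
#'
#' @param table A `landscape_table`.
#' @param chrom Chromosome.
#' @param segments Integer vector of segment ids forming the group.
#' @param scheme A `segment_scheme` resolving the ids.
#' @param map A `gene_interval_map`.
#' @param threshold -log10(p) floor for a SNP to light a cell
#'   (default 6).
#' @param window_bp SNP-to-gene window (default 100,000).
#' @return Binary integer matrix, rows = gene symbols ordered by genomic
#'   position, columns = phenotypes in z-axis order. Zero rows when
#'   nothing qualifies.
#' @export
gene_view_matrix <- function(table, chrom, segments, scheme = fixed_bins(),
                             map, threshold = 6, window_bp = 100000) {
  if (length(segments) == 0L)
    stop("gene_view_matrix: 'segments' must be non-empty", call. = FALSE)
  ph <- phenotypes(table)
  sub <- data.table::as.data.table(table)
  keep <- sub$chrom == as.integer(chrom) & sub$neglog10p > threshold
  sub <- sub[keep]
  if (nrow(sub) > 0L) {
    sub$segment <- assign_segment(scheme, sub$chrom, sub$pos)
    sub <- sub[!is.na(sub$segment) & sub$segment %in% as.integer(segments)]
  }
  empty <- matrix(integer(0), nrow = 0L, ncol = length(ph),
                  dimnames = list(character(0), ph))
  if (nrow(sub) == 0L) return(empty)
  hits <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    gs <- map_snp_to_genes(map, sub$chrom[i], sub$pos[i], window_bp)
    if (length(gs))
      hits[[i]] <- data.table::data.table(symbol = gs,
                                          phenotype = sub$phenotype[i])
  }
  hits <- data.table::rbindlist(hits[!vapply(hits, is.null, TRUE)])
  if (nrow(hits) == 0L) return(empty)
  hits <- unique(hits)
  keep_g <- map$genes$chrom == as.integer(chrom)
  g <- map$genes[keep_g]
  syms <- unique(g$symbol[g$symbol %in% hits$symbol])  # genomic order
  m <- matrix(0L, nrow = length(syms), ncol = length(ph),
              dimnames = list(syms, ph))
  m[cbind(match(hits$symbol, syms), match(hits$phenotype, ph))] <- 1L
  m
}
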