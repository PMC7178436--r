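#' Fixed-width chromosome segmentation
#'
#' Partitions every chromosome into equal base-pair interval segments.
#' Segment `k` (0-based) covers 1-based positions
#' `[k * width + 1, (k + 1) * width]`, so with the default 1 Mb width
#' "region 45" is the interval 45,000,001-46,000,000 bp.
#'
#' @param width_bp Segment width in base pairs (default 1,000,000).
#' @return A `segment_scheme` in `"fixed"` mode.
#' @export
#' @examples
#' sc <- fixed_bins()
#' assign_segment(sc, chrom = 19, pos = 45411941) # 45
fixed_bins <- function(width_bp = 1000000L) {
  if (!is.numeric(width_bp) || length(width_bp) != 1L || is.na(width_bp) ||
      width_bp < 1 || width_bp != floor(width_bp))
    stop("fixed_bins: 'width_bp' must be a positive integer", call. = FALSE)
  structure(list(mode = "fixed", width = as.numeric(width_bp)),
            class = "segment_scheme")
}

#' LD-block chromosome segmentation from a BED file
#'
#' Reads an LD-block definition file (standard BED: chrom, start, end;
#' 0-based half-open) and builds a blocks-mode segmentation. BED
#' coordinates are converted here -- and only here -- to the package's
#' internal 1-based closed convention. Blocks on one chromosome must not
#' overlap; gaps between blocks are allowed (positions falling in a gap
#' are excluded from binned views and counted by callers).
#'
#' @param path Path to a BED file with at least 3 columns.
#' @return A `segment_scheme` in `"blocks"` mode; segment ids are the
#'   0-based index of the block within its chromosome (genomic order).
#' @export
blocks_from_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("blocks_from_bed: no usable blocks in '", path, "'", call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_skipped <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("blocks_from_bed: malformed line ", i, " (need >= 3 columns)",
           call. = FALSE)
    chrom <- normalize_chrom(f[1L])
    start0 <- suppressWarnings(as.numeric(f[2L]))
    end0 <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start0) || is.na(end0) || start0 < 0 || end0 <= start0)
      stop("blocks_from_bed: malformed coordinates on line ", i, call. = FALSE)
    if (is.na(chrom)) { n_skipped <- n_skipped + 1L; next }
    # BED half-open [start, end) -> 1-based closed [start + 1, end]
    rows[[i]] <- data.table::data.table(chrom = chrom, start = start0 + 1,
                                        end = end0)
  }
  if (n_skipped > 0L)
    warning("blocks_from_bed: skipped ", n_skipped,
            " non-autosomal line(s)", call. = FALSE)
  blocks <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(blocks) == 0L)
    stop("blocks_from_bed: no usable blocks in '", path, "'", call. = FALSE)
  blocks <- unique(blocks)
  data.table::setorderv(blocks, c("chrom", "start", "end"))
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch]
    if (nrow(b) > 1L) {
      ov <- which(b$start[-1L] <= b$end[-nrow(b)])
      if (length(ov))
        stop("blocks_from_bed: overlapping blocks on chromosome ", ch, ": [",
             b$start[ov[1L]], ",", b$end[ov[1L]], "] and [",
             b$start[ov[1L] + 1L], ",", b$end[ov[1L] + 1L],
             "] (1-based)", call. = FALSE)
    }
  }
  blocks[, `:=`(segment = seq_len(.N) - 1L), by = "chrom"]
  structure(list(mode = "blocks", blocks = blocks[]),
            class = "segment_scheme")
}

#' @export
print.segment_scheme <- function(x, ...) {
  if (x$mode == "fixed")
    cat("<segment_scheme> fixed width ", format(x$width, big.mark = ","),
        " bp\n", sep = "")
  else
    cat("<segment_scheme> ", nrow(x$blocks), " LD blocks on ",
        length(unique(x$blocks$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Assign positions to segments
#'
#' Vectorized over `chrom`/`pos`. In fixed mode the segment id is
#' `floor((pos - 1) / width)`, a total monotone step function of
#' position. In blocks mode it is the 0-based index of the containing
#' block, or `NA` when the position falls in a gap between blocks (such
#' records are excluded from binned views but kept in the whole-genome
#' view).
#'
#' @param scheme A `segment_scheme`.
#' @param chrom Integer chromosome vector.
#' @param pos Integer 1-based position vector (recycled against chrom).
#' @return Integer segment ids (`NA` for gap positions in blocks mode).
#' @export
assign_segment <- function(scheme, chrom, pos) {
  stopifnot(inherits(scheme, "segment_scheme"))
  if (any(pos < 1, na.rm = TRUE))
    stop("assign_segment: positions are 1-based (pos >= 1)", call. = FALSE)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.integer(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  if (scheme$mode == "fixed")
    return(as.integer(floor((pos - 1) / scheme$width)))
  out <- rep(NA_integer_, n)
  bl <- scheme$blocks
  for (ch in unique(chrom[!is.na(chrom)])) {
    b <- bl[bl$chrom == ch]
    if (nrow(b) == 0L) next
    idx <- which(chrom == ch)
    # findInterval over block starts, then verify pos <= end
    j <- findInterval(pos[idx], b$start)
    hit <- j >= 1L & pos[idx] <= b$end[pmax(j, 1L)]
    out[idx[hit]] <- b$segment[j[hit]]
  }
  out
}

#' Genomic interval covered by a segment
#'
#' @param scheme A `segment_scheme`.
#' @param chrom Chromosome (used in blocks mode).
#' @param segment Segment id(s).
#' @return A data.table with columns `segment, start, end` (1-based
#'   closed).
#' @export
segment_bounds <- function(scheme, chrom, segment) {
  stopifnot(inherits(scheme, "segment_scheme"))
  segment <- as.integer(segment)
  if (scheme$mode == "fixed")
    return(data.table::data.table(
      segment = segment,
      start = segment * scheme$width + 1,
      end = (segment + 1) * scheme$width))
  keep <- scheme$blocks$chrom == as.integer(chrom)
  b <- scheme$blocks[keep]
  m <- match(segment, b$segment)
  if (anyNA(m))
    stop("segment_bounds: segment ", segment[which(is.na(m))[1L]],
         " not defined on chromosome ", chrom, call. = FALSE)
  data.table::data.table(segment = segment, start = b$start[m], end = b$end[m])
}
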