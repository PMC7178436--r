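#' Describe the columns of a GWAS summary-statistics file
#'
#' A column map connects the canonical field names used throughout the
#' package to the column names of a particular summary-statistics file.
#' The required fields are the SNP identifier, chromosome, base-pair
#' position and p-value; effect size, standard error and alleles are
#' optional and yield missing values when unmapped.
#'
#' @param snp_id,chrom,pos,p Column names of the required fields.
#' @param effect,se,allele1,allele2 Column names of the optional fields,
#'   or `NULL` when the file does not carry them.
#' @param p_scale Either `"raw"` (the p column holds p-values in (0, 1])
#'   or `"neglog10"` (the column is already on the -log10 scale).
#' @param effect_type Either `"beta"` (signed regression coefficient) or
#'   `"OR"` (odds ratio, stored as given, never log-transformed).
#'
#' @return An object of class `column_map`.
#' @export
#' @examples
#' column_map(snp_id = "SNP", chrom = "CHR", pos = "BP", p = "P")
column_map <- function(snp_id, chrom, pos, p,
                       effect = NULL, se = NULL,
                       allele1 = NULL, allele2 = NULL,
                       p_scale = c("raw", "neglog10"),
                       effect_type = c("beta", "OR")) {
  p_scale <- match.arg(p_scale)
  effect_type <- match.arg(effect_type)
  req <- list(snp_id = snp_id, chrom = chrom, pos = pos, p = p)
  for (nm in names(req)) {
    if (!is.character(req[[nm]]) || length(req[[nm]]) != 1L || is.na(req[[nm]]))
      stop("column_map: required field '", nm, "' must be a single column name",
           call. = FALSE)
  }
  structure(
    list(snp_id = snp_id, chrom = chrom, pos = pos, p = p,
         effect = effect, se = se, allele1 = allele1, allele2 = allele2,
         p_scale = p_scale, effect_type = effect_type),
    class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat("<column_map> p_scale=", x$p_scale, ", effect_type=", x$effect_type, "\n",
      sep = "")
  flds <- c("snp_id", "chrom", "pos", "p", "effect", "se", "allele1", "allele2")
  for (f in flds)
    cat(sprintf("  %-8s -> %s\n", f, if (is.null(x[[f]])) "<unmapped>" else x[[f]]))
  invisible(x)
}

#' Parse p-values to -log10 scale without double-precision underflow
#'
#' P-values in GWAS summary files can be far below the smallest positive
#' double (around 5e-324); naive `-log10(as.numeric(x))` returns `Inf`
#' for them. The mantissa and exponent are therefore split from the
#' *string* representation, and the result is computed as
#' `exponent - log10(mantissa)`, which is exact to ~1e-15 at any
#' exponent. Plain decimals ("0.03") are handled through `log10()`
#' directly since they cannot underflow.
#'
#' @param x Character (or numeric) vector of p-values.
#' @param p_scale `"raw"` for p-values in (0, 1], `"neglog10"` if the
#'   values are already -log10(p) (then validated and passed through).
#'
#' @return Numeric vector of finite, non-negative -log10(p) values.
#'   Unparseable elements are `NA` (callers count and drop them);
#'   p = 0, p < 0 or p > 1 raise an error identifying the offending
#'   element.
#' @export
#' @examples
#' parse_pvalue(c("1.0", "9.7e-26", "1.6e-320"))
parse_pvalue <- function(x, p_scale = c("raw", "neglog10")) {
  p_scale <- match.arg(p_scale)
  x <- trimws(as.character(x))
  if (p_scale == "neglog10") {
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(v) & (v < 0 | !is.finite(v))
    if (any(bad))
      stop("parse_pvalue: negative or non-finite -log10(p) at element ",
           which(bad)[1L], ": '", x[which(bad)[1L]], "'", call. = FALSE)
    return(v)
  }
  out <- rep(NA_real_, length(x))
  # scientific notation: mantissa e exponent
  sci <- grepl("^[+-]?[0-9]*\\.?[0-9]+[eE][+-]?[0-9]+$", x)
  if (any(sci)) {
    parts <- strsplit(x[sci], "[eE]")
    mant <- as.numeric(vapply(parts, `[[`, "", 1L))
    expo <- as.numeric(vapply(parts, `[[`, "", 2L))
    out[sci] <- suppressWarnings(-(log10(mant) + expo))
  }
  dec <- !sci & grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$", x)
  # invalid (negative / zero / > 1) inputs are rejected below; the NaN
  # they momentarily produce here is never returned
  out[dec] <- suppressWarnings(-log10(as.numeric(x[dec])))
  parsed <- sci | dec
  if (any(parsed)) {
    val <- suppressWarnings(as.numeric(x[parsed]))
    neg <- !is.na(val) & val < 0
    zero <- !is.na(val) & val == 0
    over <- !is.na(val) & val > 1
    # val underflows to 0 for tiny scientific p; a true textual zero has
    # no negative exponent
    zero <- zero & !grepl("[eE]-", x[parsed])
    firstbad <- function(w) which(parsed)[w][1L]
    if (any(zero))
      stop("parse_pvalue: p-value of 0 at element ", firstbad(which(zero)),
           call. = FALSE)
    if (any(neg))
      stop("parse_pvalue: negative p-value at element ", firstbad(which(neg)),
           call. = FALSE)
    if (any(over))
      stop("parse_pvalue: p-value > 1 at element ", firstbad(which(over)),
           ": '", x[parsed][which(over)[1L]], "'", call. = FALSE)
  }
  out
}

# "chr19", "19", "19.0", "chrX" -> integer chromosome or NA (non-autosomal)
normalize_chrom <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  v <- suppressWarnings(as.numeric(x))
  v[!is.na(v) & v != floor(v)] <- NA
  v <- as.integer(v)
  v[!is.na(v) & (v < 1L | v > 22L)] <- NA
  v
}

#' Read one per-phenotype GWAS summary-statistics file
#'
#' Reads a delimited text file (TSV/CSV/whitespace auto-detected by
#' [data.table::fread()], gzip-transparent), applies a [column_map()],
#' normalizes chromosome labels, parses p-values to the -log10 scale,
#' drops non-autosomal and unparseable rows, and collapses duplicate
#' (snp_id, chrom, pos) rows keeping the most significant one.
#'
#' @param path Path to the summary file (a header row is required).
#' @param map A [column_map()] describing the file.
#' @param phenotype Label attached to every record from this file.
#'
#' @return A [data.table::data.table] of summary records with columns
#'   `phenotype, snp_id, chrom, pos, neglog10p, effect, effect_type, se,
#'   allele1, allele2`, and a `"drop_counts"` attribute with the number
#'   of rows removed per reason (`nonautosomal`, `unparseable`,
#'   `duplicate`).
#' @export
read_summary_file <- function(path, map, phenotype) {
  stopifnot(inherits(map, "column_map"))
  if (!is.character(phenotype) || length(phenotype) != 1L)
    stop("read_summary_file: 'phenotype' must be a single label", call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          showProgress = FALSE)
  if (nrow(dt) == 0L)
    stop("read_summary_file: '", path, "' has no data rows", call. = FALSE)
  for (f in c("snp_id", "chrom", "pos", "p")) {
    if (!(map[[f]] %in% names(dt)))
      stop("read_summary_file: mapped column '", map[[f]], "' (field '", f,
           "') not found in ", path, call. = FALSE)
  }
  opt <- function(f) {
    col <- map[[f]]
    if (is.null(col)) return(rep(NA_character_, nrow(dt)))
    if (!(col %in% names(dt)))
      stop("read_summary_file: mapped column '", col, "' (field '", f,
           "') not found in ", path, call. = FALSE)
    dt[[col]]
  }
  rec <- data.table::data.table(
    phenotype = phenotype,
    snp_id = dt[[map$snp_id]],
    chrom = normalize_chrom(dt[[map$chrom]]),
    pos = suppressWarnings(as.numeric(dt[[map$pos]])),
    neglog10p = parse_pvalue(dt[[map$p]], map$p_scale),
    effect = suppressWarnings(as.numeric(opt("effect"))),
    effect_type = map$effect_type,
    se = suppressWarnings(as.numeric(opt("se"))),
    allele1 = opt("allele1"),
    allele2 = opt("allele2"))
  rec$pos[!is.na(rec$pos) & (rec$pos < 1 | rec$pos != floor(rec$pos))] <- NA
  n0 <- nrow(rec)
  bad_parse <- is.na(rec$pos) | is.na(rec$neglog10p) | is.na(rec$snp_id) |
    rec$snp_id == ""
  keep_chrom <- !is.na(rec$chrom)
  n_nonauto <- sum(!keep_chrom & !bad_parse)
  n_unparse <- sum(bad_parse)
  rec <- rec[keep_chrom & !bad_parse]
  rec$pos <- as.integer(rec$pos)
  # duplicate (snp_id, chrom, pos): keep the larger neglog10p
  data.table::setorderv(rec, c("chrom", "pos", "snp_id", "neglog10p"),
                        order = c(1L, 1L, 1L, -1L))
  dup <- duplicated(rec, by = c("snp_id", "chrom", "pos"))
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    warning("read_summary_file: ", n_dup, " duplicate (snp_id, chrom, pos) ",
            "row(s) collapsed in ", path, call. = FALSE)
    rec <- rec[!dup]
  }
  data.table::setorderv(rec, c("chrom", "pos", "snp_id"))
  stopifnot(nrow(rec) == n0 - n_nonauto - n_unparse - n_dup)
  data.table::setattr(rec, "drop_counts",
                      c(nonautosomal = n_nonauto, unparseable = n_unparse,
                        duplicate = n_dup))
  rec[]
}

#' Merge per-phenotype record tables into one harmonized landscape table
#'
#' The "phase one" step, executed once per study: all per-phenotype
#' record tables are concatenated into a single long-format table sorted
#' by (chrom, pos, phenotype), carrying a stable user-supplied phenotype
#' axis order (the z-axis of the landscape). A SNP absent from one
#' phenotype's file simply has no record for that phenotype; nothing is
#' imputed.
#'
#' @param records A list of record tables as returned by
#'   [read_summary_file()]. Unnamed lists take their phenotype labels
#'   from the records themselves.
#' @param phenotype_order Optional character vector fixing the z-axis
#'   order; defaults to the order of `records`.
#' @param build Genome build label stored in the table metadata
#'   (positions are 1-based).
#'
#' @return A `landscape_table`: a data.table with attributes
#'   `phenotypes` (axis order) and `meta` (build, per-phenotype input
#'   counts, creation time parameters).
#' @export
harmonize <- function(records, phenotype_order = NULL, build = "GRCh37") {
  if (!is.list(records) || length(records) == 0L)
    stop("harmonize: 'records' must be a non-empty list", call. = FALSE)
  if (data.table::is.data.table(records)) records <- list(records)
  labels <- vapply(records, function(r) {
    u <- unique(r$phenotype)
    if (length(u) != 1L)
      stop("harmonize: each record table must carry one phenotype", call. = FALSE)
    u
  }, "")
  if (anyDuplicated(labels))
    stop("harmonize: duplicate phenotype label '",
         labels[duplicated(labels)][1L], "'", call. = FALSE)
  labels <- unname(labels)
  if (is.null(phenotype_order)) phenotype_order <- labels
  phenotype_order <- unname(phenotype_order)
  if (!setequal(phenotype_order, labels) || anyDuplicated(phenotype_order))
    stop("harmonize: 'phenotype_order' must be a permutation of the ",
         "phenotype labels", call. = FALSE)
  tab <- data.table::rbindlist(records, use.names = TRUE)
  tab$phenotype <- factor(tab$phenotype, levels = phenotype_order)
  data.table::setorderv(tab, c("chrom", "pos", "phenotype"))
  tab$phenotype <- as.character(tab$phenotype)
  if (anyDuplicated(tab, by = c("phenotype", "chrom", "pos", "snp_id")))
    stop("harmonize: duplicate (phenotype, chrom, pos, snp_id) records",
         call. = FALSE)
  data.table::setattr(tab, "phenotypes", phenotype_order)
  data.table::setattr(tab, "meta",
                      list(build = build, positions = "1-based",
                           n_records = vapply(records, nrow, 0L)[
                             match(phenotype_order, labels)]))
  data.table::setattr(tab, "class",
                      c("landscape_table", class(tab)))
  tab[]
}

#' Phenotype axis order of a landscape table
#' @param table A `landscape_table`.
#' @return Character vector, the z-axis order.
#' @export
phenotypes <- function(table) {
  ph <- attr(table, "phenotypes")
  if (is.null(ph)) unique(table$phenotype) else ph
}

#' @export
print.landscape_table <- function(x, ...) {
  ph <- phenotypes(x)
  cat("<landscape_table> ", nrow(x), " records, ", length(ph),
      " phenotype(s): ", paste(ph, collapse = ", "), "\n", sep = "")
  NextMethod()
}

landscape_columns <- c("phenotype", "snp_id", "chrom", "pos", "neglog10p",
                       "effect", "effect_type", "se", "allele1", "allele2")

#' Write / read the canonical harmonized TSV
#'
#' The canonical on-disk form is a TSV with fixed column order
#' (phenotype, snp_id, chrom, pos, neglog10p, effect, effect_type, se,
#' allele1, allele2); writing then re-reading reproduces the table
#' field-for-field.
#'
#' @param table A `landscape_table`.
#' @param path Output (input) path.
#' @return `write_landscape` returns `path` invisibly; `read_landscape`
#'   returns a `landscape_table`.
#' @export
write_landscape <- function(table, path) {
  stopifnot(inherits(table, "landscape_table"))
  out <- data.table::as.data.table(table)[, landscape_columns, with = FALSE]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param phenotype_order Optional z-axis order for `read_landscape`;
#'   defaults to first-appearance order in the file.
#' @param build Genome build label.
#' @export
read_landscape <- function(path, phenotype_order = NULL, build = "GRCh37") {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                           colClasses = list(character = c(
                             "phenotype", "snp_id", "effect_type",
                             "allele1", "allele2"),
                             numeric = c("neglog10p", "effect", "se"),
                             integer = c("chrom", "pos")),
                           showProgress = FALSE)
  missing_cols <- setdiff(landscape_columns, names(tab))
  if (length(missing_cols))
    stop("read_landscape: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  per <- split(tab, tab$phenotype)
  if (is.null(phenotype_order)) phenotype_order <- unique(tab$phenotype)
  harmonize(per[phenotype_order], phenotype_order, build = build)
}
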