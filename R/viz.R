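#' Build a renderer-independent 3D landscape figure specification
#'
#' Turns genome-level peaks (from [genome_peaks()]) or a
#' single-chromosome peak grid (from [chromosome_peaks()]) into a
#' figure specification: one trace per phenotype, each a sequence of
#' points with an x position (chromosome or retained segment), a y
#' value, a colour value and a full hover payload. Each plotted point
#' corresponds to exactly one peak record; missing cells yield no point
#' (gaps are never interpolated or zero-filled -- a phenotype with no
#' in-stratum record in a segment simply has a hole there, which is why
#' the landscape is drawn as per-phenotype ribbons rather than a
#' continuous surface).
#'
#' In `"pvalue"` mode the y-axis is -log10(p); in `"effect"` mode the
#' y-axis is the effect size (beta or OR, as stored) while the colour
#' scale remains bound to -log10(p), so significance and effect are
#' visible simultaneously.
#'
#' The hover payload carries the phenotype, chromosome, SNP id,
#' -log10(p), effect size, standard error, both alleles, the locus
#' label (chromosome, or chrom:segment in chromosome view) and the gene
#' symbol(s); missing optional fields show the sentinel "NA", and
#' multiple overlapping genes are joined with ";".
#'
#' @param x A peaks table from [genome_peaks()] or a `bin_peak_grid`.
#' @param mode `"pvalue"` (default) or `"effect"`.
#' @param genes Optional `gene_interval_map` for gene symbols in the
#'   hover payload.
#' @param gene_window SNP-to-gene window in bp (default 100,000).
#' @return A `figure_spec`: list with `view` ("genome" or
#'   "chromosome"), `mode`, `x_labels`, `phenotypes`, `traces` (named
#'   list of data.tables with columns x, y, color, snp_id, hover), and
#'   `stratum`.
#' @export
landscape_figure <- function(x, mode = c("pvalue", "effect"), genes = NULL,
                             gene_window = 100000) {
  mode <- match.arg(mode)
  if (inherits(x, "bin_peak_grid")) {
    view <- "chromosome"
    recs <- data.table::copy(x$cells)
    ph <- x$phenotypes
    xs <- x$segments
    x_labels <- paste0("chr", x$chrom, ":", xs)
    xi <- recs$segment
    locus <- paste0(x$chrom, ":", recs$segment)
    strat <- x$stratum
  } else {
    view <- "genome"
    recs <- data.table::as.data.table(x)
    ph <- phenotypes(x)
    xs <- 1:22
    x_labels <- paste0("chr", xs)
    xi <- recs$chrom
    locus <- as.character(recs$chrom)
    strat <- stratum()
  }
  if (nrow(recs) == 0L) {
    warning("landscape_figure: no records to plot; empty figure",
            call. = FALSE)
    traces <- stats::setNames(
      rep(list(data.table::data.table(x = integer(0), y = numeric(0),
                                      color = numeric(0),
                                      snp_id = character(0),
                                      hover = character(0))), length(ph)), ph)
    return(structure(list(view = view, mode = mode, x_labels = x_labels,
                          phenotypes = ph, traces = traces, stratum = strat),
                     class = "figure_spec"))
  }
  gene_of <- function(chrom, pos) {
    if (is.null(genes)) return("NA")
    gs <- map_snp_to_genes(genes, chrom, pos, gene_window)
    if (length(gs) == 0L) "NA" else paste(gs, collapse = ";")
  }
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, trim = TRUE))
  gene_sym <- mapply(gene_of, recs$chrom, recs$pos)
  hover <- sprintf(
    paste0("phenotype: %s | chromosome: %s | SNP: %s | -log10(p): %s | ",
           "effect: %s | se: %s | allele1: %s | allele2: %s | locus: %s | ",
           "gene: %s"),
    recs$phenotype, recs$chrom, recs$snp_id, fmt(recs$neglog10p),
    fmt(recs$effect), fmt(recs$se), fmt(recs$allele1), fmt(recs$allele2),
    locus, gene_sym)
  y <- if (mode == "pvalue") recs$neglog10p else recs$effect
  pts <- data.table::data.table(phenotype = recs$phenotype, x = xi, y = y,
                                color = recs$neglog10p,
                                snp_id = recs$snp_id, hover = hover)
  traces <- lapply(ph, function(p) {
    tr <- pts[pts$phenotype == p,
              c("x", "y", "color", "snp_id", "hover"), with = FALSE]
    data.table::setorderv(tr, "x")
    tr
  })
  names(traces) <- ph
  structure(list(view = view, mode = mode, x_labels = x_labels,
                 phenotypes = ph, traces = traces, stratum = strat),
            class = "figure_spec")
}

#' @export
print.figure_spec <- function(x, ...) {
  n_pts <- sum(vapply(x$traces, nrow, 0L))
  cat("<figure_spec> ", x$view, " view, ", x$mode, " mode: ",
      length(x$traces), " trace(s), ", n_pts, " point(s), x axis of ",
      length(x$x_labels), "\n", sep = "")
  invisible(x)
}

#' Heatmap projection of a landscape figure
#'
#' Projects the 3D surface onto the plane perpendicular to the
#' phenotype axis: a matrix of -log10(p) colour values with rows = x
#' positions (retained segments, or the 22 chromosomes) and columns =
#' phenotypes. Cells with no peak record hold `NA` -- a neutral
#' sentinel kept distinct from 0, since -log10(p) = 0 is a real value.
#'
#' @param spec A `figure_spec`.
#' @return Numeric matrix with dimnames (x labels, phenotypes).
#' @export
heatmap_projection <- function(spec) {
  stopifnot(inherits(spec, "figure_spec"))
  m <- matrix(NA_real_, nrow = length(spec$x_labels),
              ncol = length(spec$phenotypes),
              dimnames = list(spec$x_labels, spec$phenotypes))
  xs <- if (spec$view == "genome") 1:22 else
    as.integer(sub("^chr[0-9]+:", "", spec$x_labels))
  for (p in spec$phenotypes) {
    tr <- spec$traces[[p]]
    if (nrow(tr) == 0L) next
    m[match(tr$x, xs), p] <- tr$color
  }
  m
}

figure_payload_json <- function(spec) {
  payload <- list(
    view = spec$view, mode = spec$mode,
    x_labels = as.list(spec$x_labels),
    phenotypes = as.list(spec$phenotypes),
    stratum = list(lo = spec$stratum$lo,
                   hi = if (is.finite(spec$stratum$hi))
                     spec$stratum$hi else "inf"),
    traces = lapply(spec$traces, function(tr)
      list(x = tr$x, y = tr$y, color = tr$color,
           snp_id = tr$snp_id, hover = tr$hover)))
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Write a landscape figure to disk
#'
#' `format = "html"` writes a fully self-contained interactive page:
#' the figure data are embedded client-side as JSON and rendered by a
#' small inlined script (heatmap projection with per-point hover
#' dialogs showing the full payload), so the file opens offline with no
#' external resources. Re-running with identical inputs reproduces a
#' byte-identical data payload. `format = "static"` writes a
#' non-interactive snapshot (PDF, PNG or SVG by file extension) of the
#' heatmap with per-phenotype significance profiles.
#'
#' @param spec A `figure_spec`.
#' @param path Output path.
#' @param format `"html"` (default) or `"static"`.
#' @param title Page/plot title.
#' @return `path`, invisibly.
#' @export
write_figure <- function(spec, path, format = c("html", "static"),
                         title = "Genome-by-phenome landscape") {
  stopifnot(inherits(spec, "figure_spec"))
  format <- match.arg(format)
  if (format == "static") return(write_figure_static(spec, path, title))
  json <- figure_payload_json(spec)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    paste0("<title>", title, "</title>"),
    "<style>",
    "body{font-family:sans-serif;margin:1em}",
    "table.hm{border-collapse:collapse}",
    "table.hm td{width:26px;height:18px;border:1px solid #ddd;cursor:pointer}",
    "table.hm th{font-size:10px;font-weight:normal;padding:2px}",
    "#dialog{margin-top:1em;padding:0.5em;border:1px solid #888;",
    "min-height:1.5em;font-size:12px;white-space:pre-wrap}",
    "</style></head><body>",
    paste0("<h2>", title, "</h2>"),
    "<div id=\"plot\"></div>",
    "<div id=\"dialog\">hover a cell for the SNP dialog</div>",
    "<script id=\"landscape-data\" type=\"application/json\">",
    as.character(json),
    "</script>",
    "<script>",
    "var D=JSON.parse(document.getElementById('landscape-data').textContent);",
    "var vmax=0;for(var t in D.traces){var c=D.traces[t].color;",
    " for(var i=0;i<c.length;i++){if(c[i]!==null&&c[i]>vmax)vmax=c[i];}}",
    "function shade(v){if(v===null||v===undefined)return '#f4f4f4';",
    " var f=vmax>0?v/vmax:0;var g=Math.round(255-205*f);",
    " return 'rgb(255,'+g+','+Math.round(g*0.55)+')';}",
    "var tb=document.createElement('table');tb.className='hm';",
    "var hr=document.createElement('tr');",
    "hr.appendChild(document.createElement('th'));",
    "D.x_labels.forEach(function(l){var th=document.createElement('th');",
    " th.textContent=l;hr.appendChild(th);});tb.appendChild(hr);",
    "D.phenotypes.forEach(function(p){",
    " var row=document.createElement('tr');",
    " var th=document.createElement('th');th.textContent=p;",
    " row.appendChild(th);",
    " var tr=D.traces[p];var byx={};",
    " for(var i=0;i<tr.x.length;i++){byx[tr.x[i]]=i;}",
    " D.x_labels.forEach(function(l,j){",
    "  var xv=(D.view==='genome')?(j+1):parseInt(l.split(':')[1]);",
    "  var td=document.createElement('td');",
    "  if(byx.hasOwnProperty(xv)){var i=byx[xv];",
    "   td.style.background=shade(tr.color[i]);",
    "   td.title=tr.snp_id[i];",
    "   td.onmouseover=function(){",
    "    document.getElementById('dialog').textContent=tr.hover[i];};",
    "  } else { td.style.background=shade(null); }",
    "  row.appendChild(td);});",
    " tb.appendChild(row);});",
    "document.getElementById('plot').appendChild(tb);",
    "</script>",
    "</body></html>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(html, con, sep = "\n")
  invisible(path)
}

write_figure_static <- function(spec, path, title) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                png = function() grDevices::png(path, width = 900,
                                                height = 600),
                svg = function() grDevices::svg(path, width = 9, height = 6),
                function() grDevices::pdf(path, width = 9, height = 6))
  dev()
  on.exit(grDevices::dev.off())
  m <- heatmap_projection(spec)
  if (all(is.na(m)) || nrow(m) == 0L) {
    graphics::plot.new()
    graphics::title(main = paste(title, "(empty)"))
    return(invisible(path))
  }
  z <- t(m)
  z[is.na(z)] <- 0
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "phenotype",
                  ylab = if (spec$view == "genome") "chromosome"
                         else "segment",
                  main = title)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 1,
                 cex.axis = 0.6)
  graphics::box()
  invisible(path)
}
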