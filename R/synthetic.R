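# GRCh37 autosome lengths (bp), used to place background SNPs
grch37_lengths <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
  59128983, 63025520, 48129895, 51304566)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Declare a planted association locus for the synthetic generator
#'
#' A planted locus is a lead SNP with declared per-phenotype
#' significance, a halo of satellite SNPs in the lead's 1 Mb segment
#' whose LD with the lead is drawn above (`n_satellites`) or below
#' (`n_weak_satellites`) the 0.75 display thresholds, and optionally a
#' secondary independent lead in the same segment (written to the LD
#' table with r2 < 0.1 to the primary lead, so recursive thinning at
#' depth 2 must surface it).
#'
#' @param chrom Chromosome 1-22.
#' @param lead_pos 1-based lead position.
#' @param phenotypes Character vector of affected phenotype labels.
#' @param neglog10p Declared -log10(p) per affected phenotype
#'   (recycled). Written exactly as declared.
#' @param lead_id Lead SNP id (default derived from position).
#' @param effect Declared effect per affected phenotype (recycled;
#'   default drawn at realization).
#' @param n_satellites Satellites with r2 and D' drawn in
#'   [0.80, 0.98] (strictly above 0.75).
#' @param n_weak_satellites Satellites with r2 and D' drawn in
#'   [0.05, 0.50].
#' @param secondary_neglog10p If non-`NULL`, plants a secondary
#'   independent lead at this significance (must sit below the primary
#'   and above the primary's satellites, which lie 3-8 units below the
#'   primary).
#' @param secondary_pos Position of the secondary lead (default: lead
#'   position + 200 kb, clipped to the segment).
#' @param secondary_phenotypes Phenotypes carrying the secondary
#'   signal (default: the first affected phenotype; the secondary must
#'   stay below the primary lead wherever both are significant).
#' @return A `planted_locus` specification.
#' @export
planted_locus <- function(chrom, lead_pos, phenotypes, neglog10p,
                          lead_id = NULL, effect = NULL,
                          n_satellites = 5L, n_weak_satellites = 2L,
                          secondary_neglog10p = NULL,
                          secondary_pos = NULL,
                          secondary_phenotypes = NULL) {
  chrom <- as.integer(chrom)
  stopifnot(chrom >= 1L, chrom <= 22L, lead_pos >= 1,
            length(phenotypes) >= 1L)
  neglog10p <- rep_len(neglog10p, length(phenotypes))
  if (!is.null(effect)) effect <- rep_len(effect, length(phenotypes))
  segment <- as.integer(floor((lead_pos - 1) / 1e6))
  if (is.null(lead_id))
    lead_id <- sprintf("rs_lead_%d_%d", chrom, segment)
  if (!is.null(secondary_neglog10p)) {
    if (is.null(secondary_pos))
      secondary_pos <- min(lead_pos + 200000, (segment + 1) * 1e6)
    if (is.null(secondary_phenotypes))
      secondary_phenotypes <- phenotypes[1L]
    stopifnot(all(secondary_phenotypes %in% phenotypes))
    too_high <- secondary_neglog10p >=
      neglog10p[match(secondary_phenotypes, phenotypes)]
    if (any(too_high))
      stop("planted_locus: secondary signal must stay below the primary ",
           "lead in its phenotype(s)", call. = FALSE)
  }
  structure(list(chrom = chrom, lead_pos = as.numeric(lead_pos),
                 lead_id = lead_id, segment = segment,
                 phenotypes = as.character(phenotypes),
                 neglog10p = neglog10p, effect = effect,
                 n_satellites = as.integer(n_satellites),
                 n_weak_satellites = as.integer(n_weak_satellites),
                 secondary_neglog10p = secondary_neglog10p,
                 secondary_pos = secondary_pos,
                 secondary_phenotypes = secondary_phenotypes),
            class = "planted_locus")
}

#' A standard set of planted loci emulating a multi-trait lipid study
#'
#' Four phenotypes; one strongly pleiotropic locus in segment 45 of
#' chromosome 19 affecting three of them (with a buried secondary
#' independent signal for thinning tests), plus single-trait loci on
#' other chromosomes.
#'
#' @param phenotypes Phenotype labels (default four lipid-like traits).
#' @return List of `planted_locus` objects.
#' @export
example_loci <- function(phenotypes = c("HDL", "LDL", "TRIG", "TC")) {
  stopifnot(length(phenotypes) >= 4L)
  list(
    planted_locus(19, 45411941, phenotypes[c(2, 4, 1)],
                  neglog10p = c(60, 40, 25), n_satellites = 5L,
                  n_weak_satellites = 3L,
                  secondary_neglog10p = 55, secondary_pos = 45650000),
    planted_locus(1, 12583000, phenotypes[1], neglog10p = 18),
    planted_locus(2, 21225000, phenotypes[2], neglog10p = 30),
    planted_locus(8, 19812000, phenotypes[3], neglog10p = 22),
    planted_locus(11, 116650000, phenotypes[c(3, 4)],
                  neglog10p = c(15, 12)))
}

# draw satellites & LD values once; everything downstream reads this
realize_loci <- function(loci, phenotype_labels, seed) {
  with_seed(seed + 104729L, {
    lapply(loci, function(lo) {
      seg_lo <- lo$segment * 1e6 + 1
      seg_hi <- (lo$segment + 1) * 1e6
      n_sat <- lo$n_satellites + lo$n_weak_satellites
      used <- c(lo$lead_pos, lo$secondary_pos)
      sat_pos <- integer(0)
      if (n_sat > 0L) {
        cand <- seg_lo:seg_hi
        sat_pos <- sample(setdiff(cand, used), n_sat)
      }
      strong <- seq_len(lo$n_satellites)
      sat <- data.table::data.table(
        snp_id = sprintf("%s_sat%d", lo$lead_id, seq_len(n_sat)),
        pos = as.numeric(sat_pos),
        r2 = c(stats::runif(lo$n_satellites, 0.80, 0.98),
               stats::runif(lo$n_weak_satellites, 0.05, 0.50)),
        dprime = c(stats::runif(lo$n_satellites, 0.80, 0.98),
                   stats::runif(lo$n_weak_satellites, 0.05, 0.50)),
        strong = seq_len(n_sat) %in% strong)
      # satellite significance rides 3-8 units below the lead (strong)
      # or stays at background level (weak)
      sat_nl <- lapply(seq_along(lo$phenotypes), function(i) {
        ifelse(sat$strong,
               pmax(0, lo$neglog10p[i] - stats::runif(n_sat, 3, 8)),
               stats::runif(n_sat, 0, 3))
      })
      names(sat_nl) <- lo$phenotypes
      effect <- if (is.null(lo$effect))
        round(stats::runif(length(lo$phenotypes), 0.1, 0.5) *
                sample(c(-1, 1), length(lo$phenotypes), TRUE), 4)
      else lo$effect
      sec <- NULL
      if (!is.null(lo$secondary_neglog10p)) {
        n2 <- 3L
        sec_sat_pos <- sample(setdiff(seg_lo:seg_hi,
                                      c(used, sat_pos)), n2)
        sec_nl <- ifelse(lo$phenotypes %in% lo$secondary_phenotypes,
                         rep_len(lo$secondary_neglog10p,
                                 length(lo$phenotypes)),
                         stats::runif(length(lo$phenotypes), 0, 3))
        sec <- list(
          snp_id = sprintf("%s_sec", lo$lead_id),
          pos = as.numeric(lo$secondary_pos),
          phenotypes = lo$secondary_phenotypes,
          neglog10p = sec_nl,
          r2_to_primary = stats::runif(1, 0.01, 0.08),
          dprime_to_primary = stats::runif(1, 0.01, 0.08),
          satellites = data.table::data.table(
            snp_id = sprintf("%s_sec_sat%d", lo$lead_id, seq_len(n2)),
            pos = as.numeric(sec_sat_pos),
            r2 = stats::runif(n2, 0.80, 0.98),
            dprime = stats::runif(n2, 0.80, 0.98),
            neglog10p = pmax(0, rep_len(lo$secondary_neglog10p,
                                        n2) -
                               stats::runif(n2, 3, 8))))
      }
      c(lo, list(satellites = sat, satellite_neglog10p = sat_nl,
                 realized_effect = effect, secondary = sec))
    })
  })
}

# -log10(p) -> scientific-notation p string with 10-digit mantissa,
# exact beyond the double-precision underflow limit
format_p <- function(neglog10p) {
  vapply(neglog10p, function(nl) {
    if (nl <= 0) return("1")
    e <- ceiling(nl)
    m <- 10^(e - nl)
    if (m >= 10) { m <- m / 10; e <- e - 1 }
    sprintf("%.10fe-%d", m, e)
  }, "")
}

#' Generate synthetic multi-phenotype GWAS summary files
#'
#' Emits one summary-statistics file per phenotype (tab-delimited,
#' columns `SNP CHR BP P BETA SE A1 A2`) containing background SNPs on
#' all 22 autosomes plus the planted loci, together with a ground-truth
#' record. Background significance is drawn uniformly on
#' [0, `background_max`] with the default cap at 3, well below the
#' retention threshold of 6, so every retained segment is planted by
#' construction; planted -log10(p) values are written exactly as
#' declared (p is printed as a scientific-notation string with a
#' 10-digit mantissa, which also exercises sub-double-precision p-value
#' parsing for values like 1e-320). The same seed reproduces
#' byte-identical files. A stress variant with `background_max` up to 7
#' exists for retention-robustness tests.
#'
#' @param n_phenotypes Number of phenotypes (default 4).
#' @param loci List of [planted_locus()] (default [example_loci()]
#'   truncated to the labels available).
#' @param background_snps_per_chrom Background SNPs per chromosome per
#'   phenotype (default 500).
#' @param seed Integer seed; fixed per dataset.
#' @param dir Output directory (created); default a fresh tempdir.
#' @param phenotype_labels Labels; default HDL, LDL, TRIG, TC, P5...
#' @param background_max Upper bound of background -log10(p)
#'   (default 3).
#' @return List with `files` (named per phenotype), `dir`, `truth`
#'   (realized loci), `phenotypes`, `genes_bed` (gene intervals
#'   covering each planted lead), `ld_table` (path, written by
#'   [simulate_ld_table()]), and `column_map`.
#' @export
simulate_summary <- function(n_phenotypes = 4L, loci = NULL,
                             background_snps_per_chrom = 500L, seed = 1L,
                             dir = tempfile("synthgwas"),
                             phenotype_labels = NULL,
                             background_max = 3) {
  if (is.null(phenotype_labels))
    phenotype_labels <- c("HDL", "LDL", "TRIG", "TC",
                          paste0("P", seq_len(max(0, n_phenotypes - 4L)) + 4L)
                          )[seq_len(n_phenotypes)]
  stopifnot(length(phenotype_labels) == n_phenotypes)
  if (is.null(loci)) loci <- example_loci(phenotype_labels)
  bad_ph <- setdiff(unlist(lapply(loci, `[[`, "phenotypes")),
                    phenotype_labels)
  if (length(bad_ph))
    stop("simulate_summary: loci reference unknown phenotype(s): ",
         paste(bad_ph, collapse = ", "), call. = FALSE)
  truth <- realize_loci(loci, phenotype_labels, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  planted <- data.table::data.table(snp_id = character(0),
                                    chrom = integer(0), pos = numeric(0),
                                    role = character(0),
                                    locus_id = character(0))
  if (length(truth)) planted <- data.table::rbindlist(lapply(truth, function(lo) {
    rows <- list(data.table::data.table(
      snp_id = lo$lead_id, chrom = lo$chrom, pos = lo$lead_pos,
      role = "lead", locus_id = lo$lead_id))
    if (nrow(lo$satellites))
      rows <- c(rows, list(data.table::data.table(
        snp_id = lo$satellites$snp_id, chrom = lo$chrom,
        pos = lo$satellites$pos, role = "satellite",
        locus_id = lo$lead_id)))
    if (!is.null(lo$secondary)) {
      rows <- c(rows, list(data.table::data.table(
        snp_id = c(lo$secondary$snp_id, lo$secondary$satellites$snp_id),
        chrom = lo$chrom,
        pos = c(lo$secondary$pos, lo$secondary$satellites$pos),
        role = c("secondary", rep("secondary_satellite",
                                  nrow(lo$secondary$satellites))),
        locus_id = lo$lead_id)))
    }
    data.table::rbindlist(rows)
  }))

  bg <- with_seed(seed, {
    per_chrom <- lapply(1:22, function(ch) {
      n <- background_snps_per_chrom
      occupied <- planted$pos[planted$chrom == ch]
      pos <- sample.int(grch37_lengths[ch], n + length(occupied))
      pos <- setdiff(pos, occupied)[seq_len(n)]
      if (anyNA(pos))
        stop("simulate_summary: could not place background SNPs clear of ",
             "planted positions on chromosome ", ch, call. = FALSE)
      data.table::data.table(
        snp_id = sprintf("rs%d%06d", ch, seq_len(n)),
        chrom = ch, pos = sort(as.numeric(pos)))
    })
    data.table::rbindlist(per_chrom)
  })

  alleles <- c("A", "C", "G", "T")
  files <- character(n_phenotypes)
  names(files) <- phenotype_labels
  for (pi in seq_len(n_phenotypes)) {
    ph <- phenotype_labels[pi]
    tab <- with_seed(seed + 7919L * pi, {
      all_snps <- data.table::rbindlist(list(
        bg[, c("snp_id", "chrom", "pos"), with = FALSE],
        planted[, c("snp_id", "chrom", "pos"), with = FALSE]))
      nl <- stats::runif(nrow(all_snps), 0, background_max)
      beta <- round(stats::rnorm(nrow(all_snps), 0, 0.02), 4)
      se <- round(stats::runif(nrow(all_snps), 0.01, 0.05), 4)
      a1 <- sample(alleles, nrow(all_snps), TRUE)
      a2 <- mapply(function(x) sample(setdiff(alleles, x), 1L), a1)
      dt <- data.table::data.table(SNP = all_snps$snp_id,
                                   CHR = all_snps$chrom,
                                   BP = all_snps$pos, nl = nl,
                                   BETA = beta, SE = se, A1 = a1, A2 = a2)
      for (lo in truth) {
        i <- match(ph, lo$phenotypes)
        if (!is.na(i)) {
          dt$nl[dt$SNP == lo$lead_id] <- lo$neglog10p[i]
          dt$BETA[dt$SNP == lo$lead_id] <- lo$realized_effect[i]
          m <- match(lo$satellites$snp_id, dt$SNP)
          dt$nl[m] <- lo$satellite_neglog10p[[ph]]
          if (!is.null(lo$secondary)) {
            dt$nl[dt$SNP == lo$secondary$snp_id] <- lo$secondary$neglog10p[i]
            if (ph %in% lo$secondary$phenotypes) {
              m2 <- match(lo$secondary$satellites$snp_id, dt$SNP)
              dt$nl[m2] <- lo$secondary$satellites$neglog10p
            }
          }
        }
      }
      dt
    })
    tab$P <- format_p(tab$nl)
    tab$nl <- NULL
    data.table::setcolorder(tab, c("SNP", "CHR", "BP", "P", "BETA", "SE",
                                   "A1", "A2"))
    data.table::setorderv(tab, c("CHR", "BP"))
    files[ph] <- file.path(dir, paste0(ph, ".tsv"))
    data.table::fwrite(tab, files[ph], sep = "\t", quote = FALSE)
  }

  genes_bed <- file.path(dir, "genes.bed")
  bed <- vapply(truth, function(lo)
    sprintf("%d\t%d\t%d\tGENE%d_%d", lo$chrom,
            as.integer(max(0, lo$lead_pos - 5001)),
            as.integer(lo$lead_pos + 5000), lo$chrom, lo$segment), "")
  writeLines(bed, genes_bed)

  ld_table <- if (length(truth))
    simulate_ld_table(truth, path = file.path(dir, "pairs.ld")) else NULL

  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(lapply(truth, function(lo) list(
    chrom = lo$chrom, segment = lo$segment, lead_id = lo$lead_id,
    lead_pos = lo$lead_pos, phenotypes = lo$phenotypes,
    neglog10p = lo$neglog10p,
    strong_satellites = lo$satellites$snp_id[lo$satellites$strong],
    secondary = if (is.null(lo$secondary)) NULL else lo$secondary$snp_id)),
    truth_json, auto_unbox = TRUE, digits = NA)

  list(files = files, dir = dir, truth = truth,
       phenotypes = phenotype_labels, genes_bed = genes_bed,
       ld_table = ld_table, truth_json = truth_json,
       column_map = column_map(snp_id = "SNP", chrom = "CHR", pos = "BP",
                               p = "P", effect = "BETA", se = "SE",
                               allele1 = "A1", allele2 = "A2"))
}

#' Write the pairwise LD table matching a realized truth record
#'
#' Emits a PLINK-style whitespace table (`CHR_A BP_A SNP_A CHR_B BP_B
#' SNP_B R2 DP`) with one row per lead-satellite pair at the declared
#' r2/D' values, the secondary lead paired to the primary at r2 < 0.1,
#' and the secondary's satellites paired to the secondary only. The
#' table is symmetric by construction once loaded through
#' [ld_backend_table()].
#'
#' @param truth Realized loci, as found in the `truth` element of
#'   [simulate_summary()]'s return value.
#' @param path Output path.
#' @return `path`, invisibly usable with [ld_backend_table()].
#' @export
simulate_ld_table <- function(truth, path) {
  rows <- lapply(truth, function(lo) {
    out <- list()
    if (nrow(lo$satellites))
      out <- c(out, list(data.table::data.table(
        CHR_A = lo$chrom, BP_A = lo$lead_pos, SNP_A = lo$lead_id,
        CHR_B = lo$chrom, BP_B = lo$satellites$pos,
        SNP_B = lo$satellites$snp_id,
        R2 = round(lo$satellites$r2, 6),
        DP = round(lo$satellites$dprime, 6))))
    if (!is.null(lo$secondary)) {
      s <- lo$secondary
      out <- c(out, list(
        data.table::data.table(
          CHR_A = lo$chrom, BP_A = lo$lead_pos, SNP_A = lo$lead_id,
          CHR_B = lo$chrom, BP_B = s$pos, SNP_B = s$snp_id,
          R2 = round(s$r2_to_primary, 6),
          DP = round(s$dprime_to_primary, 6)),
        data.table::data.table(
          CHR_A = lo$chrom, BP_A = s$pos, SNP_A = s$snp_id,
          CHR_B = lo$chrom, BP_B = s$satellites$pos,
          SNP_B = s$satellites$snp_id,
          R2 = round(s$satellites$r2, 6),
          DP = round(s$satellites$dprime, 6))))
    }
    data.table::rbindlist(out)
  })
  tab <- data.table::rbindlist(rows)
  data.table::fwrite(tab, path, sep = " ", quote = FALSE)
  invisible(path)
}
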