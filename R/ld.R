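#' LD backends: pairwise LD without genotypes
#'
#' All LD analytics go through a small backend contract: given a lead
#' SNP and candidate SNPs on the same chromosome, a backend returns the
#' pairwise `(r2, dprime)` values it knows. Two implementations ship:
#'
#' * `ld_backend_table()` -- an offline reader of a PLINK `.ld`-style
#'   whitespace-delimited table with header columns
#'   `SNP_A SNP_B R2 [DP]` (extra columns such as `CHR_A BP_A CHR_B
#'   BP_B` are ignored). Pairs are symmetrized on load; this backend is
#'   fully deterministic and is the one used by all tests.
#' * `ld_backend_rest()` -- a stub for an Ensembl-compatible REST
#'   service; constructing it records the endpoint and population, but
#'   any query raises a typed `ld_backend_unavailable` error when the
#'   service cannot be reached (this package performs no network I/O in
#'   its tested core). Callers may catch that condition and degrade to
#'   an "LD: NA" display.
#'
#' SNPs unknown to a backend are simply absent from query results (and
#' count as "not in LD" downstream); `r2`/`dprime` are validated to
#' [0, 1].
#'
#' @param x Path to a pairwise LD table, or a data.frame with columns
#'   `SNP_A, SNP_B, R2` and optionally `DP`.
#' @return An object inheriting from `ld_backend`.
#' @export
ld_backend_table <- function(x) {
  dt <- if (is.character(x)) {
    data.table::fread(x, header = TRUE, showProgress = FALSE)
  } else data.table::as.data.table(x)
  need <- c("SNP_A", "SNP_B", "R2")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("ld_backend_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!("DP" %in% names(dt))) dt$DP <- NA_real_
  pairs <- data.table::data.table(a = as.character(dt$SNP_A),
                                  b = as.character(dt$SNP_B),
                                  r2 = as.numeric(dt$R2),
                                  dprime = as.numeric(dt$DP))
  ok <- pairs$r2 >= 0 & pairs$r2 <= 1 &
    (is.na(pairs$dprime) | (pairs$dprime >= 0 & pairs$dprime <= 1))
  if (!all(ok, na.rm = FALSE))
    stop("ld_backend_table: r2/D' outside [0, 1] at row ",
         which(!ok)[1L], call. = FALSE)
  sym <- data.table::data.table(a = pairs$b, b = pairs$a,
                                r2 = pairs$r2, dprime = pairs$dprime)
  pairs <- unique(data.table::rbindlist(list(pairs, sym)))
  if (anyDuplicated(pairs, by = c("a", "b")))
    stop("ld_backend_table: conflicting r2/D' for the same SNP pair",
         call. = FALSE)
  data.table::setkeyv(pairs, c("a", "b"))
  structure(list(pairs = pairs, label = "offline-table"),
            class = c("ld_table_backend", "ld_backend"))
}

#' @rdname ld_backend_table
#' @param url Base URL of an Ensembl-compatible REST service.
#' @param population Population label (e.g. "1000GENOMES:phase_3:EUR").
#' @export
ld_backend_rest <- function(url, population) {
  structure(list(url = url, population = population, label = "rest"),
            class = c("ld_rest_backend", "ld_backend"))
}

ld_unavailable <- function(msg) {
  stop(structure(class = c("ld_backend_unavailable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Query pairwise LD between a lead SNP and candidates
#'
#' @param backend An `ld_backend`.
#' @param lead Lead SNP id.
#' @param candidates Character vector of candidate SNP ids.
#' @return A data.table `(snp_id, r2, dprime)` containing only the
#'   candidates the backend knows; symmetric in lead/candidate.
#' @export
ld_pairs <- function(backend, lead, candidates) UseMethod("ld_pairs")

#' @export
ld_pairs.ld_table_backend <- function(backend, lead, candidates) {
  candidates <- setdiff(unique(as.character(candidates)), lead)
  if (length(candidates) == 0L)
    return(data.table::data.table(snp_id = character(0), r2 = numeric(0),
                                  dprime = numeric(0)))
  hit <- backend$pairs[data.table::CJ(a = lead, b = candidates),
                       on = c("a", "b"), nomatch = NULL]
  data.table::data.table(snp_id = hit$b, r2 = hit$r2, dprime = hit$dprime)
}

#' @export
ld_pairs.ld_rest_backend <- function(backend, lead, candidates) {
  ld_unavailable(paste0("LD REST backend at '", backend$url,
                        "' is unavailable (no network access)"))
}

#' SNPs in LD with a lead SNP, at display thresholds
#'
#' Filters the backend's pairwise values conjunctively: a candidate is a
#' member when `r2 >= r2_min` AND `dprime >= dprime_min` (defaults 0.75
#' and 0.75, the display thresholds for the pop-up list of linked SNPs).
#' A backend row with missing D' passes the D' test only when
#' `dprime_min` is 0. SNPs unknown to the backend are silently absent.
#'
#' @param backend An `ld_backend`.
#' @param lead Lead SNP id.
#' @param candidates Candidate SNP ids in the same segment (the lead is
#'   removed if present).
#' @param r2_min,dprime_min Thresholds in [0, 1] (defaults 0.75).
#' @param significant_ids Optional: the candidates whose association
#'   exceeds the genome-wide significance threshold, used by
#'   [linked_proportion()].
#' @return An `ld_set`: list with `lead`, `members` (data.table snp_id,
#'   r2, dprime), `r2_min`, `dprime_min`, `significant_ids`,
#'   `n_candidates_above_threshold`, `backend_label`.
#' @export
ld_neighbors <- function(backend, lead, candidates, r2_min = 0.75,
                         dprime_min = 0.75, significant_ids = NULL) {
  if (any(c(r2_min, dprime_min) < 0) || any(c(r2_min, dprime_min) > 1))
    stop("ld_neighbors: thresholds must lie in [0, 1]", call. = FALSE)
  candidates <- setdiff(unique(as.character(candidates)), lead)
  pr <- ld_pairs(backend, lead, candidates)
  dp_ok <- if (dprime_min > 0) !is.na(pr$dprime) & pr$dprime >= dprime_min
           else is.na(pr$dprime) | pr$dprime >= 0
  members <- pr[pr$r2 >= r2_min & dp_ok]
  data.table::setorderv(members, "snp_id")
  significant_ids <- unique(as.character(significant_ids))
  structure(list(lead = lead, members = members,
                 r2_min = r2_min, dprime_min = dprime_min,
                 significant_ids = significant_ids,
                 n_candidates_above_threshold = length(significant_ids),
                 backend_label = backend$label),
            class = "ld_set")
}

#' @export
print.ld_set <- function(x, ...) {
  cat("<ld_set> lead ", x$lead, ": ", nrow(x$members),
      " linked SNP(s) at r2 >= ", x$r2_min, " & D' >= ", x$dprime_min,
      " [", x$backend_label, "]\n", sep = "")
  invisible(x)
}

#' Mutual LD SNPs across phenotypes
#'
#' Intersects the linked-SNP sets computed per phenotype for the same
#' region, exposing the SNPs in LD shared between traits.
#'
#' @param sets Named list (phenotype -> `ld_set`), length >= 2.
#' @param positions Optional named vector (snp_id -> bp) used to sort
#'   the result genomically; lexicographic otherwise.
#' @return Character vector of shared SNP ids.
#' @export
mutual_ld <- function(sets, positions = NULL) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("mutual_ld: need LD sets for at least two phenotypes",
         call. = FALSE)
  ids <- lapply(sets, function(s) {
    stopifnot(inherits(s, "ld_set"))
    s$members$snp_id
  })
  shared <- Reduce(intersect, ids)
  if (length(shared) == 0L) return(character(0))
  if (!is.null(positions) && all(shared %in% names(positions)))
    shared[order(positions[shared], shared)]
  else sort(shared)
}

#' Proportion of significant SNPs linked to the lead
#'
#' The pop-up reports the number of SNPs in LD with the segment's top
#' SNP and the total number of SNPs above the significance threshold;
#' their ratio is the proportion of linked SNPs with genome-wide
#' significance. With zero SNPs above the threshold the proportion is
#' undefined and `NA` is returned (never 0).
#'
#' @param set An `ld_set` built with `significant_ids`.
#' @return A number in [0, 1], or `NA_real_` when undefined.
#' @export
linked_proportion <- function(set) {
  stopifnot(inherits(set, "ld_set"))
  n <- set$n_candidates_above_threshold
  if (is.null(n) || n == 0L) return(NA_real_)
  length(intersect(set$members$snp_id, set$significant_ids)) / n
}

#' Recursive LD thinning (clumping from summary statistics)
#'
#' Exposes independent signals buried in a segment, without genotypes:
#' the most significant record is taken as the first lead; every record
#' in LD with it (both thresholds, `>=`) is removed along with the lead;
#' the next lead is the maximum of the remainder; and so on until
#' `depth` leads are found or the segment is exhausted. Removal applies
#' to all in-segment records in LD with the lead, significant or not.
#' By construction no output lead is in LD (per the backend) with any
#' earlier one.
#'
#' @param records data.table of in-segment records for one phenotype
#'   (columns snp_id, pos, neglog10p at least).
#' @param backend An `ld_backend`.
#' @param depth Maximum number of leads (>= 1).
#' @param r2_min,dprime_min LD removal thresholds (defaults 0.75).
#' @return data.table of lead records in discovery order, with an
#'   `ld_error` attribute set to the condition message if the backend
#'   failed mid-recursion (the result is then partial).
#' @export
thin_snps <- function(records, backend, depth = 1L, r2_min = 0.75,
                      dprime_min = 0.75) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L)
    stop("thin_snps: 'records' must be non-empty", call. = FALSE)
  if (depth < 1L) stop("thin_snps: 'depth' must be >= 1", call. = FALSE)
  remaining <- peak_order(data.table::copy(records))
  leads <- vector("list", depth)
  err <- NULL
  k <- 0L
  while (k < depth && nrow(remaining) > 0L) {
    k <- k + 1L
    lead <- remaining[1L]
    leads[[k]] <- lead
    remaining <- remaining[-1L]
    if (nrow(remaining) == 0L) break
    linked <- tryCatch(
      ld_neighbors(backend, lead$snp_id, remaining$snp_id,
                   r2_min, dprime_min)$members$snp_id,
      ld_backend_unavailable = function(e) e)
    if (inherits(linked, "condition")) { err <- conditionMessage(linked); break }
    remaining <- remaining[!(remaining$snp_id %in% linked)]
  }
  out <- data.table::rbindlist(leads[seq_len(k)])
  if (!is.null(err)) data.table::setattr(out, "ld_error", err)
  out[]
}

#' Concordance category of a reported SNP against the displayed lead
#'
#' Reproduces the locus-level concordance audit used to validate the
#' landscape against published lead SNPs. Within the segment containing
#' both SNPs:
#'
#' * `"A"` -- the reported SNP is exactly the SNP the landscape
#'   displays (the segment's most significant record);
#' * `"B"` -- the reported SNP is in LD with the displayed SNP at
#'   strictly `r2 > 0.75` and `D' > 0.75`;
#' * `"C"` with a level `k` -- neither, but recursive thinning to depth
#'   `depth_max` surfaces the reported SNP (or a SNP in strict LD with
#'   it) as the k-th independent lead;
#' * `"unmatched"` -- none of the above, or the reported SNP is absent
#'   from the records and unknown to the backend.
#'
#' @param reported_snp SNP id reported externally (e.g. by a
#'   consortium).
#' @param segment_cell The displayed record for this (segment,
#'   phenotype): one row as stored in a `bin_peak_grid` cell.
#' @param records All in-segment records for the phenotype.
#' @param backend An `ld_backend`.
#' @param depth_max Thinning depth bound for category C (default 3).
#' @param r2_min,dprime_min Strict thresholds for B/C matching
#'   (defaults 0.75; compared with `>`).
#' @return List with `category` ("A", "B", "C" or "unmatched"), `level`
#'   (integer depth for C, `NA` otherwise), and `reason` for unmatched.
#' @export
categorize_locus <- function(reported_snp, segment_cell, records, backend,
                             depth_max = 3L, r2_min = 0.75,
                             dprime_min = 0.75) {
  records <- data.table::as.data.table(records)
  cell_id <- if (is.list(segment_cell) || is.data.frame(segment_cell))
    segment_cell$snp_id else as.character(segment_cell)
  if (identical(reported_snp, cell_id))
    return(list(category = "A", level = NA_integer_, reason = NULL))
  strict_ld <- function(a, b) {
    pr <- tryCatch(ld_pairs(backend, a, b),
                   ld_backend_unavailable = function(e) NULL)
    if (is.null(pr) || nrow(pr) == 0L) return(FALSE)
    any(pr$r2 > r2_min & !is.na(pr$dprime) & pr$dprime > dprime_min)
  }
  known_pairs <- tryCatch(ld_pairs(backend, reported_snp, records$snp_id),
                          ld_backend_unavailable = function(e) NULL)
  known <- reported_snp %in% records$snp_id ||
    (!is.null(known_pairs) && nrow(known_pairs) > 0L)
  if (!known)
    return(list(category = "unmatched", level = NA_integer_,
                reason = "reported SNP absent from records and unknown to the LD backend"))
  if (strict_ld(reported_snp, cell_id))
    return(list(category = "B", level = NA_integer_, reason = NULL))
  leads <- thin_snps(records, backend, depth = depth_max,
                     r2_min = r2_min, dprime_min = dprime_min)
  for (k in seq_len(nrow(leads))) {
    if (identical(leads$snp_id[k], reported_snp) ||
        strict_ld(reported_snp, leads$snp_id[k]))
      return(list(category = "C", level = as.integer(k), reason = NULL))
  }
  list(category = "unmatched", level = NA_integer_,
       reason = "not the displayed SNP, not in LD with it, not surfaced by thinning")
}
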