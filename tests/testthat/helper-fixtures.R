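# In-code fixtures shared across test files. Nothing here is read from
# disk except files the helpers themselves write to tempdirs.

toy_records <- function(phenotype, snp_id, chrom, pos, neglog10p,
                        effect = NA_real_, se = NA_real_,
                        allele1 = NA_character_, allele2 = NA_character_) {
  n <- max(lengths(list(snp_id, chrom, pos, neglog10p)))
  data.table::data.table(
    phenotype = rep_len(phenotype, n),
    snp_id = rep_len(snp_id, n),
    chrom = as.integer(rep_len(chrom, n)),
    pos = as.integer(rep_len(pos, n)),
    neglog10p = rep_len(neglog10p, n),
    effect = rep_len(effect, n),
    effect_type = "beta",
    se = rep_len(se, n),
    allele1 = rep_len(allele1, n),
    allele2 = rep_len(allele2, n))
}

toy_table <- function(...) {
  recs <- data.table::rbindlist(list(...))
  harmonize(split(recs, recs$phenotype))
}

# random landscape fixture for property tests
random_table <- function(seed, n_per_ph = 200L,
                         phenos = c("P1", "P2", "P3"),
                         chroms = 1:4, max_pos = 5e6, nl_max = 12) {
  set.seed(seed)
  recs <- lapply(phenos, function(p) {
    toy_records(p,
                snp_id = sprintf("rs_%s_%d", p, seq_len(n_per_ph)),
                chrom = sample(chroms, n_per_ph, TRUE),
                pos = sample.int(max_pos, n_per_ph),
                neglog10p = round(runif(n_per_ph, 0, nl_max), 4),
                effect = round(rnorm(n_per_ph, 0, 0.1), 4))
  })
  harmonize(recs, phenos)
}

# brute-force per-(group, phenotype) peak with the package's tie rule
naive_peaks <- function(df, group_col) {
  df <- as.data.frame(df)
  out <- list()
  for (g in unique(df[[group_col]])) {
    for (p in unique(df$phenotype)) {
      s <- df[df[[group_col]] == g & df$phenotype == p, , drop = FALSE]
      if (nrow(s) == 0L) next
      s <- s[s$neglog10p == max(s$neglog10p), , drop = FALSE]
      s <- s[s$pos == min(s$pos), , drop = FALSE]
      s <- s[order(s$snp_id), , drop = FALSE]
      out[[length(out) + 1L]] <- s[1L, , drop = FALSE]
    }
  }
  do.call(rbind, out)
}

write_summary_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

default_map <- function(...) {
  column_map(snp_id = "SNP", chrom = "CHR", pos = "BP", p = "P", ...)
}

# one shared synthetic dataset (seed 1), built lazily and cached
.sim_cache <- new.env(parent = emptyenv())
get_sim <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- simulate_summary(seed = seed)
    recs <- lapply(names(sim$files), function(p)
      read_summary_file(sim$files[[p]], sim$column_map, p))
    sim$table <- harmonize(recs, sim$phenotypes)
    sim$backend <- ld_backend_table(sim$ld_table)
    .sim_cache[[key]] <- sim
  }
  .sim_cache[[key]]
}

segment_records <- function(table, chrom_q, phen, segment_q, width = 1e6) {
  dt <- data.table::as.data.table(table)
  keep <- dt$chrom == chrom_q & dt$phenotype == phen &
    floor((dt$pos - 1) / width) == segment_q
  dt[keep]
}
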