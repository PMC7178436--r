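test_that("sectional filter is the half-open restriction [lo, hi)", {
  tab <- random_table(7, n_per_ph = 100L, nl_max = 150)
  expect_equal(nrow(sectional_filter(tab, stratum(0, Inf))), nrow(tab))
  top <- sectional_filter(tab, stratum(100))
  expect_true(all(top$neglog10p >= 100))
  expect_equal(nrow(top), sum(tab$neglog10p >= 100))
  # disjoint cover partitions the table
  lo <- sectional_filter(tab, stratum(0, 10))
  hi <- sectional_filter(tab, stratum(10, Inf))
  expect_equal(nrow(lo) + nrow(hi), nrow(tab))
  expect_length(intersect(paste(lo$phenotype, lo$snp_id),
                          paste(hi$phenotype, hi$snp_id)), 0)
  expect_error(stratum(5, 5), "lo < hi")
  expect_error(stratum(-1, 2), ">= 0")
})

test_that("genome peaks take the per-chromosome maximum with deterministic ties", {
  tab <- toy_table(toy_records("A", c("rs1", "rs2", "rs3"), 1,
                               c(100, 200, 300), c(3, 7, 5)))
  gp <- genome_peaks(tab)
  expect_equal(nrow(gp), 1L)
  expect_equal(gp$snp_id, "rs2")
  # tie: smaller position wins
  tie <- toy_table(toy_records("A", c("rsB", "rsA"), 2, c(10, 20), c(7, 7)))
  expect_equal(genome_peaks(tie)$pos, 10L)
  # equal position too: lexicographically smaller id wins
  tie2 <- toy_table(toy_records("A", c("rsZ", "rsA"), 2, c(10, 10), c(7, 7)))
  expect_equal(genome_peaks(tie2)$snp_id, "rsA")
  expect_error(genome_peaks(toy_table(toy_records("A", "rs1", 1, 1, 1))[0]),
               "empty")
})

test_that("genome peaks recover every planted per-chromosome maximum", {
  sim <- get_sim()
  gp <- genome_peaks(sim$table)
  expect_equal(nrow(gp), 22L * length(sim$phenotypes))
  for (lo in sim$truth) {
    for (i in seq_along(lo$phenotypes)) {
      keep <- gp$chrom == lo$chrom & gp$phenotype == lo$phenotypes[i]
      cell <- as.data.frame(gp)[keep, ]
      expect_equal(cell$snp_id, lo$lead_id)
      expect_equal(cell$neglog10p, lo$neglog10p[i])
    }
  }
})

test_that("segment retention applies the strict > threshold_min rule", {
  tab <- toy_table(
    toy_records("A", c("rs1", "rs2"), 5, c(100, 1e6 + 100), c(6.2, 5.9)))
  grid <- chromosome_peaks(tab, 5, fixed_bins(), threshold_min = 6)
  expect_equal(retained_segments(grid), 0L)
  expect_equal(nrow(grid$cells), 1L)
  # exactly at the threshold is not retained (strict comparison)
  tab2 <- toy_table(toy_records("A", "rs1", 5, 100, 6))
  suppressMessages(
    grid2 <- chromosome_peaks(tab2, 5, fixed_bins(), threshold_min = 6))
  expect_length(retained_segments(grid2), 0)
  expect_equal(nrow(grid2$cells), 0L)
})

test_that("sub-floor phenotype cells are kept inside retained segments", {
  tab <- toy_table(
    toy_records("A", "rs_hi", 3, 500, 9),
    toy_records("B", "rs_lo", 3, 700, 2.5))
  grid <- chromosome_peaks(tab, 3)
  expect_equal(retained_segments(grid), 0L)
  expect_equal(sort(grid$cells$snp_id), c("rs_hi", "rs_lo"))
})

test_that("grid cells equal a naive filtered scan on random fixtures", {
  for (seed in c(11, 12, 13)) {
    tab <- random_table(seed, n_per_ph = 400L, chroms = 1:3)
    for (ch in 1:3) {
      suppressMessages(
        grid <- chromosome_peaks(tab, ch, fixed_bins(), threshold_min = 6))
      df <- as.data.frame(tab)
      df <- df[df$chrom == ch, ]
      df$segment <- floor((df$pos - 1) / 1e6)
      naive <- naive_peaks(df, "segment")
      seg_keep <- unique(naive$segment[
        vapply(naive$segment, function(s)
          max(naive$neglog10p[naive$segment == s]) > 6, TRUE)])
      expect_setequal(retained_segments(grid), seg_keep)
      naive <- naive[naive$segment %in% seg_keep, ]
      got <- as.data.frame(grid$cells[, c("segment", "phenotype", "snp_id",
                                          "neglog10p")])
      want <- naive[order(naive$segment, naive$phenotype),
                    c("segment", "phenotype", "snp_id", "neglog10p")]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("raising the floor or shrinking the stratum never adds signal", {
  tab <- random_table(21, n_per_ph = 300L, chroms = 1:2)
  g6 <- suppressMessages(chromosome_peaks(tab, 1, threshold_min = 6))
  g8 <- suppressMessages(chromosome_peaks(tab, 1, threshold_min = 8))
  expect_true(all(retained_segments(g8) %in% retained_segments(g6)))
  full <- suppressMessages(chromosome_peaks(tab, 1, strat = stratum(0, Inf)))
  narrow <- suppressMessages(chromosome_peaks(tab, 1, strat = stratum(0, 9)))
  shared <- merge(full$cells[, c("segment", "phenotype", "neglog10p")],
                  narrow$cells[, c("segment", "phenotype", "neglog10p")],
                  by = c("segment", "phenotype"))
  expect_true(all(shared$neglog10p.y <= shared$neglog10p.x))
})

test_that("disjoint strata merged by max reproduce the unstratified grid", {
  tab <- random_table(31, n_per_ph = 400L, chroms = 1:2, nl_max = 15)
  whole <- suppressMessages(chromosome_peaks(tab, 2))
  parts <- lapply(list(stratum(0, 4), stratum(4, 9), stratum(9, Inf)),
                  function(s) suppressMessages(
                    chromosome_peaks(tab, 2, strat = s))$cells)
  merged <- data.table::rbindlist(parts)
  data.table::setorderv(merged, c("neglog10p", "pos", "snp_id"),
                        order = c(-1L, 1L, 1L))
  merged <- merged[!duplicated(merged, by = c("segment", "phenotype"))]
  # the merged per-cell max must agree on every cell of the whole grid
  cmp <- merge(whole$cells[, c("segment", "phenotype", "snp_id", "neglog10p")],
               merged[, c("segment", "phenotype", "snp_id", "neglog10p")],
               by = c("segment", "phenotype"))
  expect_equal(nrow(cmp), nrow(whole$cells))
  expect_equal(cmp$snp_id.x, cmp$snp_id.y)
  expect_equal(cmp$neglog10p.x, cmp$neglog10p.y)
})

test_that("retained segments come back in genomic order from planted truth", {
  sim <- get_sim()
  planted_chr19 <- sort(unique(vapply(
    Filter(function(lo) lo$chrom == 19, sim$truth), `[[`, 0L, "segment")))
  grid <- chromosome_peaks(sim$table, 19)
  expect_equal(retained_segments(grid), planted_chr19)
  expect_false(is.unsorted(retained_segments(grid)))
  grid_tsv <- tempfile(fileext = ".tsv")
  write_grid(grid, grid_tsv)
  expect_equal(nrow(data.table::fread(grid_tsv)), nrow(grid$cells))
})
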