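# small in-memory LD world: lead1 with satellites s1..s4, lead2 with s5
toy_ld <- function() {
  ld_backend_table(data.frame(
    SNP_A = c("lead1", "lead1", "lead1", "lead1", "lead2", "lead1"),
    SNP_B = c("s1",    "s2",    "s3",    "s4",    "s5",    "lead2"),
    R2    = c(0.90,    0.80,    0.80,    0.40,    0.95,    0.05),
    DP    = c(0.95,    0.85,    0.50,    0.90,    0.97,    0.10)))
}

test_that("ld_neighbors filters conjunctively on r2 AND D'", {
  be <- toy_ld()
  set <- ld_neighbors(be, "lead1", c("s1", "s2", "s3", "s4", "unknown"))
  expect_equal(set$members$snp_id, c("s1", "s2"))  # s3 fails D', s4 fails r2
  expect_false("lead1" %in% set$members$snp_id)
  # degenerate thresholds keep everything the backend knows
  all_known <- ld_neighbors(be, "lead1", c("s1", "s2", "s3", "s4", "unknown"),
                            r2_min = 0, dprime_min = 0)
  expect_equal(all_known$members$snp_id, c("s1", "s2", "s3", "s4"))
  expect_error(ld_neighbors(be, "lead1", "s1", r2_min = 1.2), "\\[0, 1\\]")
})

test_that("offline backend queries are symmetric and idempotent", {
  be <- toy_ld()
  ab <- ld_pairs(be, "lead1", "s1")
  ba <- ld_pairs(be, "s1", "lead1")
  expect_equal(ab$r2, ba$r2)
  expect_equal(ab$dprime, ba$dprime)
  expect_identical(ld_pairs(be, "lead1", c("s1", "s2")),
                   ld_pairs(be, "lead1", c("s1", "s2")))
  expect_equal(nrow(ld_pairs(be, "lead1", character(0))), 0L)
  expect_error(ld_backend_table(data.frame(SNP_A = "a", SNP_B = "b",
                                           R2 = 1.7)), "\\[0, 1\\]")
})

test_that("mutual LD intersects member sets across phenotypes", {
  be <- ld_backend_table(data.frame(
    SNP_A = rep(c("L1", "L2", "L3"), each = 3),
    SNP_B = c("a", "b", "c", "b", "c", "d", "x", "c", "b"),
    R2 = 0.9, DP = 0.9))
  s1 <- ld_neighbors(be, "L1", c("a", "b", "c", "d"))
  s2 <- ld_neighbors(be, "L2", c("a", "b", "c", "d"))
  s3 <- ld_neighbors(be, "L3", c("a", "b", "c", "d", "x"))
  expect_equal(mutual_ld(list(P1 = s1, P2 = s2)), c("b", "c"))
  expect_equal(mutual_ld(list(P1 = s1, P2 = s2, P3 = s3)), c("b", "c"))
  # genomic ordering when positions are supplied
  expect_equal(mutual_ld(list(P1 = s1, P2 = s2), positions = c(b = 500, c = 10)),
               c("c", "b"))
  disjoint <- ld_neighbors(be, "L2", "d")
  expect_length(mutual_ld(list(P1 = s1, P2 = disjoint)), 0)
  expect_error(mutual_ld(list(P1 = s1)), "two")
})

test_that("linked proportion is |linked ∩ significant| / n_significant", {
  be <- toy_ld()
  set <- ld_neighbors(be, "lead1", c("s1", "s2", "s3", "s4"),
                      significant_ids = c("s1", "s3", paste0("g", 1:8)))
  # members {s1, s2}; significant 10; linked & significant = {s1}
  expect_equal(linked_proportion(set), 1 / 10)
  all_linked <- ld_neighbors(be, "lead1", c("s1", "s2"),
                             significant_ids = c("s1", "s2"))
  expect_equal(linked_proportion(all_linked), 1)
  none <- ld_neighbors(be, "lead1", "s1", significant_ids = character(0))
  expect_true(is.na(linked_proportion(none)))  # undefined, not 0
})

test_that("thinning at depth 1 is the segment maximum; exhaustion stops early", {
  recs <- toy_records("P", c("lead1", "s1", "s2", "lead2", "s5"),
                      1, c(100, 200, 300, 400, 500),
                      c(20, 15, 14, 18, 12))
  be <- toy_ld()
  d1 <- thin_snps(recs, be, depth = 1)
  expect_equal(d1$snp_id, "lead1")
  d2 <- thin_snps(recs, be, depth = 2)
  expect_equal(d2$snp_id, c("lead1", "lead2"))
  # s3/s4-free world: everything is linked to one of the two leads,
  # so depth 5 exhausts after the two independent signals
  d5 <- thin_snps(recs, be, depth = 5)
  expect_equal(d5$snp_id, c("lead1", "lead2"))
  expect_error(thin_snps(recs[0], be, 1), "non-empty")
  expect_error(thin_snps(recs, be, 0), ">= 1")
})

test_that("thinning leads are pairwise non-linked and match planted truth", {
  sim <- get_sim()
  lo <- Filter(function(l) !is.null(l$secondary), sim$truth)[[1]]
  ph <- lo$secondary$phenotypes[1]
  recs <- segment_records(sim$table, lo$chrom, ph, lo$segment)
  leads <- thin_snps(recs, sim$backend, depth = 2)
  expect_equal(leads$snp_id, c(lo$lead_id, lo$secondary$snp_id))
  deep <- thin_snps(recs, sim$backend, depth = 3)
  for (i in seq_len(nrow(deep) - 1L)) {
    for (j in seq(i + 1L, nrow(deep))) {
      pr <- ld_pairs(sim$backend, deep$snp_id[i], deep$snp_id[j])
      expect_true(nrow(pr) == 0L ||
                    all(pr$r2 < 0.75 | pr$dprime < 0.75))
    }
  }
  # depth 1 equals the landscape module's per-segment cell
  grid <- chromosome_peaks(sim$table, lo$chrom)
  keep <- grid$cells$segment == lo$segment & grid$cells$phenotype == ph
  expect_equal(thin_snps(recs, sim$backend, 1)$snp_id,
               grid$cells$snp_id[keep])
})

test_that("concordance categories follow the A / B / C(depth) ladder", {
  sim <- get_sim()
  lo <- Filter(function(l) !is.null(l$secondary), sim$truth)[[1]]
  ph <- lo$secondary$phenotypes[1]
  recs <- segment_records(sim$table, lo$chrom, ph, lo$segment)
  grid <- chromosome_peaks(sim$table, lo$chrom)
  keep <- grid$cells$segment == lo$segment & grid$cells$phenotype == ph
  cell <- grid$cells[keep]
  expect_equal(cell$snp_id, lo$lead_id)

  expect_equal(categorize_locus(lo$lead_id, cell, recs,
                                sim$backend)$category, "A")
  strong <- lo$satellites$snp_id[lo$satellites$strong]
  for (s in strong)
    expect_equal(categorize_locus(s, cell, recs, sim$backend)$category, "B")
  cc <- categorize_locus(lo$secondary$snp_id, cell, recs, sim$backend)
  expect_equal(cc$category, "C")
  expect_equal(cc$level, 2L)
  # secondary's own satellites surface through LD with the depth-2 lead
  sat2 <- lo$secondary$satellites$snp_id[1]
  cc2 <- categorize_locus(sat2, cell, recs, sim$backend)
  expect_equal(cc2$category, "C")
  expect_equal(cc2$level, 2L)
  un <- categorize_locus("rs_not_anywhere", cell, recs, sim$backend)
  expect_equal(un$category, "unmatched")
  expect_match(un$reason, "unknown")
})

test_that("every in-segment record falls into exactly one category", {
  sim <- get_sim()
  lo <- Filter(function(l) !is.null(l$secondary), sim$truth)[[1]]
  ph <- lo$secondary$phenotypes[1]
  recs <- segment_records(sim$table, lo$chrom, ph, lo$segment)
  grid <- chromosome_peaks(sim$table, lo$chrom)
  keep <- grid$cells$segment == lo$segment & grid$cells$phenotype == ph
  cell <- grid$cells[keep]
  cats <- vapply(recs$snp_id, function(s)
    categorize_locus(s, cell, recs, sim$backend)$category, "")
  expect_true(all(cats %in% c("A", "B", "C", "unmatched")))
  expect_equal(sum(cats == "A"), 1L)
})

test_that("the REST backend raises a typed unavailability error", {
  be <- ld_backend_rest("https://rest.example.org", "EUR")
  expect_error(ld_pairs(be, "rs1", "rs2"),
               class = "ld_backend_unavailable")
  recs <- toy_records("P", c("a", "b"), 1, c(1, 2), c(9, 8))
  out <- thin_snps(recs, be, depth = 2)
  expect_equal(out$snp_id, "a")  # partial result, flagged
  expect_match(attr(out, "ld_error"), "unavailable")
})
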