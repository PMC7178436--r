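test_that("parse_pvalue handles printed extremes beyond double underflow", {
  # frozen against an arbitrary-precision oracle: -log10(m 10^-k) = k - log10(m)
  expect_equal(parse_pvalue("1.0"), 0)
  expect_equal(parse_pvalue("9.7e-26"), 25.013228265733755, tolerance = 1e-12)
  expect_equal(parse_pvalue("1.6e-320"), 319.79588001734408, tolerance = 1e-12)
  expect_equal(parse_pvalue("1.4e-66"), 65.853871964321762, tolerance = 1e-12)
  expect_true(is.finite(parse_pvalue("1e-350")))
  expect_equal(parse_pvalue("0.05"), -log10(0.05))
})

test_that("parse_pvalue agrees with the mantissa/exponent oracle to 1e-9", {
  for (m in c("1.0", "1.6", "9.7")) {
    expos <- c(1:35 * 10, 1:9)
    got <- parse_pvalue(sprintf("%se-%d", m, expos))
    oracle <- expos - log10(as.numeric(m))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("parse_pvalue rejects invalid probabilities and flags the element", {
  expect_error(parse_pvalue(c("0.5", "0")), "element 2")
  expect_error(parse_pvalue("-0.1"), "negative")
  expect_error(parse_pvalue("1.5"), "> 1")
  expect_true(is.na(parse_pvalue("not-a-number")))
  # already -log10 scale passes through
  expect_equal(parse_pvalue(c("7.25", "0"), p_scale = "neglog10"), c(7.25, 0))
  expect_error(parse_pvalue("-3", p_scale = "neglog10"), "negative")
})

test_that("read_summary_file parses, filters non-autosomes and counts drops", {
  path <- write_summary_fixture(c(
    "SNP\tCHR\tBP\tP",
    "rs1\t1\t100\t0.5",
    "rs2\tchr19\t45411941\t1.6e-320",
    "rs3\t2\t2000\t9.7e-26"))
  rec <- read_summary_file(path, default_map(), "HDL")
  expect_equal(nrow(rec), 3L)
  expect_equal(unique(rec$phenotype), "HDL")
  expect_equal(rec$chrom, c(1L, 2L, 19L))
  expect_equal(rec$neglog10p[rec$snp_id == "rs2"], 319.79588001734408,
               tolerance = 1e-9)
  expect_true(all(is.na(rec$effect)))
  expect_equal(attr(rec, "drop_counts"),
               c(nonautosomal = 0L, unparseable = 0L, duplicate = 0L))

  path2 <- write_summary_fixture(c(
    "SNP\tCHR\tBP\tP",
    "rs1\t1\t100\t0.5",
    "rsX\tX\t100\t0.5",
    "rsbad\t2\tnot_a_pos\t0.5"))
  rec2 <- read_summary_file(path2, default_map(), "HDL")
  expect_equal(nrow(rec2), 1L)
  dc <- attr(rec2, "drop_counts")
  expect_equal(dc[["nonautosomal"]], 1L)
  expect_equal(dc[["unparseable"]], 1L)
})

test_that("duplicate (snp_id, chrom, pos) keeps the more significant row", {
  path <- write_summary_fixture(c(
    "SNP\tCHR\tBP\tP",
    "rs1\t1\t100\t0.5",
    "rs1\t1\t100\t1e-8"))
  expect_warning(rec <- read_summary_file(path, default_map(), "T"),
                 "duplicate")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$neglog10p, 8)
  expect_equal(attr(rec, "drop_counts")[["duplicate"]], 1L)
})

test_that("missing mapped columns and empty files are configuration errors", {
  path <- write_summary_fixture(c("SNP\tCHR\tBP\tQ", "rs1\t1\t100\t0.5"))
  expect_error(read_summary_file(path, default_map(), "T"), "'P'")
  empty <- write_summary_fixture("SNP\tCHR\tBP\tP")
  expect_error(read_summary_file(empty, default_map(), "T"), "no data rows")
  expect_error(column_map(snp_id = "SNP", chrom = "CHR", pos = "BP",
                          p = NULL), "required field 'p'")
})

test_that("harmonize concatenates, orders and preserves the phenotype axis", {
  shared <- toy_records("A", sprintf("rs%d", 1:5), 1, 1:5 * 100,
                        c(1, 2, 3, 4, 5))
  extra <- toy_records("B", sprintf("rs%d", 1:7), 1, 1:7 * 100, 1)
  tab <- toy_table(shared, extra)
  expect_equal(nrow(tab), 12L)
  expect_equal(phenotypes(tab), c("A", "B"))
  # explicit order is respected even against alphabetical
  tab2 <- harmonize(list(shared, extra), phenotype_order = c("B", "A"))
  expect_equal(phenotypes(tab2), c("B", "A"))
  expect_true(!is.unsorted(tab$chrom))
  # single-phenotype identity
  one <- harmonize(list(shared))
  expect_equal(nrow(one), nrow(shared))
  expect_equal(one$snp_id, shared$snp_id)
  expect_error(harmonize(list(shared, shared)), "duplicate phenotype")
})

test_that("canonical TSV round-trip reproduces the table field-for-field", {
  tab <- random_table(42, n_per_ph = 40L)
  path <- tempfile(fileext = ".tsv")
  write_landscape(tab, path)
  back <- read_landscape(path, phenotype_order = phenotypes(tab))
  expect_equal(phenotypes(back), phenotypes(tab))
  for (col in c("phenotype", "snp_id", "chrom", "pos", "neglog10p",
                "effect", "se"))
    expect_equal(back[[col]], tab[[col]], info = col)
})

test_that("ingest conserves records: in = out + counted drops", {
  sim <- get_sim()
  for (p in sim$phenotypes) {
    n_in <- length(readLines(sim$files[[p]])) - 1L
    rec <- read_summary_file(sim$files[[p]], sim$column_map, p)
    expect_equal(nrow(rec) + sum(attr(rec, "drop_counts")), n_in)
    expect_equal(sum(attr(rec, "drop_counts")), 0L)
  }
  expect_equal(nrow(sim$table),
               sum(vapply(sim$phenotypes, function(p)
                 length(readLines(sim$files[[p]])) - 1L, 0L)))
})
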