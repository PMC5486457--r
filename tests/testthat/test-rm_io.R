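make_out_file <- function(lines) {
  f <- tempfile(fileext = ".out")
  writeLines(c("header line 1", "header line 2", "", lines), f)
  f
}

test_that("parser echoes fields and normalises the C-strand dialect", {
  f <- make_out_file(c(
    "463 10.0 0.0 0.0 chr1 1001 1500 (8500) + CR1-X LINE/CR1 1 500 (0) 1",
    "463 10.0 0.0 0.0 chr1 2001 2500 (7500) C CR1-X LINE/CR1 (0) 500 1 2 *"
  ))
  rec <- parse_repeatmasker_out(f)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$sw_score, c(463L, 463L))
  expect_equal(rec$divergence_percent, c(10, 10))
  expect_equal(rec$query_name, c("chr1", "chr1"))
  expect_equal(rec$query_begin, c(1001L, 2001L))
  expect_equal(rec$query_end, c(1500L, 2500L))
  expect_equal(rec$strand, c("+", "-"))
  expect_equal(rec$repeat_class_family, c("LINE/CR1", "LINE/CR1"))
  # C-strand repeat coordinates (left) end begin are reordered, not mangled
  expect_equal(rec$repeat_begin, c(1L, 1L))
  expect_equal(rec$repeat_end, c(500L, 500L))
  expect_equal(rec$overlap_flag, c(FALSE, TRUE))
})

test_that("malformed lines are rejected naming the line number", {
  f <- make_out_file("463 10.0 0.0 chr1 1001")
  expect_error(parse_repeatmasker_out(f), "line 4")
  f2 <- make_out_file(
    "463 xx 0.0 0.0 chr1 1001 1500 (8500) + CR1-X LINE/CR1 1 500 (0) 1")
  expect_error(parse_repeatmasker_out(f2), "line 4")
})

test_that("records outside the Jukes-Cantor domain are dropped with warning", {
  f <- make_out_file(c(
    "463 10.0 0.0 0.0 chr1 1001 1500 (8500) + CR1-X LINE/CR1 1 500 (0) 1",
    "463 80.0 0.0 0.0 chr1 2001 2500 (7500) + CR1-X LINE/CR1 1 500 (0) 2"
  ))
  expect_warning(rec <- parse_repeatmasker_out(f), "75")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$query_begin, 1001L)
})

test_that("parse -> write -> parse is the identity on all stored fields", {
  set.seed(5)
  sim <- simulate_genome(simulation_config(seed = 5))
  f <- tempfile(fileext = ".out")
  write_repeatmasker_out(sim$records, f, genome = sim$genome_index)
  rec2 <- parse_repeatmasker_out(f)
  expect_identical(sim$records, rec2)
  # second trip is byte-stable too
  f2 <- tempfile(fileext = ".out")
  write_repeatmasker_out(rec2, f2, genome = sim$genome_index)
  expect_identical(readLines(f), readLines(f2))
})

test_that("classification maps class/family strings per the TE taxonomy", {
  got <- classify_family(c("LINE/CR1", "LINE/L2", "LINE/R2", "LINE/RTE-BovB",
                           "LTR/ERVL-MaLR", "LTR/ERVK", "LTR/ERV1",
                           "SINE/tRNA", "DNA/hAT-Charlie", "FooBar"))
  expect_equal(got$te_type,
               c("LINE", "LINE", "LINE", "LINE", "LTR", "LTR", "LTR",
                 "SINE", "DNA", "Unclassified"))
  expect_equal(got$clade,
               c("CR1", "OtherLINE", "R2", "RTE", "ERV3", "ERV2", "ERV1",
                 "None", "None", "None"))
})

test_that("classification is total and deterministic on arbitrary strings", {
  set.seed(99)
  junk <- replicate(50, paste(sample(c(LETTERS, "/", "-", "?"), 8, TRUE),
                              collapse = ""))
  a <- classify_family(junk)
  b <- classify_family(junk)
  expect_identical(a, b)
  expect_equal(nrow(a), 50)
  expect_true(all(!is.na(a$te_type)) && all(!is.na(a$clade)))
})

test_that("the shipped taxonomy file loads and matches the built-in rules", {
  f <- system.file("extdata", "taxonomy.tsv", package = "telandscape")
  expect_true(nzchar(f))
  tax <- read_taxonomy(f)
  expect_equal(tax, default_taxonomy())
})

test_that("FASTA round trip preserves ids and upper-cases sequences", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b desc ignored", "acgtn"), f)
  lib <- read_fasta(f)
  expect_equal(names(lib), c("a", "b"))
  expect_equal(as.character(lib), c(a = "ACGT", b = "ACGTN"))
  f2 <- tempfile(fileext = ".fa")
  write_fasta(lib, f2)
  expect_equal(as.character(read_fasta(f2)), as.character(lib))
  # duplicate identifiers are an error
  f3 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f3)
  expect_error(read_fasta(f3), "duplicate")
})
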