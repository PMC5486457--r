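test_that("the higher-scoring record claims shared bases", {
  rec <- repeat_records(sw_score = c(500L, 400L), divergence_percent = c(5, 6),
                        query_name = "chr1",
                        query_begin = c(1001L, 1401L),
                        query_end = c(1500L, 1900L),
                        strand = "+", repeat_name = c("A", "B"),
                        repeat_class_family = "LINE/CR1")
  pieces <- resolve_overlaps(rec)
  expect_equal(pieces$start, c(1001L, 1501L))
  expect_equal(pieces$end, c(1500L, 1900L))
  expect_equal(pieces$record, c(1L, 2L))
  expect_equal(sum(pieces$end - pieces$start + 1), 900)
})

test_that("non-overlapping records pass through unchanged", {
  rec <- repeat_records(sw_score = c(100L, 200L), divergence_percent = 5,
                        query_name = "chr1",
                        query_begin = c(10L, 500L), query_end = c(100L, 700L),
                        strand = "+", repeat_name = c("A", "B"),
                        repeat_class_family = "LINE/CR1")
  pieces <- resolve_overlaps(rec)
  expect_equal(pieces$start, rec$query_begin)
  expect_equal(pieces$end, rec$query_end)
})

test_that("overlap resolution equals a per-base sweep on random records", {
  set.seed(31)
  for (rep in 1:10) {
    gi <- c(chrT = sample(5000:10000, 1))
    rec <- random_records(sample(5:25, 1), gi[["chrT"]])
    pieces <- resolve_overlaps(rec, genome = gi)
    got <- integer(nrow(rec))
    agg <- tapply(pieces$end - pieces$start + 1, pieces$record, sum)
    got[as.integer(names(agg))] <- as.integer(agg)
    expect_identical(got, brute_coverage_bp(rec, gi))
  }
})

test_that("a single 500 bp CR1 record on a 10 kb genome covers 5.00%", {
  rec <- repeat_records(463L, 10, "chr1", 1001L, 1500L, "+", "CR1-X",
                        "LINE/CR1")
  rep <- coverage_report(rec, c(chr1 = 10000))
  cr1 <- rep[rep$level == "clade" & rep$clade == "CR1", ]
  expect_equal(cr1$covered_bp, 500)
  expect_equal(cr1$covered_percent, 5)
  expect_equal(rep$covered_bp[rep$level == "total"], 500)
})

test_that("coverage is conservative, hierarchical and order-invariant", {
  set.seed(77)
  for (rep_i in 1:8) {
    gi <- c(chrT = 20000)
    rec <- random_records(20, gi[["chrT"]])
    cov <- coverage_report(rec, gi)
    total <- cov$covered_bp[cov$level == "total"]
    # conservation: masked + unmasked = genome length
    pieces <- resolve_overlaps(rec, genome = gi)
    masked <- sum(pieces$end - pieces$start + 1)
    expect_equal(total, masked)
    expect_lte(total, sum(gi))
    # type totals equal the sum of their clade rows
    for (ty in c("LINE", "LTR")) {
      ty_bp <- cov$covered_bp[cov$level == "type" & cov$te_type == ty]
      cl_bp <- sum(cov$covered_bp[cov$level == "clade" & cov$te_type == ty])
      expect_equal(ty_bp, cl_bp)
    }
    # grand total equals the sum of type rows
    expect_equal(total, sum(cov$covered_bp[cov$level == "type"]))
    # shuffling record order changes nothing
    perm <- sample(nrow(rec))
    cov2 <- coverage_report(rec[perm, ], gi)
    expect_equal(cov$covered_bp, cov2$covered_bp)
  }
})

test_that("overlapping records of two clades never double-count bases", {
  rec <- repeat_records(sw_score = c(300L, 200L), divergence_percent = 5,
                        query_name = "chr1",
                        query_begin = c(100L, 300L), query_end = c(600L, 800L),
                        strand = "+", repeat_name = c("A", "B"),
                        repeat_class_family = c("LINE/CR1", "LTR/ERVL"))
  cov <- coverage_report(rec, c(chr1 = 10000))
  total <- cov$covered_bp[cov$level == "total"]
  expect_lt(total, sum(rec$query_end - rec$query_begin + 1))
  expect_equal(total, 701)  # union of [100,600] and [300,800]
})

test_that("invalid inputs are rejected", {
  rec <- repeat_records(100L, 5, "chr1", 900L, 1200L, "+", "A", "LINE/CR1")
  expect_error(resolve_overlaps(rec, genome = c(chr1 = 1000)),
               "past their sequence length")
  expect_error(resolve_overlaps(rec, genome = c(chr2 = 2000)), "absent")
  expect_error(coverage_report(rec, genome = numeric(0)))
})
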