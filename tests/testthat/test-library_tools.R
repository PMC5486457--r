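rand_dna_chr <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

test_that("pair similarity on constructs with a unique optimum", {
  set.seed(8)
  a <- rand_dna_chr(200)
  # identical pair
  s <- pair_similarity(a, a)
  expect_equal(s$identity, 1)
  expect_equal(s$coverage, 1)
  # exact fragment: full coverage of the shorter sequence
  frag <- substr(a, 1, 100)
  s2 <- pair_similarity(a, frag)
  expect_equal(s2$identity, 1)
  expect_equal(s2$coverage, 1)
  # fragment coverage can be measured against the longer sequence instead
  s3 <- pair_similarity(a, frag, coverage_of = "longer")
  expect_equal(s3$coverage, 0.5)
  # single central mismatch
  b <- a
  substr(b, 100, 100) <- chartr("ACGT", "TGAC", substr(a, 100, 100))
  s4 <- pair_similarity(a, b)
  expect_equal(s4$identity, 199 / 200)
  expect_equal(s4$coverage, 1)
  # oracle agrees exactly on all of these
  for (pair in list(c(a, a), c(a, frag), c(a, b))) {
    imp <- pair_similarity(pair[1], pair[2])
    ora <- sw_ref_similarity(pair[1], pair[2])
    expect_equal(imp$score, ora$score)
    expect_equal(imp$identity, ora$identity)
    expect_equal(imp$coverage, ora$coverage)
  }
})

test_that("pair similarity is symmetric and strand-invariant", {
  set.seed(12)
  a <- rand_dna_chr(150)
  b <- mutate_jc(a, 15)
  ab <- pair_similarity(a, b)
  ba <- pair_similarity(b, a)
  expect_equal(ab$score, ba$score)
  expect_equal(ab$identity, ba$identity)
  expect_equal(ab$coverage, ba$coverage)
  rc <- revcomp_chr(b)
  arc <- pair_similarity(a, rc)
  expect_equal(arc$score, ab$score)
  expect_equal(arc$strand, "-")
  expect_error(pair_similarity("ACGT", "ACXT"), "non-nucleotide")
})

test_that("alignment scores match the exhaustive DP reference", {
  set.seed(19)
  for (k in 1:12) {
    n1 <- sample(60:160, 1)
    a <- rand_dna_chr(n1)
    b <- switch(k %% 4 + 1,
                rand_dna_chr(sample(60:160, 1)),
                mutate_jc(a, 10),
                mutate_jc(substr(a, 1, n1 %/% 2), 5),
                revcomp_chr(mutate_jc(a, 25)))
    imp <- pair_similarity(a, b)
    ora <- sw_ref_similarity(a, b)
    expect_equal(imp$score, ora$score)
    # identity/coverage are defined up to co-optimal alignments; the 80-80
    # decision both make must agree
    expect_equal(imp$identity > 0.8 && imp$coverage > 0.8,
                 ora$identity > 0.8 && ora$coverage > 0.8)
  }
})

test_that("80-80 clustering merges families and splits distant relatives", {
  set.seed(4)
  a <- rand_dna_chr(400)
  # two identical sequences form one family
  lib <- Biostrings::DNAStringSet(c(s1 = a, s2 = a))
  cl <- cluster_80_80(lib)
  expect_equal(length(cl$families), 1)
  expect_setequal(cl$families[[1]], c("s1", "s2"))
  # a 70%-identity full-length pair stays split (checked by the DP oracle)
  b <- a
  flip <- seq(1, 400, by = 10)
  flip <- c(flip, flip + 1, flip + 2)  # 120/400 sites = 30% divergence
  for (i in flip)
    substr(b, i, i) <- chartr("ACGT", "CATG", substr(a, i, i))
  ora <- sw_ref_similarity(a, b)
  expect_lt(ora$identity, 0.8)
  cl2 <- cluster_80_80(Biostrings::DNAStringSet(c(s1 = a, s2 = b)))
  expect_equal(length(cl2$families), 2)
  # chains merge by single linkage: fragment links to member links to cons
  lib3 <- Biostrings::DNAStringSet(c(
    cons = a, m1 = mutate_jc(a, 8), frag = substr(a, 1, 200)))
  cl3 <- cluster_80_80(lib3)
  expect_equal(length(cl3$families), 1)
  # representative is the longest member, and dedup keeps it
  expect_equal(names(cl3$families), "cons")
  expect_equal(names(nonredundant_library(lib3, cl3)), "cons")
})

test_that("clustering equals brute-force single linkage and ignores order", {
  for (seed in 1:3) {
    sl <- simulate_library(n_families = 2, lengths = c(90L, 120L),
                           members = 2, fragments = 1, decoys = 1,
                           unrelated = 1, seed = seed)
    cl <- cluster_80_80(sl$library)
    expect_identical(canon_partition(cl$families),
                     canon_partition(brute_cluster(sl$library)))
    # input order invariance
    perm <- sample(length(sl$library))
    cl_p <- cluster_80_80(sl$library[perm])
    expect_identical(canon_partition(cl$families),
                     canon_partition(cl_p$families))
  }
})

test_that("clustering is invariant to reverse-complementing a member", {
  set.seed(23)
  sl <- simulate_library(n_families = 2, lengths = c(100L, 80L), members = 1,
                         fragments = 0, decoys = 0, unrelated = 1, seed = 23)
  lib_rc <- sl$library
  lib_rc[[2]] <- Biostrings::reverseComplement(lib_rc[[2]])
  expect_identical(canon_partition(cluster_80_80(sl$library)$families),
                   canon_partition(cluster_80_80(lib_rc)$families))
})

test_that("ORF finder reports ATG-to-stop spans in all six frames", {
  set.seed(3)
  # ATG + 600 sense codons + TAA: one ORF of 601 aa including the Met
  s <- paste0("ATG", strrep("GCA", 600), "TAA")
  orfs <- find_orfs(s)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$length_aa, 601L)
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$start, 1L)
  expect_equal(orfs$end, nchar(s))
  # a sequence of only stop codons has no ORFs
  expect_equal(nrow(find_orfs(strrep("TAA", 30))), 0)
  # an ATG without a downstream stop is not an ORF
  expect_equal(nrow(find_orfs(paste0("ATG", strrep("GCA", 50)))), 0)
  # reverse-complementing the input flips strands and mirrors coordinates
  x <- paste0(rand_dna_chr(20), "ATG", strrep("GAC", 40), "TGA",
              rand_dna_chr(22))
  fw <- find_orfs(x)
  rv <- find_orfs(revcomp_chr(x))
  L <- nchar(x)
  mirrored <- data.frame(strand = chartr("+-", "-+", fw$strand),
                         start = L - fw$end + 1L, end = L - fw$start + 1L,
                         length_aa = fw$length_aa)
  o1 <- mirrored[order(mirrored$start, mirrored$strand), ]
  o2 <- rv[order(rv$start, rv$strand), c("strand", "start", "end", "length_aa")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("LINE screening follows the intactness ladder", {
  se <- simulate_elements(seed = 41)
  line_truth <- se$truth[se$truth$mode == "line", ]
  got <- screen_line(se$elements[line_truth$id], se$rt_refs)
  expect_equal(got$category, line_truth$category)
  # the boundary element: ORF2 of exactly 600 aa is not full
  b <- got[got$id == "line_orf1_boundary", ]
  expect_equal(b$orf2_length_aa, 600L)
  expect_true(b$has_ORF1)
  expect_false(b$category == "full_LINE")
  # an element with no ORFs at all is defective
  no_orf <- Biostrings::DNAStringSet(c(x = strrep("TAA", 200)))
  expect_equal(screen_line(no_orf, se$rt_refs)$category, "defective")
  expect_error(screen_line(no_orf, Biostrings::AAStringSet()), "empty")
})

test_that("ERV screening requires all three domains for a full element", {
  se <- simulate_elements(seed = 42)
  erv_truth <- se$truth[se$truth$mode == "erv", ]
  got <- screen_erv(se$elements[erv_truth$id], se$erv_refs)
  expect_equal(got$category, erv_truth$category)
  full <- got[got$id == "erv_full", ]
  expect_equal(full$erv_domains, "ENV,GAG,POL")
  expect_equal(c(full$env_aa, full$gag_aa, full$pol_aa), c(500, 520, 850))
  pol_only <- got[got$id == "erv_pol_only", ]
  expect_equal(pol_only$category, "partial_ERV")
  expect_equal(pol_only$erv_domains, "POL")
  # POL match of exactly 800 aa does not count (strict >)
  boundary <- got[got$id == "erv_pol_boundary", ]
  expect_equal(boundary$pol_aa, 800)
  expect_false(grepl("POL", boundary$erv_domains))
  # unlabeled references are rejected
  bad_refs <- se$erv_refs
  names(bad_refs)[1] <- "mystery_protein"
  expect_error(screen_erv(se$elements[1], bad_refs), "label")
})

test_that("extending a planted domain never demotes the category", {
  rank <- c(defective = 0, partial_ERV = 1, full_ERV = 2)
  plan <- default_element_plan()
  grow <- plan[plan$id == "erv_pol_boundary", ]
  cats <- character(0)
  for (pol in c(800, 810, 900)) {
    grow$pol_aa <- pol
    se <- simulate_elements(grow, seed = 5)
    cats <- c(cats, screen_erv(se$elements, se$erv_refs)$category)
  }
  expect_true(all(diff(rank[cats]) >= 0))
  expect_equal(cats[1], "defective")
  expect_equal(cats[2], "partial_ERV")
})

test_that("screening summaries count every element exactly once", {
  empty <- data.frame(category = character(0))
  tab0 <- summarize_screen(empty)
  expect_true(all(tab0$n == 0))
  se <- simulate_elements(seed = 43)
  line_truth <- se$truth[se$truth$mode == "line", ]
  got <- screen_line(se$elements[line_truth$id], se$rt_refs)
  tab <- summarize_screen(got, clade = line_truth$clade)
  expect_equal(sum(tab$n), nrow(line_truth))
  want <- summarize_screen(line_truth, clade = line_truth$clade)
  expect_equal(tab, want)
})
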