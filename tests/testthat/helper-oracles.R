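# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the aligner is an exhaustive Gotoh local
# DP in plain R, coverage is a per-base sweep, clustering is union-find over
# all pairs scored by the DP aligner.

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

# Exhaustive Smith-Waterman / Gotoh local alignment with affine gaps
# (gap of length L costs gap_open + L * gap_extend) and full traceback.
sw_ref <- function(a, b, match = 1, mismatch = -1, gap_open = 5,
                   gap_extend = 1) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  go <- gap_open + gap_extend
  # Mm[i+1, j+1] = best score of a local alignment ending with av[i] ~ bv[j]
  Mm <- matrix(NEG, n + 1, m + 1)
  Em <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (consumes bv[j])
  Fm <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (consumes av[i])
  for (i in 1:n) {
    si <- ifelse(av[i] == bv, match, mismatch)
    for (j in 1:m) {
      Mm[i + 1, j + 1] <- max(0, Mm[i, j], Em[i, j], Fm[i, j]) + si[j]
      Em[i + 1, j + 1] <- max(Mm[i + 1, j] - go, Em[i + 1, j] - gap_extend,
                              Fm[i + 1, j] - go)
      Fm[i + 1, j + 1] <- max(Mm[i, j + 1] - go, Fm[i, j + 1] - gap_extend,
                              Em[i, j + 1] - go)
    }
  }
  best <- max(Mm)
  if (best <= 0)
    return(list(score = 0, identity = 0, span_a = 0, span_b = 0))
  pos <- unname(which(Mm == best, arr.ind = TRUE)[1, ])
  i <- pos[1] - 1
  j <- pos[2] - 1
  ai_end <- i; bj_end <- j
  ai_start <- i; bj_start <- j
  matches <- 0L
  cols <- 0L
  state <- "M"
  repeat {
    if (state == "M") {
      cols <- cols + 1L
      if (av[i] == bv[j]) matches <- matches + 1L
      ai_start <- i; bj_start <- j
      s <- if (av[i] == bv[j]) match else mismatch
      target <- Mm[i + 1, j + 1] - s
      if (target == 0) break   # fresh local start is (co-)optimal: stop
      if (Mm[i, j] == target) { i <- i - 1; j <- j - 1; state <- "M" }
      else if (Em[i, j] == target) { i <- i - 1; j <- j - 1; state <- "E" }
      else if (Fm[i, j] == target) { i <- i - 1; j <- j - 1; state <- "F" }
      else stop("traceback failure in M")
    } else if (state == "E") {
      cols <- cols + 1L
      bj_start <- j
      v <- Em[i + 1, j + 1]
      if (Mm[i + 1, j] == v + go) { j <- j - 1; state <- "M" }
      else if (Em[i + 1, j] == v + gap_extend) { j <- j - 1; state <- "E" }
      else if (Fm[i + 1, j] == v + go) { j <- j - 1; state <- "F" }
      else stop("traceback failure in E")
    } else {
      cols <- cols + 1L
      ai_start <- i
      v <- Fm[i + 1, j + 1]
      if (Mm[i, j + 1] == v + go) { i <- i - 1; state <- "M" }
      else if (Fm[i, j + 1] == v + gap_extend) { i <- i - 1; state <- "F" }
      else if (Em[i, j + 1] == v + go) { i <- i - 1; state <- "E" }
      else stop("traceback failure in F")
    }
  }
  list(score = best, identity = matches / cols,
       span_a = ai_end - ai_start + 1, span_b = bj_end - bj_start + 1)
}

# both-strand wrapper mirroring pair_similarity's conventions
sw_ref_similarity <- function(a, b, ...) {
  fwd <- sw_ref(a, b, ...)
  rev <- sw_ref(a, revcomp_chr(b), ...)
  res <- if (rev$score > fwd$score) rev else fwd
  la <- nchar(a)
  lb <- nchar(b)
  cov_a <- res$span_a / la
  cov_b <- res$span_b / lb
  res$coverage <- if (la < lb) cov_a else if (lb < la) cov_b
                  else max(cov_a, cov_b)
  res
}

# per-base sweep: every base goes to the covering record with the highest
# score, ties to the earlier start, then the earlier input row
brute_coverage_bp <- function(records, genome) {
  gi <- genome
  out <- integer(nrow(records))
  for (q in unique(records$query_name)) {
    L <- gi[[q]]
    best_score <- rep(-Inf, L)
    best_start <- rep(Inf, L)
    best_idx <- rep(NA_integer_, L)
    rows <- which(records$query_name == q)
    for (i in rows) {
      span <- records$query_begin[i]:records$query_end[i]
      s <- records$sw_score[i]
      b <- records$query_begin[i]
      win <- s > best_score[span] |
        (s == best_score[span] & b < best_start[span]) |
        (s == best_score[span] & b == best_start[span] &
           i < replace(best_idx[span], is.na(best_idx[span]), Inf))
      upd <- span[win]
      best_score[upd] <- s
      best_start[upd] <- b
      best_idx[upd] <- i
    }
    tab <- table(best_idx[!is.na(best_idx)])
    out[as.integer(names(tab))] <- out[as.integer(names(tab))] + as.integer(tab)
  }
  out
}

# brute-force all-pairs single-linkage clustering over the DP reference
brute_cluster <- function(library, min_identity = 0.8, min_coverage = 0.8) {
  seqs <- as.character(library)
  ids <- names(library)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        sim <- sw_ref_similarity(seqs[i], seqs[j])
        if (sim$identity > min_identity && sim$coverage > min_coverage) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(ids, root), sort))
}

# canonical form of a partition (list of member vectors) for set comparison
canon_partition <- function(fams) {
  x <- unname(lapply(fams, sort))
  x[order(vapply(x, `[`, character(1), 1))]
}

# quick random annotation table (overlaps allowed) for coverage tests
random_records <- function(n, genome_len,
                           classes = c("LINE/CR1", "LINE/L2", "LTR/ERVL",
                                       "LTR/ERV1", "SINE/tRNA", "DNA/hAT",
                                       "FooBar")) {
  len <- sample(50:400, n, replace = TRUE)
  qb <- vapply(len, function(l) sample.int(genome_len - l + 1, 1), integer(1))
  repeat_records(
    sw_score = sample(1:20, n, replace = TRUE) * 50,  # frequent score ties
    divergence_percent = round(runif(n, 0, 40), 1),
    query_name = "chrT",
    query_begin = qb, query_end = qb + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    repeat_name = paste0("rep", seq_len(n)),
    repeat_class_family = sample(classes, n, replace = TRUE),
    linkage_id = seq_len(n))
}
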