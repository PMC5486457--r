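#' Pairwise similarity of two nucleotide sequences
#'
#' Local alignment (Smith-Waterman with affine gaps: a gap of length L costs
#' `gap_open + L * gap_extend`) summarised as the two quantities the 80-80
#' family rule needs: the fraction of identical aligned columns and the
#' fraction of the shorter sequence covered by the aligned span. Both
#' strands of `b` are tried when `both_strands = TRUE` (the default), so the
#' result is invariant to reverse-complementing either sequence; the
#' forward strand wins score ties.
#'
#' @param a,b sequences (`DNAString` or character); alphabet `A/C/G/T/N`.
#' @param match,mismatch,gap_open,gap_extend alignment scores (defaults
#'   +1 / -1 / 5 / 1; gap penalties are positive costs).
#' @param both_strands also align against the reverse complement of `b`.
#' @param coverage_of which sequence's aligned fraction defines coverage:
#'   the `"shorter"` (default; fragments of a longer family member reach
#'   full coverage), the `"longer"`, or `"both"` (the minimum of the two).
#' @return A list with `identity` (matches / aligned columns, gaps
#'   included), `coverage`, `score`, and `strand` (`"+"` or `"-"`). A pair
#'   with no positive-scoring local alignment has identity and coverage 0.
#' @examples
#' pair_similarity("ACGTACGTAC", "ACGTACGTAC")
#' @export
pair_similarity <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 1,
                            both_strands = TRUE,
                            coverage_of = c("shorter", "longer", "both")) {
  coverage_of <- match.arg(coverage_of)
  a <- .as_dna(a)
  b <- .as_dna(b)
  fwd <- .align_stats(a, b, match, mismatch, gap_open, gap_extend)
  res <- fwd
  res$strand <- "+"
  if (both_strands) {
    rev <- .align_stats(a, Biostrings::reverseComplement(b),
                        match, mismatch, gap_open, gap_extend)
    if (rev$score > fwd$score) {
      res <- rev
      res$strand <- "-"
    }
  }
  cov_a <- res$span_a / length(a)
  cov_b <- res$span_b / length(b)
  res$coverage <- switch(coverage_of,
    shorter = if (length(a) < length(b)) cov_a
              else if (length(b) < length(a)) cov_b
              else max(cov_a, cov_b),
    longer = if (length(a) > length(b)) cov_a
             else if (length(b) > length(a)) cov_b
             else min(cov_a, cov_b),
    both = min(cov_a, cov_b))
  res[c("identity", "coverage", "score", "strand")]
}

.as_dna <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  x <- toupper(as.character(x))
  if (length(x) != 1 || nchar(x) == 0) stop("sequence must be a single non-empty string")
  if (grepl("[^ACGTN]", x))
    stop("non-nucleotide characters (other than N) in sequence")
  Biostrings::DNAString(x)
}

.nuc_matrix <- function(match, mismatch) {
  key <- paste0("nuc_", match, "_", mismatch)
  if (is.null(.te_cache[[key]]))
    .te_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
  .te_cache[[key]]
}

.align_stats <- function(a, b, match, mismatch, gap_open, gap_extend) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = .nuc_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  cols <- nchar(aln)
  if (sc <= 0 || cols == 0)
    return(list(identity = 0, score = sc, span_a = 0, span_b = 0))
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  list(identity = Biostrings::nmatch(aln) / cols,
       score = sc,
       span_a = IRanges::end(pat) - IRanges::start(pat) + 1,
       span_b = IRanges::end(sub) - IRanges::start(sub) + 1)
}

#' Cluster a repeat library with the 80-80 family rule
#'
#' Two sequences belong to the same family if they can be aligned over more
#' than 80% of their length with more than 80% identity (both strict, both
#' configurable). Families are the connected components of the resulting
#' pair graph (single linkage), so a chain of above-threshold pairs merges
#' into one family. The representative of a family is its longest member,
#' ties broken by lexicographically smallest identifier — the longest member
#' best preserves the family consensus span, which is what redundancy
#' removal wants to keep.
#'
#' @param library a named `DNAStringSet` (or named character vector) with
#'   unique identifiers.
#' @param min_identity,min_coverage thresholds; membership requires strictly
#'   greater values (default 0.8 and 0.8).
#' @param ... passed to [pair_similarity()] (scoring, `coverage_of`,
#'   `both_strands`).
#' @return An object of class `te_family_clustering`: a list with
#'   `membership` (`data.frame` with `id`, `family`, `representative`) and
#'   `families` (list of character vectors of ids, named by representative).
#' @export
cluster_80_80 <- function(library, min_identity = 0.8, min_coverage = 0.8,
                          ...) {
  if (!methods::is(library, "DNAStringSet"))
    library <- Biostrings::DNAStringSet(library)
  n <- length(library)
  if (n == 0) stop("library is empty")
  ids <- names(library)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("library sequences must carry unique non-empty identifiers")
  # union-find over all pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ri <- find(i); rj <- find(j)
        if (ri == rj) next
        sim <- pair_similarity(library[[i]], library[[j]], ...)
        if (sim$identity > min_identity && sim$coverage > min_coverage)
          parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  fam_ids <- match(root, sort(unique(root)))
  lens <- Biostrings::width(library)
  representative <- character(max(fam_ids))
  families <- vector("list", max(fam_ids))
  for (f in seq_len(max(fam_ids))) {
    members <- which(fam_ids == f)
    # longest member; ties by lexicographic id
    o <- members[order(-lens[members], ids[members])]
    representative[f] <- ids[o[1]]
    families[[f]] <- ids[members]
  }
  names(families) <- representative
  out <- list(
    membership = data.frame(id = ids, family = fam_ids,
                            representative = representative[fam_ids],
                            stringsAsFactors = FALSE),
    families = families)
  class(out) <- "te_family_clustering"
  out
}

#' @export
print.te_family_clustering <- function(x, ...) {
  cat(length(x$families), "families over", nrow(x$membership), "sequences\n")
  for (f in seq_along(x$families))
    cat(sprintf("  %s: %s\n", names(x$families)[f],
                paste(x$families[[f]], collapse = ", ")))
  invisible(x)
}

#' Non-redundant library after 80-80 clustering
#'
#' @param library the clustered `DNAStringSet`.
#' @param clustering result of [cluster_80_80()].
#' @return A `DNAStringSet` holding one representative per family.
#' @export
nonredundant_library <- function(library, clustering) {
  if (!methods::is(library, "DNAStringSet"))
    library <- Biostrings::DNAStringSet(library)
  library[names(clustering$families)]
}
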