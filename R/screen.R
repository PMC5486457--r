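#' Find open reading frames in a nucleotide sequence
#'
#' ORFs are ATG-to-stop spans under the standard genetic code, searched in
#' all six frames. Within each in-frame segment between stop codons the ORF
#' runs from the first ATG to the stop (the longest possible), so reported
#' ORFs never nest. Coordinates are on the forward strand of the input,
#' 1-based inclusive, and include the stop codon; `length_aa` excludes it.
#' A stop codon is required — an ATG running off the sequence end is not an
#' ORF. Set `require_atg = FALSE` for stop-to-stop mode, where every
#' in-frame segment between stops counts regardless of an initiator.
#'
#' @param x a `DNAString` or character sequence of length >= 3.
#' @param min_aa minimum ORF length in amino acids (default 1).
#' @param require_atg require an ATG initiator (default `TRUE`).
#' @return A `data.frame` with columns `frame` (1-3 within its strand),
#'   `strand`, `start`, `end`, `length_aa`, sorted longest first.
#' @examples
#' find_orfs(paste0("ATG", strrep("GCA", 10), "TAA"))
#' @export
find_orfs <- function(x, min_aa = 1, require_atg = TRUE) {
  x <- .as_dna(x)
  L <- length(x)
  if (L < 3) stop("sequence must be at least 3 nt")
  pat <- if (require_atg) "M[^*]*\\*" else "[^*]+\\*"
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") x else Biostrings::reverseComplement(x)
    for (frame in 1:3) {
      n_codon <- (L - frame + 1) %/% 3
      if (n_codon < 2) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(s, frame, frame + 3 * n_codon - 1),
        if.fuzzy.codon = "X"))
      m <- gregexpr(pat, aa)[[1]]
      if (m[1] == -1) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      for (k in seq_along(starts)) {
        nt_s <- frame + 3 * (starts[k] - 1)
        nt_e <- nt_s + 3 * lens[k] - 1
        if (strand == "-") {
          tmp <- L - nt_e + 1
          nt_e <- L - nt_s + 1
          nt_s <- tmp
        }
        rows[[length(rows) + 1]] <- data.frame(
          frame = frame, strand = strand, start = nt_s, end = nt_e,
          length_aa = lens[k] - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      length_aa = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[out$length_aa >= min_aa, , drop = FALSE]
  out <- out[order(-out$length_aa, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# translation of one ORF row, stop codon removed
orf_protein <- function(x, orf) {
  x <- .as_dna(x)
  s <- Biostrings::subseq(x, orf$start, orf$end)
  if (orf$strand == "-") s <- Biostrings::reverseComplement(s)
  aa <- Biostrings::translate(s, if.fuzzy.codon = "X")
  Biostrings::subseq(aa, 1, length(aa) - 1)
}

# best local protein alignment of an ORF translation against a reference
# set; returns the widest qualifying span on the ORF (0 if none qualifies)
.protein_hit <- function(prot, refs, min_identity, gap_open = 11,
                         gap_extend = 1) {
  best_span <- 0
  best_identity <- 0
  for (r in seq_along(refs)) {
    aln <- Biostrings::pairwiseAlignment(
      prot, refs[[r]], type = "local", substitutionMatrix = blosum62(),
      gapOpening = gap_open, gapExtension = gap_extend)
    cols <- nchar(aln)
    if (Biostrings::score(aln) <= 0 || cols == 0) next
    identity <- Biostrings::nmatch(aln) / cols
    if (identity < min_identity) next
    pat <- Biostrings::pattern(aln)
    span <- IRanges::end(pat) - IRanges::start(pat) + 1
    if (span > best_span) {
      best_span <- span
      best_identity <- identity
    }
  }
  list(span = best_span, identity = best_identity)
}

.screen_categories <- c("full_LINE", "ORF2_only", "ORF1_only",
                        "intact_RT_only", "full_ERV", "partial_ERV",
                        "defective")

#' Screen candidate LINE elements for intactness
#'
#' Classifies each element by the ladder used for "ORF-preserving" LINEs:
#' ORF2 is the longest ORF whose translation aligns locally to a reverse
#' transcriptase (RT) reference (BLOSUM62; acceptance requires identity of
#' at least `min_rt_identity` over at least `min_rt_aa` aligned residues of
#' the element — both interpretations documented as configurable, since the
#' underlying survey protocol does not fix them). ORF1 is any other ORF of
#' at least `min_orf1_aa` amino acids upstream of ORF2 on the same strand.
#' The RT domain is intact when the accepted alignment lies within a single
#' ORF, i.e. is uninterrupted by stop codons or frameshifts — which holds by
#' construction for any hit found here, so `has_intact_RT` is true whenever
#' an RT-bearing ORF exists. Categories (first match wins):
#' `full_LINE` (ORF1 present and ORF2 strictly longer than `full_orf2_aa`),
#' `ORF2_only`, `ORF1_only`, `intact_RT_only`, `defective`.
#'
#' @param elements a `DNAStringSet` (or single sequence) of candidates.
#' @param rt_refs an `AAStringSet` of RT reference proteins (non-empty).
#' @param min_rt_identity,min_rt_aa RT acceptance thresholds (defaults 0.25
#'   and 200 aa).
#' @param min_orf1_aa minimum ORF1 length (default 100 aa).
#' @param full_orf2_aa full-element ORF2 threshold, strict `>` (default
#'   600 aa).
#' @return A `data.frame` with one row per element: `id`, `has_intact_RT`,
#'   `has_ORF1`, `orf2_length_aa` (0 when no RT-bearing ORF), `category`.
#' @export
screen_line <- function(elements, rt_refs, min_rt_identity = 0.25,
                        min_rt_aa = 200, min_orf1_aa = 100,
                        full_orf2_aa = 600) {
  if (!methods::is(elements, "DNAStringSet"))
    elements <- Biostrings::DNAStringSet(elements)
  if (is.null(names(elements)))
    names(elements) <- paste0("element", seq_along(elements))
  if (length(rt_refs) == 0) stop("RT reference set is empty")
  if (!methods::is(rt_refs, "AAStringSet"))
    rt_refs <- Biostrings::AAStringSet(rt_refs)
  res <- vector("list", length(elements))
  for (e in seq_along(elements)) {
    el <- elements[[e]]
    orfs <- find_orfs(el)
    has_rt <- FALSE
    orf2 <- NULL
    orf2_len <- 0L
    if (nrow(orfs) > 0) {
      for (i in seq_len(nrow(orfs))) {     # longest-first
        if (orfs$length_aa[i] < min_rt_aa) break
        hit <- .protein_hit(orf_protein(el, orfs[i, ]), rt_refs,
                            min_rt_identity)
        if (hit$span >= min_rt_aa) {
          has_rt <- TRUE
          orf2 <- orfs[i, ]
          orf2_len <- orfs$length_aa[i]
          break
        }
      }
    }
    has_orf1 <- FALSE
    if (has_rt) {
      others <- orfs[orfs$length_aa >= min_orf1_aa &
                     orfs$strand == orf2$strand &
                     !(orfs$start == orf2$start & orfs$end == orf2$end), ,
                     drop = FALSE]
      if (nrow(others) > 0) {
        upstream <- if (orf2$strand == "+") others$end < orf2$start
                    else others$start > orf2$end
        has_orf1 <- any(upstream)
      }
    }
    category <- if (has_orf1 && orf2_len > full_orf2_aa) "full_LINE"
      else if (orf2_len > full_orf2_aa) "ORF2_only"
      else if (has_orf1) "ORF1_only"
      else if (has_rt) "intact_RT_only"
      else "defective"
    res[[e]] <- data.frame(id = names(elements)[e], has_intact_RT = has_rt,
                           has_ORF1 = has_orf1, orf2_length_aa = orf2_len,
                           category = category, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Screen candidate ERV elements for GAG/POL/ENV domains
#'
#' A domain is present when some ORF translation aligns locally (BLOSUM62,
#' identity at least `min_identity`) to a reference protein carrying that
#' label and the matched span on the element strictly exceeds the domain's
#' threshold: ENV > 480 aa, GAG > 500 aa, POL > 800 aa. Elements with all
#' three domains are `full_ERV`, with at least one `partial_ERV`, otherwise
#' `defective`. Reference labels are taken from the leading `ENV`/`GAG`/
#' `POL` token of each reference name.
#'
#' @param elements a `DNAStringSet` (or single sequence) of candidates.
#' @param domain_refs an `AAStringSet` whose names start with `ENV`, `GAG`
#'   or `POL` (case-insensitive); at least one reference per label.
#' @param min_identity alignment acceptance identity (default 0.25).
#' @param thresholds named vector of strict lower bounds in aa.
#' @return A `data.frame` with one row per element: `id`, `env_aa`,
#'   `gag_aa`, `pol_aa` (best matched spans, 0 when no accepted alignment),
#'   `erv_domains` (comma-separated subset of ENV/GAG/POL), `category`.
#' @export
screen_erv <- function(elements, domain_refs, min_identity = 0.25,
                       thresholds = c(ENV = 480, GAG = 500, POL = 800)) {
  if (!methods::is(elements, "DNAStringSet"))
    elements <- Biostrings::DNAStringSet(elements)
  if (is.null(names(elements)))
    names(elements) <- paste0("element", seq_along(elements))
  if (!methods::is(domain_refs, "AAStringSet"))
    domain_refs <- Biostrings::AAStringSet(domain_refs)
  labels <- toupper(sub("^(env|gag|pol).*$", "\\1", names(domain_refs),
                        ignore.case = TRUE))
  bad <- !labels %in% c("ENV", "GAG", "POL")
  if (any(bad))
    stop("reference(s) without an ENV/GAG/POL label: ",
         paste(names(domain_refs)[bad], collapse = ", "))
  if (!all(c("ENV", "GAG", "POL") %in% labels))
    stop("need at least one reference per label (ENV, GAG, POL); have: ",
         paste(unique(labels), collapse = ", "))
  res <- vector("list", length(elements))
  for (e in seq_along(elements)) {
    el <- elements[[e]]
    orfs <- find_orfs(el)
    span <- c(ENV = 0, GAG = 0, POL = 0)
    min_thr <- min(thresholds)
    for (i in seq_len(nrow(orfs))) {
      if (orfs$length_aa[i] < min_thr) next   # too short for any domain
      prot <- orf_protein(el, orfs[i, ])
      for (lab in c("ENV", "GAG", "POL")) {
        hit <- .protein_hit(prot, domain_refs[labels == lab], min_identity)
        span[lab] <- max(span[lab], hit$span)
      }
    }
    present <- names(thresholds)[span[names(thresholds)] > thresholds]
    category <- if (length(present) == 3) "full_ERV"
      else if (length(present) >= 1) "partial_ERV"
      else "defective"
    res[[e]] <- data.frame(id = names(elements)[e],
                           env_aa = unname(span["ENV"]),
                           gag_aa = unname(span["GAG"]),
                           pol_aa = unname(span["POL"]),
                           erv_domains = paste(present, collapse = ","),
                           category = category, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tabulate screening results
#'
#' Counts per category (all ladder categories are kept as levels, so absent
#' categories show 0), optionally split by clade. Counts always sum to the
#' number of screened elements.
#'
#' @param results a `data.frame` from [screen_line()] or [screen_erv()],
#'   optionally with a `clade` column (or supplied via `clade`).
#' @param clade optional character vector of clade labels, parallel to
#'   `results`.
#' @return A `data.frame` of counts with columns `clade` (if given),
#'   `category`, `n`.
#' @export
summarize_screen <- function(results, clade = NULL) {
  stopifnot(is.data.frame(results), "category" %in% names(results))
  if (is.null(clade) && "clade" %in% names(results)) clade <- results$clade
  cat_f <- factor(results$category, levels = .screen_categories)
  if (any(is.na(cat_f)))
    stop("unknown screening category: ",
         paste(unique(results$category[is.na(cat_f)]), collapse = ", "))
  if (is.null(clade)) {
    tab <- table(category = cat_f)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("category", "n")
  } else {
    stopifnot(length(clade) == nrow(results))
    tab <- table(clade = as.character(clade), category = cat_f)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("clade", "category", "n")
    out <- out[order(out$clade), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
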