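#' Resolve overlapping repeat hits into disjoint attributed intervals
#'
#' RepeatMasker reports overlapping hits; masked-base accounting needs every
#' base attributed to exactly one record. Among records covering a base, the
#' one with the highest Smith-Waterman score claims it; ties are broken by
#' earlier start, then input order. This mirrors RepeatMasker's own masking
#' precedence.
#'
#' @param records a records `data.frame` (see [repeat_records()]).
#' @param genome optional genome index ([genome_index()]); when supplied,
#'   records extending past their sequence end raise an error.
#' @return A `data.frame` with columns `query_name`, `start`, `end`
#'   (1-based inclusive, pairwise disjoint) and `record` (row index of the
#'   claiming record), sorted by sequence and start.
#' @export
resolve_overlaps <- function(records, genome = NULL) {
  validate_records(records)
  if (!is.null(genome)) {
    gi <- genome_index(genome)
    unknown <- setdiff(unique(records$query_name), names(gi))
    if (length(unknown) > 0)
      stop("records on sequences absent from the genome index: ",
           paste(unknown, collapse = ", "))
    over <- records$query_end > gi[records$query_name]
    if (any(over))
      stop(sum(over), " record(s) extend past their sequence length")
  }
  n <- nrow(records)
  if (n == 0)
    return(data.frame(query_name = character(0), start = integer(0),
                      end = integer(0), record = integer(0)))
  # global claiming priority: score desc, then earlier start, then input order
  prio <- order(-records$sw_score, records$query_begin, seq_len(n))
  claimed <- list()
  pieces <- vector("list", n)
  for (i in prio) {
    q <- records$query_name[i]
    ir <- IRanges::IRanges(records$query_begin[i], records$query_end[i])
    free <- if (is.null(claimed[[q]])) ir else IRanges::setdiff(ir, claimed[[q]])
    if (length(free) > 0) {
      pieces[[i]] <- data.frame(query_name = q,
                                start = IRanges::start(free),
                                end = IRanges::end(free),
                                record = i, stringsAsFactors = FALSE)
      claimed[[q]] <- if (is.null(claimed[[q]])) IRanges::reduce(ir) else
        IRanges::reduce(c(claimed[[q]], ir))
    }
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  out <- out[order(out$query_name, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome coverage per TE type and clade
#'
#' Overlap-resolved masked-base totals in the shape of a standard TE survey
#' table: one row per clade, a subtotal per TE type, and a grand total of
#' interspersed repeats. Because every base is attributed to exactly one
#' record, clade rows partition their type's bases and
#' `grand total + unmasked = genome length` holds on every input.
#'
#' @param records a records `data.frame`.
#' @param genome a genome index ([genome_index()]); its `sum()` is the
#'   denominator of all percentages.
#' @param taxonomy a taxonomy rule table (default [default_taxonomy()]).
#' @return A `data.frame` of class `te_coverage_report` with columns
#'   `te_type`, `clade` (`NA` on type and total rows), `level`
#'   (`"clade"`/`"type"`/`"total"`), `covered_bp` and `covered_percent`.
#'   Percentages are kept at full precision; the print method rounds to two
#'   decimals.
#' @examples
#' rec <- repeat_records(500, 10, "chr1", 1001, 1500, "+", "CR1-X", "LINE/CR1")
#' coverage_report(rec, c(chr1 = 10000))
#' @export
coverage_report <- function(records, genome, taxonomy = default_taxonomy()) {
  gi <- genome_index(genome)
  total_len <- sum(gi)
  records <- classify_repeats(records, taxonomy)
  pieces <- resolve_overlaps(records, genome = gi)
  bp_of <- function(idx) {
    if (length(idx) == 0) return(0)
    sel <- pieces$record %in% idx
    sum(pieces$end[sel] - pieces$start[sel] + 1)
  }
  rows <- list()
  type_order <- c("SINE", "LINE", "LTR", "DNA", "Unclassified")
  for (ty in type_order) {
    idx_ty <- which(records$te_type == ty)
    rows[[length(rows) + 1]] <- data.frame(
      te_type = ty, clade = NA_character_, level = "type",
      covered_bp = bp_of(idx_ty), stringsAsFactors = FALSE)
    clades <- unique(taxonomy$clade[taxonomy$te_type == ty])
    clades <- clades[clades != "None"]
    for (cl in clades) {
      idx_cl <- idx_ty[records$clade[idx_ty] == cl]
      rows[[length(rows) + 1]] <- data.frame(
        te_type = ty, clade = cl, level = "clade",
        covered_bp = bp_of(idx_cl), stringsAsFactors = FALSE)
    }
    # bases of the type not claimed by a named clade (e.g. clade None)
    if (length(clades) > 0) {
      idx_other <- idx_ty[!records$clade[idx_ty] %in% clades]
      if (length(idx_other) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          te_type = ty, clade = "None", level = "clade",
          covered_bp = bp_of(idx_other), stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    te_type = "Total interspersed repeats", clade = NA_character_,
    level = "total", covered_bp = bp_of(seq_len(nrow(records))),
    stringsAsFactors = FALSE)
  rep_df <- do.call(rbind, rows)
  rep_df$covered_percent <- 100 * rep_df$covered_bp / total_len
  attr(rep_df, "total_length") <- total_len
  class(rep_df) <- c("te_coverage_report", "data.frame")
  rep_df
}

#' @export
print.te_coverage_report <- function(x, ...) {
  total_len <- attr(x, "total_length")
  cat(sprintf("Genome coverage of TEs (genome size %s bp)\n",
              format(total_len, big.mark = ",")))
  for (i in seq_len(nrow(x))) {
    label <- if (x$level[i] == "clade") paste0("  ", x$clade[i]) else x$te_type[i]
    cat(sprintf("%-28s %6.2f%% / %s bp\n", label, x$covered_percent[i],
                format(x$covered_bp[i], big.mark = ",")))
  }
  invisible(x)
}
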