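#' @title RepeatMasker annotation I/O
#' @description Read and write the whitespace-delimited RepeatMasker `.out`
#'   dialect: three header lines followed by one record per annotated repeat
#'   copy. Complement-strand hits are flagged `C` and print their repeat
#'   coordinates as `(left) end begin`; both conventions are normalised on
#'   input and restored on output, so that parse -> write -> parse is the
#'   identity on every stored field.
#' @name rm_io
NULL

.record_columns <- c(
  "sw_score", "divergence_percent", "deletion_percent", "insertion_percent",
  "query_name", "query_begin", "query_end", "strand",
  "repeat_name", "repeat_class_family",
  "repeat_begin", "repeat_end", "repeat_left",
  "linkage_id", "overlap_flag"
)

#' Construct a table of annotated repeat copies
#'
#' Canonical in-memory form of a RepeatMasker record: 1-based inclusive
#' genome coordinates, strand `"+"`/`"-"`, percent divergence `D` from the
#' family consensus (must satisfy `0 <= D < 75`, the domain of the
#' Jukes-Cantor correction), and a slash-delimited class/family label such
#' as `"LINE/CR1"`.
#'
#' @param sw_score integer Smith-Waterman scores.
#' @param divergence_percent percent mismatch to the consensus, in `[0, 75)`.
#' @param query_name,query_begin,query_end genome sequence and 1-based
#'   inclusive coordinates (`query_begin <= query_end`).
#' @param strand `"+"` or `"-"`.
#' @param repeat_name,repeat_class_family repeat identifier and class/family
#'   label.
#' @param deletion_percent,insertion_percent percent deleted/inserted bases.
#' @param repeat_begin,repeat_end,repeat_left coordinates in the repeat
#'   consensus; default to the copy span.
#' @param linkage_id integer id grouping fragments of one insertion.
#' @param overlap_flag logical; RepeatMasker's trailing `*` (hit overlaps a
#'   higher-scoring one).
#' @return A `data.frame` with one row per repeat copy.
#' @export
repeat_records <- function(sw_score, divergence_percent, query_name,
                           query_begin, query_end, strand,
                           repeat_name, repeat_class_family,
                           deletion_percent = 0, insertion_percent = 0,
                           repeat_begin = 1L,
                           repeat_end = query_end - query_begin + 1L,
                           repeat_left = 0L,
                           linkage_id = seq_along(sw_score),
                           overlap_flag = FALSE) {
  n <- length(sw_score)
  r <- function(x) if (n == 0) x[0] else rep_len(x, n)
  divergence_percent <- r(divergence_percent)
  deletion_percent <- r(deletion_percent)
  insertion_percent <- r(insertion_percent)
  query_name <- r(query_name)
  query_begin <- r(query_begin)
  query_end <- r(query_end)
  strand <- r(strand)
  repeat_name <- r(repeat_name)
  repeat_class_family <- r(repeat_class_family)
  repeat_begin <- r(repeat_begin)
  repeat_end <- r(repeat_end)
  repeat_left <- r(repeat_left)
  linkage_id <- r(linkage_id)
  overlap_flag <- r(overlap_flag)
  rec <- data.frame(
    sw_score = as.integer(sw_score),
    divergence_percent = as.numeric(divergence_percent),
    deletion_percent = as.numeric(deletion_percent),
    insertion_percent = as.numeric(insertion_percent),
    query_name = as.character(query_name),
    query_begin = as.integer(query_begin),
    query_end = as.integer(query_end),
    strand = as.character(strand),
    repeat_name = as.character(repeat_name),
    repeat_class_family = as.character(repeat_class_family),
    repeat_begin = as.integer(repeat_begin),
    repeat_end = as.integer(repeat_end),
    repeat_left = as.integer(repeat_left),
    linkage_id = as.integer(linkage_id),
    overlap_flag = as.logical(overlap_flag),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
  rec
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.record_columns, names(records))
  if (length(missing) > 0)
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$query_begin < 1L) || any(records$query_end < records$query_begin))
    stop("invalid coordinates: need 1 <= query_begin <= query_end")
  if (!all(records$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- records$divergence_percent < 0 | records$divergence_percent >= 75
  if (any(bad))
    stop("divergence_percent outside [0, 75) for ",
         sum(bad), " record(s); the Jukes-Cantor correction is undefined there")
  invisible(records)
}

.paren_int <- function(tok, line_no) {
  if (!grepl("^\\([0-9]+\\)$", tok))
    stop("malformed record at line ", line_no,
         ": expected parenthesized integer, got '", tok, "'")
  as.integer(sub("^\\(([0-9]+)\\)$", "\\1", tok))
}

.num_field <- function(tok, line_no, what) {
  x <- suppressWarnings(as.numeric(tok))
  if (is.na(x))
    stop("malformed record at line ", line_no, ": bad ", what, " '", tok, "'")
  x
}

#' Parse a RepeatMasker .out annotation file
#'
#' Skips the three header lines, then reads one whitespace-delimited record
#' per line. Complement-strand hits (`C`) are normalised to strand `"-"` and
#' their `(left) end begin` repeat coordinates reordered; a trailing `*`
#' (overlap with a higher-scoring hit) is recorded in `overlap_flag`.
#' Records with divergence at or above 75% lie outside the domain of the
#' Jukes-Cantor correction and are dropped with a warning.
#'
#' @param file path to a `.out` file (or a connection).
#' @return A records `data.frame` (see [repeat_records()]), input order
#'   preserved.
#' @seealso [write_repeatmasker_out()]
#' @export
parse_repeatmasker_out <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 3)
    stop("not a RepeatMasker .out file: fewer than 3 header lines")
  body_idx <- seq_along(lines)[-(1:3)]
  rows <- vector("list", length(body_idx))
  drop_warn <- character(0)
  k <- 0
  for (i in body_idx) {
    line <- trimws(lines[i])
    if (line == "") next
    tok <- strsplit(line, "[ \t]+")[[1]]
    if (length(tok) < 15 || length(tok) > 16)
      stop("malformed record at line ", i, ": expected 15-16 fields, got ",
           length(tok))
    strand_tok <- tok[9]
    if (!strand_tok %in% c("+", "C"))
      stop("malformed record at line ", i, ": strand must be '+' or 'C', got '",
           strand_tok, "'")
    if (strand_tok == "+") {
      r_begin <- .num_field(tok[12], i, "repeat begin")
      r_end <- .num_field(tok[13], i, "repeat end")
      r_left <- .paren_int(tok[14], i)
    } else {
      r_left <- .paren_int(tok[12], i)
      r_end <- .num_field(tok[13], i, "repeat end")
      r_begin <- .num_field(tok[14], i, "repeat begin")
    }
    div <- .num_field(tok[2], i, "divergence")
    if (div >= 75) {
      drop_warn <- c(drop_warn, paste0("line ", i, " (divergence ", div, "%)"))
      next
    }
    qb <- .num_field(tok[6], i, "query begin")
    qe <- .num_field(tok[7], i, "query end")
    .paren_int(tok[8], i) # query (left); derived, validated but not stored
    if (qb < 1 || qe < qb)
      stop("malformed record at line ", i, ": query coordinates ", qb, "-", qe)
    k <- k + 1
    rows[[k]] <- data.frame(
      sw_score = as.integer(.num_field(tok[1], i, "score")),
      divergence_percent = div,
      deletion_percent = .num_field(tok[3], i, "deletion"),
      insertion_percent = .num_field(tok[4], i, "insertion"),
      query_name = tok[5],
      query_begin = as.integer(qb),
      query_end = as.integer(qe),
      strand = if (strand_tok == "C") "-" else "+",
      repeat_name = tok[10],
      repeat_class_family = tok[11],
      repeat_begin = as.integer(r_begin),
      repeat_end = as.integer(r_end),
      repeat_left = as.integer(r_left),
      linkage_id = as.integer(.num_field(tok[15], i, "linkage id")),
      overlap_flag = length(tok) == 16 && tok[16] == "*",
      stringsAsFactors = FALSE
    )
  }
  if (length(drop_warn) > 0)
    warning("dropped ", length(drop_warn),
            " record(s) with divergence >= 75% (outside the Jukes-Cantor ",
            "domain): ", paste(head(drop_warn, 5), collapse = "; "),
            if (length(drop_warn) > 5) "; ..." else "")
  if (k == 0) {
    out <- repeat_records(integer(0), numeric(0), character(0), integer(0),
                          integer(0), character(0), character(0), character(0),
                          linkage_id = integer(0))
    return(out)
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  validate_records(out)
  out
}

#' Write records to RepeatMasker .out format
#'
#' Inverse of [parse_repeatmasker_out()]: emits the three header lines and
#' one whitespace-delimited record per row, restoring the `C`-strand
#' coordinate convention. `(left)` in the query block is computed from
#' `genome` when supplied, else printed as `(0)`.
#'
#' @param records a records `data.frame`.
#' @param file output path.
#' @param genome optional genome index (see [genome_index()]) used to
#'   compute the bases left of each hit.
#' @return `file`, invisibly.
#' @export
write_repeatmasker_out <- function(records, file, genome = NULL) {
  validate_records(records)
  header <- c(
    paste("  SW   perc perc perc  query     position in query           ",
          "matching  repeat         position in repeat"),
    paste("score  div. del. ins.  sequence  begin  end        (left)    ",
          "repeat    class/family    begin  end (left)     ID"),
    ""
  )
  fmt_num <- function(x) formatC(x, format = "f", digits = 1)
  lines <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    q_left <- 0L
    if (!is.null(genome)) {
      gi <- genome_index(genome)
      if (!r$query_name %in% names(gi))
        stop("query '", r$query_name, "' not in genome index")
      q_left <- as.integer(gi[[r$query_name]] - r$query_end)
    }
    rep_cols <- if (r$strand == "+") {
      c(r$repeat_begin, r$repeat_end, paste0("(", r$repeat_left, ")"))
    } else {
      c(paste0("(", r$repeat_left, ")"), r$repeat_end, r$repeat_begin)
    }
    lines[i] <- paste(
      r$sw_score, fmt_num(r$divergence_percent), fmt_num(r$deletion_percent),
      fmt_num(r$insertion_percent), r$query_name, r$query_begin, r$query_end,
      paste0("(", q_left, ")"), if (r$strand == "-") "C" else "+",
      r$repeat_name, r$repeat_class_family,
      rep_cols[1], rep_cols[2], rep_cols[3], r$linkage_id,
      if (isTRUE(r$overlap_flag)) "*" else NULL
    )
  }
  writeLines(c(header, lines), file)
  invisible(file)
}

#' Genome index: sequence lengths and total size
#'
#' Normalises a genome representation into a named vector of sequence
#' lengths, the denominator of all coverage percentages.
#'
#' @param x a named numeric vector of lengths, a `DNAStringSet`, or the path
#'   to a two-column (name, length) tab-separated file.
#' @return Named numeric vector of per-sequence lengths; `sum()` of it is
#'   the genome size.
#' @export
genome_index <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    tab <- utils::read.table(x, header = FALSE, sep = "\t",
                             col.names = c("name", "length"),
                             stringsAsFactors = FALSE)
    x <- stats::setNames(as.numeric(tab$length), tab$name)
  } else if (methods::is(x, "DNAStringSet")) {
    x <- stats::setNames(as.numeric(Biostrings::width(x)), names(x))
  }
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("genome index must be a named numeric vector of sequence lengths")
  if (length(x) == 0 || any(x <= 0))
    stop("genome index is empty or has non-positive lengths")
  x
}

#' Read and write FASTA sequence libraries
#'
#' Thin wrappers around Biostrings that enforce the library contract:
#' unique identifiers (first whitespace token of the header), non-empty
#' sequences, and upper-cased nucleotides.
#'
#' @param file path to a FASTA file.
#' @return `read_fasta()`: a `DNAStringSet`; `write_fasta()`: `file`,
#'   invisibly.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence identifiers in ", file, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0))
    stop("empty sequence(s) in ", file)
  # normalise to upper case so masking case carries no information
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' @rdname read_fasta
#' @param x a `DNAStringSet` or named character vector of sequences.
#' @export
write_fasta <- function(x, file) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sequences must carry unique names")
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
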