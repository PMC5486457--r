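#' TE taxonomy: mapping class/family strings to (type, clade)
#'
#' RepeatMasker class/family labels (e.g. `"LINE/CR1"`, `"LTR/ERVL-MaLR"`)
#' vary with the repeat library release, so the mapping onto the reported
#' taxonomy — SINE, LINE (CR1 / R2 / RTE / other), LTR (ERV1 / ERV2 / ERV3 /
#' other), DNA, Unclassified — is an ordered rule table: the first regular
#' expression that matches a record's `repeat_class_family` wins, and
#' anything unmatched falls through to `(Unclassified, None)`.
#'
#' The default table maps RepBase-style labels: `LTR/ERVK` to ERV2
#' (beta/alpha-like) and `LTR/ERVL` to ERV3 (spuma/ERV-L-like), alongside
#' the literal `LTR/ERV1`, `LTR/ERV2`, `LTR/ERV3` spellings.
#'
#' @name taxonomy
NULL

.te_types <- c("SINE", "LINE", "LTR", "DNA", "Unclassified")
.te_clades <- c("CR1", "R2", "RTE", "OtherLINE",
                "ERV1", "ERV2", "ERV3", "OtherLTR", "None")

#' @describeIn taxonomy the built-in rule table, a `data.frame` with columns
#'   `pattern` (regex on `repeat_class_family`, case-insensitive), `te_type`
#'   and `clade`.
#' @export
default_taxonomy <- function() {
  data.frame(
    pattern = c("^SINE",
                "^LINE/CR1", "^LINE/R2", "^LINE/RTE", "^LINE",
                "^LTR/ERVL", "^LTR/ERVK",
                "^LTR/ERV1", "^LTR/ERV2", "^LTR/ERV3", "^LTR",
                "^DNA"),
    te_type = c("SINE",
                "LINE", "LINE", "LINE", "LINE",
                "LTR", "LTR", "LTR", "LTR", "LTR", "LTR",
                "DNA"),
    clade = c("None",
              "CR1", "R2", "RTE", "OtherLINE",
              "ERV3", "ERV2", "ERV1", "ERV2", "ERV3", "OtherLTR",
              "None"),
    stringsAsFactors = FALSE
  )
}

validate_taxonomy <- function(taxonomy) {
  stopifnot(is.data.frame(taxonomy),
            all(c("pattern", "te_type", "clade") %in% names(taxonomy)))
  if (!all(taxonomy$te_type %in% .te_types))
    stop("unknown te_type value(s): ",
         paste(setdiff(taxonomy$te_type, .te_types), collapse = ", "))
  if (!all(taxonomy$clade %in% .te_clades))
    stop("unknown clade value(s): ",
         paste(setdiff(taxonomy$clade, .te_clades), collapse = ", "))
  invisible(taxonomy)
}

#' @describeIn taxonomy read a rule table from a tab-separated file with
#'   columns `pattern`, `te_type`, `clade` (header required).
#' @param file path to a tab-separated taxonomy file.
#' @export
read_taxonomy <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  validate_taxonomy(tab)
  tab
}

#' Classify class/family strings into the TE taxonomy
#'
#' Total and deterministic: every input string maps to exactly one
#' `(te_type, clade)` pair; the first matching rule wins and unmatched
#' strings become `(Unclassified, None)`.
#'
#' @param x character vector of `repeat_class_family` strings.
#' @param taxonomy a rule table (default [default_taxonomy()]).
#' @return A `data.frame` with columns `te_type` and `clade`, one row per
#'   element of `x`.
#' @examples
#' classify_family(c("LINE/CR1", "LINE/L2", "FooBar"))
#' @export
classify_family <- function(x, taxonomy = default_taxonomy()) {
  validate_taxonomy(taxonomy)
  x <- as.character(x)
  te_type <- rep("Unclassified", length(x))
  clade <- rep("None", length(x))
  unset <- rep(TRUE, length(x))
  for (i in seq_len(nrow(taxonomy))) {
    hit <- unset & grepl(taxonomy$pattern[i], x, ignore.case = TRUE)
    te_type[hit] <- taxonomy$te_type[i]
    clade[hit] <- taxonomy$clade[i]
    unset <- unset & !hit
  }
  data.frame(te_type = te_type, clade = clade, stringsAsFactors = FALSE)
}

#' Attach taxonomy columns to a records table
#'
#' @param records a records `data.frame` (see [repeat_records()]).
#' @param taxonomy a rule table (default [default_taxonomy()]).
#' @return `records` with `te_type` and `clade` columns appended.
#' @export
classify_repeats <- function(records, taxonomy = default_taxonomy()) {
  validate_records(records)
  cls <- classify_family(records$repeat_class_family, taxonomy)
  records$te_type <- cls$te_type
  records$clade <- cls$clade
  records
}
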