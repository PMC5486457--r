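#' Jukes-Cantor correction of repeat divergence
#'
#' Converts the observed proportion of mismatched sites `D` between a repeat
#' copy and its family consensus (in percent, as printed in RepeatMasker
#' output) into the substitution level `K`, correcting for multiple hits
#' under the one-parameter substitution model:
#' `K = -300/4 * ln(1 - D * 4/300)`, both in percent units. `K >= D`
#' everywhere, `K(0) = 0`, and `K -> D` as `D -> 0`; the formula diverges at
#' `D = 75`, which is therefore excluded from the domain.
#'
#' @param D percent divergence, `0 <= D < 75` (vectorised).
#' @return `K`, the estimated substitutions per site in percent units.
#' @examples
#' jukes_cantor_K(10)   # ~10.73
#' @export
jukes_cantor_K <- function(D) {
  if (any(!is.finite(D)) || any(D < 0) || any(D >= 75))
    stop("divergence D must satisfy 0 <= D < 75 (percent); ",
         "the Jukes-Cantor correction is undefined at D >= 75")
  -75 * log(1 - D / 75)
}

#' Expected observed divergence at a given substitution level
#'
#' Closed-form inverse of [jukes_cantor_K()]: a sequence that has accumulated
#' `K` percent substitutions per site shows an expected proportion
#' `D = 75 * (1 - exp(-4K/300))` percent of differing sites.
#'
#' @param K substitution level in percent units, `K >= 0`.
#' @return Expected percent divergence `D < 75`.
#' @export
divergence_from_K <- function(K) {
  if (any(!is.finite(K)) || any(K < 0)) stop("K must be >= 0")
  75 * (1 - exp(-K / 75))
}

#' Insertion age from substitution level
#'
#' `t = K / (2r)`: under neutrality a copy that has accumulated `K`
#' substitutions per site (here given in percent units and converted to a
#' per-site fraction) since inserting diverged for `t` years at rate `r`
#' substitutions per site per year on each lineage-independent copy.
#'
#' @param K substitution level in percent units, `K >= 0` (vectorised).
#' @param r substitution rate per site per year, `r > 0`.
#' @return Age in years.
#' @examples
#' age_from_K(6, r = 2.0e-9) / 1e6   # 15 My
#' @export
age_from_K <- function(K, r) {
  if (any(!is.finite(K)) || any(K < 0)) stop("K must be >= 0")
  if (length(r) != 1 || !is.finite(r) || r <= 0)
    stop("substitution rate r must be a single value > 0")
  (K / 100) / (2 * r)
}

#' Neutral substitution rates for five avian species
#'
#' Average nucleotide substitution rates per site per year used to convert
#' substitution levels into insertion ages.
#'
#' @return Named numeric vector (per site per year) for budgerigar, chicken,
#'   medium ground finch, turkey and zebra finch.
#' @export
species_rates <- function() {
  c(budgerigar = 2.22e-9,
    chicken = 2.00e-9,
    medium_ground_finch = 3.56e-9,
    turkey = 2.05e-9,
    zebra_finch = 3.44e-9)
}

#' Binned insertion-age landscape per TE class
#'
#' Converts each record's divergence to an age via [jukes_cantor_K()] and
#' [age_from_K()] and accumulates the record's span (raw length, no overlap
#' resolution: the landscape is a divergence distribution, not a masked-base
#' total) into half-open age bins `[lo, hi)` of `bin_width_My` million
#' years. Bin values are percent of the genome, so the sum over bins of a
#' class equals that class's total span among aged records. Records with
#' divergence at or above 75% are excluded and counted in the
#' `"excluded_records"` attribute.
#'
#' @param records a records `data.frame`.
#' @param genome a genome index ([genome_index()]).
#' @param species species name looked up in `rates` (ignored when `rate`
#'   is given).
#' @param rate substitution rate per site per year; overrides `species`.
#' @param rates named rate vector, default [species_rates()].
#' @param bin_width_My bin width in million years (default 5).
#' @param by `"clade"` (default; clade-less types fall back to their type
#'   label) or `"te_type"`.
#' @param taxonomy taxonomy rule table.
#' @return A `data.frame` with columns `bin_lo_My`, `bin_hi_My`, `class`,
#'   `percent`, with attributes `excluded_records`, `bin_width_My` and
#'   `rate`.
#' @export
age_landscape <- function(records, genome, species = NULL, rate = NULL,
                          rates = species_rates(), bin_width_My = 5,
                          by = c("clade", "te_type"),
                          taxonomy = default_taxonomy()) {
  by <- match.arg(by)
  gi <- genome_index(genome)
  if (is.null(rate)) {
    if (is.null(species) || !species %in% names(rates))
      stop("unknown species '", if (is.null(species)) "<none>" else species,
           "'; known species: ", paste(names(rates), collapse = ", "))
    rate <- rates[[species]]
  }
  if (bin_width_My <= 0) stop("bin_width_My must be > 0")
  # tolerate in-memory tables carrying out-of-domain divergences: such
  # records cannot be aged and are only counted
  aged <- records$divergence_percent < 75
  excluded <- sum(!aged)
  records <- classify_repeats(records[aged, , drop = FALSE], taxonomy)
  cls <- if (by == "te_type") records$te_type else
    ifelse(records$clade == "None", records$te_type, records$clade)
  if (nrow(records) == 0) {
    out <- data.frame(bin_lo_My = numeric(0), bin_hi_My = numeric(0),
                      class = character(0), percent = numeric(0))
  } else {
    K <- jukes_cantor_K(records$divergence_percent)
    t_My <- age_from_K(K, rate) / 1e6
    bin <- floor(t_My / bin_width_My)
    len <- records$query_end - records$query_begin + 1
    classes <- sort(unique(cls))
    bins <- 0:max(bin)
    grid <- expand.grid(bin = bins, class = classes,
                        stringsAsFactors = FALSE)
    bp <- vapply(seq_len(nrow(grid)), function(i) {
      sum(len[bin == grid$bin[i] & cls == grid$class[i]])
    }, numeric(1))
    out <- data.frame(bin_lo_My = grid$bin * bin_width_My,
                      bin_hi_My = (grid$bin + 1) * bin_width_My,
                      class = grid$class,
                      percent = 100 * bp / sum(gi),
                      stringsAsFactors = FALSE)
  }
  attr(out, "excluded_records") <- excluded
  attr(out, "bin_width_My") <- bin_width_My
  attr(out, "rate") <- rate
  out
}
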