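#' Synthetic TE data with ground truth
#'
#' Generators for toy genomes, annotation files, repeat libraries and
#' candidate elements in which every quantity the pipeline estimates —
#' coverage, insertion age, family partition, screening category — is known
#' by construction. Copies are consensus sequences evolved under the
#' Jukes-Cantor substitution process (substitutions only, no indels, so the
#' realised divergence is the sole driver of the age estimate) and placed
#' without overlap, which keeps generation independent of the
#' overlap-resolution logic under test. All randomness is governed by a
#' single integer seed; identical configuration and seed give byte-identical
#' output files.
#'
#' @name synthetic_data
NULL

.dna_bases <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(.dna_bases, n, replace = TRUE), collapse = "")
}

#' Mutate a sequence under the Jukes-Cantor process
#'
#' Each site is substituted independently so that the expected number of
#' substitutions per site is `K/100`; the final base is drawn from the exact
#' JC transition distribution (stay with probability
#' `1/4 + 3/4 exp(-4K/300)`, otherwise uniformly one of the other three
#' bases). The expected observed divergence therefore follows the closed
#' form `D = 75 (1 - exp(-4K/300))` percent (see [divergence_from_K()]).
#' `N` sites are left untouched.
#'
#' @param x a `DNAString` or character sequence.
#' @param K_percent substitution level in percent units, `K >= 0`.
#' @param seed optional integer seed for reproducibility.
#' @return The mutated sequence, same class as the input.
#' @export
mutate_jc <- function(x, K_percent, seed = NULL) {
  if (length(K_percent) != 1 || !is.finite(K_percent) || K_percent < 0)
    stop("K_percent must be a single value >= 0")
  if (!is.null(seed)) set.seed(seed)
  was_dna <- methods::is(x, "DNAString")
  chars <- strsplit(toupper(as.character(x)), "")[[1]]
  p_same <- 0.25 + 0.75 * exp(-K_percent / 75)
  idx <- match(chars, .dna_bases)
  mutable <- !is.na(idx)
  hit <- mutable & (stats::runif(length(chars)) > p_same)
  if (any(hit)) {
    shift <- sample.int(3, sum(hit), replace = TRUE)
    chars[hit] <- .dna_bases[((idx[hit] - 1 + shift) %% 4) + 1]
  }
  out <- paste(chars, collapse = "")
  if (was_dna) Biostrings::DNAString(out) else out
}

#' Simulation configuration for a toy genome
#'
#' The default configuration emulates, at desk scale, the TE profile of a
#' compact avian-like genome: interspersed repeats near 10% of the genome,
#' dominated by CR1 LINEs, with ERV3 the most abundant ERV class, ERV1 and
#' ERV2 minor, and DNA/SINE repeats rare; LINE copies span old (30 My) to
#' recent (10 My) insertions while DNA and SINE copies are ancient fossils.
#' Ages are converted to the substitution level each copy must carry via
#' `K = 2rt`, the inverse of the age equation `t = K/2r`.
#'
#' @param genome_length genome size in bp (default 100000).
#' @param genome_name name of the single simulated sequence.
#' @param species species whose substitution rate is used (default
#'   `"chicken"`; see [species_rates()]).
#' @param rate substitution rate per site per year; overrides `species`.
#' @param families `data.frame` with columns `id`, `class_family`, `length`:
#'   the consensus set.
#' @param plan `data.frame` with columns `consensus_id`, `count`, `age_My`:
#'   how many copies of each consensus to plant at which true age.
#' @param seed integer seed fixing all randomness.
#' @return A list of class `te_sim_config`.
#' @export
simulation_config <- function(genome_length = 100000,
                              genome_name = "chr_sim",
                              species = "chicken",
                              rate = NULL,
                              families = NULL,
                              plan = NULL,
                              seed = 1) {
  if (is.null(rate)) {
    rates <- species_rates()
    if (!species %in% names(rates))
      stop("unknown species '", species, "'; known species: ",
           paste(names(rates), collapse = ", "))
    rate <- rates[[species]]
  }
  if (is.null(families))
    families <- data.frame(
      id = c("CR1_sim", "ERV1_sim", "ERV2_sim", "ERV3_sim",
             "SINE_sim", "DNA_sim"),
      class_family = c("LINE/CR1", "LTR/ERV1", "LTR/ERVK", "LTR/ERVL",
                       "SINE/tRNA", "DNA/hAT"),
      length = c(600L, 450L, 450L, 450L, 130L, 300L),
      stringsAsFactors = FALSE)
  if (is.null(plan))
    plan <- data.frame(
      consensus_id = c("CR1_sim", "CR1_sim", "CR1_sim", "ERV3_sim",
                       "ERV1_sim", "ERV2_sim", "DNA_sim", "SINE_sim"),
      count = c(6L, 4L, 2L, 3L, 1L, 1L, 1L, 1L),
      age_My = c(30, 20, 10, 25, 15, 16, 45, 50),
      stringsAsFactors = FALSE)
  stopifnot(all(c("id", "class_family", "length") %in% names(families)),
            all(c("consensus_id", "count", "age_My") %in% names(plan)),
            all(plan$consensus_id %in% families$id),
            all(plan$count >= 0), all(plan$age_My >= 0),
            genome_length > 0)
  structure(list(genome_length = as.integer(genome_length),
                 genome_name = genome_name, rate = rate,
                 families = families, plan = plan, seed = as.integer(seed)),
            class = "te_sim_config")
}

#' Simulate a genome with planted TE copies and its annotation
#'
#' Draws a random background genome, evolves each planted copy from its
#' consensus to the substitution level `K = 2rt` implied by its true age,
#' inserts the copies at random non-overlapping positions on random strands,
#' and emits the matching annotation records (the realised divergence of
#' each copy, rounded to one decimal as annotation files print it) together
#' with a ground-truth table.
#'
#' @param config a [simulation_config()].
#' @param outdir optional directory; when given, `genome.fa`,
#'   `annotation.out` and `truth.tsv` are written there.
#' @return A list with `genome` (named `DNAStringSet`), `records`
#'   (annotation `data.frame`), `truth` (per-copy `data.frame` with true
#'   coordinates, clade, `true_K`, `true_age_My`, `realized_D`),
#'   `genome_index`, and `files` (paths, when `outdir` was given).
#' @export
simulate_genome <- function(config = simulation_config(), outdir = NULL) {
  stopifnot(inherits(config, "te_sim_config"))
  set.seed(config$seed)
  fam <- config$families
  consensus <- stats::setNames(
    vapply(fam$length, random_dna, character(1)), fam$id)
  plan <- config$plan[config$plan$count > 0, , drop = FALSE]
  copies <- if (nrow(plan) == 0) data.frame() else
    data.frame(consensus_id = rep(plan$consensus_id, plan$count),
               age_My = rep(plan$age_My, plan$count),
               stringsAsFactors = FALSE)
  n <- nrow(copies)
  genome_chars <- sample(.dna_bases, config$genome_length, replace = TRUE)
  records <- repeat_records(integer(0), numeric(0), character(0), integer(0),
                            integer(0), character(0), character(0),
                            character(0), linkage_id = integer(0))
  truth <- data.frame(copy = integer(0), consensus_id = character(0),
                      class_family = character(0), te_type = character(0),
                      clade = character(0), begin = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), true_K = numeric(0),
                      true_age_My = numeric(0), realized_D = numeric(0))
  if (n > 0) {
    copies <- copies[sample.int(n), , drop = FALSE]
    len <- fam$length[match(copies$consensus_id, fam$id)]
    total <- sum(len)
    if (total > config$genome_length)
      stop("insertion plan exceeds genome capacity: ", total,
           " bp of copies into a ", config$genome_length, " bp genome")
    # true K (percent) from true age: K = 2 r t, t in years
    true_K <- 2 * config$rate * copies$age_My * 1e6 * 100
    free <- config$genome_length - total
    cuts <- sort(sample.int(free + 1, n, replace = TRUE) - 1L)
    starts <- cuts + c(0L, cumsum(len)[-n]) + 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    realized_D <- numeric(n)
    for (i in seq_len(n)) {
      cons <- consensus[[copies$consensus_id[i]]]
      mut <- mutate_jc(cons, true_K[i])
      realized_D[i] <- 100 *
        sum(strsplit(mut, "")[[1]] != strsplit(cons, "")[[1]]) / nchar(cons)
      placed <- if (strands[i] == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
      else mut
      genome_chars[starts[i]:(starts[i] + len[i] - 1)] <-
        strsplit(placed, "")[[1]]
    }
    cls <- fam$class_family[match(copies$consensus_id, fam$id)]
    mismatches <- round(realized_D * len / 100)
    records <- repeat_records(
      sw_score = pmax(1L, as.integer(len - 2 * mismatches)),
      divergence_percent = round(realized_D, 1),
      query_name = config$genome_name,
      query_begin = starts, query_end = starts + len - 1L,
      strand = strands, repeat_name = copies$consensus_id,
      repeat_class_family = cls,
      repeat_begin = 1L, repeat_end = len, repeat_left = 0L,
      linkage_id = seq_len(n))
    tax <- classify_family(cls)
    truth <- data.frame(copy = seq_len(n), consensus_id = copies$consensus_id,
                        class_family = cls, te_type = tax$te_type,
                        clade = tax$clade, begin = starts,
                        end = starts + len - 1L, strand = strands,
                        length = len, true_K = true_K,
                        true_age_My = copies$age_My,
                        realized_D = realized_D, stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(genome_chars, collapse = ""), config$genome_name))
  out <- list(genome = genome, records = records, truth = truth,
              genome_index = genome_index(genome), consensus = consensus,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- c(genome = file.path(outdir, "genome.fa"),
               annotation = file.path(outdir, "annotation.out"),
               truth = file.path(outdir, "truth.tsv"))
    write_fasta(genome, files[["genome"]])
    write_repeatmasker_out(records, files[["annotation"]],
                           genome = out$genome_index)
    utils::write.table(truth, files[["truth"]], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    out$files <- files
  }
  out
}

#' Simulate a redundant repeat library with known families
#'
#' Each planted family consists of a consensus, full-length members diverged
#' from it by a configurable substitution level, and truncated fragments —
#' the redundancy the 80-80 rule is meant to collapse. Unrelated singleton
#' sequences are added as their own families. Defaults keep family members
#' well inside the 80-80 thresholds (K = 8%, observed identity around 0.92)
#' and include one decoy relative far outside them (K = 40%, observed
#' identity around 0.69, below the 80% rule), so the true partition is
#' unambiguous.
#'
#' @param n_families number of planted families (default 4).
#' @param lengths consensus lengths, recycled over families.
#' @param members full-length diverged members per family (default 2).
#' @param member_K substitution level of members, percent (default 8).
#' @param fragments truncated members per family (default 1).
#' @param fragment_frac fraction of the consensus kept in a fragment.
#' @param decoys per-family distant relatives that must NOT cluster
#'   (default 1).
#' @param decoy_K substitution level of decoys, percent (default 40).
#' @param unrelated number of unrelated singletons (default 2).
#' @param seed integer seed.
#' @return A list with `library` (named `DNAStringSet`) and `truth`
#'   (`data.frame` with `id`, `family`).
#' @export
simulate_library <- function(n_families = 4, lengths = c(480L, 420L, 520L, 360L),
                             members = 2, member_K = 8,
                             fragments = 1, fragment_frac = 0.5,
                             decoys = 1, decoy_K = 40,
                             unrelated = 2, seed = 1) {
  set.seed(seed)
  lengths <- rep_len(lengths, n_families)
  seqs <- character(0)
  ids <- character(0)
  family <- character(0)
  for (f in seq_len(n_families)) {
    cons <- random_dna(lengths[f])
    fam_name <- paste0("fam", f)
    add <- function(id, s, fam) {
      seqs <<- c(seqs, s); ids <<- c(ids, id); family <<- c(family, fam)
    }
    add(paste0(fam_name, "_consensus"), cons, fam_name)
    for (m in seq_len(members))
      add(paste0(fam_name, "_m", m), mutate_jc(cons, member_K), fam_name)
    for (fr in seq_len(fragments)) {
      keep <- max(30L, as.integer(round(fragment_frac * lengths[f])))
      add(paste0(fam_name, "_frag", fr),
          mutate_jc(substr(cons, 1, keep), member_K), fam_name)
    }
    for (d in seq_len(decoys))
      add(paste0(fam_name, "_decoy", d), mutate_jc(cons, decoy_K),
          paste0(fam_name, "_decoy", d))
  }
  for (u in seq_len(unrelated)) {
    seqs <- c(seqs, random_dna(sample(300:500, 1)))
    ids <- c(ids, paste0("unrel", u))
    family <- c(family, paste0("unrel", u))
  }
  list(library = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
       truth = data.frame(id = ids, family = family, stringsAsFactors = FALSE))
}

# fixed codon per amino acid (standard code); TAA terminates every ORF
.codon_table <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                  L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

encode_protein <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  bad <- !chars %in% names(.codon_table)
  if (any(bad)) stop("cannot encode amino acid(s): ",
                     paste(unique(chars[bad]), collapse = ", "))
  paste0(paste(.codon_table[chars], collapse = ""), "TAA")
}

random_protein <- function(n, start_met = FALSE) {
  aa <- sample(names(.codon_table), n, replace = TRUE)
  if (start_met && n > 0) aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Default plan of planted LINE/ERV elements
#'
#' One row per element to synthesise, spanning every screening category of
#' both ladders, including the strict-threshold boundaries (an ORF2 of
#' exactly 600 aa is not a full LINE; POL and ENV matches of exactly 800 and
#' 480 aa do not count as domains).
#'
#' @return A `data.frame` with columns `id`, `mode` (`"line"`/`"erv"`),
#'   `clade`, `category` (planted truth), and per-feature lengths in aa
#'   (`orf1_aa`, `orf2_aa`, `rt_aa`, `env_aa`, `gag_aa`, `pol_aa`; 0 means
#'   absent).
#' @export
default_element_plan <- function() {
  line <- function(id, clade, category, orf1, orf2, rt)
    data.frame(id = id, mode = "line", clade = clade, category = category,
               orf1_aa = orf1, orf2_aa = orf2, rt_aa = rt,
               env_aa = 0, gag_aa = 0, pol_aa = 0, stringsAsFactors = FALSE)
  erv <- function(id, clade, category, env, gag, pol)
    data.frame(id = id, mode = "erv", clade = clade, category = category,
               orf1_aa = 0, orf2_aa = 0, rt_aa = 0,
               env_aa = env, gag_aa = gag, pol_aa = pol,
               stringsAsFactors = FALSE)
  rbind(
    line("line_full_cr1", "CR1", "full_LINE", 300, 680, 250),
    line("line_full_r2", "R2", "full_LINE", 250, 900, 250),
    line("line_orf2_only", "CR1", "ORF2_only", 0, 700, 250),
    line("line_orf1_boundary", "CR1", "ORF1_only", 300, 600, 250),
    line("line_rt_only", "CR1", "intact_RT_only", 0, 350, 250),
    line("line_defective", "CR1", "defective", 0, 150, 0),
    erv("erv_full", "ERV1", "full_ERV", 500, 520, 850),
    erv("erv_pol_only", "ERV3", "partial_ERV", 0, 0, 850),
    erv("erv_env_gag", "ERV2", "partial_ERV", 500, 520, 0),
    erv("erv_pol_boundary", "ERV3", "defective", 0, 0, 800),
    erv("erv_env_boundary", "ERV1", "defective", 480, 0, 0),
    erv("erv_defective", "ERV2", "defective", 0, 0, 0)
  )
}

#' Simulate candidate elements with planted ORFs and domains
#'
#' Builds nucleotide elements realising a plan of screening categories:
#' planted ORFs are real ATG-to-stop reading frames encoding either random
#' protein (ORF1, decoy ORFs) or exact prefixes of the emitted stand-in
#' reference proteins (RT inside ORF2; ENV/GAG/POL domains), so the matched
#' alignment spans equal the planted lengths exactly. Reference proteins
#' are synthetic stand-ins generated alongside (they model only the
#' alignability the screen requires, not real retroviral domains).
#'
#' @param plan an element plan, see [default_element_plan()].
#' @param seed integer seed.
#' @param pad_nt random padding around planted ORFs (default 30 nt; short
#'   enough never to harbour a spurious 100-aa upstream ORF).
#' @return A list with `elements` (named `DNAStringSet`), `truth`
#'   (`plan` columns `id`, `mode`, `clade`, `category`), `rt_refs` and
#'   `erv_refs` (`AAStringSet` stand-in references).
#' @export
simulate_elements <- function(plan = default_element_plan(), seed = 1,
                              pad_nt = 30) {
  set.seed(seed)
  rt_ref <- random_protein(400)
  env_ref <- random_protein(600, start_met = TRUE)
  gag_ref <- random_protein(600, start_met = TRUE)
  pol_ref <- random_protein(900, start_met = TRUE)
  refs <- list(ENV = env_ref, GAG = gag_ref, POL = pol_ref)
  pad <- function() random_dna(pad_nt)
  # in-frame stop ahead of each planted ORF so random padding can never
  # prepend codons to it (an upstream in-frame ATG would otherwise lengthen
  # a boundary ORF past its planted size)
  orf <- function(aa) paste0("TAA", encode_protein(aa))
  elements <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    parts <- pad()
    if (p$mode == "line") {
      if (p$rt_aa > 0 && p$rt_aa + 1 > p$orf2_aa)
        stop("element '", p$id, "': requested RT span (", p$rt_aa,
             " aa) inconsistent with ORF2 length (", p$orf2_aa, " aa)")
      if (p$orf1_aa > 0)
        parts <- c(parts, orf(random_protein(p$orf1_aa, start_met = TRUE)),
                   pad())
      if (p$orf2_aa > 0) {
        if (p$rt_aa > 0) {
          lead <- p$orf2_aa - p$rt_aa - 1   # M + lead filler + RT prefix
          half <- lead %/% 2
          orf2 <- paste0("M", random_protein(half),
                         substr(rt_ref, 1, p$rt_aa),
                         random_protein(lead - half))
        } else {
          orf2 <- random_protein(p$orf2_aa, start_met = TRUE)
        }
        parts <- c(parts, orf(orf2), pad())
      }
    } else {
      for (lab in c("GAG", "POL", "ENV")) {
        want <- p[[paste0(tolower(lab), "_aa")]]
        if (want > 0) {
          # exact reference prefix (reference starts with M), so the
          # matched span equals the planted length exactly
          parts <- c(parts, orf(substr(refs[[lab]], 1, want)), pad())
        }
      }
    }
    elements[i] <- paste(parts, collapse = "")
  }
  list(elements = Biostrings::DNAStringSet(stats::setNames(elements, plan$id)),
       truth = plan[, c("id", "mode", "clade", "category")],
       rt_refs = Biostrings::AAStringSet(c(RT_ref = rt_ref)),
       erv_refs = Biostrings::AAStringSet(c(ENV_ref = env_ref,
                                            GAG_ref = gag_ref,
                                            POL_ref = pol_ref)))
}
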