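---
title: "Methods: TE landscapes from RepeatMasker annotations"
author: "telandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE landscapes from RepeatMasker annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telandscape)
```

# Scope

`telandscape` covers the post-annotation stage of a transposable-element
(TE) survey of a compact genome, of the kind run on avian assemblies:
given RepeatMasker-style annotation records and the genome's sequence
lengths, it classifies repeat copies into a TE taxonomy, accounts for
masked bases per class, converts copy divergence into insertion ages and
age landscapes, collapses redundant repeat libraries with the 80-80 family
rule, and screens candidate LINE and ERV elements for intactness. It does
not run the upstream discovery tools (RepeatMasker, RepeatModeler, LTR or
non-LTR miners); it consumes their output formats.

# The annotation model

A repeat record is one annotated TE copy: 1-based inclusive genome
coordinates, strand, a Smith-Waterman score, a repeat name, a
slash-delimited class/family label, and the percent divergence $D$ of the
copy from its family consensus. $D$ is taken exactly as printed in the
`.out` file — including CpG sites, which tends to make age estimates older;
no CpG or Kimura-2-parameter correction is applied, and each record
(including fragments sharing a linkage id) is aged independently, because
divergence is reported per fragmented copy.

Class/family strings vary with the repeat-library release, so
classification is an ordered rule table (regex on the class/family string,
first match wins, unmatched strings fall through to Unclassified). The
default table maps onto SINE; LINE with clades CR1, R2, RTE and OtherLINE;
LTR with ERV1 (gamma-like, `LTR/ERV1`), ERV2 (beta/alpha-like, `LTR/ERVK`),
ERV3 (spuma/ERV-L-like, `LTR/ERVL`) and OtherLTR; DNA; Unclassified. The
table ships as an editable TSV (`inst/extdata/taxonomy.tsv`).

# Coverage accounting

RepeatMasker emits overlapping hits, while a coverage table reports masked
bases, so every base must be attributed to exactly one record. Among
records covering a base the highest Smith-Waterman score claims it, with
ties broken by earlier start and then input order — the same precedence
RepeatMasker itself uses when masking. After this resolution, clade rows
partition their type's bases, type rows sum to the grand total, and

> masked bp + unmasked bp = genome length

holds on every input; the tests verify this identity, the clade/type
hierarchy, and exact agreement with a per-base brute-force sweep on random
record sets. Percentages are kept at full precision internally and printed
to two decimals. Whether published coverage tables counted each base once
across classes is ambiguous in general; disjoint attribution is what this
package implements, and the invariants above are the consequence.

# Divergence correction and insertion age

Observed divergence underestimates the substitutions a copy has actually
accumulated because of multiple hits at one site. With $D$ in percent
units, the one-parameter (Jukes-Cantor) correction is

$$K = -\frac{300}{4}\,\ln\!\left(1 - \frac{4D}{300}\right),$$

which is strictly increasing, satisfies $K(0)=0$ and $K \ge D$, approaches
$D$ for small $D$, and diverges at $D = 75\%$ — the saturation point of a
4-letter alphabet. Records at or above 75% divergence are therefore
rejected at parse time (with a warning) and, if present in an in-memory
table, excluded from aging and counted separately. They would still be
countable as masked bases, which is why the coverage module does not share
this restriction.

The insertion age is $t = K/2r$ with $K$ converted to a per-site fraction
and $r$ the species' neutral substitution rate per site per year. The five
preloaded rates (budgerigar $2.22\times10^{-9}$, chicken
$2.00\times10^{-9}$, medium ground finch $3.56\times10^{-9}$, turkey
$2.05\times10^{-9}$, zebra finch $3.44\times10^{-9}$) ship in
`species_rates()` and `inst/extdata/species_rates.tsv`.

An age landscape bins each record's span by its age in half-open intervals
$[lo, hi)$ of 5 My by default (the width is configurable; published
landscape figures plot million-year axes without fixing a width, and 5 My
resolves the 0-60 My range these genomes span without emptying bins). Two
deliberate choices:

* **Raw record lengths, no overlap resolution.** The landscape is a
  divergence distribution of copies, not a masked-base total; this is a
  documented divergence from the coverage module's semantics.
* **Denominator = total genome length**, matching "percentage of the
  genome" on the y-axis, not the TE fraction.

The mass identity — the sum over bins of a class equals that class's total
span among aged records — holds by construction and is asserted on every
simulated input.

# The 80-80 family rule

Two library sequences belong to one family if they can be aligned over
more than 80% of their length with more than 80% identity. The package
operationalises this as follows, with every choice configurable:

* **Alignment**: local (Smith-Waterman) with affine gaps; match $+1$,
  mismatch $-1$, a gap of length $L$ costs $5 + L$. Both strands are tried,
  so clustering is invariant to reverse-complementing any member.
* **Identity**: matching columns / aligned columns (gap columns count
  against identity).
* **"80% of their length"**: fraction of the *shorter* sequence covered by
  the aligned span, so fragments are absorbed into their parent family —
  the behaviour redundancy removal needs in a combined library
  (`coverage_of = "longer"` or `"both"` are available).
* **Thresholds are strict** (`> 0.80`), following the wording "more than
  80%".
* **Clustering is single linkage** (connected components of the
  above-threshold pair graph): the rule itself defines a relation on pairs,
  not a scheme, and single linkage is the only choice that never splits an
  above-threshold pair. The representative is the longest member (ties by
  lexicographically smallest identifier), because the longest member best
  preserves the family's consensus span.

Local alignments are often co-optimal: several different tracebacks attain
the same optimal score, and identity/coverage can differ slightly between
them. Scores are therefore the exactly-testable quantity; the test suite
checks scores against an independent exhaustive dynamic-programming
reference on every random pair, checks identity/coverage exactly on
constructed pairs whose optimum is unique, and checks that the 80-80
decision — and hence the family partition — agrees with the reference
everywhere.

# Intactness screening

**LINEs.** ORFs are ATG-to-stop spans under the standard genetic code in
all six frames (a stop-to-stop mode exists; the ATG definition is the
default because "ORF" in element screening conventionally means a
translatable protein). ORF2 is the longest ORF whose translation aligns
locally (BLOSUM62, gap open 11, extend 1) to a reverse-transcriptase
reference with identity $\ge 0.25$ over $\ge 200$ aligned residues —
thresholds that are not fixed by any published protocol and are therefore
explicit, documented defaults. ORF1 is any other ORF of $\ge 100$ aa
upstream of ORF2 on the same strand. "Intact RT" is interpreted as an
accepted RT alignment lying within a single ORF — uninterrupted by stops or
frameshifts — which is automatic for any hit found by this procedure; a
disrupted RT splits across ORFs, each piece failing the 200-aa floor. The
category ladder is: `full_LINE` (ORF1 present and ORF2 strictly longer
than 600 aa), `ORF2_only`, `ORF1_only`, `intact_RT_only`, `defective`.

**ERVs.** A domain (ENV, GAG, POL) is present when some ORF translation
aligns to a reference of that label and the matched span on the element
strictly exceeds the domain threshold: ENV > 480 aa, GAG > 500 aa,
POL > 800 aa. All three domains make a `full_ERV`; at least one, a
`partial_ERV`; none, `defective`. Reference proteins are user-supplied
(the GenBank ERV set used in published avian surveys is not
redistributable here); the synthetic module emits labelled stand-in
references for testing.

Thresholds at exactly the boundary do **not** qualify (an ORF2 of exactly
600 aa is not full; a POL match of exactly 800 aa is not a POL domain) —
the wording is "longer than"/"greater than" throughout.

# The synthetic-data generator

The generator exists so that every estimate has a known truth without
multi-GB assemblies. It emulates:

* **TE copies of known age**: a copy planted at age $t$ is the consensus
  mutated to $K = 2rt$ under the exact Jukes-Cantor transition kernel
  (stay probability $\tfrac14 + \tfrac34 e^{-4K/300}$), substitutions
  only. With no indels, realised divergence is the sole driver of the age
  estimate, which isolates the aging math under test. An annotation file
  carries each copy's realised divergence rounded to one decimal, as
  annotation files print it.
* **Non-overlapping placement** on a random background genome, so coverage
  truth is exact and generation stays independent of the
  overlap-resolution logic; overlap fixtures for that logic are
  constructed separately and deterministically in the tests.
* **Redundant libraries**: planted families with full-length members at
  $K = 8\%$ (observed identity $\approx 0.92$, safely above the 0.8 rule),
  fragments at half length (absorbed via shorter-sequence coverage), and
  decoy relatives at $K = 40\%$ (observed identity $\approx 0.69$, safely
  below), plus unrelated singletons. Divergences deliberately straddle the
  threshold from both sides without sitting on it: a pair exactly at 80%
  identity is a measure-zero edge whose side can flip between co-optimal
  alignments, so the planted truth would be undefined there.
* **Planted elements**: ORFs are real ATG-to-stop frames encoding either
  random protein (ORF1, decoys) or exact prefixes of the emitted stand-in
  references (RT inside ORF2, ENV/GAG/POL domains), so matched spans equal
  planted lengths exactly; an in-frame stop guards each planted ORF so
  random padding can never prepend codons to a boundary-length ORF.

The default genome configuration is a 100 kb sequence carrying ~9.9%
interspersed repeats with the composition of a compact avian-like genome —
CR1 dominant (7.2%), ERV3 the largest ERV class, ERV1/ERV2 minor, DNA and
SINE rare and ancient, insertion ages between 10 and 50 My at the chicken
rate. What the generator does *not* emulate: indels and fragmentation,
nested insertions, CpG hypermutability, solo-LTR formation, and
library-version idiosyncrasies in class strings. Passing tests therefore
demonstrate correctness of the accounting and inference machinery under
the substitution-only model, not robustness to every artefact of real
annotations.

# Problem sizes and determinism

All randomness flows from a single integer seed per generator call;
identical configuration and seed give byte-identical output files. The
test and acceptance workloads are sized for a single CPU: divergence
inversion uses 100 kb of sequence; age recovery uses 200 copies of 10 kb
(median age within 5% of truth); coverage oracles sweep genomes up to
100 kb over 50 random record sets; clustering oracles run 20 libraries of
up to ~15 sequences of 70-140 bp against the exhaustive DP reference
(the reference is quadratic per pair in plain R, which is why oracle
sequences are short — the package's own aligner handles kb-scale library
sequences routinely); screening uses a 30-element planted library covering
every category and boundary.

# Known limitations

* Divergence is used as printed; no CpG-adjusted or Kimura-2-parameter
  distances (the correction's domain excludes $D \ge 75\%$ either way).
* Single-linkage 80-80 clustering can chain distinct families through
  intermediates; this is inherent to the rule's pairwise definition.
* Screening depends on the supplied reference proteins; absent or
  divergent references demote elements to `defective` regardless of their
  true structure.
* The `.out` parser reads the standard whitespace dialect only (no
  `.align`/`.cat` files), and coverage has no per-chromosome breakdown.
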