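---
title: "Bubble-hairpin guide design and evaluation: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bubble-hairpin guide design and evaluation: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhsgrna)
```

# The model

Base editors deaminate bases in the single-stranded loop that Cas9
exposes on target binding. Complete R-loop formation requires the full
spacer to hybridise with the protospacer; a guide that carries, 5′ of
its spacer, the reverse complement of the spacer's PAM-distal end folds
back on itself and competes with that hybridisation. The competition is
tuned by three integers:

* **H** — hairpin (extension) length, the number of spacer 5′ residues
  reverse-complemented into the extension (loop excluded). Editing
  activity falls steeply once H exceeds ~4 and is essentially abolished
  at H = 12 for a perfect stem.
* **B** — bubble size: B consecutive extension residues substituted so
  they can pair *neither* Watson–Crick *nor* G–U wobble with the spacer
  positions they face. The bubble locally re-opens the stem.
* **P** — bubble start, given as the first protospacer position facing
  the bubble (protospacer position 1 = PAM-distal end). Placing the
  bubble opposite the middle of the editing window restores on-target
  activity best.

The package's defaults are the recommended designs: `H12-B3-P5` for
CBEs (editing window 4–8, bubble opposite 5–7, i.e. hairpin positions
6–8) and `H12-B3-P4` for ABEs (window 4–7, bubble opposite 4–6, hairpin
7–9). The connecting tetraloop is 5′-ACAA-3′, a motif known to introduce
a sharp turn that promotes stem formation.

## Coordinates

Hairpin position *p* (1-based from the extension 5′ end) faces
protospacer position *H + 1 − p*; the map is its own inverse. All
user-facing coordinates — protospacer positions, hairpin positions, VCF
POS, scan output — are 1-based; only internal index arithmetic is
0-based where R makes that natural.

## Bubble residue choice

The design rule only requires that the bubble not pair. To make
constructs reproducible, `choose_bubble_nt()` excludes the Watson–Crick
partner and the wobble partner of the opposing spacer residue, then
takes the first remaining residue in the fixed order C, A, G, U. This
is one valid instantiation, not a claim about any particular published
construct; `build_bh_sgrna(bubble_seq =)` accepts an explicit bubble,
validated by the same predicate. Mismatched-guide enumeration
(`enumerate_mismatched_guides()`) similarly uses a fixed
transversion-first substitution (A↔C, G↔U) with an explicit override.

# Structural validation

`nussinov_maxpairs()` maximises the number of base pairs (G–U allowed,
minimum loop 3) by dynamic programming, with a deterministic traceback.
Pair maximisation was chosen over thermodynamic folding because the
claims being checked are topological — can the intended stem form, does
the bubble stay open — and pair counts admit an *exact* brute-force
oracle, which the test suite exercises on all sequences up to length 14.
An export of designed sequences for external thermodynamic folding is a
comparison aid only, never a test dependency.

`hairpin_report()` answers "does the intended stem survive?" exactly:
pairs get weight 1000 plus a bonus of 1 when intended, so the optimum is
lexicographic — first maximise pair count, then maximise intended-pair
inclusion — and the reported fraction is the best attainable over *all*
maximum-pairing structures, not an artefact of one traceback.

Two deliberate choices:

* **The tetraloop is held unpaired by default** (`exclude_loop = TRUE`).
  The ACAA loop is a structural turn; if its residues may pair, loop
  A·U/C·G alternatives outscore stem pairs even for spacers with no
  self-structure, making the diagnostic useless. With the loop fixed,
  the stem wins outright whenever the spacer lacks competing
  self-complementarity.
* **A `FAIL` verdict is information, not an error.** Strongly
  self-complementary spacers admit maximum-pairing structures that
  exclude part of the intended stem; the report surfaces the attainable
  fraction so such designs can be flagged, rather than pretending the
  stem always dominates. Folding covers extension + loop + spacer only;
  the tracrRNA scaffold (never part of the designed 5′ region) is
  excluded.

# Quantification of editing outcomes

Reads are aligned semi-globally (every read base aligned, unpenalised
reference overhangs) with match +2, mismatch −2, gap open −6, gap
extend −1, via Biostrings; indels are then left-aligned so placement in
repeats is deterministic, matching common variant-normalisation
practice. Reads failing to cover the full protospacer, or with mean
base quality < Q20, are flagged and excluded from tallies; individual
substitutions below Q20 are masked (treated as reference calls). With
the threshold at 0, masking is a no-op, which the suite checks.

The headline statistic follows the "at least one edit within the
editing window" convention: a read counts as edited iff it carries ≥1
canonical conversion (C→T for CBE, A→G for ABE, evaluated on the
protospacer strand) at a window position. Whether non-canonical window
substitutions should count is ambiguous; the default counts canonical
conversions only, and `any_substitution = TRUE` provides the broader
reading. Indel frequency counts reads with ≥1 indel overlapping the
protospacer interval (configurable ±N flank). Per-position depth
subtracts reads whose deletion removes the base, so by-product
fractions are fractions of actual base calls.

`specificity_metrics()` reports off-target frequencies, on:off ratios
and fold reductions against a comparator run; frequencies below the
detection floor (default 0.1%) are censored at the floor and fold
changes flagged as lower bounds. Replicate summaries are mean ± SEM
(sd/√n) and the two-tailed equal-variance Student *t* test
(`stats::t.test`, pooled df).

# Off-target enumeration and SNV classification

`scan_offtargets()` returns every locus, on either strand, within
`max_mm` mismatches of the spacer (default 4) and adjacent to a PAM
(default NGG; `N` wildcards only — no bulges, matching the
mismatch-only convention of standard predictors). Coordinates are
1-based inclusive; minus-strand candidates report both the + strand
interval and the stranded 5′ end.

`classify_snvs()` applies the similarity rule for guide-dependent
off-targets: a locus sharing at least `min_matches = 15` of the 20
protospacer positions (i.e. ≤5 mismatches) qualifies; an SNV inside a
perfect-match locus is on-target, inside any other qualifying locus
guide-dependent, otherwise guide-independent. "Over 15-nt similarity"
is read as ≥15 matches, consistent with the companion statement that
off-target editing is unlikely beyond 5 mismatches; `strict = TRUE`
gives the literal >15 reading. The scan behind classification requires
a PAM by default; `pam = NULL` classifies on protospacer similarity
alone, since the rule's phrasing mentions only sequence similarity. The
attribution flank around qualifying protospacers defaults to 0 (the SNV
must fall inside the protospacer); this is a package choice, exposed as
`window_flank`.

# Synthetic data: what it emulates, what it does not

The generators produce the three inputs the pipeline consumes, with
recorded truth:

* `simulate_amplicon_reads()` — single-end full-length amplicon reads;
  per-position canonical edits (Bernoulli at the configured rate),
  non-canonical substitutions at target bases, at most one indel per
  read inside the protospacer, uniform sequencing errors, constant Q30
  qualities with the error rate deliberately decoupled from the quality
  string. Not modelled: paired-end structure and merging, adapter
  content, realistic Illumina error profiles, PCR duplicates, coverage
  nonuniformity. Passing recovery tests therefore demonstrates
  estimator correctness, not robustness to real library artefacts.
* `make_toy_genome()` — uniform-composition background, rejection-
  resampled until every window on either strand is ≥ `clean_min_mm = 8`
  mismatches from the spacer, then planted sites with exact mismatch
  counts and concrete PAMs. The margin makes oracle tests exact: any
  scan at `max_mm ≤ 6` can only report planted sites. Spacers with
  strong self-similarity (quasi-palindromes, internal repeats) can make
  clean planting infeasible — their own planted copies echo at shifted
  offsets or on the opposite strand — and the generator then errors
  rather than emit a genome with ill-defined truth.
* `simulate_snvs()` — guide-dependent SNVs placed inside qualifying
  planted loci and independent SNVs ≥ 20 bp away from all of them, both
  carrying the CBE signature (C→T on the protospacer strand, read as
  G→A on + for minus-strand loci).

Every generator takes a mandatory seed and is byte-reproducible.

# Numerical choices and problem sizes

* Alignment scoring and leftmost-normalisation as above; deterministic
  tie-breaking throughout (smallest-index preference in the folding
  traceback; (contig, start, strand) ordering in scans).
* Window defaults CBE 4–8, ABE 4–7; PAM NGG; prediction cap 4
  mismatches; dependence threshold 15 matches; detection floor 0.1%;
  quality threshold Q20; minimum folding loop 3.
* The validation suite runs at the sizes the guarantees are stated for:
  1,000 random spacers for bubble validity; 200 random sequences up to
  length 14 against the brute-force folding oracle; 50 toy genomes of
  20–50 kb against the exhaustive scan oracle for 0–6 mismatches;
  10,000 reads for rate recovery at planted rates 0.01/0.1/0.3/0.9 and
  indel rate 0.1, judged by exact binomial 99% intervals.
* Rate recovery is validated per planted quantity: substitution rates
  in an indel-free run, the indel rate in its own run. When an edit
  abuts an indel, score-equivalent alignments can absorb the
  substitution into the gap, so a joint per-base check would test
  alignment ambiguity, not the estimator. The indel statistic itself is
  presence-based and exact up to interval-edge placement, which a small
  flank resolves.

# Known limitations

* Pair maximisation is topological: it has no stacking energies, so it
  neither reproduces any specific folding tool's drawings nor resolves
  near-degenerate structures the way a thermodynamic model would.
* Mismatch-only off-target scanning does not model RNA:DNA bulges.
* The quantifier assumes pre-merged single reads and does not aim for
  feature parity with full amplicon pipelines (no UMI handling, no
  adapter trimming).
* Wet-lab headline numbers (editing efficiencies at genomic sites,
  WGS SNV counts) are measurements, not computable quantities; the
  package reproduces the design rules, statistics and classification
  logic that surround them.
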