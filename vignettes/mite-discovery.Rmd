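---
title: "Genome-wide MITE discovery: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide MITE discovery: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescan)
```

## The problem

Miniature inverted-repeat transposable elements (MITEs) are short
(50–800 bp) non-autonomous DNA transposons. A family typically has tens
to hundreds of near-identical genomic copies, each bounded by terminal
inverted repeats (TIRs) and flanked by a target site duplication (TSD) —
a 2–10 nt direct repeat created when the element integrates. Because
TIRs and TSDs are short, chance sequence easily imitates them: naive
signature scanning produces mostly false positives, and processing every
copy of every family repeats the same work hundreds of times.

`mitescan` discovers MITE families de novo from a FASTA genome database
and reports **one exemplar per family**. Two ideas carry the design:

1. **A family needs to be found only once.** Every deposited sequence
   (genuine or false) joins a filter database that hard-masks all later
   portions of the genome, so the same family is never processed twice.
2. **Mobility leaves a population signature.** A genuine family has many
   near-identical full-length copies *in diverse genomic contexts*. A
   repeat whose copies all carry the same 50-nt flanks is an internal
   fragment of something larger (typically a retroelement body) and is
   quarantined as a false family.

## Pipeline

Each database entry is sliced into windows of at most 100,000 nt.
Consecutive windows overlap by `max_element_len + 2 * flank_window`
(900 nt by default) so that no element plus its TSD context can straddle
two windows undetected; candidates rediscovered inside an overlap are
deduplicated by their global coordinates. Per window the pipeline:

1. hard-masks regions matching the filter database
   (`mask_known()`), then low-complexity regions by windowed Shannon
   entropy (`mask_low_complexity()`);
2. detects candidate TIR pairs against the window's reverse complement
   (`find_inverted_repeats()`), discarding simple inverted repeats
   (mono/dinucleotide runs, single-class {A,T} or {G,C} arms;
   `is_simple_arm()`);
3. screens each pair for a TSD in the 10-nt flanks, falling back to the
   most terminal 5 nt of the TIRs (`find_tsd_with_fallback()`) — some
   superfamilies (*Stowaway*, *PiggyBac*) carry the duplicated site
   within their TIR termini;
4. counts full-length copies genome-wide and classes the 50-nt flanking
   contexts of up to 20 copies (`evaluate_candidate()`):
   `candidate` (≥ `copy_threshold` copies, ≥ `flank_class_threshold`
   flank classes), `false_family` (enough copies, too few contexts), or
   `below_copy_threshold` (ignored);
5. deposits the exemplar into `candidates.fasta` or `false.fasta` plus
   the filter database, unless a similar sequence is already in the
   corresponding output (`is_redundant()`), and appends a progress row
   to `report.tsv`.

Copy counting always sees the *whole* genome, masked or not, so copy
numbers do not depend on how much has already been deposited or on early
stopping.

### The sampling model and early stopping

If the N copies of a family are placed uniformly at random, the
probability that none lies in the first fraction $X$ of the database is
$P = (1-X)^N$; inverting, $X = 1 - P^{1/N}$ of the database suffices to
see at least one copy with probability $1-P$. A 10-copy family is missed
with probability 0.01 after scanning 37% of the genome; 20 copies need
21%, 50 copies under 9%, and a >100-copy family under 5% at $P=0.005$
(`coverage_fraction()`, `miss_probability()`). Setting `p_miss`
truncates *discovery* scanning at
`coverage_fraction(p_miss, copy_threshold)`; the guarantee applies to
families at the copy threshold and is conservative for larger ones.
Discovery truncation cuts at a nucleotide boundary, so a copy straddling
the cut can be lost; the effect is of order element length / genome
length and is absorbed by the stochastic tolerance used in the tests.

## Inverted-repeat detection

An arm pair is an ungapped alignment of a left arm against the reverse
complement of a right arm. All placements pairing position $p$ with
position $q$ share the anti-diagonal constant $c = p + q$, which reduces
scanning to one-dimensional work per diagonal. A window is accepted iff
its ends are complementary matches, it contains no `N`, its length is at
least `min_arm_len` (10 nt, the conventional MITE TIR floor), its
identity is at least `min_arm_identity` (0.80), it contains an exact
match run of at least `seed_len` (8 nt by default; the `sensitivity`
levels map to 10/8/6), and the element span lies within
[`min_element_len`, `max_element_len`] with non-overlapping arms.

Two design points deserve explanation:

* **The exact-seed run is part of the acceptance contract,** not just an
  implementation trick. It makes seeded scanning provably exhaustive
  (every accepted window contains a seed hit, so hashing seed k-mers
  against the reverse complement flags every diagonal that can carry an
  accepted window), and `brute_force_ir()` — a direct enumeration of all
  placements used as the test oracle — applies the identical rule, so
  the two engines return equal sets.
* **Window choice is by alignment score, not length.** Among accepted
  windows on one diagonal (grouped by transitive overlap) the reported
  window maximizes `matches − mismatch_penalty × mismatches` (+1/−3,
  BLAST-like), with ties to the longer arm and then the smaller element
  span. A long clean arm at the 0.80 identity floor "banks" enough
  identity to absorb a tail of mismatches, so a length-maximal rule lets
  arms creep several nt into flanking sequence, shifting the element
  junctions. Score-maximal windows stop at the TIR boundary (a genuinely
  palindromic target site still extends the arm — that is real inverted
  repeat, and exactly the case the TIR-terminal TSD fallback handles).

Within a slice, surviving pairs are evaluated in descending arm score.
A weak chance pair that overlaps a genuine element but starts slightly
earlier would otherwise be evaluated first, deposit as a false family
(its copies share the element-interior flank), and mask the genuine
family genome-wide. Strongest-first lets the clean TIR pair deposit
first; overlapping artifacts are then suppressed by the redundancy
check against the output.

## TSD detection

`find_tsd()` anchors the direct repeat at the junctions: one copy must
terminate at the right end of the left flank, the other begin at the
left start of the right flank, longest (2–10 nt) winning. If the flanks
yield nothing, the most terminal 5 nt of the TIRs are searched for a
repeat anchored at the element termini (`source = "tir_terminal"`).

The *pipeline* relaxes anchoring by default (`tsd_anywhere = TRUE`):
the repeat may sit anywhere within the two 10-nt windows, with
junction-proximal then lexicographic tie-breaking. Local arm alignment
can over- or under-shoot the true boundary by a base or two whenever
flanking sequence happens to extend the inverted repeat (25% per
flanking base; deterministically for palindromic target sites such as
`TA`), and a strictly anchored search then misses the genuine TSD
sitting 1–2 nt from the detected junction. Strict anchoring remains
available (`tsd_anywhere = FALSE`, CLI `--tsd-abutting`).

## Family evaluation

Copy counting is seed-and-verify: 12-mers sampled every 4 nt along the
query are looked up in a precomputed genome index; each implied locus is
verified by direct ungapped identity over the full element on both
strands, requiring `copy_identity_min` ≥ 0.80 over
`full_length_coverage_min` ≥ 0.90 of the query ("full length" tolerates
young-family divergence while excluding fragments). Hits overlapping by
more than half the shorter hit collapse to the best locus.

Flank classing compares at most `subset_max = 20` copies (190 pairwise
comparisons; for a genuine false family *every* pair shares context, so
a small subset suffices). Two copies share a flank class when either
50-nt side matches the other's corresponding side above 0.80 identity
over the shorter length, anchored at the junction; classes merge by
single linkage. `flank_class_threshold = 3` asks for three independent
insertion contexts — minimal robust evidence of mobility.

All similarity in the package (copy counting, masking, redundancy) is
ungapped. This matches the substitution-dominated divergence of young
MITE families and keeps every decision reproducible and fast; heavily
indel-diverged copies will be under-counted (see Limitations).

## The simulator

`simulate_genome()` builds the test bed the pipeline is validated on:

* i.i.d. background at a given GC content (43% default, plant-like);
* true families: TIR + random interior + reverse-complement TIR, planted
  at uniformly random non-overlapping loci; at each locus the adjacent
  background becomes the target site and is duplicated on both sides
  (true TSD semantics, so every copy has its own TSD); copies mutate
  independently (substitutions only; the terminal 5 nt and the TSD stay
  intact by default so the structural signature stays decidable at high
  rates — `mutate_all` removes the exemption);
* false families: an IR core with abutting direct repeats buried inside
  a cassette of fixed 400-nt contexts, planted verbatim — every copy
  carries identical flanks. The deep context mirrors a retroelement
  body: with a shallow (50-nt) context a chance arm pair can span the
  whole cassette and acquire locus-specific flanks on both sides,
  making the decoy literally indistinguishable from a mobile element —
  a small planted repeat *is* mobile by construction;
* simple repeats: homopolymer, `(AT)n`, `(GC)n` stretches.

The default scenario (`default_simulation_specs()`) is a 2-Mb, 4-entry
genome with 8 true families (copy numbers 12–40, element lengths
90–600 nt, TIRs 11–30 nt, TSDs 2–9 nt, per-copy mutation 0–5%), 5
identical-flank decoys of 15 copies, and 10 simple-repeat stretches.
Truth tables carry exact final coordinates and per-copy identities; an
`avoid` mechanism keeps later plantings out of earlier copies.

What the simulator does **not** model — and what passing tests therefore
do not establish about real genomes: indel divergence, nested and
fragmented insertions, subfamily structure, non-uniform insertion-site
preference (real MITEs favour TA-rich and genic regions), genome-scale
composition heterogeneity, and assembly artefacts. The recall and
precision achieved on this test bed are upper bounds for real data.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; human-readable outputs
  (FASTA headers, truth BED) are 1-based inclusive.
* Identity thresholds compare integer match counts against
  `ceiling(threshold × length − 1e-9)`, so engines in R and C++ agree
  exactly at boundary cases like 8/10 at 0.80.
* Non-ACGT input characters become `N`; `N` never participates in a
  seed, an arm, a TSD, or an identity match (it counts as mismatch).
* Sequences shorter than the minimum element length scan to an empty
  result, not an error; an empty interval list masks nothing; an empty
  filter database masks nothing; zero-deposit runs write header-only
  reports and empty FASTA files.
* `is_simple_arm()` treats arms of length ≤ 2 and arms containing `N`
  as simple (unusable).
* `workers` is accepted for interface compatibility and recorded in the
  log; evaluation and deposits are processed serially in discovery
  order, so outputs are identical for any worker count by construction.
  The run writes all outputs plus a `state.txt` slice marker after each
  deposit, so an interrupted run is inspectable, but there is no resume
  entry point — desk-scale runs complete in minutes.
* Problem sizes used by the test suite: the recovery scenario is the
  2-Mb default above; the discovery-decay check uses 20 uniform-placed
  families in 800 kb; the early-stopping check uses 200 replicates of a
  5-copy family in 30 kb at `p_miss = 0.05`; oracle equivalence uses
  100+ sequences up to 2 kb.

## Limitations

* Ungapped similarity throughout: indel-diverged copies are undercounted
  and may split families.
* One exemplar per family by first-strongest deposit: the exemplar is a
  single genomic copy, not a consensus, and may carry a base or two of
  boundary jitter.
* The early-stopping guarantee assumes uniform copy placement; clustered
  families (e.g. pericentromeric) are missed more often than `p_miss`
  suggests.
* Superfamily-specific TSD priors (TA for *Stowaway*, TTA/TAA for
  *Tourist*) and downstream classification are out of scope.
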