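---
title: "Methods: descriptor filtering and covariance-model validation for rnpB gene finding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor filtering and covariance-model validation for rnpB gene finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

RNase P RNA — the ribozyme core of ribonuclease P, encoded by *rnpB* in
bacteria — is hard to annotate by sequence similarity alone: family-wide
sequence conservation is weak, the gene is 250–550 nt in most organisms,
and the diagnostic signal lives in secondary structure (up to 19 stems,
P1–P19, with five conserved regions CR-I–CR-V including the P4 pseudoknot
formed by CR-I/CR-V). A full covariance-model search is sensitive but far
too slow for genome- or metagenome-scale scans; a pure pattern matcher is
fast but cannot rank candidates statistically.

`rnpscan` implements the classic resolution of this trade-off as a
*filter-then-validate cascade*: per-subfamily structural descriptors
(arcA, arcM, bacA, bacB, nucA, fugA, fugB are the recognised structural
classes) act as fast filters, and a simplified covariance model (CM)
validates candidates, assigns E-values and refines gene boundaries. The
wrapping strategy is *local to global and selective to general*:

1. The **selective** descriptor (tight budgets, low false-positive rate)
   proposes candidates; each is validated by the subfamily CM in local
   mode. If no candidate validates, the **general** descriptor (relaxed
   budgets; catches aberrant genes at a higher false-positive rate) is
   tried.
2. Every validated candidate is extended by 150 nt at the 5' end and
   300 nt at the 3' end (in transcript orientation) and re-aligned with
   the whole model over the extended window; the aligned core gives the
   refined gene boundaries.
3. Both phases require an E-value of at most `1e-10` (a call exactly at
   the threshold is accepted).

A CM-only sliding-window mode (`scan_cm_only()`) is provided for genes the
descriptors cannot see; it is roughly two orders of magnitude slower.

## Descriptor models

A descriptor is an ordered topology of single-strand (SS) elements and
helices. SS elements mix IUPAC symbols with bounded runs `N(min,max)` and
carry a *mismatch budget*; helices are fixed-length strand pairs with a
*mispair budget* and a pair set that includes the G–U wobble by default.
Because the two strands of a helix are independent topology slots, crossed
helices — the P4 pseudoknot — are directly expressible, which a
context-free CM cannot do.

Matching semantics (deterministic by construction): elements are consumed
in topology order; run tokens branch over lengths, shortest first; the
first success per anchor wins. Budget rules:

* SS: a position violating its IUPAC symbol costs one mismatch. A subject
  `N` satisfies every pattern symbol (assembly gaps should not kill a
  filter match).
* Helix opening strand: symbols must match exactly.
* Helix closing strand: a position is **one mispair** when its own symbol
  check *or* its pairing check against the recorded opening span fails.
  Folding symbol violations into the mispair budget is deliberate: when a
  curator writes the closing strand as the literal complement, a strict
  symbol rule would make the mispair budget unreachable, since every
  pairing violation would already fail the symbol. A subject `N` in a
  helix always counts as a mispair (conservative toward assembly gaps).

Helices are fixed-length; length variation is expressed by flanking run
tokens. This keeps the pairing check linear in helix length and the
enumeration order trivially deterministic, at the cost of not expressing
bulged helices directly.

The matcher core is C++ (a depth-first walk with early budget cut-offs);
the test suite checks it against an independent R oracle that enumerates
every run-length combination as a flat grid and verifies each layout with
vectorized position arithmetic, on 1000 random model/sequence pairs plus
dedicated pseudoknot cases.

### Building descriptors from alignments

`build_descriptor()` mechanizes descriptor emission from an annotated
alignment: column consensus uses the degenerate-IUPAC rule (the unique
code whose expansion equals exactly the set of observed bases) and the gap
rule (any gap in the column makes it a gap column); selected regions
become SS/helix elements; gap stretches inside and between regions become
run tokens bounded by the ungapped stretch lengths observed across rows,
widened by a `slack` knob. Region *selection* stays an input: which
regions are conserved enough to anchor a filter is a curation decision,
and pretending otherwise would hide the quality of the filter behind an
arbitrary conservation statistic. `column_entropy()` is provided as
advice, not authority.

## The simplified covariance model

`build_cm()` turns a structural alignment into a profile SCFG with a guide
tree of MATL (unpaired consensus column), MATP (paired columns), BIF and
END nodes. Columns with a gap fraction below `gap_threshold` (default
0.5) are match columns; structure pairs whose partner is not a match
column are demoted to unpaired with a warning; pseudoknot tiers are
dropped (inherent context-free limitation — the descriptors carry the
pseudoknot instead). Emissions are Laplace-smoothed log-odds in bits:
`log2((count + pc) / (total + k*pc) / bg)` with background 1/4 (singles,
k = 4) and 1/16 (pairs, k = 16), pseudocount `pc = 1` by default.
Ambiguous subject residues emit the average-probability log-odds.

Deliberate simplifications relative to a full Infernal-style model:

* no per-node learned transitions — four fixed, configurable gap penalties
  (insert open/extend −3/−1, delete open/extend −3/−1 bits);
* a MATP either emits both pair residues or deletes both columns (no
  half-pair ML/MR states);
* delete runs are affine along the guide-tree chain; the affinity context
  resets across inserts and across the right branch of a bifurcation;
* CYK (max-score parse) only — no Inside scoring, no bands.

These choices keep the dynamic programming small enough to verify against
an exhaustive parse-enumeration oracle (M ≤ 8, subjects ≤ 12 nt in the
tests), which is the property that matters here: the cascade needs
trustworthy validation and boundary scores, not Infernal parity.

`cm_score_global()` aligns whole model to whole input (flanking residues
are charged as inserts; matched span is the full input by contract).
`cm_score_local()` aligns the whole model but leaves subject flanks free
(score 0 per flanking residue) — model-global, sequence-local, i.e. the
"glocal" mode of standard CM scanners. Model truncation is out of scope:
the descriptor has already localized the candidate.

### Which scorer refines the window

The refinement phase aligns the whole model over the 150/300 nt-extended
window. Charging ~450 flanking residues as inserts (as sequence-global
scoring would) would subtract ~450 bits from every refinement score and no
call could ever reach the threshold, and the refined span would be the
whole window rather than the gene. The cascade therefore refines with the
free-flank scorer (`cm_score_local()`), whose matched span — the region
covered by consensus columns — is the boundary estimate. This matches how
glocal CM alignment is used by the tools this design follows, and it is
what makes ±5 nt boundary recovery measurable at all.

## E-value calibration

Local-mode scores of a CM on random sequence follow an extreme-value
(Gumbel) law. `cm_calibrate()` scores `n_decoys` (≥ 50; default 150–200)
dinucleotide-shuffled windows of length `2M` and fits (λ, μ) by maximum
likelihood (method of moments on non-convergence). The shuffle is the
Euler-path construction: the sequence is an Eulerian path in the
dinucleotide multigraph; a random last-exit arborescence toward the
terminal vertex plus a random permutation of the remaining edges yields a
uniform sample with *exactly* the original dinucleotide counts — the
invariance the tests assert on a thousand random inputs.

E-values are `E = W · (1 − exp(−exp(−λ(s − μ))))` with window count
`W = strands · search_space / M`, where `search_space` is the length of
the current record (record-local E, matching per-organism reporting) and
the strand factor is 2 for double-stranded scans. The calibration window
length `2M` matches the scan geometry of the cm-only mode.

Because calibration is a re-specification (not a port of any external
calibration), absolute E-values are comparable only within this package.
Extrapolating a 150-decoy fit to the `1e-10` tail is the usual leap of
faith behind all EVD calibrations; the specificity property (zero calls on
100 shuffled 50 kb genomes) is the empirical check that the leap holds at
the scales exercised here.

## Cascade bookkeeping

* "Valid hit" means a descriptor hit that passes CM local validation; the
  selective→general fallback triggers when the selective stage yields
  **zero validated** hits for the record. Validation sits downstream of
  both descriptor stages, so a spurious selective match cannot mask a real
  gene.
* Overlapping calls on the same strand resolve to the lowest E-value;
  ties break by higher global score, then lexicographically first
  subfamily — fully deterministic.
* One call survives per locus, but multiple loci per record are allowed
  (multi-copy genomes are real).
* Minus-strand candidates are scored on the reverse complement and
  reported in forward coordinates; extensions apply in transcript
  orientation, so the 5' extension grows the forward-coordinate end on
  the minus strand.
* Sub-threshold refined candidates are dropped unless
  `report_partials = TRUE`, which emits them flagged `low_confidence`.
* In cm-only mode, overlapping passing windows are merged before
  refinement so a gene straddling a window edge yields one call, not two.

## The synthetic test bed

Real model curation (the production descriptor/CM library for the seven
subfamilies) is expert work on hundreds of curated sequences and is out of
scope; `make_toy_library()` builds a synthetic two-subfamily stand-in that
preserves the *structure* of the problem:

* a `bacA`-style model with two nested helices, and an `arcA`-style model
  with a crossed helix pair exercising the pseudoknot path;
* ~100–110 match columns per model. The size is chosen so that (a) CYK
  refinement of a 550 nt window runs in well under a second and (b) a
  planted consensus-level gene scores far enough above the decoy
  distribution that `E ≤ 1e-10` is reachable in a 50 kb record with an
  order-of-magnitude margin — a fixture that could only marginally clear
  its own threshold would make every downstream test a coin flip;
* selective variants with zero budgets and fixed run widths; general
  variants with budgets +1 and run bounds ±2;
* eight sampled members per subfamily form the training alignment (fixed
  run widths make the members gap-free and alignment-trivial by
  construction), plus one held-out *aberrant* member carrying a single
  helix mispair — it fails the selective descriptor and is caught by the
  general one, which is exactly the fallback scenario the cascade exists
  for;
* calibrated CMs (150 decoys per model by default).

`simulate_genomes()` plants one descriptor-consistent gene per i.i.d.
random background (replacement, not insertion, so coordinates stay
stable), subfamilies cycled and strands alternated (half the plants on the
minus strand), at least 1 kb from the record ends.

What the fixtures do *not* emulate: biologically realistic sequence
evolution, compositional heterogeneity of real genomes, fragmented
metagenomic reads, and genes whose boundaries are ambiguous in truth.
Passing the planted-recovery and specificity properties therefore shows
the machinery is correct and internally consistent — not that the toy
models have the sensitivity/specificity of a curated production library
on real data.

## Validation scales and numerical choices

The test suite and `scripts/acceptance.R` regenerate everything from
seeds: 1000 (300 in the script) random descriptor cases against the
enumeration oracle; 200 (120) tiny CM cases against the parse oracle; 100
(50) planted 50 kb genomes with ±5 nt boundary agreement — 5 nt being the
granularity at which curated annotations are usually compared; an equal
number of 50 kb shuffled decoys expecting zero calls; Gumbel λ recovery
within 15% from 500 simulated scores; and byte-identical TSV output across
reruns.

Numerical details worth knowing: scores are IEEE doubles and the CYK
traceback re-derives decisions with a 1e-6 tolerance, preferring match
over delete over insert on ties; the Gumbel tail switches to its
asymptotic form `exp(−z)` beyond `z = 30` to avoid underflow of
`1 − exp(−exp(−z))`; empty scan results are well-formed zero-row tables;
an input shorter than half the model length still scores (all-delete
parse) but is flagged `short_input`.

## Worked example

```{r, eval = FALSE}
library(rnpscan)

lib <- make_toy_library(seed = 42)
sim <- simulate_genomes(3, genome_length = 50000, seed = 7, library = lib)

calls <- scan_all(sim$genomes, lib, scan_config())
calls
write_calls(calls, "calls.tsv", style = "tsv")

# post-scan analyses
u <- dedup_calls(calls)
subfamily_summary(u)
gc_content(calls$sequence)
```

## Known limitations

* Fixed shared gap penalties make boundary refinement slightly less exact
  than learned transitions would; on clean fixtures the refined spans are
  exact, on diverged real genes they may wobble by a few nucleotides.
* The Gumbel fit extrapolates far into the tail; E-values are ranking
  statistics, not calibrated probabilities of error.
* Helices are fixed-length in the descriptor dialect; a bulged helix needs
  to be modelled as two helices or absorbed into run tokens.
* CM-only mode slides fixed `2M` windows; a gene longer than `2M` (heavy
  insertion load) could be truncated at window merge boundaries.
* The built-in homolog assignment uses a simple local aligner with a
  heuristic Karlin–Altschul constant; it is meant for marker-style
  nearest-neighbour assignment, not for rigorous similarity statistics.
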