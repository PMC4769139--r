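---
title: "extscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{extscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extscan)
```

# The problem

Extensins (EXTs) are plant cell-wall hydroxyproline-rich glycoproteins
(HRGPs). Their defining sequence signature is the Ser-Pro$_n$ motif — a
serine followed by $n \ge 3$ prolines — repeated many times; in vivo the
prolines are hydroxylated to hydroxyproline and O-glycosylated, and
Tyr-X-Tyr (YXY) triplets form isodityrosine-type cross-links within and
between chains. Because hydroxylation is post-translational, a screen over
*predicted* proteomes must treat every proline as potential hydroxyproline;
extscan does so throughout.

EXTs fall into seven architecture classes: **classical** (repeats
essentially throughout the mature protein, usually behind a cleavable
signal peptide), **short** (under 200 aa), **LRX** (signal peptide,
leucine-rich-repeat domain, then a C-terminal EXT domain), **PERK**
(N-terminal EXT-like region, transmembrane segment, intracellular kinase
domain, no signal peptide), **FH** (formin-homology-2 domain plus
repeats), **long chimeric** (over 2,000 aa, found in green algae), and
**other chimeric** (EXT domain plus material foreign to the family). A
candidate that fits no class is a **potential EXT**.

extscan re-implements this screen as a tested library and CLI: motif
scanning, region heuristics, local-alignment homology evidence, an ordered
rule list for classification, class-level statistics, and a synthetic
proteome generator that makes the whole pipeline verifiable offline.

# Motif counting conventions

Counting conventions are where tools silently disagree, so extscan fixes
them explicitly:

* **Maximal munch for SP runs.** An S followed by $k \ge 3$ consecutive P
  yields exactly one hit, binned by $k$: SP3, SP4, or SP5PLUS ("SP5 or
  more"). `SPPPPP` is one SP5PLUS, never SP4 plus a leftover. The three
  bins are mutually exclusive, which is what makes per-bin frequency
  statistics well defined.
* **Anchor counting for the candidate screen.** A protein is a candidate
  iff it has **two or more maximal runs** (equivalently two Ser anchors
  each followed by $\ge 3$ Pro), not two substring occurrences of `SPPP`.
  `SPPPPPP` has one anchor and does not pass. The two readings differ only
  in pathological cases, and anchors are the biologically meaningful
  glycosylation sites.
* **Overlap counting for YXY.** Every index $i$ with Tyr at $i$ and $i+2$
  is a hit, so `YAYAY` counts 2. Each Tyr pair is a potential cross-link;
  no published convention exists, so the more inclusive one is used and
  documented.
* The unknown residue `X` never matches S, P or Y.

Coordinates are 0-based half-open everywhere inside the package; the
single conversion to 1-based inclusive happens in `write_motif_gff()`.
This one-conversion-point rule is what keeps off-by-one drift out of the
coordinate-validity invariants.

# Region heuristics and their parameters

The original workflow relied on external predictors for signal peptides
and GPI anchors. extscan replaces them with documented heuristics plus a
TSV adapter (`load_external_regions()`) so real predictor output can
override the heuristics when available — external calls always win per
record and region type. Heuristic scores live in [0,1] and are never
compared across sources.

| Parameter | Default | Meaning |
|---|---|---|
| `hrgp_window` | 50 aa | sliding window for HRGP composition |
| `hrgp_threshold` | 0.6 | min. P/A/V/S/G/T fraction per window |
| `tm_window` | 19 aa | Kyte–Doolittle averaging window |
| `tm_threshold` | 1.6 | mean hydropathy cutoff |
| signal peptide | — | M at 0; $\ge 7$ hydrophobics starting $\le 8$; small (-3,-1) cut at 15–30 |
| GPI ω-site | — | small ω and ω+2 in last 25 aa; $\ge 8$ hydrophobic tail within 12 |

The HRGP domain notion ("rich in Pro, Ala, Val, Ser, Gly, Thr") is
qualitative in the literature; window 50 / threshold 0.6 were chosen once
so that every repeat block the generator emits from the published motif
grammar is accepted while average-composition background (≈ 0.39 on the
six-residue class) is rejected, and both knobs are config-exposed. The
Kyte–Doolittle 19/1.6 pair is the original membrane-segment convention.
TM calls overlapping a signal-peptide call are suppressed, because an
h-region is itself a hydrophobic stretch.

The signal-peptide heuristic is intentionally conservative. It is *not* a
SignalP replacement on real data; it is engineered to be exact on
unambiguous N-termini, which is what the synthetic tests require. A
classical EXT without a detectable signal peptide is known from the
literature, so classification records the call as evidence but never hard
-requires it.

# Homology evidence

BLAST against a reference database is replaced by exact Smith–Waterman
(affine gaps, BLOSUM62 with `X` scoring −1 against everything, gap
existence/extension 11/1, a gap of length $k$ costing $11 + k$) against a
small bundled set of domain exemplars: LRR, kinase, FH2, a globular
"OTHER" domain, and representative classical/short EXT repeat regions.
Scores are normalized by the reference self-score — a length-free,
reproducible criterion (default threshold 0.25) in place of e-values,
which would require database-size statistics the bundle cannot supply.
The bundle is **synthetic** (constructed exemplars; the file name and
headers say so) because shipping database extracts is not possible here;
it is user-replaceable by any FASTA with `family=` header tags. The
normalized-score sensitivity around the 0.25 default is deliberately
surfaced in the config rather than hidden.

The aligner is implemented from scratch (Rcpp) with deterministic
tie-breaking — diagonal over up over left during traceback, first-best
end cell in row-major order — and is checked against an independent
full-matrix DP oracle in the test suite, 200 random instances per run.

# The classifier

Rules fire in a fixed order, first match wins. The order itself is a
design decision the original software never stated; making it explicit is
what makes the classifier testable:

* **R0** fewer than 2 SP runs → NON_EXT.
* **R1** length > 2,000 aa *and* chimeric character (a non-EXT domain hit
  or HRGP coverage < 0.5) → LONG_CHIMERIC. Requiring chimeric character
  keeps a hypothetical pure-repeat giant eligible for CLASSICAL, since
  long chimerics are described as chimeric, not merely long.
* **R2** LRR hit located before the SP-motif span → LRX.
* **R3** kinase hit after the SP span, with a TM segment between them
  *or* N-terminal SP bias ≥ 0.7 → PERK. The bias fallback exists because
  PERK repeats are predominantly N-terminal, which is measurable from
  motif positions even when the TM call is not confident.
* **R4** FH2 hit → FH_EXT.
* **R5** length < 200 aa with an HRGP domain → SHORT.
* **R6** HRGP coverage ≥ 0.5, ≥ 4 SP runs, no non-EXT domain hit →
  CLASSICAL (signal peptide recorded, not required).
* **R7** HRGP domain plus foreign material → OTHER_CHIMERIC.
* **R8** otherwise → POTENTIAL.

Architecture rules precede length rules so that an LRX under 200 aa stays
LRX. "Repeats throughout" for classical EXTs is quantified as HRGP
coverage ≥ 0.5 — an explicit stand-in for a qualitative notion, exposed
in `classifier_config()` and exercised by a monotonicity test (raising it
never increases the CLASSICAL count). "Foreign material" in R7 is made
concrete as: a non-EXT-family homology hit, a TM segment outside every
HRGP region, or a contiguous non-HRGP, non-signal-peptide stretch of at
least `foreign_min_len` (150 aa) — long enough to be a folded domain
rather than a linker.

Every classification carries an evidence list and the rule trace (rules
evaluated, fired rule last), so any label can be audited.

# Summary statistics

`spn_frequencies()` pools SP3/SP4/SP5PLUS run counts over a label set
(default: classical EXTs, where SP4 dominance is the observation of
interest) and normalizes to sum 1; the restriction set is a parameter
because the published figure legend is ambiguous between "classical EXTs"
and "each species". `mean_yxy()` averages per-protein YXY counts over the
classical and non-classical EXT groups with per-group denominators —
the other reading of an ambiguous legend (a combined denominator) can be
recomputed trivially from the census, but per-group means are what the
published 5.7–27.5 vs < 2 contrast requires. Human-readable output prints
means to one decimal; TSV output keeps full precision.

# The synthetic proteome generator

`generate_proteome()` emits a seeded proteome with planted, labelled
members of every class plus background negatives. It is a stated world,
not a tuning dial:

* Repeat blocks follow the published motif grammar: SP4-dominant mix
  (0.25 / 0.65 / 0.10 over SP3/SP4/SP5PLUS, matching the observed 56–80%
  SP4 dominance), YXY interleaved at density 0.5 in classical blocks and
  0.1–0.15 elsewhere (non-classical EXTs average under two YXY motifs).
* Background residues follow the Swiss-Prot average composition, so
  negatives are not accidentally HRGP-rich.
* Spacers inside repeat blocks use {A,V,G,T} (HRGP-class residues that
  cannot seed SP or YXY motifs); planted YXY triplets are followed by two
  non-Tyr residues so planted motifs cannot overlap into unplanned ones.
* After assembly every sequence is *scrubbed*: unplanned SP runs and YXY
  triplets are mutated away (only outside planted intervals), and window
  composition outside repeat blocks is capped at 0.48 — 20% below the
  HRGP threshold. This is what makes the planted truth exhaustive: the
  scanners re-detect exactly the planted coordinates, which the test
  suite asserts for every generated record.
* Signal peptides are built so the heuristic's earliest valid cleavage
  *is* the planted one (all-Leu h-region; the only small-residue −3/−1
  pair is at the planted cut). Background N-termini have their
  hydrophobic runs broken, making them unambiguous negatives.
* At ambiguity 0, planted proteins clear every threshold they must clear
  by ≥ 20% (classical length ≥ 280 aa and coverage ≈ 0.9 vs 0.5; short
  ≤ 160 aa vs 200; long chimerics ≈ 2,500 aa vs 2,000; foreign segments
  well over 150 aa). The `ambiguity` knob only jitters the SHORT length
  toward/across 200 aa and the OTHER_CHIMERIC block composition toward
  the HRGP threshold, so the only confusions it can create are
  SHORT↔CLASSICAL and OTHER_CHIMERIC↔POTENTIAL — pushing classical
  coverage below 0.5 instead would create confusions the degradation
  contract does not allow.

What the generator does **not** emulate: real genome redundancy, splice
isoforms, borderline signal peptides, compositional drift between
lineages, or homology that is similar-but-not-identical to the exemplars.
A green planted-recovery test therefore establishes that the pipeline's
logic is self-consistent and its conventions are implemented exactly — it
does not establish field accuracy on Phytozome proteomes, whose census
numbers depend on proteome releases and curation this package does not
ship.

# Numerical and degenerate-input choices

* Empty proteomes, empty hit lists and zero-denominator statistics return
  empty tables, `NULL`, or `NA` ("absent") rather than NaN; the CLI exits
  0 with header-only outputs for valid-but-empty inputs and nonzero (with
  partial outputs removed) for validation failures.
* Sequences shorter than a window: HRGP profiling evaluates one
  whole-sequence window; TM and GPI prediction return empty; signal
  peptide prediction requires 18 residues.
* A single trailing `*` is stripped; internal stops are kept but flagged;
  B/Z/J/U/O map to X with a warning; duplicate FASTA ids get `.2`, `.3`
  suffixes instead of being dropped, so censuses cannot silently shrink.
* Alignment ties are broken deterministically (see above), and
  `classify_proteome()` is deterministic end to end, including rule
  traces — asserted by the invariant tests.

# Known limitations

* The heuristic region predictors are engineered for unambiguous cases;
  on real proteomes they should be overridden with genuine SignalP/big-PI
  output via the external-regions adapter.
* The homology bundle is synthetic; real LRR/kinase/FH2 exemplars (or a
  user-curated EXT reference set) should replace it for production
  screening.
* The published genome-census numbers (candidate and per-class totals
  across 16 proteomes) are not reproducible here by design: they require
  specific proteome releases. The acceptance machinery instead verifies
  per-protein worked counts and full recovery of the generator's planted
  world.
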