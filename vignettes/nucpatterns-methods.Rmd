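---
title: "Methods: dyad-aligned sequence patterns of nucleosome populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyad-aligned sequence patterns of nucleosome populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpatterns)
```

## The problem

A nucleosome core particle (NCP) wraps ~147 bp of DNA around a histone
octamer. The bendability of that DNA is sequence-dependent: A/T-containing
(W) dinucleotides prefer positions where the minor groove faces the octamer
(half-integer superhelix locations, SHL ±0.5, ±1.5, ... ±6.5) and G/C (S)
dinucleotides prefer the major-groove bending sites (integer SHLs). This
canonical WW/SS pattern sets the *rotational* positioning of nucleosomes; a
counter-phased anti-WW/SS pattern, shifted by about half a helical turn,
also occurs in an appreciable minority of nucleosomes. On top of the
periodic pattern, localized "off-peak" W enrichments near SHL ±4 (P1) and
SHL ±1 (P2) — sites contacted by the H2A and H4 histone N-terminal tails —
carry a strand-specific preference for adenine over thymine.

`nucpatterns` takes populations of mapped nucleosome-sized fragments
(BED + reference, BAM, or plain FASTA) and quantifies this organisation:

1. **profiles** — dyad-aligned positional frequencies of A, T, W and of the
   WW/SS dinucleotide classes, with 3-bp running averages, dyad
   symmetrisation, SHL coordinates, off-peak detection and A−T strand
   asymmetry;
2. **differential** — ΔW/ΔA/ΔT profiles between two populations (reference
   minus comparison), baseline statistics over designated regions,
   position-wise significance, and the ΔW-vs-W counterphase correlation;
3. **dcc** — the occurrence-weighted distance cross-correlation between two
   dyad maps, its peaks, and the partition of its mass into in-phase (10n)
   and counterphase (10n + 5) shifts;
4. **rotational classification** — a per-fragment phase score against the
   canonical WW/SS template, separating canonical from anti-WW/SS
   nucleosomes;
5. **synthetic data** — populations with planted, analytically known
   structure so that every stage above can be verified against ground truth.

## Coordinate conventions

Internally all positions are 0-based half-open on the reference, and
profile columns are dyad-relative (−73 .. +73 for mononucleotides). All
user-facing outputs use 1-based nucleosomal positions 1..147 with the dyad
at position 74 (so SHL −4 corresponds to position 32).

The dyad of a fragment of length L starting at `start` is
`start + floor((L − 1)/2)` — the exact centre for odd L, and the base 5′ of
centre on the reference-forward strand for even L. No convention for even
lengths is canonical in the field; this one is deterministic and documented.
Fragment sequences are stored reference-forward, and the "leading strand"
of a nucleosome is taken to be the reference-forward strand of its
fragment; all A-vs-T asymmetry statements are relative to that convention.

Fragments of the filtered lengths (typically 147–149 bp, or 146–148 bp for
more heavily trimmed preparations) are aligned at their dyads and
contribute to exactly the positions they cover: denominators are
coverage-weighted, and N bases (or uncovered positions) are excluded from
both numerator and denominator rather than dropping the whole fragment.

## Parameters that matter

* **Helical period** (`period`, default 10.4 bp/turn): used for SHL ↔ bp
  conversion, the phase template, and the synthetic generator. 10.4 bp is
  the canonical nucleosomal DNA twist and maps SHL −4 to positions 30–34,
  consistent with the H2A-tail contact window.
* **Length filter** (`min_len`, `max_len`): defaults 147–149 bp; a band of
  ±1–2 bp around the core length keeps the dyad assignment accurate while
  retaining most of a mononucleosomal library.
* **Baseline regions** (default 10–29 and 35–74, 1-based): the 60 positions
  over which ΔW baseline mean and population SD are computed; they exclude
  the fragment ends, the SHL ±4 window and the dyad-distal half (which is
  redundant after symmetrisation).
* **DCC occurrence threshold** (`min_occurrence`, strictly greater-than):
  0 for synthetic data; 5000 is the documented setting for deep in vitro
  libraries, where only strongly repositioned dyads are informative.
* **DCC phase windows**: centres at multiples of 10 and at 10n + 5, each
  ±2 bp; every integer distance is assigned to its nearest centre, so the
  partition is exhaustive. Distances 0–2 count as in-phase.
* **Classifier threshold** (default 0.1): |score| above the threshold is
  typed canonical/anti; below it the fragment is "weak". Fractions are
  reported both over all fragments and over confidently typed ones, and the
  threshold is exposed because the weak class depends on the periodic
  amplitude of the library.

## Numerical and design choices

* **Smoothing** is a 3-bp running mean with a shrinking window at the
  edges (no positions dropped). Note that a 3-bp mean attenuates a 10.4-bp
  cosine by (1 + 2cos(2π/10.4))/3 ≈ 0.88; amplitude estimates should use
  the raw profile or correct for this factor.
* **Symmetrisation** reflection-averages values through the dyad
  (mononucleotide mirror(i) = −i, dinucleotide-start mirror(i) = −i − 1).
  For complement-closed motif sets (W, S, WW, SS) a profile is averaged
  with its own mirror. For strand-specific motifs, plain reflection would
  erase A-vs-T asymmetry, so a complement-aware mode averages the A profile
  with the mirrored T profile instead — this is exactly what re-tallying
  after reverse-complementing every fragment produces, which is how it is
  tested. Smoothing and symmetrisation commute on full-coverage profiles
  and symmetrisation is idempotent.
* **Off-peak detection** looks for a strict interior local maximum within
  ±3 bp of the nominal site (SHL ±4 for P1, ±1 for P2) and measures its
  amplitude above the straight line joining the profile values at the two
  flanking integer-SHL sites. A planted bump only registers as "present"
  when its curvature exceeds that of the periodic trough it sits in
  (height/width² > a(2π/period)²); gentler enrichments appear as shoulders
  and are reported absent. Amplitude ≤ 0 likewise means absent.
* **Significance testing** uses raw, unsmoothed, unsymmetrised counts in a
  per-position two-proportion z-test with Bonferroni correction over the
  147 positions (Benjamini–Hochberg available via `method=`). Smoothed or
  symmetrised values would break the binomial model, so they are used only
  for display and Δ profiles. Positions with zero coverage get p = 1 and
  are flagged.
* **DCC** counts each unordered cross-population pair once at its unsigned
  distance (a signed variant is available behind `signed = TRUE`), which
  makes the 5 × 10 = 50 worked example hold exactly and gives the mass
  identity Σ dcc = N₁ × N₂ when no threshold or distance cap bites.
* **Phase template** for classification is −cos(2π(i + 0.5)/period)
  evaluated at dimer centres over |SHL| ≤ 6.5. Evaluating at centres makes
  the template exactly dyad-symmetric, so scores are exactly invariant
  under reverse complement; anchoring it analytically (rather than fitting
  it to data) keeps classification deterministic and data-independent.

## What the synthetic generator emulates — and what it does not

`sample_population()` draws dyad sites with inter-site spacings uniform in
160–220 bp (bracketing typical nucleosome repeat lengths, and keeping
neighbouring sites outside the default 100-bp DCC window so planted shifts
are read out cleanly), per-site occurrence counts (fixed or lognormal),
fragment lengths from a 146–149 bp distribution, and fragment sequences
base-by-base from a position-specific probability matrix in the dyad frame.
The W probability is baseline + a·cosine (maxima at half-integer SHLs, or
integer SHLs under `phase_flip`) + Gaussian bumps with an A-over-T bias;
defaults mimic the printed magnitudes of the motivating system: an
H2A-like scenario plants a single adenine-only bump of height 0.02 at SHL
±4, an H4-like scenario plants 30% counterphase (10n + 5) dyad shifts and
uses a periodic amplitude of 0.1.

Deliberate simplifications:

* bases are independent across positions — WW/SS periodicity is induced
  through mononucleotide W probabilities, with no dinucleotide Markov
  structure, CpG avoidance, or k-mer composition of a real genome;
* fragments are sampled from the model, not cut from a genome, so there is
  no translational competition between overlapping positions;
* no MNase cleavage kinetics, ExoIII trimming chemistry, sequencing error
  or mapping artefacts (an optional terminal W `end_bias` is the only
  nuisance toggle);
* the small global W deficit (~0.4%) reported between wild-type and
  tailless libraries is *not* planted in the packaged scenarios: a global offset
  legitimately spreads significance over all positions, which would defeat
  the localisation checks the scenarios exist to verify.

A green test on synthetic data therefore establishes that the estimators
recover planted structure of realistic magnitude at realistic depth — not
that real libraries are free of the biases listed above.

## Known limitations

* The rotational classifier is a transparent phase-correlation surrogate
  for the published four-type clustering procedure (which is defined in a
  separate reference); published fractions such as 23% anti-WW/SS in vitro
  are a motivating magnitude, not a number this surrogate is guaranteed to
  reproduce.
* Off-peaks that do not rise above the local periodic curvature are
  reported absent (see above); with heavily smoothed, high-amplitude
  profiles the detector is conservative.
* The two-proportion z-test treats fragments as independent draws; PCR
  duplicates or highly clonal libraries violate that and inflate
  significance.
* BED input requires a reference FASTA; BAM sequences are taken from the
  reference when provided, otherwise from reads with alignment span equal
  to read length (indel-containing records are dropped with a message).
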