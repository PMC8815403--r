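---
title: "Discovering side-chain arginylation with a two-pass restricted search"
author: "argsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering side-chain arginylation with a two-pass restricted search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argsite)
```

## The problem

Arginylation is a post-translational modification in which arginyltransferase
(Ate1) conjugates an arginine to a protein — classically to the N-terminus,
but also to the carboxyl side chains of internal aspartate and glutamate.
Detecting side-chain arginylation by shotgun proteomics is treacherous for
one arithmetic reason: adding an Arg residue to a side chain changes the
peptide mass by exactly the Arg residue mass (+156.10111 Da monoisotopic),
which is also what one extra missed tryptic cleavage contributes when the
neighboring genomic residue happens to be arginine. A naive open search
therefore confuses genuine arginylation with ragged cleavage. `argsite`
implements a discovery pipeline built around that confound:

1. **Pass 1** searches all MS/MS scans against the full protein database
   with arginylation *disabled*.
2. **Pass 2** searches against a restricted database of proteins of interest
   with variable addition of Arg, monomethyl-Arg (+170.11676 Da), and
   dimethyl-Arg (+184.13241 Da) to D/E side chains (and, optionally, the
   protein N-terminus).
3. Arginylated pass-2 identifications are discarded when (a) they fail the
   1% target-decoy FDR, (b) their scan already has a confident unmodified
   explanation from pass 1, or (c) the peptide is flanked by a genomic R so
   the match is isobaric with a missed-cleavage artifact.

The same package quantifies the downstream immunofluorescence readout
(band-localized staining in retinal sections) and runs the paired tests used
to compare wild-type and knockout littermates.

## Mass chemistry

Monoisotopic residue masses are fixed to standard 5-decimal values
(`residue_masses()`), water is 18.01056 Da and the proton 1.007276 Da. A
peptidoform's neutral mass is the residue sum plus water plus modification
deltas, exactly additive, and its precursor is $(M + z\,m_p)/z$. Fragments
are restricted to singly and doubly protonated b and y ions with no neutral
losses; this is sufficient to annotate the worked examples and keeps the
scorer fully specified. The arginyl deltas are Arg plus 0, 1, or 2 CH2
groups (14.01565 Da each).

Two identities matter downstream and are enforced by tests:

* complementarity: $b_i + y_{n-i} = M + 2m_p$ for singly charged ions;
* the confound identity: a peptide with a side-chain Arg anywhere is
  isobaric (to $<10^{-9}$ Da) with the same peptide extended by a literal
  C-terminal or N-terminal arginine.

## Digestion and peptidoform enumeration

Digestion follows trypsin/P: cleavage after every K or R with no proline
suppression. Defaults — up to 2 missed cleavages, peptide length 7–30, at
most 5 variable modifications — are common search-engine defaults, declared
here because the upstream study delegates them to its search engine without
printing them. Fixed carbamidomethyl on Cys reflects iodoacetamide
alkylation; variable modifications are protein N-terminal acetylation and
Met oxidation, plus the arginylation set in pass 2. Enumeration allows at
most one modification per position and at most one arginylation per
peptidoform (the discovery setting: single or ambiguous-single sites).

N-terminal arginylation deserves a note. Arginylation happens in vivo,
before digestion, so the only N-terminus that can carry it is the protein
N-terminus; an internal tryptic peptide's N-terminus did not exist when the
transferase acted. The default registry therefore restricts the N-terminal
variants to protein N-termini (peptides starting at position 1 or 2, the
latter covering initiator-Met cleavage). This also avoids a structural
artifact: a peptide-N-term placement is fragment-indistinguishable from a
side-chain placement on residue 1, which would force spurious localization
ties.

## Scoring, localization, FDR

The scorer is a binomial-survival score: with $n$ theoretical ladder ions,
$k$ of them matched (greedy nearest observed peak within the fragment
tolerance, one observed peak per theoretical ion), and per-ion chance match
probability $p = \min(1,\, 2\,\tau\,N_{\text{peaks}}/\text{span})$, the
score is $-10\log_{10} P(X \ge k)$. It is deterministic, has no fitted
parameters, and every value can be checked against a direct binomial tail
summation. It does not attempt to reproduce any commercial engine's scores;
it is this package's defined scoring function.

Site localization rescores the arginylation at every legal alternative
placement; placements within `localization_epsilon` (default 1 score unit)
of the best form the localization set, and sets larger than one are flagged
ambiguous — this is how an "E or D, two residues apart, no discriminating
ions" case is reported as an ambiguous pair rather than a forced pick.

FDR control is target-decoy with full-protein sequence reversal, searched
identically. Targets and decoys compete within each scan; each PSM's
q-value is the minimum of (decoys at or above) / (targets at or above) over
all accepting score sets containing it, and acceptance at `q_threshold`
(default 0.01) is monotone in the threshold. "Protein-level" FDR is
simplified to the best-peptide q-value; site-level control falls out of the
PSM-level filter plus localization.

Two numerical guards are part of the engine definition:

* **Precursor tolerance 6 ppm** covers the largest printed mass error among
  the worked examples (−5 ppm) with margin; fragment tolerance is 0.02 Da.
* **Minimum evidence floor `min_matched = 6`.** A binomial score can assign
  a nominally high value to a 3–5-ion chance match, and in clean data the
  decoy tail is too sparse to calibrate such events (an empty decoy tail
  yields q = 0 regardless). Under the binomial null at typical ladder sizes
  ($n \approx 100$, $p \approx 10^{-3}$), six matched ions have probability
  about $10^{-10}$ per comparison — far below one event per desk-scale run —
  while a true identification of a minimum-length tryptic peptide at charge
  ≥ 2 has 24 matchable ions. The floor is applied identically to targets
  and decoys, so the competition stays unbiased.

Ties anywhere in ranking are broken by fewer modifications, then
lexicographic peptide, then the canonical modification string, then target
before decoy — results are bit-reproducible.

## The exclusion filters

The three exclusion predicates are independent of one another, so the
surviving set does not depend on the order they are applied in; for
reporting, each excluded PSM is labeled with one reason in the fixed
precedence `fdr`, `scan-identified-in-pass-1`, `terminal-Arg-confound`.
Scan exclusion keys on *accepted* (post-FDR) pass-1 PSMs: "identified" is
taken to mean passing the same 1% criterion as everything else. The
terminal-Arg confound is decided by the sequence-neighbor test (previous or
next genomic residue is R), which captures exactly the isobaric
missed-cleavage ambiguity; manual spectrum inspection, which the original
workflow used for the same purpose, is not computable.

Coverage and depth are computed from pass-1 identifications only: coverage
is the percentage of residues spanned by at least one accepted peptide, and
depth is the mean number of identifying MS/MS scans per covered residue,
counting repeat identifications. Reproducing the published coverage/depth
table itself requires the original raw files and the full mouse proteome
and is out of scope; the implementation is instead verified against a
per-base brute-force accumulator on randomized fixtures.

## Image quantification

Section images are z-projected by the mean (the acquisition averaged
0.3 µm slices), normalized so the mean intensity of the outer nuclear layer
(ONL) — the non-specific background — equals 1, and thresholded by that
background: pixels at or below 1 are zeroed. The threshold is inclusive so
that a pure-background region measures exactly zero. Two measures follow:

* **ROI means**: 6 × 6 µm squares stepped without overlap along the band
  centerline polyline, averaged per section;
* **central-window totals**: the perpendicular intensity profile is sampled
  at pixel pitch with bilinear interpolation, averaged along the band, and
  summed over the 1.1 µm window centered on the profile maximum. Because
  the window tracks the maximum, the total is invariant to lateral shifts.

Per-retina values are simple means over 1–4 sections, then normalized in
two stages: all samples on a slide to mean 1, then each WT/KO pair to mean
1. The whole chain is invariant to global intensity rescaling, which is
what makes the slide normalization legitimate. The box-plot-style statistic
is computed per retina (consistent with averaging "1 to 4 sections per
retina" before comparison).

Manual line drawing is replaced by polylines in a JSON geometry sidecar (or
emitted with known truth by the synthetic generator); the manual step is
not computable and the polyline is the exact information it produced.

## Synthetic data: what it emulates and what it does not

`make_proteome()` draws random proteins with controllable D/E density and
K/R spacing and can embed given peptides at clean tryptic boundaries
(flanked by K, or deliberately by R to construct confound cases).
`simulate_spectra()` emits the singly/doubly charged b/y ladder of each
true peptidoform, optionally subsampled, with log-normal intensities,
uniform noise peaks over the ladder span, and uniform precursor ppm jitter
— the simplest model consistent with the scorer's assumptions, and exactly
deterministic per seed. `simulate_section_pair()` builds two Gaussian
cross-section bands (σ = 0.6 µm, 10 µm apart, standing in for the two
starburst-amacrine bands in the inner plexiform layer) over a uniform
background of 40 raw counts with additive Gaussian noise (sd 4) at
0.2 µm/pixel, with the band amplitude (default 300 raw counts) several-fold
above background, as bright band staining is over ONL autofluorescence.
The amplitude margin matters: the central window sums signal *plus*
background, so the recovered KO/WT ratio of window totals is compressed
toward 1 by the background share; at amplitude ≈ 7.5 × background the
compression stays under 10% for true ratios up to 2, which is the regime
the recovery tests certify.

What the generators do not emulate: chromatography, isotope envelopes,
co-isolation chimeras, channel crosstalk, or tissue morphology beyond the
two-bands-over-background geometry. Passing tests certify the pipeline's
bookkeeping and statistics under the stated generative model, not
instrument realism.

## Paired statistics

`paired_t()` is the standard one-sample t on KO − WT differences (two
sided), with an explicit error on zero-variance differences. The exact
paired Wilcoxon signed-rank test drops zero differences, midranks ties, and
enumerates the null distribution of the positive-rank sum exactly — the
dynamic program over doubled midranks is arithmetic-identical to summing
over all $2^n$ sign assignments — reporting twice the smaller tail, capped
at 1. Exact enumeration is supported to n = 25, far beyond the cohort sizes
(3 and 7 pairs) this design targets. With 3 pairs the attainable two-sided
exact p-values are {0.25, 0.5, 0.75, 1}; published values outside that grid
for n = 3 cannot be exact signed-rank p-values and are not targeted.

## Problem sizes and determinism

The test suite runs entirely on synthetic data at desk scale: a 40-protein
proteome with 1,000 spectra for the end-to-end two-pass check, 10 replicate
noisy searches of 400 spectra each for the FDR check, 7 image pairs per
amplitude ratio, and exhaustive enumeration up to $2^{10}$ for the
signed-rank oracle. All randomness flows through explicit integer seeds;
regenerating any artifact with the same seed is bit-identical.

## Limitations

* The scorer is deliberately simple (no intensity model, no neutral
  losses); it is well calibrated for its own simulated spectra but is not a
  drop-in replacement for a production search engine on instrument data.
* Decoys are full-protein reversals only.
* I and L are treated as distinct characters but are indistinguishable by
  mass; truth comparisons in tests normalize I to L.
* mzML input is not required by the pipeline contract; MGF is the
  interchange format.
* The terminal-Arg confound filter is conservative: it discards genuine
  arginylation that happens to sit next to a genomic R, trading sensitivity
  for specificity exactly as the two-pass design intends.
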