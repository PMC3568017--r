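---
title: "Homopolymer-aware frame-shift alignment: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homopolymer-aware frame-shift alignment: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowalign)
```

## The problem

Pyrosequencing platforms (Roche 454, and similarly Ion Torrent) read DNA by
cycling nucleotide reagents over the template and recording one signal
intensity — a *flowpeak* — per flow.  The called length of a homopolymer run
is the rounded flowpeak, so sequencing errors appear as whole-base
insertions and deletions concentrated in homopolymer runs rather than as
base miscalls.  In translated searches (nucleotide read vs. protein
database) each such indel breaks the reading frame, truncating alignments
and corrupting downstream protein-space analysis.

`flowalign` aligns a nucleotide read against a protein locally while
*allowing* frame-shifts at a position-specific cost that reflects how
plausible a homopolymer miscall is at that position — from the raw flowpeak
when SFF input is available, or from the called run lengths for plain FASTA.

## Alignment model

The dynamic programme extends Smith-Waterman-Gotoh over a protein (rows
$i$) by nucleotide (columns $j$) table.  The cell score is

$$S_{i,j} = \max \begin{cases}
  S_{i-1,j-w} + m_w(p_i, q_{j-w+1..j}), & w \in \{1,2,3,4,5\} \\
  E_{i,j} \\
  H_{i,j} \\
  0
\end{cases}$$

with affine protein-space gaps
$E_{i,j} = \max(S_{i-1,j} - G_0,\, E_{i-1,j} - G_e)$ and codon-space gaps
$H_{i,j} = \max(S_{i,j-3} - G_0,\, H_{i,j-3} - G_e)$.  The width-3 match
$m_3$ is the substitution score of the residue against the translated
codon.  The frame-breaking widths are composite scores

$$m_w(p_i, \cdot) = \max_k \big( m_3(p_i, T_k) - P_k \big)$$

over every candidate triplet $T_k$ reachable by deleting one or two bases
from a 4- or 5-base window, or inserting one or two bases into a 2- or
1-base window.  The combinatorics are small and fixed: 4 single deletions,
10 double deletions (4 adjacent pairs priced by the double-gap penalty $D$,
6 split pairs priced as two singles), 12 single-insertion combinations (10
distinct triplets) and 48 double-insertion combinations (37 distinct
triplets).  All $m_w$ values are pre-computed into a query profile, so the
inner DP loop costs only four extra comparisons per cell relative to the
classical algorithm.

### Position-specific frame-shift penalties

A frame-shift event pays a base penalty $P_0$ ($S$ for singles, $D$ for
grouped doubles), reduced when the flowpeak of the affected homopolymer
makes a miscall plausible.  The deviation needed to re-call an $n$-mer with
flowpeak $p$ as an $m$-mer is

$$\mathrm{Dev}_m(p, n) = \begin{cases}
  p - (m + 0.5) & m < n \\
  0 & m = n \\
  (m - 0.5) - p & m > n
\end{cases}$$

clamped at 0, and the reduction factor is
$f = 1 - \mathrm{Dev}/(k \cdot \max(n, 1))$, clamped to $[0,1]$.  The
penalty paid is $P = P_0 - P_0(1-h) f$, i.e. linear between $P_0$ (at
$f=0$) and the floor $P_0 h$ (at $f=1$).  The scale $k$ is thus the
relative deviation at which the full penalty applies: with $k = 0.2$ a
2-mer is reduced below deviation 0.4 and pays in full from 0.4 on.  For
FASTA input $p = n$, so insertion and deletion penalties coincide at every
(integer) flowpeak and decay with run length; with SFF input they split
according to where the measured peak actually lies.

Which events qualify for reduction:

* deletions of a base charged against its run's flowpeak ($m = n-1$, or
  $n-2$ for a grouped double within one run);
* insertions that extend a flanking run ($m = n+1$ or $n+2$);
* insertions backed by a *zero flow*: with SFF input, a nucleotide whose
  reagent was flowed between the flanking bases' flows but called 0 is
  priced from that flow's value ($\mathrm{Dev}_1(p, 0)$ — e.g. a 0.49
  zero flow gives $f = 1 - 0.01/k$).

Everything else — grouped doubles spanning two different runs, two
different nucleotides inserted at one gap, insertions with no homopolymer
support — pays the full $S$ or $D$.  This is a deliberate reading of the
model: no single flowpeak deviation explains such events, so they get no
flowpeak discount.

### Insertion validation (`V`)

With flow data (or a flow order simulated over the called sequence), an
insertion between two bases is only plausible if its reagent was actually
flowed between the two flanking peaks, or if it extends a flanking run.
With the default cycle `TACG`, no G can be inserted between adjacent T- and
C-peaks of one cycle.  When `V` is on, the candidate enumeration drops
invalid inserted nucleotides; read ends always permit all four.

### Parameter constraints and defaults

`validate_params()` refuses combinations under which the model degenerates:
$D \le 2S$ (otherwise two single gaps always beat a grouped double) and
$Sh + Dh > G_0$ (otherwise frame-shift corrections could substitute for
protein-space gaps).  Defaults, per mode:

| mode      | input | S  | D  | h   | k   | V   |
|-----------|-------|----|----|-----|-----|-----|
| flow454   | SFF   | 20 | 40 | 0.3 | 0.4 | on  |
| fasta454  | FASTA | 12 | 24 | 0.5 | 0.6 | off |
| neutral   | any   | 8  | 15 | —   | —   | —   |

Protein gap open/extension default to $G_0 = 8$, $G_e = 2$, with BLOSUM62
scoring.  The neutral mode prices every frame-shift at the constant $S$ (or
$D$), recovering a classical frame-shift-capable model with separate single
and double gap costs.

## Numerical and tie-breaking choices

* **Scores are doubles** throughout: reduced penalties are non-integral.
* **Stop codons** score a fixed $-16$, below every BLOSUM62 entry, so
  optimal alignments never cross a stop but the total order stays defined.
  This constant is a package choice; N-containing triplets score as `X`.
* **Flowpeak call interval** is standard rounding,
  $n - 0.5 \le p < n + 0.5$.
* **Tie-breaks** are fully deterministic: the cell maximum prefers
  $m_1 \dots m_5$, then $E$, then $H$, then 0, in that order; among
  equal-scoring candidates of one window the enumeration order wins (fewer
  frame-shift events, then leftmost event, then alphabetical inserted
  nucleotide); the traceback starts at the first (row-major) global
  maximum.  Identical inputs therefore give byte-identical output.
* $H$ is undefined for $j < 3$ and both gap states hold the floor value at
  their borders; all $S$ entries are floored at 0 (local alignment).
* Each event in a 5- or 1-width window is priced by its own context; two
  split events may both claim homopolymer-reduced pricing independently.

## What the synthetic benchmark emulates

The benchmark reproduces a study design in which reads with known
homopolymer errors are aligned back to increasingly diverged protein
targets and the recovered indels are scored by Matthews correlation:

1. a random coding seed (default 650 codons, uniform over the 61 sense
   codons — no internal stops) is translated;
2. targets are derived by substituting exactly
   $\mathrm{round}((1 - \mathrm{id}/100) L)$ uniformly chosen positions,
   the replacement drawn $\propto 2^{s/2}$ from the off-diagonal of the
   BLOSUM matrix whose clustering level is nearest the target identity
   (available levels 45/50/62/80/100 — inverted log-odds under a uniform
   background, since the matrices' raw target frequencies are not shipped);
3. reads cover uniformly placed ~350 nt template windows; each positive
   flow draws its peak from $N(n, \sigma(n))$ truncated at 0 and each zero
   flow from $|N(0, \sigma_0)|$, with calls by rounding and every miscall
   recorded as ground truth in read coordinates;
4. predictions are the frame-shift events of the alignment; a true
   positive is a deletion inside the called span of an overcalled run, or
   an insertion of the correct nucleotide at a gap adjacent to an
   undercalled run; unmatched predictions are FP, unmatched truth events
   inside the aligned region FN (events outside it are ignored), and the
   remaining aligned base positions TN.  Counts are pooled over reads per
   (mode, identity) before computing MCC.

The default noise schedule is $\sigma(n) = 0.05 + 0.065\,n$,
$\sigma_0 = 0.12$.  It was fixed once by matching the closed-form expected
miscall rate (normal tails at the $\pm 0.5$ call boundaries, averaged over
the geometric run-length distribution of random sequence) to roughly one
homopolymer indel per ~260 bases — the error-density scale of 454 Titanium
data — and both the closed form and the simulator's agreement with it are
asserted in the test suite.

**What the simulator does not model:** signal droop and phase (CAFIE)
noise, quality decline along the read, chimeric or adapter artefacts,
non-uniform flow cycles, and sequence-composition bias of real genomes
(the seed is uniform-random coding sequence).  Benchmark results therefore
demonstrate the *relative* behaviour of the alignment models under a clean
flowpeak error model — the test suite asserts the mode ordering
(flow-aware ≥ FASTA-homopolymer ≥ neutral at every identity) and that the
flow-aware model at defaults at least doubles the neutral model's mean MCC
— not absolute accuracy on any real instrument's output.

### True-negative definition

TN is counted over aligned query *base* positions (aligned length minus
positions carrying a truth or predicted event).  Counting flow-space
positions instead would shrink TN by the zero flows; since TN enters MCC
only through factors shared by all modes, the comparison between models is
insensitive to this choice.

### Problem sizes

The shipped acceptance checks run 1,000 simulated reads against targets at
100/80/60/40 % identity under all three modes (12,000 alignments of ~350 nt
× ~650 aa), 100+ randomised tiny instances cross-checked against an
exhaustive oracle, and 25 reductions to classical three-frame protein
alignment cross-checked against the Biostrings aligner.

## Known limitations

* No heuristic prefilter: every query-database pair is fully aligned
  (quadratic time per pair).  Seed-and-extend tools can be used upstream to
  shortlist candidate pairs.
* Only the three forward frames are searched; the CLI's `--both-strands`
  re-runs the reverse complement and reports the better strand.
* No per-position correction tracking: with legal parameter settings this
  is harmless (the validation constraints exclude the degenerate penalty
  combinations), but homopolymer lengths are not stably re-estimated, only
  locally corrected.
* The SFF reader covers v1.00 with format code 1 and skips index blocks;
  flowgram re-basecalling and quality scores are out of scope.
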