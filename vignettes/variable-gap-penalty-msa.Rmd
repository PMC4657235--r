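---
title: "Variable gap penalties from indel flanking regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable gap penalties from indel flanking regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelmsa)
```

## The model

`indelmsa` is a progressive global aligner for protein sequences whose
gap penalty varies along each sequence. The premise is biological:
insertions and deletions are not uniformly placed but concentrate in
flexible regions, and the *flanking regions* — the segments immediately
left and right of an indel — have a composition that a sequence model
can learn. An *indel flanking region* (IndelFR) is an indel together
with both flanks.

### Flank scoring with PPM

Two prediction-by-partial-match (PPM) models, one trained on left
flanks and one on right flanks, are variable-order Markov models with
escape probabilities. We use the PPM-C escape scheme without exclusions:
a context seen `N` times with `q` distinct successors predicts a seen
symbol `s` with weight `count(s)/(N+q)` and escapes to the
next-shorter context with probability `q/(N+q)`; the recursion ends in
a uniform distribution over the 20-residue alphabet, so every
probability is strictly positive and each context's distribution sums
to one (both are asserted in the test suite). PPM-C was chosen because
it is the canonical default among escape schemes and its arithmetic is
small enough to verify by hand; the hand-expanded values are frozen in
the tests.

A window of length `L` starting at position `i` is scored by its
average log-loss,
$$-\frac{1}{L}\sum_{k=0}^{L-1}\log_2 P\!\left(s_{i+k}\mid\text{the }\min(k, D)\text{ preceding window symbols}\right),$$
where `D` is the model order. Each term conditions only on symbols
inside the window, so windows are scored independently of their
context and never cross sequence ends.

### From log-loss to gap penalties

Scanning a sequence of length `n` gives left and right profiles
`LPPM_i`, `RPPM_i` for window starts `i = 1..n-L+1`. The
position-specific gap opening penalty is their elementwise minimum;
positions `n-L+2..n` have no window of their own and repeat the value
at `n-L+1`. We implement this tail rule literally; interpolation over
the tail would be an alternative reading, but the constant tail is the
simpler contract and affects at most `L-1` positions.

Predicted IndelFR intervals make the gap *extension* penalty
region-specific: zero inside an interval, equal to the opening penalty
outside. Long gaps are therefore cheap exactly where indels are
predicted plausible, and as expensive as repeated openings elsewhere.

### IndelFR extraction

The extraction rule is a deliberate, fully deterministic design choice
(the literature it descends from does not fix an algorithm): position
`p` is a left-flank anchor if `lppm[p]` is a strict local minimum lying
below `mean(lppm) - c * sd(lppm)`; right anchors analogously on `rppm`.
Each left anchor pairs with the nearest right anchor at most `W`
positions downstream, spanning `[p, right + L)`; unpaired anchors of
either kind claim a window-length interval. Overlaps are merged.
Defaults `c = 1.0` and `W = 30` mean "clearly below baseline" and "an
indel region rarely exceeds three windows"; both are exposed as
parameters. A flat profile has no strict local minima (and zero
standard deviation), so featureless sequences yield no intervals. An
optional width-3 moving average (`smooth`) is off by default: raw
profiles keep the rule exactly reproducible from the scan.

### Pairwise and profile alignment

Alignment is global three-state dynamic programming over match and two
gap states. A gap run over positions `i1..i2` of one side costs that
side's `gpo[i1] + sum(gpe[i1..i2])`; terminal gaps are charged like
internal ones (no terminal exemption is part of the model). Boundary
rows use the same prefix sums with a single opening. We allow direct
transitions between the two gap states (charged as a fresh opening):
this makes the recursion's optimum equal, by construction, to the
maximum over *all* global alignments under the run-based cost, which
the test suite verifies against exhaustive enumeration on small
instances with arbitrary per-position penalties, and against an
independent affine-gap implementation (`Biostrings::pairwiseAlignment`)
when penalties are constant. The comparison with the external aligner
uses a `1e-4` tolerance, reflecting that implementation's internal
score scaling; our own equality assertions use `1e-6` or tighter.

Columns of two profiles score as
`occA * occB * sum_xy fA(x) fB(y) S(x, y)` with `f` the residue
frequencies over non-gap entries and `occ` the non-gap fraction —
the simplest frequency-weighted generalization that reduces exactly to
`S(a, b)` for single residues. The substitution matrix is GONNET250
(shipped as a plain-text table). When profiles merge, penalties merge
column-wise: both-aligned columns add, gap columns copy the non-gap
side. By induction this keeps every column's opening penalty equal to
the sum of the single-sequence penalties of the residues present in
it; zero-extension (IndelFR) columns stay zero through gap columns.

Traceback ties prefer match, then gap-in-B, then gap-in-A, making
outputs deterministic.

The linear-space mode finds the same-scoring trace by
divide-and-conquer over the middle row, joining forward state vectors
with backward vectors computed by a suffix recursion; a gap run
crossing the split is handled by a join on the gap state whose
right-hand continuation waives the second opening, and the left
subproblem is then constrained to end in that state. The score contract
is identity with the full matrix (tested on hundreds of random pairs,
including deep recursion with a tiny base case).

### Distances and guide tree

Pairwise distances use one-mismatch pattern matching: every length-3
word of the shorter sequence earns the best `(3 - mismatches)/3` credit
over the longer sequence's words, counting only word pairs with at most
one mismatch, and the identity is the mean credit. This word-credit
scheme is the natural weighting that reports 67% identity for the pair
`ABCABCABC` / `ABDABDABD` (where exact 3-tuple matching reports zero
shared patterns) and degrades to exact k-tuple identity when mismatches
are disallowed. Normalizing by the shorter sequence keeps the identity
in `[0, 1]` and symmetric. Distance is one minus identity.

The guide tree is textbook UPGMA — size-weighted average linkage with
each merge at half the cluster distance — computed by
`stats::hclust(method = "average")`, with ultrametricity and monotone
merge heights property-tested. Tie-breaking among equal-distance pairs
follows `hclust`'s deterministic ordering. Profiles are merged
bottom-up in the tree's merge order; the root profile is the final
alignment, re-ordered to input order.

## Scoring against references

SP is the fraction of residue pairs co-occurring in *core* reference
columns that the test alignment reproduces; TC the fraction of core
columns whose residues all share one test column. Core blocks default
to every column; a mask file of 1-based ranges restricts them.
Reference columns with gaps still contribute their present residue
pairs to SP; for TC we count only columns with at least two residues
as "aligned columns", which makes SP and TC coincide exactly in the
pairwise case. Matched-pair significance testing across many
alignments is deliberately left to stock routines
(`stats::wilcox.test`).

## The synthetic-data generator

`simulate_family()` evolves a star phylogeny from a random ancestor.
The ancestor alternates conserved *core* blocks (uniform residue
background, lengths 10–16) with indel-prone *loop* blocks (lengths
6–12) drawn from a composition enriched in the small/polar residues
that dominate real loops (G, P, S, N, D, E, Q, K, T). Each descendant
receives i.i.d. substitutions (probability 0.15 per site, resampled
from the local background) and indel events anchored at loop sites
(probability 0.06 per loop site; insertion or deletion with equal
probability; geometric lengths with mean 3, capped at 8). Events are
kept at least two ancestor positions apart so the bookkeeping is exact:
each deletion is one gap run in its own row, each insertion one gap run
in every other row. The true alignment assigns one column per ancestor
position and a private column block per insertion (insertions of
different descendants are not homologous). Everything is
seed-deterministic.

The loop/core structure is the generator's model of reality, and it is
what makes the end-to-end test meaningful: flanks carry a learnable
composition, as real indel flanks do. What the generator does *not*
emulate: tree-shaped phylogenies (a star keeps the true alignment
unambiguous), empirical indel length spectra, rate heterogeneity
beyond the two-block structure, and substitution-matrix-biased
exchanges (a GONNET-derived sampler would be a straightforward
extension). Passing tests therefore demonstrate the mechanism — flank
learning steering gap placement — not benchmark-grade accuracy on real
protein families.

Training corpora pair, for every recorded indel, the up-to-`F = 10`
residues left of the breakpoint with the up-to-`F` residues right of it
(events touching a sequence end are dropped from both corpora, keeping
them the same size). `F = 10` matches the window length: the influence
of an indel on its flanks fades within about ten residues.

## Study sizes and numerical choices

The end-to-end comparison trains on 30 simulated families, evaluates on
10 held-out families, and averages over 20 seeds — sizes chosen so the
whole experiment is a desk-scale computation (about two minutes) while
still averaging over a few hundred alignments. The control pipeline is
built from the same components with each family's mean opening penalty
as a constant `gpo` and `gpe = gpo`, so the comparison isolates the
*variability* of the penalty, not its scale. With the defaults above
the variable-penalty pipeline recovers true alignments at least as well
as the constant control on average; the margin is modest at these
divergences, as expected for closely related families.

Other numerical points: scores accumulate in double precision; the
divide-and-conquer and full-matrix paths are compared at `1e-6`;
probability normalization at `1e-9`; ultrametricity at `1e-9`. Strict
alphabet mode rejects non-standard letters; permissive mode maps them
to `X`, scored as the row minimum of the substitution matrix — a
conservative penalty that invents no chemistry. Gap characters `.` are
normalized to `-` on input. Sequences shorter than the scan window
cannot be annotated; in permissive mode they receive the corpus-mean
log-loss as a constant opening penalty (the uniform-model value
`log2 20` if no sequence could be scanned), documented as a fallback
rather than a prediction.

## Limitations

* Predictor quality is bounded by the flank corpora; a predictor
  trained on one fold family does not transfer to unrelated folds.
* The extraction rule's anchors are scan-level heuristics; the
  intervals are predictions, not annotations.
* Purely progressive: no iterative refinement or consistency
  transformation, so early misalignments persist.
* The one-mismatch identity is an approximation to alignment-based
  distance and saturates for highly diverged pairs.
* Linear-space mode reduces memory, not time; both modes are quadratic
  in sequence length per node.
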