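---
title: "Feature-amplified voting: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-amplified voting: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(favat)
```

## The problem

Within a protein superfamily, sequence similarity and function can
dissociate: a target enzyme may share 50–80% identity with close relatives
that *lack* its activity, while enzymes that *share* the activity sit at
only 30–40% identity. Plain conservation analysis over such a family is
misled — the strongest conservation signal comes from the close,
functionally-negative relatives. FAVAT (feature-amplified voting) turns the
discrepancy itself into signal. Two groups are declared by the user:

* **A group** — proteins with the target's functional property, however
  distant in sequence;
* **~A group** — proteins without the property, however close in sequence.

A residue that the target shares with the A group but not with the ~A
group is a candidate functional residue.

## Stage 1: three-profile alignment

The target (a one-sequence profile) and the two pre-aligned group profiles
are aligned jointly by dynamic programming, so that the comparison in
stage 2 is column-wise meaningful. Each alignment column has one of seven
*shapes* — each profile either contributes its next column (`r`) or an
all-gap column (`-`); `---` is not a column. The objective is a
sum-of-pairs score over the three pairwise projections:

* a projected residue–residue column adds the weighted pair-profile score
  `Sp(x, y) = Σ_{a,b} W_a W_b M[r_x(a), r_y(b)]`, where `M` is the
  substitution matrix and pairs involving an intra-profile gap contribute
  0 (alignment-level gaps already carry the affine penalties; charging
  intra-profile gaps as well would penalise ragged groups twice);
* a projected residue–gap column is charged affinely: GOP when the run
  opens, GEP for each further column of the run;
* a projected gap–gap column scores 0.

**Gap convention.** Affine costs are charged independently per pairwise
projection with *quasi-natural* accounting: the opening decision looks
only at the immediately preceding column, so a residue-vs-gap column costs
GEP exactly when the previous column has the same projected gap direction,
otherwise GOP. In particular a gap run resuming after an intervening
gap–gap column is re-opened. Fully "transparent" gap–gap columns (natural
gap costs) would require remembering each projection's last non-gap-gap
state, i.e. more DP state than one layer per column shape; the
quasi-natural convention is the standard compromise that seven shape
layers realise exactly, and the configuration it over-charges (a gap run
interrupted by a gap–gap column in the same projection) is rarely optimal.
The brute-force oracle and `rescore()` evaluate this same column-sequence
objective from its definition, so DP-vs-oracle equality is exact, not
approximate.

**States and traceback.** One DP layer per shape (seven layers; with
`end_gaps_free` each layer is further split by a lead/mid/trail phase per
projection so that terminal gap runs are free). Traceback ties are broken
by the fixed shape preference `rrr > rr- > r-r > -rr > r-- > -r- > --r`,
which makes alignments byte-reproducible across runs. The DP core is
implemented in C++ and runs in `O(L1·L2·L3)` time over the seven layers;
three profiles of length 150 align in well under a minute on one CPU.
The free-end-gap variant carries more state and is intended for the
shorter inputs where terminal overhangs actually matter.

**Parameters.** `gap_open` (default 10) and `gap_extend` (default 0.5)
are in the units of the substitution matrix (half-bits for BLOSUM62) and
assume the default *uniform* sequence weighting (`W_a = 1/m`), which keeps
`Sp` on the scale of a single substitution score regardless of group size,
so one GOP/GEP setting works across group sizes. `"unit"` weighting
(`W_a = 1`) is provided for unweighted sum-of-pairs scoring; if you use it
with large groups, scale the gap penalties accordingly. Terminal gaps are
penalised like internal ones by default — the simpler contract — with
`end_gaps_free = TRUE` as the alternative for domain-in-context
alignments.

## Stage 2: voting

For every alignment column where the target shows residue `t`, each
(A-sequence, ~A-sequence) pair casts a vote

&nbsp;&nbsp;&nbsp;&nbsp;`V = M[t, a] − M[t, na]`,

positive when `t` resembles the functional group more than the
non-functional one. The raw T-score of the position is the sum of all
`m·n` votes; voting always uses unweighted matrix scores, whatever
weighting the alignment stage used. Useful identities (all tested):
`V(t,x,y) = −V(t,y,x)` and `V(t,x,x) = 0`, so a residue conserved across
*both* groups cancels exactly — the statistic amplifies only the
discrepancy.

**Gap rule.** Under the default `"any_gap_zero"`, a column in which any
group sequence shows a gap gets a raw T-score of 0 (and is flagged): an
insertion region gives no evidence either way. The alternative
`"target_gap_skip"` only drops the individual gap terms and still scores
the column; it reproduces literal pair-by-pair accumulation. The default
is the stricter, column-level reading; both are exposed because the two
conventions genuinely differ on ragged families.

**Normalization.** `norm = (T − min) / (max − min) × 100` over all
reported positions, gap-zeroed ones included (they are real observations
of "no evidence"). A degenerate table (all raw scores equal) normalizes to
all zeros with a warning rather than an error, so pipelines on toy inputs
do not die. Note the consequence: normalized scores are *relative* within
one vote — some position always scores 100 — which is why selection uses a
threshold *within* each vote and confidence comes from *merging* votes
against independent A groups (`merge_votes()` keeps positions that exceed
the threshold, strictly — "over 60" — in both).

## The synthetic family generator

`generate_family()` builds the study design the method targets: a random
target; an A group at ~35% identity whose sequences preserve the target
residue at every planted position; a ~A group at ~65% identity whose
sequences are forcibly substituted there, drawing replacements among
residues with BLOSUM62 score ≤ 0 against the target residue so the
functional contrast is guaranteed by construction. Identity is exact
matches over aligned non-gap positions divided by target length, and the
substitution counts are chosen so measured identities land on the
configured bands. With `indel_rate = 0` (default) the groups are natively
aligned and results are exactly analysable; with a positive rate, indels
are placed away from planted positions and the emitted sequences are
unaligned, so the user (or test harness) must pre-align groups first, as
with real data.

What the generator does *not* emulate: phylogenetic correlation within
groups (sequences are i.i.d. mutants of the target), realistic
substitution processes (background mutations are uniform over the 19
alternatives), compositional bias and long indels. Passing the recovery
test therefore shows the statistic works when its assumptions hold; it
does not certify performance on real superfamilies, where group curation
and alignment quality dominate.

**Reference conditions.** The standard fixture is a length-120 target,
6 planted positions, 4 A and 4 ~A sequences at the 0.35/0.65 identity
bands, no indels; across 20 seeds the pipeline is required to rank all six
planted positions inside the top 10 normalized T-scores in at least 90% of
seeds. The null check uses equal identity bands (0.65/0.65), no planted
positions, a length-60 target and 50 seeds: because normalization pins
each seed's maximum at 100, "no systematic candidate" is read
per position — no single position may exceed the 60 threshold in more
than half the seeds; 50 seeds keep the maximum of the 60 per-position
frequencies clear of its chance extreme.

## Numerical and interface choices

* Scores are kept as doubles end to end; DP-vs-oracle and
  traceback-rescore comparisons use an absolute tolerance of 1e-9.
* The built-in BLOSUM62 is the canonical 24-symbol NCBI half-bit table
  (so the ambiguity codes B/Z/X and `*` are scored from the table itself);
  symbols absent from a matrix are an error, never a silent zero, because
  silent zeros would corrupt T-scores undetectably.
* Profile columns are 1-based everywhere in the API, matching R
  convention; reports are 1-based positions in the ungapped target.
* `'-'` and `'.'` are both accepted as gaps on input; `'-'` is written on
  output.
* The brute-force oracle refuses profiles longer than 6 columns — past
  that, enumeration of the seven-shape column sequences explodes
  combinatorially.
* The selection threshold default is 60 with strict inequality ("over
  60"); ties at exactly 60 are excluded.

## Known limitations

Three-way DP memory grows as `L1·L2·L3` backpointers, which bounds
practical target lengths to a few hundred residues on one machine; the
voting stage assigns no statistical significance to T-scores (ranks are
relative within a vote); and group membership (A vs ~A) is an input — the
method amplifies a contrast it is given, it does not discover one.
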