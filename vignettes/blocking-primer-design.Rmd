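---
title: "Designing and evaluating host-blocking primers in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating host-blocking primers in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockprimr)
```

## The problem

Metabarcoding of host-associated microbial eukaryotes with universal 18S
rRNA primers returns mostly host reads: the host template outnumbers every
protist template, and the universal V4 primer pair amplifies it just as
well. A blocking primer counters this at the annealing step. It is an
oligo whose 5′ portion lies on the 3′ end of the universal reverse
primer's binding site and whose remainder extends into sequence found only
in the host; a Spacer C3 group at its 3′ end prevents elongation. On host
templates the blocker out-competes the reverse primer and the template is
not amplified; on non-host templates the host-specific portion does not
anneal and amplification proceeds.

`blockprimr` implements the computational side of this strategy: deciding
which database sequences a degenerate primer pair amplifies, deriving
blocking candidates from the host amplicons, scoring their specificity,
and profiling the outcome per taxonomic group.

## Matching model

All matching is IUPAC set-intersection: each code denotes a base set
(Y = {C,T}, R = {A,G}, N = {A,C,G,T}, ...), and two positions are
compatible when their sets share a base. A template `N` therefore matches
any primer position. This is the permissive convention appropriate for
reference databases that contain ambiguity codes; it never creates false
negatives, at the cost of counting a fully ambiguous stretch as a match.
Mismatches are counted uniformly across the primer — there is no 3′-anchor
weighting — and a primer binds a window when the count is at most
`max_mismatch`.

The default allowance is one mismatch. This reflects the host system the
package was built around: known oyster sequences differ from the universal
V4 reverse primer at exactly one position, so an exact-match criterion
would discard the very templates the blocker must target.

Coordinates are 0-based half-open on the stored strand throughout, so
`end - start` is always a length; minus-strand sites mean the primer
matches the reverse complement of the reported interval. An amplicon
requires a forward and a reverse site in amplifiable orientation and spans
from the first to the last primer base — lengths quoted by the package
include both primer regions, matching how PCR product sizes are usually
stated. When degenerate primers produce several site pairings, all are
reported and the shortest product is flagged primary; nothing is silently
picked.

## Design procedure

1. **Amplify the host pool.** Host records are amplified in silico with
   the universal pair; records without a complete amplicon contribute
   nothing.
2. **Stack the 3′ windows.** The last `window_len` = 40 nt of each host
   amplicon (the reverse-primer region plus the adjacent host-specific
   sequence) are stacked, right-anchored at the primer site, into a
   per-column IUPAC consensus. Right-anchored stacking replaces a multiple
   alignment here: because every window ends at the same primer-defined
   position, columns are already homologous and an aligner would add a
   dependency without changing the decision quantity (does a candidate hit
   the off-target pool?). The equivalence is behavioral, not
   bit-identical, and is exercised by the planted-motif tests.
3. **Enumerate candidates.** Candidates are reverse complements of
   consensus substrings whose 5′ end sits exactly `overlap_len` = 10 bases
   inside the reverse-primer site, one per length in
   [`min_len`, `max_len`] = [18, 29] nt. Exactly ten overlapping bases —
   rather than at least ten — keeps the candidate series nested and the
   host-specific portion maximal for a given length; the overlap
   requirement is configurable for users who prefer the looser reading.
4. **Filter by melting temperature.** Each candidate's Tm must lie within
   `tm_tolerance` = 3 °C of the mean Tm of the primer pair, so the blocker
   competes at the same annealing temperature. Out-of-tolerance candidates
   are reported but not selectable.
5. **Score and select.** Each candidate is searched against the host and
   off-target pools (both restricted to records the pair amplifies); a
   record counts as blocked when the candidate has a site within
   `block_max_mismatch` = 0 mismatches on either strand. Selection is a
   total lexicographic order: maximal target fraction, minimal off-target
   fraction, minimal |ΔTm|, shorter length, alphabetical sequence.
   Permuting the input cannot change the winner.

The strict `block_max_mismatch = 0` default takes the conservative reading
of what "removed by the blocking primer" should mean in silico: a blocker
is only credited with suppressing templates it matches exactly
(IUPAC-compatibly). The in-vitro threshold is unknowable from sequence
alone, so the parameter is exposed.

## Melting temperature

Tm uses the unified nearest-neighbor thermodynamic model: duplex ΔH° and
ΔS° are sums of the ten Watson–Crick stacking terms plus terminal
initiation terms (G·C: ΔH = 0.1 kcal/mol, ΔS = −2.8 cal/mol·K; A·T: 2.3,
4.1), the entropy is salt-corrected by 0.368·(N−1)·ln[Na⁺], and

Tm(°C) = 1000·ΔH° / (ΔS° + R·ln(C_T/4)) − 273.15

with R = 1.987 cal/mol·K, [Na⁺] = 50 mM and C_T = 0.25 µM by default
(both configurable in mol/L). The model needs a concrete duplex, so
degenerate positions are resolved before Tm is computed: candidates
enumerated from a consensus are evaluated on the per-column modal base of
the underlying host windows (ties alphabetical), and degenerate *primers*
are assigned the mean Tm over their full expansion (an error beyond 64
variants). Sequences shorter than 8 nt are rejected — the nearest-neighbor
model is unreliable there.

One property worth stating because it is commonly assumed: extending an
oligo by one base does *not* always raise this Tm. The terminal-initiation
swap plus the salt and concentration terms make a few percent of random
single-base extensions mildly destabilizing. The test suite therefore pins
the implementation to an independent longhand evaluation of the model
rather than to a monotonicity axiom, and checks only the majority trend.

## Classification and profiling

Against a primer configuration every record receives exactly one status:
`AMPLIFIED` (complete amplicon, no blocking site inside it), `BLOCKED`
(complete amplicon but the blocker binds within it — only ever a demotion
from AMPLIFIED), `INCOMPLETE` (one site only, or mis-ordered sites:
a partial reference record), or `NO_SITE`. Completeness filtering — which
replaces similarity-search-based screening for records spanning the whole
amplicon region with a direct, deterministic two-site-plus-length-bounds
criterion — keeps AMPLIFIED records whose product length falls in a
configurable interval. Group profiles tally statuses per taxonomy label at
a chosen rank depth; records annotated too shallowly go to an
`unresolved` bin rather than being dropped, so per-group counts always sum
to the database size. `fraction_amplifiable` counts records with a
complete amplicon regardless of blocking; `fraction_amplified` and
`fraction_blocked` split it.

## The simulator: what it emulates, and what it does not

`simulate_reference_db()` builds each record as
`pad + forward-site instance + insert + [blocking motif] + reverse-site
instance + pad`. Per clade it controls the number of mismatches planted in
each primer site, the probability `p_block` that a record carries the
blocking motif (laid so its 3′ sense bases coincide with the start of the
reverse-primer site — the geometry a blocker needs), and a truncation
probability `q_trunc` that cuts the record before the reverse site,
emulating partial database entries. Background substitutions touch only
pads and insert, so truth labels stay exact. One master seed is split
arithmetically per clade, so appending a clade never changes earlier
clades' sequences, and a fixed spec yields byte-identical FASTA across
runs.

Default dimensions mirror the oyster study conditions the package was
validated under: a host clade whose reverse-primer site differs from the
universal primer at exactly one position (implied by the 25-nt blocking
motif itself, which is planted fully conserved and overlaps the site by
10 nt), insert lengths around 152 nt so products are near 190 nt, and
protist clades with exact primer sites and no motif. Validation scenarios
use a host clade of 20 records against three protist clades of 50, and a
partially conserved sister clade at `p_block` = 0.82 with n = 500 records,
checked against the closed-form expectations of
`planted_truth_profile()` within 99% binomial intervals. These sizes keep
the full suite fast while leaving the binomial checks well-powered.

What the simulator does **not** emulate: rRNA secondary structure,
phylogenetically correlated evolution along a tree, chimeras, or the
length and composition biases of real SSU databases. Passing tests on
synthetic data therefore demonstrate correctness of the machinery —
matching, geometry, bookkeeping, selection — not that any particular
blocker will perform identically against a real reference release, whose
taxon sampling dominates the resulting percentages.

## Numerical and degenerate-input choices

* Site search is vectorized over windows via 4-bit base masks; the test
  suite proves it identical to naive all-window enumeration on both
  strands over a thousand random (sequence, primer, allowance) triples.
* Ties anywhere in selection resolve deterministically (documented
  lexicographic order); profile rows order by descending group size.
* Empty inputs: an empty FASTA reads as a zero-row database and flows
  through amplify/profile; an empty target pool is an error (specificity
  is undefined), as is a window shorter than the reverse primer.
* Records with more than 10% ambiguity codes are flagged, never dropped —
  there is no silent quality filter.
* Overlap measurement (`overlap_length()`) scans k from the full primer
  length downward and reports the largest k within the allowance, so a
  long spurious overlap can never shadow the intended one.

## Limitations

The package evaluates annealing-site sequence only: no secondary
structure, primer-dimer or hairpin screening, no modeling of the Spacer C3
chemistry beyond a metadata flag, no position-weighted mismatch scoring,
and no multiplex design. In-silico blocking fractions are upper bounds on
what a blocker achieves in a PCR mix, where template ratios and kinetics
intervene.
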