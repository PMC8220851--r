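---
title: "Motif-matrix screening for ApaH-like phosphatases: model and methods"
author: "alphscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-matrix screening for ApaH-like phosphatases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphscreen)
```

## The screening model

ApaH-like phosphatases (ALPHs) are recognised by six short conserved
motifs: the four PPP-superfamily signature motifs (a GDxHG-like metal
binding motif, a GDxxDKG-like motif, a GNHE-like motif and HGG) and two
ALPH-specific C-terminal motifs. Each motif is modelled as an ordered
list of allowed-residue sets; a sequence window matches if and only if
every residue belongs to the set at its position. The model is
deliberately *not* probabilistic: no PSSM, no log-odds, no threshold.
The families to be excluded (ApaH, SLP, RLPH and the canonical PPPs)
differ from ALPHs by a small number of diagnostic residues, and a crisp
set-membership rule keeps the decision auditable residue by residue.

Two matrix flavours exist for every motif:

* the **narrow** matrices drive the primary pass;
* the **extended** matrices are supersets of the narrow sets that also
  tolerate the unknown-residue code `X`/`x` at every position (draft
  proteomes contain unsequenced residues). At most
  `extended_budget = 2` motifs per protein may be matched *only* by
  their extended matrix. In practice extended matches are rare in true
  ALPHs (about 2% of motifs, about 11% of proteins), so the default
  budget is generous rather than restrictive.

One exclusion overrides everything: **arginine at position 6 of
motif 2 never matches**. That arginine is precisely what distinguishes
the GDxxDRG motif of ApaH/RLPH/PPP enzymes from the ALPH variant (which
carries lysine), and admitting it would collapse the family boundary.
The rule is enforced inside the window test itself, not as a
post-filter, so a custom matrix cannot silently re-admit it; an
explicit `allow_r6 = TRUE` is the only way through.

## Distance constraints and their convention

Three inter-motif spacings are conserved enough to be constraints:
14–150 residues between motifs 1 and 2, 25–80 between 2 and 3, and
17–40 between 5 and 6. Spacings 3→4 and 4→5 carry no bound (the first
is conserved only within some lineages; the second hardly at all).

Published descriptions of such screens rarely state whether a
"distance" is measured start-to-start or as the gap between motifs.
Both conventions are implemented behind
`distance_constraints(convention = ...)`; the default is **gap** —
residues strictly between the last residue of the upstream motif and
the first residue of the downstream one — because distances drawn
between motif *boxes* in domain schematics are gaps. The two
conventions differ exactly by the upstream motif length, so results can
be converted without rescreening; the active convention is recorded in
every call and summary.

## The assignment search

Scanning is exhaustive: every window of every protein is tested against
both flavours of all six matrices (vectorised membership over an
A–Z lookup). Assembly is a depth-first search over occurrences in motif
order with pruning on ordering, non-overlap, the three distance bounds
and the extended budget. Motifs are 3–7 residues, occurrence lists are
short, and the constrained windows are tight, so the search space is
tiny and the walk enumerates *every* feasible assignment — it is exact,
as the test suite verifies against brute-force 6-tuple enumeration.

Where several assignments are feasible, the screen minimises the number
of extended-matrix motifs first and breaks remaining ties by the
lexicographically smallest start-position tuple. The tie-break is a
design choice (any valid assignment identifies the same protein); it is
fixed so outputs are deterministic and reproducible byte for byte.
Two further choices where the method description is silent: motifs may
not overlap (all conserved spacings are large relative to the motif
lengths, so this costs nothing and avoids degenerate calls), and one
call is made per protein — the rare second ALPH domain in a single
protein is reported in the notes when `multi_domain = TRUE`, never as a
second row.

## Audit modes

The **one-motif-missing scan** waives one motif at a time: it reports a
protein iff the remaining five motifs admit a valid assignment (bounds
involving the waived motif are dropped) *and* the full screen is
negative. It serves two purposes: auditing the matrices (a recurrent
near-miss at one position suggests the matrix is too strict) and
flagging candidate truncated ALPHs — proteins missing the N- or
C-terminal motif, typically from mis-annotated start codons or
sequencing gaps. Waiving motif 1 or 6 tags the outcome as a candidate
N- or C-terminal truncation respectively. Rescue of such proteins is
deliberately manual; the package surfaces candidates and stops there.

## Coordinates and outputs

All reported coordinates are 1-based with inclusive ends; internal
arithmetic uses the same convention throughout, so what is printed is
what is indexed. The catalytic domain is defined as motif-1 start − 6
through motif-6 end + 8, clipped at the sequence termini; the clipped
definition guarantees that N-terminus, catalytic domain and C-terminus
always partition the protein length exactly, an invariant the tests
enforce on every annotation. TSV outputs are written with a fixed
column order and no quoting, so identical inputs give byte-identical
files.

## The synthetic-data generator

Real reference proteomes are large downloads pinned to specific
releases; the package instead ships a generator whose defaults encode
the observed features of real ALPH corpora, so every pipeline stage is
testable offline:

* spacing 1→2 concentrated on 28–30 (mode 29, 72%; 93.7% within 28–30,
  remainder spread over the legal 14–150);
* spacing 2→3 on 26 (83%; 98% within 25–33);
* spacing 3→4 94% within 55–64; spacing 4→5 broad (uniform 20–120);
* spacing 5→6 exactly 19 for 92.5%;
* annotated N- and C-terminal extensions lognormal with medians 87 and
  26 residues (the planted flanks are 6 and 8 residues longer, which
  the catalytic domain reclaims);
* 11.3% of positives carry exactly one extended-only motif (hence 1.9%
  of motifs; never two per protein);
* 25% of ALPH-positive organisms carry more than one isoform, 81% of
  those exactly two.

Motif residues are sampled from the matrices themselves; spacers and
termini are uniform draws over the 20 standard amino acids,
rejection-sampled until they contain no extended-matrix occurrence of
any motif, so no spurious motif set can arise in a background region.
Each planted positive is additionally required to be *canonical*: the
screen's optimal assignment must coincide with the planted spans
(sequences where a junction window would offer an equally valid, more
leftmost placement are resampled). Decoys each violate exactly one
property — arginine at motif-2 position 6, one spacing pushed outside
its bound, one motif erased (replacement windows re-drawn until nothing
matching that motif survives around the span), a terminus cut through
motif 1 or 6, or pure background — and are verified negative before
being emitted. All randomness flows from the single spec seed;
identical seeds give byte-identical FASTA and truth tables.

What the generator does **not** emulate: homologous sequence context
(backgrounds are i.i.d. uniform, not real protein composition),
evolutionary divergence of the motifs beyond the matrix sets, isoform
sequence similarity within an organism, and mis-annotation artefacts
other than clean truncation. Passing the planted-truth tests therefore
demonstrates the correctness of the combinatorial screen, not the
biological adequacy of the matrices — the latter rests on the curation
that produced them.

## Problem sizes and numerical choices

The test suite checks oracle equivalence (screen vs exhaustive 6-tuple
enumeration) on 1000 short sequences (500 planted with compact
spacings, 500 random of 30–300 residues), exact planted-truth recovery
on a 2250-protein corpus (1000 positives, 250 decoys per class), and
generative-parameter recovery on a 10,000-positive corpus within three
binomial standard errors. The acceptance script uses 2000 positives and
250 decoys per class. These sizes make binomial noise small relative to
the tested fractions while keeping a full run in a few minutes on one
CPU.

There is no floating-point subtlety anywhere in the screen — matching
is set membership and distances are integer arithmetic — so no
tolerances are needed: equality assertions are exact. Degenerate inputs
are handled explicitly: empty sequences are an error at ingestion,
sequences shorter than a motif yield empty occurrence lists, `*` stop
codons and the ambiguity codes B/Z/U/O simply never match any position,
and terminal-proximal motifs clip the catalytic domain rather than
producing negative flank lengths.

## Known limitations

* The matrices are taken as given; the iterative curation loop that
  produced them (training proteomes, BLAST control) is out of scope, as
  are localisation prediction, domain databases and tree building.
* The screen counts proteins, not domains; tandem ALPH domains are only
  noted.
* Corpus-level numbers from real proteome releases depend on the pinned
  release; the package documents the screen, not a frozen corpus.
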