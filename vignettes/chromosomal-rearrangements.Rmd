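---
title: "Inferring chromosomal rearrangement histories from comparative genetic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromosomal rearrangement histories from comparative genetic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkaryo)
```

## The model

`synkaryo` analyses chromosomal evolution in a clade from genetic (linkage)
maps that share single-copy orthologous markers. The observable is marker
*order*: centimorgan distances reflect recombination, differ in scale
between crosses, and are never compared across species here. One species —
in the packaged Solanaceae data, tomato, the most densely mapped — serves
as the common reference, and every other map is projected onto it: each
shared marker receives the reference chromosome and the 1-based order index
("rank") of its ortholog. Two kinds of event are then read off the
projection:

* **Translocations.** A query chromosome whose shared markers are painted
  by two or more reference chromosomes is split into segments (`E4a`,
  `E4b`, ... in top-to-bottom map order) at each colour change. The
  breakpoint region of a junction is the open interval between the two
  adjacent mapped markers that span it — on the query map a named marker
  pair, on the reference axis a *gap interval* (gap `g` lies between the
  markers of rank `g` and `g + 1`). The pattern X / Y / X with the two X
  segments rank-contiguous is recognised as an *insertional* (embedded)
  translocation and counted as one event; a pair of junctions on two
  chromosomes exchanging complementary spans of the same two reference
  chromosomes is counted as one *reciprocal* event.

* **Inversions.** Within one segment, shared-marker ranks in query order
  are decomposed into maximal strictly monotone runs; each maximal
  decreasing run whose rank set is contiguous is one inversion, with
  breakpoint gap intervals just outside the block. Because marker order on
  a map is unsigned, one physical inversion has two complementary
  descriptions (invert block B, or flip the whole segment and invert its
  complement); both readings are decomposed and the more parsimonious one
  is kept, with ties going to the unflipped reading. When reversing the
  detected runs does not restore reference order, the residual span is
  emitted as a single event annotated `k+`: `k = max(1, ceiling(b/2))`
  where `b` counts residual breakpoints, the classic lower bound on the
  number of reversals. Nested scenarios are deliberately *not* resolved
  into a minimal reversal series — the method reports what the marker
  order proves, not an optimal scenario.

## Timing events on the dated tree

Each event, observed as a difference between some species and the
reference, is a two-state character on the fixed dated phylogeny: every
species either *carries* the event, demonstrably shows the *reference
order* in the event's region, or is *uninformative* there (region
translocated, scrambled by other events, or too sparsely mapped). Timing is
strict parsimony: a set of branches explains the pattern if flipping the
state once per branch reproduces every informative tip;
`minimal_change_edge_sets()` enumerates all minimal explanations.

Three consequences matter:

* the reference is not privileged — if every informative species carries
  "the event relative to the reference", the single-change explanation is
  the reference's own terminal branch, and that is what is reported;
* when exactly one branch explains the pattern the event is determined;
  equally parsimonious single branches become a *candidate set*
  (`outgroup_uninformative`) with no tie-breaking, and such events flow
  into count *ranges* (minimum excludes them, maximum includes them) —
  they are never silently dropped;
* a pattern needing two or more changes is reported as that many
  independent events.

The packaged Solanaceae observations encode each species' state per event
exactly as the multi-species narrative uses it. In particular the most
distant species is uninformative for inversions in most regions (too many
sequential rearrangements have shuffled its marker order) but informative
for translocations; the packaged table scores it per event rather than by
a blanket rule, and the detection pipeline exposes the region-level
informativeness test (at least two of the event's own markers, inside one
intact segment, outside any of the species' own inverted blocks, standing
in the segment's reference direction).

## Ancestral karyotypes

Internal nodes are reconstructed tip-ward to root-ward, chromosome by
chromosome (chromosomes are named by their reference orthologs). The two
daughter lineages are compared on their common markers: agreement means
both preserve the ancestral arrangement; disagreement is arbitrated by the
nearest outgroup that matches exactly one daughter. Arrangements are
block structures — maximal runs of same-painted markers in canonical
orientation with their neighbouring markers recorded by identity, not just
by paint: two independent insertions of different markers at the same spot
must not masquerade as a shared arrangement. With no decisive outgroup the
chromosome is `partially_resolved` when the daughters still agree on
within-segment marker order (translocation organisation undecidable), else
`unknown`. A node with no species outside it (the root of the sampled
tree) is refused outright: polarity would require a more distant species.
A reconstructed node is represented by the extant arrangement that matches
it, which is how later (root-ward) nodes can reuse it.

## Rates and breakpoint reuse

Per-branch counts divided by branch durations (million years, from the
node ages) give rates; undetermined events propagate to `[min, max]`
ranges, and printed rates are rounded to one decimal, half away from zero.
The per-chromosome normalisation divides by the clade's constant
chromosome number (12 by default). Breakpoint reuse screens independent
translocation events per reference chromosome: pairwise intersection of
breakpoint gap intervals, closed transitively, with groups requiring at
least two distinct lineages; the shared region narrows to the intersection
and is tested for centromere proximity (within one marker gap of the
centromere's flanking interval, by default — the window is exposed because
"near the centromere" is a convention, not a measurement).

Because the original per-species figures are not machine-readable, the
packaged breakpoint and centromere tables use *synthetic ranks* on a
uniform 20-marker reference scaffold, constructed to satisfy every
overlap and proximity relation the observations state. Tests assert those
relations (six groups, five centromere-proximal), not the invented
coordinates.

## The simulator and what a green test establishes

`simulate_history()` evolves a root genome of 12 chromosomes along the
dated tree: per branch, `Poisson(rate x duration)` inversions and
translocations in random interleaved order. Defaults are the estimates the
Solanaceae analysis itself produces — 0.5 inversions/MY and 0.3
translocations/MY per lineage, 40 markers per chromosome, 20% per-species
marker dropout applied after evolution (each species maps a different
marker subset), reciprocal and insertional translocations in equal
proportion, inserted blocks reversed half the time, inversion blocks
uniform over rank intervals with a 2-marker minimum. Breakpoints fall in
marker gaps, never through markers — mirroring the resolution limit of
map data. An optional hotspot model concentrates breakage on chosen gap
positions, emulating fragile sites; a property test checks that it
produces strictly more positional reuse than the uniform model. cM
positions are cumulative uniform gaps; chromosome number never changes (no
fissions or fusions, matching the clade's conserved karyotype number).

The recorded true history (every event with its cut positions and
flanking markers, every internal-node genome, every species' retained
marker set) is the oracle. `evaluate_inference()` scores the full pipeline
against it:

* *recall* — a true event counts as recovered if a detected event of the
  same kind intersects it in at least one species where it is visible
  against the reference;
* *breakpoint containment* — asserted for cleanly detected events in
  regions the reference itself has not reshuffled (elsewhere the
  single-event claim is not well-posed);
* *branch assignment accuracy* — measured over events with an informative
  outgroup, operationalised as: the event is cleanly observable in every
  species where it is visible (or physically invisible there after
  dropout), and its observation cluster is not a merger of several events
  with coinciding breakpoint regions. Events failing these conditions are
  exactly the ones the method itself reports as undetermined or cannot
  distinguish — breakpoint coincidence fooling the comparison rules is a
  documented limit of the approach, not an implementation defect;
* *ancestral accuracy* — every `resolved` chromosome must equal the true
  ancestral genome's arrangement on the compared marker set. This is
  asserted without exception for chromosomes whose inversions do not
  overlap across branches; where two inversions on different branches hit
  the same region, a later event can exactly undo an earlier one on the
  surviving marker subset, and then *every* outgroup honestly witnesses
  the wrong ancestral order — homoplasy that no parsimony method can see
  through. Such chromosomes are held to an aggregate floor (98% of
  resolved chromosomes correct) rather than to the exact claim; this is
  the reconstruction-level face of the "informative outgroup" premise.
  Relatedly, when a disagreement between daughters is settled by an
  outgroup, the resolved arrangement is asserted only on the markers that
  outgroup actually shares — the corroborated subset — never on the
  daughters' full common marker set.

A green simulation suite therefore establishes that the implementation
recovers what the data can express: single events in regions with
surviving markers, correct polarity wherever some outgroup genuinely
witnesses the ancestral state, and ancestors exactly where parsimony is
sound. It does **not** establish robustness to features real maps have
and the simulator lacks: genotyping and ordering errors (beyond the
low-confidence flag), locally varying marker density, missing chromosomes,
paralogy masquerading as orthology, or lineage-specific marker loss.

## Numerical choices and conventions

* Co-segregating markers (tied cM positions) are ordered by marker id —
  their true order is unknowable from a genetic map; the convention is
  deterministic and documented.
* Segments need `min_run = 2` markers; single stray markers are treated as
  potential mapping noise and excluded from events (runs of the same paint
  merge across a stray).
* Inversions need 3 markers for a `high`-confidence call; two-marker flips
  are reported but flagged `uncertain`, being indistinguishable from local
  mapping error. A wholly reversed segment counts as one inversion only
  with 3 or more markers.
* Two detected inversions in different species are the *same* event only
  if both breakpoint intervals intersect their counterparts; overlapping
  spans with a differing breakpoint are independent events. Translocation
  breakpoints sharing one intersecting interval are possibly shared, and
  the region narrows to the intersection.
* Seeds: one integer seed reproduces an entire simulated dataset
  bit-exactly; all stochastic tests fix their seeds.

## Known limitations

* Counts are event *observations*, not minimal rearrangement scenarios;
  heavily reworked regions carry `k+` lower bounds and the true count may
  be higher.
* Timing resolution is bounded by the tree: events private to the species
  adjacent to the root are confounded with the root-adjacent internal
  branch (their candidate set names both).
* Breakpoint regions are only as narrow as the local marker density; two
  genuinely different breakpoints closer than one marker gap cannot be
  separated, which both enables the reuse analysis and limits it.
* The eggplant-lineage inversion count in the packaged data is likely
  inflated (and the ATE-or-pepper undetermined set likely deflated) by the
  distant species' uninformativeness — the count ranges carry exactly this
  uncertainty.
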