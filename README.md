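# synkaryo

Chromosomal rearrangement inference from multi-species genetic maps.

## The problem

Comparative linkage maps built on shared single-copy orthologous markers
(COSII-style) let us see how chromosomes have been reshuffled since a group
of species diverged: inverted marker blocks betray inversions, chromosomes
painted by two or more reference chromosomes betray translocations. For a
set of species on a dated phylogeny, `synkaryo` turns such maps into:

* **segments and breakpoint regions** — every non-reference chromosome is
  partitioned by reference-chromosome painting; each junction is a
  translocation breakpoint bracketed by the two adjacent mapped markers;
* **inversion events** — maximal reversed marker runs per segment, with
  flanking-marker breakpoint intervals and `k+` lower-bound annotations for
  unresolvable nests;
* **event timing** — two-state parsimony on the fixed dated tree decides on
  which branch each event happened. The reference species is *not*
  privileged: an "inversion relative to the reference" carried by every
  informative species is assigned to the reference's own terminal branch.
  When the distant outgroups cannot polarise an event, it is reported with
  a candidate branch set, never dropped;
* **ancestral karyotypes** — chromosome-by-chromosome reconstruction of
  internal-node genomes, with explicit `unknown` status where no outgroup
  settles the organisation;
* **rearrangement rates** — per-branch events per million years, with
  `[min, max]` ranges carrying the undetermined events;
* **breakpoint reuse** — independent translocations whose breakpoint
  intervals intersect on the reference, screened for centromere proximity
  (the fragile-breakage signature).

All interval logic is rank-based (marker order), never centimorgan-based:
cM scales are not comparable between species. A breakpoint region is the
open interval between the two adjacent mapped markers that flank a
junction; its resolution is limited by marker density.

The package ships two data worlds:

1. a packaged transcription of the classic Solanaceae five-species
   comparison (tomato, potato, eggplant, pepper, *Nicotiana*; ancestors
   ATPt 7.3, ATE 15.5, ATP 19.6, ATN 23.7 MYA), and
2. a seeded simulator of marker-map evolution (Poisson inversions and
   translocations per branch, per-species marker dropout) whose recorded
   true history is the oracle for every inference step.

## Worked example

The packaged observations through the timing and rate machinery:

```r
library(synkaryo)

phy <- solanaceae_phylogeny()
obs <- solanaceae_observations()
asg <- assign_lineages(obs, phy, reference = "tomato")
counts <- count_events_by_branch(asg, phy)
inv <- counts[counts$kind == "inversion", ]
inv[inv$count_max > 0, c("branch", "count_min", "count_max")]
#>     branch count_min count_max
#>        ATE         1        12
#>       ATPt         4         4
#>     tomato         4         4
#>     potato         2         2
#>   eggplant        16        16
#>     pepper         1        12

undetermined_between(asg, c("ATE", "pepper"))
#> [1] 11
```

Four inversions on the tomato branch, two on potato, four on the
tomato-potato ancestor's branch, sixteen on eggplant, one each definitely
on the ATE and pepper branches — and eleven that parsimony can only place
on *either* the ATE or the pepper branch, because the most distant species
is uninformative for inversions. Rates divide these counts by branch
durations:

```r
r <- estimate_rates(inv, phy)
r[r$branch %in% c("tomato", "potato", "eggplant", "pepper"),
  c("branch", "duration_MY", "rate_min_rounded", "rate_max_rounded")]
#>     branch duration_MY rate_min_rounded rate_max_rounded
#>     tomato         7.3              0.5              0.5
#>     potato         7.3              0.3              0.3
#>   eggplant        15.5              1.0              1.0
#>     pepper        19.6              0.1              0.6
```

Breakpoint reuse on the packaged translocation intervals:

```r
g <- detect_breakpoint_reuse(solanaceae_breakpoints(),
                             solanaceae_centromeres(),
                             solanaceae_reference_map())
g[, c("ref_chromosome", "n_members", "centromere_proximal")]
#>   ref_chromosome n_members centromere_proximal
#>            T11          3                TRUE
#>            T12          3                TRUE
#>             T3          2               FALSE
#>             T4          2                TRUE
#>             T5          3                TRUE
#>             T9          2                TRUE
```

Six independent-breakpoint groups; five sit at the centromere.

Map-level detection, from the packaged miniature example (a chromosome
combining two reference chromosomes, with an inversion and a named
breakpoint marker pair):

```r
tom <- read_genetic_map(system.file("extdata", "example_tomato.tsv",
                                    package = "synkaryo"))
egg <- read_genetic_map(system.file("extdata", "example_eggplant.tsv",
                                    package = "synkaryo"))
orth <- read_orthology_table(system.file("extdata", "example_orthology.tsv",
                                         package = "synkaryo"))
seg <- partition_segments(project_onto_reference(egg, tom, orth))
seg$segments[, c("segment_id", "ref_chromosome", "first_marker", "last_marker")]
#>   segment_id ref_chromosome first_marker last_marker
#>          E4a            T10           b1       TG386
#>          E4b             T4         T677          a5
seg$junctions[, c("left_marker", "right_marker")]
#>   left_marker right_marker
#>         TG386         T677
```

And a full simulation round-trip:

```r
sim <- simulate_history(simulation_params(), seed = 42)  # 12 chr x 40 markers
ev <- evaluate_inference(sim)   # detection + timing + reconstruction vs truth
ev
#> Simulation evaluation:
#>   recall: 0.931 (79 events)
#>   ...
```

## Command line

```sh
exec/synkaryo fixture  --out fixture_dir
exec/synkaryo time     --observations fixture_dir/solanaceae_observations.tsv \
                       --tree fixture_dir/solanaceae_tree.nwk \
                       --config fixture_dir/solanaceae_config.json --out out_dir
exec/synkaryo simulate --seed 42 --out sim_dir
```

## Documentation

The methods vignette (`vignettes/chromosomal-rearrangements.Rmd`) describes
the comparison rules, the parsimony model and its assumptions, the
simulator's stated world, numerical conventions, and known limitations.
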