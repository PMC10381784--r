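---
title: "Detecting conserved G-quadruplex motifs in promoter sets and testing their loop variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved G-quadruplex motifs in promoter sets and testing their loop variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4cons)
```

## The problem

Guanine-rich DNA can fold into G-quadruplexes (G4s), four-stranded
structures built from stacked G-tetrads. G4-forming sequences (G4 motifs)
concentrate in promoters, where they can modulate transcription and
interfere with DNA repair, and their presence has been linked to elevated
local mutation rates. `g4cons` implements a complete pipeline for asking,
over a set of homologous promoter sequences from related species: where are
the G4 motifs, which of them are evolutionarily conserved, and do their
loop sequences accumulate more substitutions than comparable motif-free
sequence?

The pipeline operates on 1000-bp promoter fragments, one per species,
given on the coding strand with the last position abutting the
transcription start site (TSS). Its stages are:

1. **Scanning** (`scan_promoter()`, `scan_set()`) — constrained pattern
   matching on both strands.
2. **Block alignment** (`build_blocks()`) — reliable local multiple
   alignments of promoter fragments within one order.
3. **Clustering** (`cluster_blocks()`, `find_clusters()`) — motifs of two
   or more species whose alignment-column intervals mutually intersect.
4. **Conserved-group calling** (`call_groups()`) — clusters whose members'
   four G-tracts can be placed on identical alignment columns.
5. **Substitution analysis** (`count_loop_substitutions()`,
   `select_control()`, `run_order_test()`) — consensus-based substitution
   densities in loops versus matched motif-free controls, compared with a
   one-sided paired Wilcoxon signed-rank test and Holm–Bonferroni
   correction across orders.
6. **Simulation** (`sim_config()`, `generate_order()`) — a
   promoter-evolution generator with complete ground truth that stands in
   for downloaded genome data in all tests.

## The motif model

A G4 motif is four G-tracts of at least three consecutive guanines
separated by three loops of 1–30 nt, with three constraints: the total
span may not exceed 45 nt; every tract must fit inside the 45-nt window
anchored at the first tract's start; and tracts are strictly ordered
without overlap. `N` never counts as G (it breaks a tract), while loops
may contain any symbol. Motifs on the noncoding strand are detected on the
reverse complement and reported in coding-strand coordinates, where their
tracts appear as C-tracts.

Candidate tracts are drawn from maximal G-runs: a run of length three is
one placement; a longer run contributes the whole run plus every length-3
sub-run. This preserves, for the downstream conservation step, the freedom
to shift a tract inside a longer run — different species may "use"
different guanines of the same run.

Overlapping candidates are reduced to a non-overlapping set greedily by a
fully specified score,

```
score = 10 * min(tract lengths, capped at 5)
        - population variance of the three loop lengths
        - (total length - 15) / 2
```

with ties broken by smaller start, shorter total length, then the
lexicographic concatenation of loop sequences. The score reproduces the
documented preferences of pattern-based G4 scanners (longer minimum
tracts, short and equal loops, compact motifs) while being exactly
reproducible; an exhaustive-enumeration oracle pins the scanner's
behaviour in the test suite.

Each motif is assigned a TSS-distance zone from its TSS-proximal edge:
core (0–180), proximal (181–500), distal (501 and beyond).

## Reliable alignment blocks

Conservation judgements need a common coordinate system. A *block* is a
local multiple alignment of fragments from two or more species with at
least 80% identical columns over at least 100 columns, locally maximal
(no single-column extension keeps it passing). A column is identical only
when every row carries the same A/C/G/T symbol — any gap or `N`
disqualifies it, the strictest reading of "identical columns". Blocks are
named `h{fragments}x{width}`.

Block construction is deliberately a transparent stand-in for pangenome
alignment tools: shared unique 12-mers anchor promoter pairs; colinear
anchors are chained (diagonal deviation ≤ 50); chains sharing promoter
intervals are grouped into proto-blocks; fragments are aligned by
center-star progressive alignment over pairwise global alignments
(match +1, mismatch −1, gap −2), with a gap-free fast path when an
ungapped stacking of equally long fragments already meets the identity
threshold. All maximal qualifying column windows are then extracted
(recursively taking the widest qualifying window and greedily extending
each seed column-by-column), so multiple — possibly overlapping — blocks
can come from one aligned region. Pre-computed blocks in the aligned-FASTA
dialect (`>SPECIESCODE/start-end`) can be imported with `read_blocks()`
and used in place of built ones; height-maximality rests on the anchor
stage, which recruits every promoter sharing a colinear anchor chain with
a block member.

A consequence of the strict identity rule worth stating explicitly:
under a star phylogeny where each of `n` species independently accumulates
substitutions at per-site rate `r`, the expected identical-column fraction
is `(1 - r)^n`. Reliable blocks therefore only exist when
`(1 - r)^n` is comfortably above 0.8 — e.g. 20 species at 0.5%
divergence (0.905), or 3 species at 5% (0.857), but *not* 10 species at
5% (0.599). Experiment designs in the tests respect this arithmetic.

## Clusters and conserved groups

Motif coordinates are projected into block columns through each fragment's
gap structure (`map_motif_to_columns()`); motifs sticking out of a
fragment are flagged partial. Within one block and strand, clusters are
maximal sets of intervals from two or more species sharing a common column
window of at least `min_intersection` columns (default 12 — the minimal
guaranteed shared content of two motifs, four tracts × 3 G). For 1-D
intervals a common window certifies pairwise intersection, so clusters are
found by sweeping candidate windows; each interval joins at most one
cluster (largest common window first), and two motifs of the same species
never share a cluster.

A cluster becomes a *conserved group* when its members' four tracts can be
placed on identical alignment columns. For every member species, all
placements compatible with the scanner's constraints are enumerated from
the letter-runs of its ungapped row near the cluster window, including
length-3 shifts within longer runs; the tract-column 4-tuple realizable by
the most species wins. Ties prefer, in order: larger overlap with the
cluster's common window (anchoring the group to the motifs that formed the
cluster, rather than to incidental nearby runs), more total tract columns
(preferring whole runs over minimal sub-runs), smaller first column, then
a lexicographic signature. Groups need at least two members; species of
the block without a feasible placement are kept attached as non-member
rows. A group's zone is the modal zone of its members (ties toward the
TSS).

Loop columns are the inter-tract columns, *minus* edge columns in which
every member still carries the tract letter: such columns belong to the
conserved run (a conserved tract may have "three or more" guanines), and
counting them as loop would dilute loop substitution densities with
positions that cannot vary among members by definition.

## Substitutions, controls, and the test

Within a group, every loop column is compared against the member
consensus (most frequent A/C/G/T, ties to the alphabetically first base);
every differing member base is one substitution record. Gaps and `N` are
neither consensus nor substitutions, but gap columns still count toward
loop length, keeping the density denominator equal to the fixed per-group
loop length that controls are matched to. Member tract columns carry no
substitutions by construction — this invariant is re-checked in the tests.
Disruptive tract substitutions are instead read off the attached
non-member rows against the tract letter (G, or C for noncoding-strand
groups), labelled as unordered pairs in coding-strand orientation
(`C<->T` and `G<->A` spectra separate cleanly by strand).

Each group's control is a sub-alignment over exactly the member species
with total column length equal to the group's loop length, intersecting no
predicted motif of any species mapped into the block, with no gap run of 3
or more columns in any member row. The search is deterministic: windows
adjacent to the group scanned outward one column at a time, upstream
first, then downstream, then other blocks containing all members
(left-to-right), and finally a two-segment split around the group. Groups
without any eligible control are excluded from the test and reported.

Per order, loop and control densities form matched pairs; the
alternative hypothesis is one-sided (loop density greater). Zero
differences are dropped; with at most 25 informative pairs and no tied
absolute differences the exact signed-rank null distribution is used,
otherwise the normal approximation with tie and continuity correction
(`stats::wilcox.test` supplies both branches; an exhaustive sign-pattern
enumeration verifies the exact branch in the tests). Holm–Bonferroni
adjustment is applied across the family of orders analysed in one run —
with five orders, a smallest raw p of 0.003947 becomes 0.019735, matching
the step-down arithmetic exactly.

## The simulator and what it does (not) show

`generate_order()` builds one ancestor per order: background bases from a
configurable composition, with `n_motifs` planted G4 motifs (tracts 3–5
nt, loops G-free on the motif strand, span ≤ 45) spaced across
equal-width slots. Each species then descends independently (star
phylogeny): substitutions at `background_rate` per site, loop positions at
`background_rate * loop_multiplier`, tract positions only through an
explicit per-motif disruption probability, plus optional short indels and
runs of N outside planted motifs. Every event is recorded, and replaying
the record reproduces each species exactly. Planted-motif flanks are kept
free of competing G/C runs (within 32 nt), so the planted coordinates are
identifiable ground truth; without this, an adjacent background run can
support an equally valid conserved-motif variant and no recovery metric is
well-defined.

Design choices, made once:

* **Star phylogeny** rather than a tree: the analysis counts differences
  from a consensus, not lineage-polarised mutations, so independence
  across species suffices for calibration and keeps ground truth simple.
  The cost is that per-species rates must be interpreted as divergence
  from the consensus ancestor, not as pairwise distances.
* **Default conditions**: 20 species of 1000 bp with 6 planted motifs at
  0.5% background divergence — the regime in which many-fragment blocks
  pass the 80% rule, matching the block structure the analysis assumes.
* **Calibration experiments** (used by the acceptance checks): 8 species,
  1600 bp, 20 planted motifs, 2% divergence, loop multiplier 1 (null) or
  2 (alternative). Twenty groups give the signed-rank test a reasonably
  continuous null; a priori power arithmetic (loop substitution counts
  roughly Poisson with mean ~1.9 vs ~3.8 per pair) puts power well above
  80% at the doubled rate. Recovery is measured at zero noise (10
  species) and at 5% divergence with intact tracts — with 3 species, per
  the identity arithmetic above. 500 null and 200 alternative replicates
  keep Monte-Carlo error on the type-I estimate near one percentage
  point.

What passing these simulations does *not* show about real data: the
generator has no tree-shaped correlation between species, no selection, no
CpG or TF-site promoter grammar, uniform base composition away from
planted motifs, and clean 1000-bp orthologous fragments with no assembly
error. Results on real promoter sets additionally depend on the upstream
orthology and TSS assignments, which are out of scope here.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive everywhere; the promoter's last
  position abuts the TSS, and `tss_distance` uses the motif's TSS-proximal
  edge (distance 0 is zone core).
* Consensus ties go to the alphabetically smallest base; all-gap columns
  have no consensus and contribute nothing.
* Empty inputs return empty, typed results (empty motif tables, empty
  block lists, all-zero summary tables); an all-zero difference vector
  yields a `none` test result rather than an error.
* A group whose trimmed loops are empty cannot form a density pair and is
  excluded like a control-less group.
* All stages are deterministic given input order and seeds; reruns are
  byte-identical, which the tests assert.

## Worked example

```{r example}
cfg <- sim_config(n_species = 8, promoter_length = 1000, n_motifs = 5,
                  background_rate = 0.02, loop_multiplier = 2, seed = 7)
sim <- generate_order(cfg)
res <- run_order_analysis(sim$set)
res$zone_table[, c("order_code", "total_coding", "total_noncoding",
                   "n_no_motifs")]
length(res$groups)
res$test[c("n_pairs", "p_raw", "method", "n_loop_exceeds_control")]
```

The scripts under `analysis/` run this workflow over five simulated
orders sized like the five well-sampled mammalian orders (14–27 species)
and write every table the pipeline defines under `results/analysis/`.

## Known limitations

* Block building is a specified stand-in, not a re-implementation of a
  pangenome aligner; imported blocks are validated under this package's
  strict identity definition and may be flagged near-miss rather than
  rejected.
* Group calling implements the stated membership-maximisation objective
  algorithmically; an expert curator with the same objective could still
  differ on ties not covered by the documented tie-breaks.
* The substitution analysis counts differences from consensus; it does
  not polarise mutations on a phylogeny.
* With few informative pairs (small orders) the exact signed-rank test is
  discrete and conservative; order-level conclusions need tens of groups.
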