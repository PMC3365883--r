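---
title: "Methods: COI barcode identification of predator and prey from stomach contents"
author: "barcodediet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI barcode identification of predator and prey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stomach contents of a predatory reef fish are mostly unidentifiable by
eye: digestion leaves tissue plugs, skeleton fragments, and the
occasional intact juvenile. A ~658 bp fragment of the mitochondrial
cytochrome c oxidase I gene (the COI barcode) amplified from each prey
item can still identify it, provided (i) the fragment survives quality
control, (ii) it can be matched against a reference library of barcodes
of known species, and (iii) something sensible is done when the true
species is absent from that library — the routine situation for
invertebrate prey. This package implements that workflow end to end,
together with the diet statistics computed from the resulting
assignments and a simulator that generates data with the same
statistical structure for validation.

## Quality control of degraded fragments

Three gates are applied per fragment (`qc_sequence()`):

* **Length** — fragments shorter than 100 bp are rejected. Mini-barcodes
  down to about 100 bp still identify species with high efficiency;
  below that the information content collapses. Default `min_len = 100`.
* **Ambiguity** — at most 2% of bases may be IUPAC ambiguity codes
  (`max_ambiguous = 0.02`). The survey data this emulates report no
  ambiguity statistics, so the default is conservative barcode-community
  practice and configurable.
* **Reading frame** — the frame (1–3) minimising internal stop codons is
  selected under a mitochondrial genetic code (vertebrate by default,
  invertebrate selectable for crustacean work); any stop codon in the
  best frame flags a likely pseudogene or artefactual read. Frame
  selection is done by stop minimisation rather than by alignment to a
  reference because the most interesting queries (dark taxa) may have no
  close reference. Codons containing ambiguous bases and the trailing
  partial codon are ignored.

Indels cannot be observed in a single unaligned sequence; they surface
later as gap openings inside the aligned overlap, which the distance
layer counts and reports as a diagnostic rather than an automatic
rejection (clean COI data are expected to show none).

## Alignment and distances

Fragments are aligned to full-length references with a semi-global
(free end-gap) affine-gap alignment (match 1, mismatch −1, gap open 10,
gap extend 1): terminal overhangs are free, so a fragment aligns to its
containing region at no cost. The dynamic program is a standard Gotoh
three-state recursion implemented in C++ with deterministic tie-breaking
(diagonal over up over left). Batch comparisons first locate the
diagonal best supported by shared 8-mers and align within a ±24 band
around it — exact whenever the optimal alignment stays in the band,
which for indel-free barcode data is the ungapped diagonal itself — and
fall back to the full dynamic program when seeding fails (fewer than 4
supporting 8-mers) or when the banded solution contains a gap. The
banded path is verified against the full program in the test suite.

Distances over the aligned overlap use pairwise deletion: a site
contributes only if both sequences carry an unambiguous base there.
Two quantities are reported per pair:

* **percent similarity**, `100 (1 − p)` with `p` the proportion of
  mismatching sites (this is what reference-database match lists print),
  and
* the **Kimura two-parameter distance**
  `d = −½ ln((1 − 2P − Q) √(1 − 2Q))`, with `P` and `Q` the transition
  and transversion proportions. When the argument of the logarithm is
  non-positive the pair is saturated and `d` is reported as `Inf`
  rather than clamped, so downstream tree building is told the truth;
  such pairs arise only between dark taxa and very distant references.

The 3% species rule is applied to the K2P distance (×100), matching the
divergence statistic the rule was formulated for; similarity is reported
alongside because match tables print it. At these scales the two differ
by far less than the decision margin.

## Identification

For each QC-passed query (`assign_query()`):

1. Rank all references by similarity (ties by K2P, then id).
2. If any reference lies within the 3% K2P band, assign at species rank
   — capped at the finest rank on which **all** in-band references
   agree with non-empty labels. A genus-only reference therefore yields
   a genus-level call, and in-band species disagreement degrades the
   call to genus (or coarser), mirroring the conservative behaviour of
   public ID engines.
3. Otherwise fall back to the tree-based **strict criterion**: build a
   neighbor-joining tree of the references plus the query from K2P
   distances, root it at the midpoint of the longest
   reference-to-reference path, take the smallest clade containing the
   query and at least one reference, and assign the finest rank at
   which every reference in that clade carries one identical label.
4. If no rank is unanimous, the query is left unassigned.

Two design choices deserve comment.

* **Strict-tree calls are capped at genus.** Step 3 is only reached when
  no reference is within 3% — a species-level claim there would
  contradict the species rule itself, so the clade unanimity search
  starts at genus. `strict_criterion()` as a standalone function still
  supports species-rank unanimity for direct use.
* **One tree per unresolved query, not one joint tree.** Queries must
  be transparent to each other (prey fragments should not cross-validate
  each other). Building the NJ tree per query over all usable references
  satisfies transparency exactly, reuses the query–reference distances
  already computed for ranking, and avoids an awkward failure mode of a
  joint tree: two short fragments cut from opposite ends of the barcode
  share no aligned sites, so their pairwise distance is undefined.
  References with saturated (infinite) distance to the query are dropped
  from that query's tree.

Neighbor joining itself is the classic Q-criterion algorithm with
branch lengths from the two-point formulas, negative branch lengths
clamped to zero, and ties broken everywhere by lexicographic id so runs
are bit-reproducible. Midpoint rooting excludes query leaves when
locating the longest path so a divergent query cannot drag the root
toward itself.

**Known limitation.** When a query's entire genus (or family) is absent
from the reference library, the smallest-clade rule tends to attach the
query as sister to its nearest referenced relative and then assigns
that relative's genus (or family) — an over-resolved call whose
coarser ranks are still correct. This is the documented failure mode of
clade-nesting criteria under sparse reference sampling; with richer
reference libraries the query attaches deeper and receives the coarser
rank. Species-level safety is unaffected by the genus cap.

## Diet composition

`percent_n()` computes percent composition by number with explicit
denominator scopes, reproducing the reporting conventions of diet
surveys: class-level %N over all prey items; fish family and species %N
over fish items only; crustacean order %N over crustacean items only.
Only this combination reproduces every published percentage from the
bundled survey tables simultaneously (125 fish + 43 crustacean items).
Richness counts a genus-only record (e.g. an unmatched *Astrapogon*) as
one additional species-equivalent taxon, which is how the survey reaches
34 prey "species" from 33 named ones. New-record flagging compares
species-rank assignments against a prior regional checklist;
genus-level records are never flagged. Base-composition summaries
(per-base percentages, GC overall and per codon position, min / mean /
max / SE with SE = sd/√n) exclude ambiguous bases from denominators.

The published crustacean order percentages 93 / 4.6 / 2.4 are mutually
inconsistent with their own counts (40, 2, 1 of 43 give 93.0, 4.65,
2.33; the trailing figures appear forced to sum to 100). The package
reports the count-derived values.

## The simulator

`simulate_reference_library()` evolves one random in-frame coding
ancestor down a balanced, ultrametric four-rank taxonomy under a K80
substitution process — the same two-rate model the K2P estimator
assumes, which makes divergence recovery a sharp test. Expected
pairwise divergences are controlled per rank: `intraspecific_div`
between conspecific haplotypes (default 0.5%), `interspecific_div`
between congeners (default 5%), multiplied by `deeper_div` (default 2)
per coarser rank. Substitutions creating an in-frame stop codon are
redrawn; no indels are ever introduced, matching clean COI data.
Defaults: 5 orders × 2 families × 2 genera × 2 species × 2 haplotypes
(40 species), 658 bp, transition/transversion ratio κ = 3 (a typical
fish-COI value).

`simulate_queries()` cuts fragments from library haplotypes with the
observed read-length mixture — 85% at 600+ bp, 13% at 300–500 bp, 2%
at 100–199 bp — uniform start positions, and stop-preserving point
substitutions at `query_error_rate` (default 0.5%; the degradation rate
of digested tissue is not quantified anywhere, so this is the
simulator's one free parameter). A fraction of queries (default 9.5%,
the survey's cannibalism rate) comes from the predator species itself,
and a fraction (default 25.6%, the survey's crustacean share) from
"dark" species withheld from the reference library.
`choose_withheld_species()` withholds at three depths — lone species
with a referenced congener, whole genera, whole families — skewed deep,
so simulated dark queries span the 79–96% similarity band that real
unreferenced invertebrate prey show.

What the simulator does **not** emulate: indels and chimeras, quality
scores, PCR/primer bias, heterogeneous rates across sites or lineages,
non-ultrametric taxonomy structure, and real nucleotide composition
(the ancestor is uniform-random subject to stop-codon screening, so
GC statistics of simulated panels are near 50% rather than the ~46.7%
of real fish COI). Passing tests therefore demonstrate correctness of
the algorithms under the model's assumptions, not robustness to every
artefact of real amplicon data.

## Numerical choices and problem sizes

Tie-breaks (alignment traceback, NJ joins, midpoint path, hit ranking)
are all deterministic, so any run is reproducible from its seed.
Saturated distances propagate as `Inf` and are excluded from tree
building per query. Percentages are kept at full precision internally
and rounded only for display (1 decimal for %N, 2 for similarity).

Validation sizes used by the bundled analyses and tests: libraries of
16–100 sequences, 1000 queries for the recovery study (99%+ species
recovery among referenced species; dark queries at coarser ranks), 30
conspecific barcodes at 0.054% expected divergence for the
intraspecific check, and NJ recovery on additive matrices up to 12
taxa, verified against quartet four-point enumeration and an
independent implementation.
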