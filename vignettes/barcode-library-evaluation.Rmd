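---
title: "Evaluating multi-marker DNA barcode reference libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-marker DNA barcode reference libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

A DNA barcode reference library for a local flora pairs voucher specimens
(with expert morphological identifications) with short standardized gene
regions — for land plants typically the chloroplast coding markers *rbcL*
and *matK* plus the nuclear ribosomal spacer ITS2.  Before such a library
can serve identification, two questions must be answered quantitatively:

1. **Resolution** — which species can the markers actually tell apart, alone
   and in combination?
2. **Reliability** — which sequences in the library are untrustworthy
   (pseudogenes, fungal/algal contaminants, paralogous ITS2 copies,
   misidentified vouchers)?

`barcodeval` implements both analyses over pre-aligned per-marker FASTA
files plus a specimen-metadata table, and ships a seeded synthetic-library
generator with planted anomalies so that every stage can be validated
against known ground truth without any external data.

## The species-resolution criterion

A species $s$ with specimen set $M_s$ in a character matrix is **resolved**
when both of the following hold on the maximum-parsimony (MP) consensus
tree:

* **monophyly** — some edge of the (possibly multifurcating) unrooted tree
  induces exactly the bipartition $M_s \mid \bar M_s$; singletons and
  complements of singletons are trivially monophyletic;
* **diagnosability** — at least one alignment column exists where every
  member of $M_s$ carries the same single unambiguous base and *no other
  specimen in the matrix* carries that base.

Both conditions are deliberately conservative.  A singleton species still
needs a diagnostic column (otherwise every rare species would trivially
"resolve").  A missing or ambiguous cell in a *member* disqualifies a
column, while missing/ambiguous cells in non-members do not block it —
being generous with missing data only on the side that cannot create false
diagnosability.  Comparison against *all* other specimens (not only
congeners) is the default; a congener-only mode is available via
`species_resolution(..., congener_only = TRUE)`.

Because many genera in northern floras are represented by a single species,
the summary separates **polytypic** genera (true species-level resolution,
"congeners") from **monotypic** genera (effectively generic-level
resolution), while the overall percentage includes both.

## Supermatrix construction

`concatenate()` builds a partitioned supermatrix over a user-declared
marker order (default `rbcL, matK, ITS2`).  Partition coordinates are
0-based half-open internally and exported 1-based inclusive in the common
RAxML dialect.  Missing partitions are filled with `'?'` rather than
`'-'` so that "no data" and "alignment gap" remain distinguishable at file
level, although both are treated as missing states by the parsimony engine.

Three inclusion rules are built in.  The combined-analysis default
(`"paper"`) admits a specimen when it has the nuclear marker plus at least
one chloroplast marker; for marker combinations that span only one genome
it degrades to "any marker of the combination".  Whether combined matrices
should additionally require *matK* is genuinely ambiguous in practice, so
`"all_markers"` is provided as the strict alternative; the default follows
the more inclusive reading.

## Distances and MPD tables

`pairwise_distance()` and `mpd_by_family()` use pairwise deletion with a
strict comparability rule: a column counts for a pair only when **both**
sequences carry a plain base there.  IUPAC ambiguity codes are excluded
entirely (no fractional matching); this keeps every statistic reproducible
by a trivial brute-force loop, which the test suite exploits.

The mean pairwise distance (MPD) for a family averages over *all*
within-family specimen pairs, inter- and intraspecific alike, and is
reported in percent with a dispersion $\sigma$ (the sample, $n-1$,
standard deviation over the pair distances; a single pair reports
$\sigma = 0$).  The p-distance is the default model; Kimura's
two-parameter distance is provided as well because barcoding convention
often reports K2P and the upstream data system leaves the model unstated —
reports label the model explicitly.

Cross-marker correlations use family MPD values as covariates: Pearson $r$
over shared families with a two-sided p-value from the Fisher
z-transform, $z = \operatorname{atanh}(r)\sqrt{n-3}$.  At least three
shared families are required.

## Maximum parsimony

Tree length is the Fitch parsimony score, computed in-package with cell
states as base sets: a plain base is a singleton, an IUPAC code its base
set, and `'-'`/`'?'` the full set \{A,C,G,T\}.  Gaps are *not* a fifth
state, because supermatrix missing-fill dominates the matrices and the
input alignments are assumed indel-curated.  Polytomies are scored by
sequential binary merging, which is exact for binary trees (including the
basal trifurcation of unrooted trees).

The search is the parsimony ratchet: seeded random-addition start trees,
SPR hill climbing (phangorn's Fitch/SPR engine drives the rearrangements),
then iterations that upweight a random 25% of columns by a factor of 2,
re-optimise, restore unit weights and re-optimise again.  Defaults (50
iterations, 25%, x2, 5 start trees) follow the original ratchet recipe;
SPR rather than TBR is a deliberate simplification adequate at reference-
library scale.  All distinct topologies attaining the global best length
are pooled (keyed by canonical bipartition sets), and on small matrices an
additional leaf-SPR sweep around the optimum collects equally parsimonious
neighbours.  Resolution is scored on the **strict consensus** of the
pooled optima — the conservative choice when the optimum is not unique.
Every random decision flows from one integer seed through named
substreams, so runs are exactly reproducible.

For validation, `exhaustive_search()` enumerates all unrooted topologies
(at most 9 leaves) with an independent recursive edge-insertion
enumerator; the test suite requires the ratchet to match its optimum on
30 random small matrices, and checks `fitch_length` against brute-force
minimisation over all internal state assignments.

## Quality-control flags

* **Pseudogenes** (`orf_check`): a coding sequence is flagged when its
  ungapped length differs from the modal ungapped length by a non-multiple
  of 3 (`pseudogene_frameshift`), or when its stated reading frame contains
  an internal stop codon (`pseudogene_stop`).  The frame defaults to the
  one minimising internal stops over the modal sequence; the modal-length
  reference is recomputed once after excluding stop-flagged rows.  The
  plastid and standard genetic codes share the TAA/TAG/TGA stop set, so the
  `genetic_code` switch is presently cosmetic but kept for clarity.
* **Contamination** (`contaminant_screen`): a k-mer containment classifier
  against user-supplied plant and contaminant reference sets (defaults
  k = 8, margin 0.1).  This is a deliberately simple, deterministic
  reference-based screen — adequate for the kingdom-level plant versus
  fungal/algal split the application needs, with no external database.
* **Clade conflict** is operationalised as nearest-neighbour distance
  conflict (`nn_conflict`): a specimen conflicts with its label for a
  marker when its nearest heterospecific specimen is *strictly* closer
  (p-distance, pairwise deletion) than its nearest conspecific; exact ties
  are concordant.  This rule is deterministic and trivially oracle-testable,
  and unlike tree-clade membership it is robust to consensus polytomies.
* **ITS2 paralogy** (`paralogy_flags`): nuclear conflict while *every*
  informative chloroplast marker is concordant (at least one required) —
  the nuclear copy disagrees with a plastid-plus-morphology species
  assignment.
* **Misidentification** (`misidentification_flags`): *every* informative
  marker conflicts and the implicated nearest-heterospecific species agrees
  across markers.  A single-marker case is still flagged, with the low
  support noted in the evidence.  The two rules are mutually exclusive by
  construction.

The pipeline (`run_pipeline`) excludes pseudogene- and contaminant-flagged
sequences before tree building (a `keep_flagged` override exists), then
computes the label-conflict flags on the cleaned data — the order matters,
since a contaminant ITS2 sequence would otherwise masquerade as paralogy.

## The synthetic-library generator

`simulate_library()` emulates the statistical structure the analyses
assume.  Defaults: 10 families, 1–5 genera each (about 30 genera), a 0.6
monotypic-genus fraction, 2 + Poisson(1) species in polytypic genera, 2–5
specimens per species, and three markers — rbcL (552 bp, coding, rate 1),
matK (800 bp, coding, rate 2.4), ITS2 (350 bp, non-coding, rate 7).  The
rate ordering reproduces the empirical within-family MPD ordering
rbcL < matK < ITS2.

Sequences evolve by exact Jukes–Cantor transition sampling (per-site
substitution probability $\frac34(1-e^{-4b/3})$ for branch length $b$)
along a grafted tree: family root → genus ancestor (branch 0.05
substitutions/site at rate 1) → a pure-birth species tree of depth 0.025
within each genus → a guaranteed private species stem (0.0125) → specimen
branches (0.001 each, i.e. 0.002 between conspecifics).  There are no
indels, so alignments are exact by construction.  Coding markers are kept
ORF-clean: roots are sampled codon-wise excluding stops, and any stop
codon arising along a branch is reverted to the ancestral codon — a
slight departure from i.i.d. JC that guarantees zero false ORF flags on
clean data (the JC calibration test therefore uses a non-coding marker).

**Diagnostic tags.**  Under pure JC at these depths the fast markers
saturate across a whole library, and a species can fail to carry any
column that is uniform within it and absent from every other specimen —
whereas the generator is meant to produce libraries whose clean-data
resolvability is *certain*, so that deviations measured downstream are
attributable to the pipeline or to planted anomalies, not to generator
luck.  The generator therefore adds a conserved diagnostic block: reserved
column $i$ of each marker is fixed to C library-wide, and species $i$
alone carries a G there.  This mirrors the real mechanism that makes
barcodes diagnostic — species-specific substitutions at otherwise
conserved positions — and is stop-safe for coding markers (no T can enter
those codons).  Set `diagnostic_tags = FALSE` to study raw JC behaviour.

**Planted anomalies** (`inject_anomalies`) are constrained so each is
unambiguously detectable and the planted sets stay disjoint:

* *introgression*: one genus (forced to 9 species) shares a single
  chloroplast haplotype, copied verbatim across all species except one
  divergent holdout — the classic willow pattern.  Chloroplast-only
  resolution within such a genus is exactly 1/9 by construction.
* *paralogy*: the ITS2 of one specimen per target species (≥ 3 nuclear
  records required) is replaced by a sequence evolved from another genus's
  ITS2 ancestor, leaving the chloroplast markers concordant.
* *pseudogene*: a single base is deleted from a coding sequence (columns
  shift, a terminal gap pads the row) — caught by the mod-3 length rule.
* *contamination*: an ITS2 row is replaced by a mutated copy of a
  synthetic contaminant reference; the generator also emits the plant and
  contaminant reference sets used by the screen.
* *misidentification*: species labels of specimens from different genera
  are rotated.  Target species need ≥ 3 specimens and their intraspecific
  variation is first collapsed to a single haplotype, so that the
  relabelled specimen conflicts on every marker while its true siblings
  retain a zero-distance conspecific and can never be false-flagged under
  the strict-inequality rule.  (Zero intraspecific plastid variation is
  also the empirically common case.)
* *herbarium dropout*: a seeded fraction of specimens (default 0.4) is
  marked herbarium and markers are removed with per-source failure
  probabilities calibrated to observed recovery rates — fresh
  0.05/0.17/0.11 and herbarium 0.15/0.47/0.12 for rbcL/matK/ITS2 — the
  herbarium rates increasing with amplicon length.  Outcomes are recorded
  in the recovery table.

`GroundTruth` records every planted anomaly once, plus
`expected_resolvable`: per-species diagnosability computed by an
independent, loop-based oracle (`oracle_resolvable`) on the post-exclusion
data — never by the pipeline under test.  On clean data the pipeline's
per-species resolution must equal this oracle exactly, which is asserted in
the acceptance tests.

## What the simulations do and do not show

Passing tests on synthetic libraries demonstrate that the implementation
is faithful to its stated rules and recovers planted structure exactly.
They do not show that real libraries behave this way: real data add
alignment error and indels, ITS2 concerted-evolution dynamics, rate
heterogeneity across sites and lineages, incomplete lineage sorting, and
far weaker diagnostic signal (real floras resolve at 50–70%, not 100%).
The generator makes no attempt to model those processes (no coalescent
discordance, no indels, JC only); it is a correctness instrument, not an
empirical emulator.

## Numerical choices and degenerate inputs

* Distances: pairs with zero comparable columns are `NA` (signalled, never
  silently 0) and are dropped from MPD means and dispersions; K2P is `NA`
  at saturation (non-positive log arguments).
* NN conflict ties are concordant — conservative against false flags.
* Strict consensus of a singleton set is the input tree; differing leaf
  sets are an error, not a pruned union.
* Empty MPD tables and strata with zero attempts are reported as absent,
  with warnings, rather than as zeros.
* Test and acceptance problem sizes are the package's choices: the default
  library (~30 genera, ~50 species, ~190 specimens, 1702 columns) with
  8–12 ratchet iterations and 2 start trees completes a combined analysis
  in well under a minute; exhaustive checks use ≤ 7 taxa where the full
  topology space (945 trees) is enumerable.

## Known limitations

* SPR (not TBR) rearrangements; on highly homoplastic matrices the ratchet
  may need more iterations than the defaults to find all optima.
* The pooled-optima set is whatever the search visited; strict consensus is
  therefore conservative only relative to the trees actually found.
* Fitch scoring on internal polytomies (consensus trees) is an upper
  bound; lengths are only reported for binary search trees.
* The contamination screen is reference-based: it cannot flag a
  contaminant resembling nothing in either reference set.
* `nn_conflict` uses distances, not tree clades; a tree-based conflict
  mode can disagree near polytomies (the distance rule is the default
  precisely because it is deterministic).
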