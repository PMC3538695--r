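# barcodeval

Evaluation of multi-marker DNA barcode reference libraries for local
floras — the *rbcL* + *matK* + ITS2 setting typical of vascular-plant
barcoding campaigns.

Building a barcode library is only half the work; the other half is
quantifying what it can do.  `barcodeval` answers the two standing
questions about such a library:

* **Species resolution.** A species is *resolved* by a marker combination
  when its specimens form a monophyletic clade in the maximum-parsimony
  (MP) consensus tree **and** share at least one consistent diagnostic
  character — an alignment column where every member carries the same
  unambiguous base found in no other specimen in the study.  Resolution is
  reported overall and separately for congeners (polytypic genera) versus
  monotypic genera, whose "species" resolution is effectively generic.
* **Library reliability.** QC screens flag pseudogenes (frameshift lengths,
  internal stop codons), fungal/algal contamination (k-mer containment
  against reference sets), ITS2 paralogy (nuclear placement conflicting
  with a chloroplast-supported species assignment) and misidentified
  vouchers (all markers placing a specimen with another species).

Around that core the package provides: per-marker FASTA + metadata-TSV
input with taxonomy validation; partitioned supermatrix construction with
specimen-inclusion rules (e.g. "ITS2 plus at least one chloroplast
marker"); within-family mean pairwise distances (MPD, % — p-distance or
K2P) with σ and Fisher-z-tested cross-marker correlations; sequencing
success tabulations by tissue source and specimen age; a seeded parsimony
ratchet with strict consensus of all pooled optima; and a fully seeded
synthetic-library simulator (Jukes–Cantor, planted anomalies, ground
truth) that makes the whole pipeline testable offline.

## Worked example

Simulate a realistic library (about 35 genera, 60% monotypic, 2–5
specimens per species, herbarium dropout, two planted ITS2 paralogs and
two label swaps), build the three-gene supermatrix, search, and score:

```r
library(barcodeval)

params <- simulation_params(seed = 42, n_paralogs = 2,
                            n_misidentifications = 2)
lib <- simulate_library(params)
lib$dataset
#> <barcode_library> 214 specimens, 60 species, 35 genera, 10 families
#>   rbcL: 187 sequences x 552 columns
#>   matK: 163 sequences x 800 columns
#>   ITS2: 183 sequences x 350 columns
#>   recovery table: 642 records

sm <- concatenate(lib$dataset, c("rbcL", "matK", "ITS2"), rule = "paper")
sm
#> <supermatrix> 177 specimens x 1702 columns; partitions: rbcL[0,552) matK[552,1352) ITS2[1352,1702)

rr <- parsimony_ratchet(sm, search_params(ratchet_iterations = 10,
                                          n_start_trees = 2, seed = 7))
rr
#> <ratchet_result> best length 19647; 3 distinct optimal topologies; seed 7

rep <- species_resolution(strict_consensus(rr$trees), sm, lib$dataset)
rep
#> <resolution_report> 60 species evaluated (0 absent from matrix)
#>   overall resolved: 95.0%  congeners (polytypic genera, n=38): 94.7%  monotypic genera (n=22): 95.5%
```

The 95% (not 100%) reflects the planted anomalies: the two relabelled
specimens spoil their species' diagnosability, and the QC screens find
them:

```r
misidentification_flags(lib$dataset)
#>   specimen_id         flag_type                                                 evidence
#> 1     SPM0012 misidentification all informative markers place specimen with Genus004 sp1
#> 2     SPM0073 misidentification all informative markers place specimen with Genus013 sp2
```

Distance statistics reproduce the expected marker speed ordering:

```r
sapply(c("rbcL", "matK", "ITS2"),
       function(m) mean(mpd_by_family(lib$dataset, m)$mpd_percent))
#> rbcL: 10.98   matK: 20.01   ITS2: 38.27   (mean family MPD, %)
```

`run_pipeline(run_config(...))` chains everything — QC, exclusion of
flagged sequences, one ratchet + consensus + resolution report per marker
combination, MPD/correlation/recovery tables, paralogy and
misidentification flags — into a reproducible report bundle (TSV, Newick,
JSON, run log).  A thin command-line front end with `simulate`, `qc`,
`concat`, `tree`, `resolve`, `mpd` and `report` subcommands lives in
`inst/scripts/barcodelib.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","barcodelib.R",package="barcodeval"))') \
    simulate --out lib_dir --seed 3
```

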