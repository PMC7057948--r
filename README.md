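# trmine

Genome mining and quantitative characterisation of transcription-factor-based
metabolite biosensors in bacteria.

Many bacterial transcriptional regulators (TRs) — LysR-type regulators above
all — sit divergently transcribed from the catabolic operon they control,
sharing a compact intergenic region that carries both promoters. The TR binds
a small-molecule effector, usually the entry compound of the operon-encoded
pathway, and switches the divergent promoter on. Each such locus is a
ready-made inducible gene-expression system: regulator, promoter and ligand,
all discoverable from an annotated genome. `trmine` implements that screen
and the downstream workflow that turns a discovered locus into a
characterised biosensor.

## What it does

**Mining** (`mine_inducible_systems()`). From a GenBank flat file the package
flags TR genes by annotation keywords, groups co-directional genes with
intergenic gaps ≤ 150 bp into operons, and pairs every TR with operons that
face it head-to-head across an intergenic region ≤ 500 bp. Operons with
fewer than two genes of annotated catalytic function are filtered out. For
the survivors the operon's EC numbers are looked up in a reaction
knowledgebase (a TSV table standing in for an enzyme database), cofactors
are removed, and the candidate ligand is inferred as the *primary substrate*
of the encoded pathway — the compound consumed by the operon's reactions but
produced by none of them (a source of the directed substrate→product graph).

**Dose–response characterisation** (`fit_hill()` and friends). Plate-reader
time courses are blank-corrected and OD-normalised
(`(FL − FL_blank)/(OD − OD_blank)`), read at the 80-min minimal induction
interval, and fitted by non-linear least squares to the Hill function

    RFP(I) = b_max · I^h / (K_m^h + I^h) + b_min

giving the basal output `b_min`, amplitude `b_max`, half-maximal inducer
concentration `K_m` and Hill coefficient `h`. The dynamic range is
`µ = b_max/b_min` with propagated uncertainty
`σ_µ = µ·sqrt((σ_bmax/b_max)² + (σ_bmin/b_min)²)`.

**Cross-reactivity screening** (`build_matrix()`). Relative induction of a
test compound is `100·(FL_compound − FL_uninduced)/(FL_primary −
FL_uninduced)` percent. A non-cognate compound is a *hit* when it reaches
≥ 5% relative induction **and** ≥ 5-fold absolute induction; a system is
*orthogonal* when every non-cognate compound stays strictly below 5%.

**Auxiliary**: intracellular metabolite concentration from pellet
extractions (`intracellular_concentration()`, wet-pellet volume from a cell
density of 1.105 g/mL), fold induction, relative response curves, and seeded
generators for synthetic genomes with planted TR–operon systems
(`generate_toy_genome()`) and simulated plate data
(`simulate_plate_timecourse()`), so the whole pipeline runs and tests
without any downloads.

## Worked example

```r
library(trmine)

# a synthetic genome with 2 planted systems and 3 decoy arrangements
out <- file.path(tempdir(), "demo")
gen <- generate_toy_genome(plant_spec(n_systems = 2, n_decoys = 3, seed = 42), out)
cand <- mine_inducible_systems(gen$genome, gen$kb)
cand[, c("tr_gene_id", "tr_family", "intergenic_length", "n_catalytic", "status")]
#>   tr_gene_id tr_family intergenic_length n_catalytic       status
#> 1   SYS01_TR      LysR               287           2     proposed
#> 2   SYS02_TR      MarR               109           3     proposed
#> 3   DEC03_TR      MocR                98           1 filtered_out

cand$ligands[[1]]
#>    compound consumed_by produced_by rank
#> 1 cpd_s01_0           1           0    1
#> 2 cpd_s01_1           1           1    2
```

Both planted systems are recovered with their true entry compounds at rank 1
(consumed once, produced never — a pathway source); the divergent decoy with
a single catalytic gene is rejected. Characterising a simulated biosensor
(true parameters `b_min` 100 AFU/OD, `b_max` 800, `K_m` 201 µM, `h` 0.75,
5% measurement noise in triplicate):

```r
fit <- recover_hill_from_simulation(
  sim_spec(b_min = 100, b_max = 800, K_m = 201e-6, h = 0.75,
           noise_cv = 0.05, seed = 1))
fit
#> hill_fit: b_max = 793.1 +/- 36, b_min = 101.3 +/- 18
#>           K_m = 0.0001965 +/- 2.9e-05 M, h = 0.737 +/- 0.074
#>           dynamic range mu = 7.827 +/- 0.73 (fold)
```

All four parameters are recovered within their reported uncertainties; the
dynamic range of ~7.8-fold means full induction raises reporter output
nearly eightfold over basal expression.

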