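---
title: "Methods: mining and characterising metabolite-inducible systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterising metabolite-inducible systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmine)
```

This vignette documents the models, parameter choices and numerical
decisions behind `trmine`. It is the package's own account of its methods;
every number quoted as an outcome here is computed by the test suite or the
acceptance script, not asserted.

## The genomic screen

The screen exploits a conserved regulatory architecture: a transcriptional
regulator (TR) transcribed divergently from the operon it controls, with
both promoters in the shared intergenic region, and the TR's effector being
the entry metabolite of the operon-encoded pathway. The pipeline is four
predicates applied to an annotated genome:

1. **TR detection** is keyword-based on the CDS `product` text. The default
   lexicon contains family tokens (LysR, MarR, AsnC, MocR, IclR, TetR,
   AraC, GntR, LacI, XRE, sigma-54 dependent) and generic phrases
   ("transcriptional regulator/activator/repressor", "transcription
   factor"). Family tokens are matched first so that "LysR family
   transcriptional regulator" is classified by family and not as
   "unknown". Keyword matching inherits the annotation's quality — an
   unannotated regulator is invisible, which is a screen property, not a
   defect the package can repair.

2. **Operon inference** groups consecutive co-directional genes whose
   intergenic gap is at most `max_gap` (default **150 bp**, a common
   prokaryotic operon-calling heuristic; configurable because no canonical
   threshold exists). An interposed opposite-strand gene always breaks a
   run. TR genes never join an operon and never count toward its catalytic
   tally, so a TR carrying an EC number cannot help its own operon pass the
   filter below.

3. **Divergence pairing** pairs each TR with opposite-strand operons whose
   first gene faces it head-to-head (5′ ends toward each other) across an
   intergenic region of at most `max_intergenic` (default **500 bp**;
   divergent promoter regions are compact — the canonical benzoate example
   is 146 bp). Convergent and co-directional neighbours are excluded, as
   are overlapping genes (negative gap). The promoter interval must contain
   no CDS; when a TR has eligible operons on both flanks, both pairs are
   emitted ranked by distance, since nothing forbids one regulator serving
   two regulons.

4. **Catalytic filter**: the operon must encode at least `min_catalytic`
   (default **2**) genes of annotated catalytic function — having an EC
   number, or a product matching an enzyme-suffix lexicon ("-ase" classes:
   dehydrogenase, decarboxylase, transferase, ...). This operationalises
   "an operon with annotated catalytic functions" without depending on
   complete EC annotation.

Coordinates are normalised to 0-based half-open intervals internally
(GenBank is 1-based inclusive); interval length is always `end − start` and
promoter intervals are directly BED-compatible. Compound (`join`) CDS
locations are flattened to their outer span — the screen needs orientation
and distance, not exon structure. Pseudo-genes and non-CDS features are
ignored.

## Ligand inference

"Compare each enzyme's substrates and products and conclude the primary
substrate" is formalised as **graph-source inference**. Reactions looked up
by EC number define a directed compound graph (substrate → product);
blacklisted cofactors (water, protons, ATP/ADP/AMP, NAD(P)(H), CoA,
phosphate, CO2, O2, ammonia) are removed first, since they would otherwise
be spurious sources or sinks of almost every pathway. Candidate ligands are
compounds consumed by at least one reaction; the primary substrate is a
graph **source** — consumed but never produced within the operon's reaction
set. Ranking is by `produced_by` ascending, then `consumed_by` descending,
then compound id for determinism.

Two deliberate conservatisms:

* **Reversible reactions** contribute edges in both directions, which can
  eliminate sources. When no source survives (a cycle), the result is
  flagged ambiguous rather than guessed.
* **Intermediate-as-effector** cases exist in nature (a regulator may
  respond to a pathway intermediate rather than the entry compound, as
  known for kynurenine-pathway regulators). These cannot be resolved from
  reaction topology alone, so the full ranked list is always emitted and a
  curator can override rank 1.

A third decision: the screen does **not** additionally require the operon's
reactions to form a weakly connected compound graph as a proxy for
"association with a distinct metabolic pathway". Disconnected reaction sets
simply produce several sources in the ranked list, which the flagging and
the ranked output already make visible; a hard connectivity rule would
silently discard loci that a curator should instead inspect.

Compound identity is by normalised identifier string; there is no chemical
structure resolution — the knowledgebase supplier controls the vocabulary.

## Normalisation and the induction window

Absolute normalised fluorescence is `(FL − mean blank FL)/(OD − mean blank
OD)` per time point (AFU/OD). Time points with corrected OD at or below
`od_floor` (default **0.01**) are masked: dividing by near-zero biomass
amplifies noise without bound. Dose–response values are read at the sample
**nearest 80 min** after induction — no interpolation, mirroring how values
are read off a 5-min acquisition grid. The 80-min default is the minimal
induction interval: long enough for reporter synthesis and maturation,
short enough that inducer catabolism has not yet depressed the response; it
is a configurable constant, not something the package estimates.

## The Hill fit

The model is `RFP(I) = b_max·I^h/(K_m^h + I^h) + b_min`. Fitting is
non-linear least squares over all replicate points, unweighted, via
Levenberg–Marquardt with box constraints (`minpack.lm`):

* **Initialisation**: `b_min` at the uninduced mean, `b_max` at
  `max(RFP) − b_min`, `h = 1`, and `K_m` at the best point of a 25-node
  log-spaced grid over the observed concentration range. The grid start
  makes convergence insensitive to the orders-of-magnitude spread of
  plausible `K_m` values.
* **Bounds**: `h ∈ [0.1, 10]`; `K_m` within `[min I>0 / 100, max I × 100]`;
  `b_max > 0`, `b_min ≥ 0`. A fit at the `h` bounds, or on data with zero
  dynamic spread, is flagged degenerate.
* **`b_min` is a free parameter**, initialised — not pinned — at the
  uninduced mean: the model includes the basal term as fitted, while the
  *uncertainty* of the basal level is taken from the replicate spread of
  the uninduced wells. Both conventions are honoured where they belong:
  the fitted `b_min` enters `µ`, the replicate SD enters `σ_µ`.
* **Failure is a value, not an exception**: `converged = FALSE` lets a
  batch over many systems mark one as "ND" (not determined) and continue —
  a response that never saturates at soluble concentrations is a real
  outcome, not an error.
* At least **4 distinct non-zero concentrations** and one uninduced point
  are required; parameter SDs come from the fit covariance.

Derived quantities: dynamic range `µ = b_max/b_min` with
`σ_µ = µ·sqrt((σ_bmax/b_max)² + (σ_bmin/b_min)²)`; relative response
`100·(RFP − RFP_uninduced)/b_max`, with the highest tested concentration
pinned to 100% when `b_max` is undefined; fold induction
`induced/uninduced`. `µ` follows the amplitude convention of the model
equation exactly as written (`b_max` is the inducible amplitude, so
saturation output is `b_max + b_min`).

The test suite checks the fit against an independent oracle: an exhaustive
coarse grid over `(K_m, h)` with the two linear parameters solved in closed
form at each node. The returned SSE must never exceed the grid optimum.

## Cross-reactivity and orthogonality

Relative induction is `100·(FL_compound − FL_uninduced)/(FL_primary −
FL_uninduced)` — invariant under any common affine rescaling of the
fluorescence channel, so gain settings cancel. Negative values (repression)
are reported as-is; some regulators genuinely repress. The diagonal of a
systems × compounds matrix is 100% by construction. Two asymmetric
boundary conventions are deliberate, following how the screening rules are
stated: a **hit** requires relative induction **≥ 5%** *and* absolute fold
induction **≥ 5** (inclusive); **orthogonality** requires every non-cognate
relative induction **strictly < 5%**. A cell at exactly 5% is therefore a
hit and breaks orthogonality. Missing measurements stay absent (`NA`),
never zero.

## Intracellular concentration

From a pellet extraction, `V_pellet = wet mass / 1.105 g/mL` (cell density
of non-PHB-accumulating cells) and
`C_intracellular = ((V_pellet + V_solvent)/V_pellet) × C_extract`. The
dilution factor is ≥ 1, so the computed intracellular concentration is
never below the extract concentration.

## Synthetic data: what it emulates, what it does not

**Genomes** (`generate_toy_genome()`): planted systems are a minus-strand,
family-labelled TR CDS facing a plus-strand operon of 2–4 EC-annotated CDS
across an 80–300 bp promoter; the ECs form a linear pathway in the
companion toy knowledgebase, so the planted entry compound is the unique
graph source. Decoys cycle through the three arrangements the screen must
reject: convergent pairs, co-directional pairs, and divergent single-gene
operons. Elements are separated by 800-bp spacers — longer than both
`max_gap` and `max_intergenic` — so arrangements never merge. A JSON
manifest carries the ground truth; outputs are byte-identical under a fixed
seed.

**Plates** (`simulate_plate_timecourse()`): OD follows logistic growth,
inducer-independent, starting at OD 0.19 (exponentially growing cells at
OD600 0.2 diluted 142.5/150 into the well, as in the dose–response
acquisition protocol) with a ~2 h doubling time typical of minimal-medium
growth; raw fluorescence is reconstructed as
`Hill(I)·OD + medium autofluorescence` and perturbed by multiplicative
log-normal noise of the stated CV (plate-reader error scales with signal;
mean-corrected so noise is unbiased). Blank wells carry the medium signals
alone. The default concentration design is 12 log-spaced points spanning
0.01×–100× the true `K_m`, in triplicate. In the noise-free limit the
composition simulate → normalise → window → fit is the identity on the Hill
parameters, which the tests assert to 0.1% relative error.

What the simulator does **not** model — and hence what passing tests do not
show about real data: inducer uptake limits and catabolism (the reason the
80-min window exists at all), effector-dependent growth boosts (an optional
growth model hook is deliberately absent; growth is shared across wells),
reporter maturation kinetics, plate-position effects, and annotation noise
in real genomes (mislabelled products, missing EC numbers). Mining
recall/precision of 1 on planted genomes demonstrates the geometry
predicates, not robustness to sloppy annotation.

Note also that because multiplicative noise applies to the *raw*
fluorescence (signal plus medium autofluorescence), the effective noise on
the normalised scale exceeds the nominal CV at low signal-to-background —
at the default conditions the measured median `K_m` recovery error (5% CV,
triplicates) sits close to the design's Cramér–Rao bound, i.e. the
estimator extracts nearly all the information the design carries.

## Problem sizes used in the tests

Unit and property tests run on small instances chosen to exercise the
logic: 100 randomly specified planted genomes (0–4 systems, 0–6 decoys)
for the mining recall/precision property, 500 random acyclic reaction sets
(4–10 compounds) against the brute-force source oracle, 20 random datasets
against the grid-search SSE oracle, and 200 simulation seeds for the
`K_m`-recovery robustness estimate. These sizes give stable Monte-Carlo
estimates while keeping the full suite under a minute of compute.

## Known limitations

* GenBank parsing covers the flat-file subset the screen needs (LOCUS,
  FEATURES with CDS, ORIGIN); GFF3/EMBL dialects and NCBI downloads are out
  of scope.
* The knowledgebase is user-supplied and string-matched; no live database
  access, stoichiometry, or chemical-similarity reasoning.
* Operon calling is distance-based only; no transcriptomic evidence.
* The Hill fit assumes a monotone steady-state response at the window
  time; systems dominated by uptake dynamics violate the model's reading
  of `K_m` as an extracellular affinity, which is a caveat of the assay
  design the package inherits.
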