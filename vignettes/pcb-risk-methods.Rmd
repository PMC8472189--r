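---
title: "Methods: PCB transformation products and their environmental risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCB transformation products and their environmental risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbtrans)
```

## Scope

Polychlorinated biphenyls (PCBs) degrade and metabolize in the environment
along several routes, and the products -- chlorobenzoic acids, hydroxylated
and methylsulfonyl metabolites, less-chlorinated congeners -- can carry
persistent-organic-pollutant risks of their own. `pcbtrans` implements the
computational side of screening those products: congener arithmetic,
rule-based product enumeration for four transformation pathways, a
CoMFA-style field/PLS 3D-QSAR engine for toxicity endpoints, and a
five-endpoint change-rate risk characterization. The study's printed data
tables ship as CSV fixtures so every stage runs without downloads.

## Congener representation and numbering

A congener is a pair of chlorine locant sets on the two phenyl rings,
positions 2--6 each (position 1 is the inter-ring bond). Rotation about
that bond makes each ring's 2/6 and 3/5 positions conformationally
equivalent, and the two rings are interchangeable, giving an 8-element
symmetry group. `canonicalize_rings()` picks the lexicographically smallest
image with `ring_a <= ring_b`; the 1024 raw pattern pairs collapse to
exactly 210 classes (biphenyl plus 209 chlorinated congeners).

The standard congener numbering is *derived*, not transcribed:
`derive_bz_numbering()` names each class (the more-chlorinated ring
unprimed, ties to the lexicographically smaller pattern; locants ordered
with `n < n' < n+1`) and sorts by homolog class, then locant sequence. The
single deviation of the historical numbering from strict locant order --
congeners 107--109, where the accepted assignment is 107 = 2,3,3',4',5,
108 = 2,3,3',4,5', 109 = 2,3,3',4,6 -- is applied as a fixed, documented
exception. The derivation is pinned by tests against 39 well-known
assignments and by the packaged transformation table, whose 50 rows only
reproduce under a correct numbering.

## Transformation rules

Each pathway is a small rule engine over ring patterns:

* **Plant degradation** -- dioxygenase attack needs free 2,3 positions, so
  the *less*-chlorinated ring is oxidized and opened; the product is the
  chlorobenzoic acid keeping the surviving ring's pattern verbatim
  (carboxyl at position 1). Ties emit both rings' acids, deduplicated.
  Dihydrodiol and ring-opening intermediates are deliberately collapsed to
  the terminal acid.
* **Microbial aerobic degradation** -- one OH per free meta/para position
  (via epoxide intermediates that are not enumerated); para attack is
  flagged preferred. Ortho additions are not generated.
* **Microbial anaerobic degradation** -- every single-chlorine removal,
  annotated by site class. Meta/para are the main reductive sites and are
  flagged preferred, but ortho removals are kept: observed product sets
  include ortho losses (e.g. the 2,2',3,4',5 pentachloro congener losing an
  ortho chlorine to give PCB-68), and verification is set *membership*
  because the printed mappings list observed, not exhaustive, products.
* **Biometabolism** -- one MeSO2 group per free meta/para position.
* **Photodegradation** -- breadth-first reachability over sequential single
  dechlorinations up to `max_steps`, each product reported with its minimal
  step count and the site classes of an ortho-first (ortho > para > meta)
  preference path. No kinetic model is attempted; the source describes no
  rates.

### Product naming

Metabolite names keep the parent congener number (`4'-OH-CB97` style). Two
conventions interact:

* The prime marks the parent's *primed* ring (less-chlorinated, ties
  lexicographic). This reproduces the standard metabolite names.
* The added group's locant is minimized over the flip of its own ring:
  the known `3-MeSO2-CB110` metabolite requires renumbering the attacked
  ring so the group, not the chlorines, takes the low locant. The
  alternative (chlorine-locant precedence) would name it `5-MeSO2-CB110`
  and was rejected against the packaged table.

Two rows of the packaged mapping table (`4-OH-CB109`, `4-MeSO2-CB174`)
carry primes inconsistent with every other row (the only free attack site
sits on the less-chlorinated ring, which the convention primes). Each
product therefore also records a prime-toggled `alias`, and
`verify_product_mappings()` accepts canonical name or alias -- a structural
match, not a string heuristic. All 50 packaged mappings reproduce.

## Geometry, fields, and PLS

`embed_and_minimize()` delegates 3D embedding and minimization to Open
Babel (MMFF94, deterministic; iteration cap and convergence criterion are
configurable and recorded in metadata, defaults 10000 and 0.005) and
assigns Gasteiger-type iteratively equalized partial charges. The mol2
charges are printed at four decimals; the rounding residue is spread evenly
so neutral molecules are exactly neutral. `align_to_template()` performs a
least-squares (Kabsch) superposition of the aromatic core -- 12 carbons for
biphenyls, 6 for benzoic acids mapped onto the template's first ring --
trying all ring-order/walk-direction mappings and keeping the best.

Fields follow standard CoMFA conventions, since the source names only the
method: an sp3-carbon, charge +1 probe on a rectangular grid (default
2.0 Angstrom spacing, 4.0 Angstrom margin); steric = Lennard-Jones 6-12
with Tripos-like van der Waals parameters; electrostatic =
`332 * q / r^2`, i.e. a distance-dependent dielectric `eps = r`; both
truncated to +/-30 kcal/mol, so the fields are finite everywhere by
construction. Electrostatic values at grid points buried inside a molecule
(steric at the cutoff) carry no information and are replaced by the column
mean over non-buried molecules. Near-constant columns (sd at or below
0.05 kcal/mol) are dropped before regression.

`fit_pls()` is NIPALS PLS1 on mean-centered data (no autoscaling, the
standard field-QSAR choice; both are configurable). The number of latent
variables maximizes leave-one-out q2 over 1..10 (ties to the smaller
model); the source reports 7- and 8-component models but not its selection
rule, so argmax-q2 with a cap of 10 is used. q2 is `1 - PRESS/SS` with SS
from the full response mean and every held-out prediction refitted on the
remaining samples; a test pins it to an independent naive refit oracle at
1e-10. Model quality statistics use `r2 = 1 - RSS/SS`,
`SEE = sqrt(RSS/(N - c - 1))`, and `F = (r2/c) / ((1 - r2)/(N - c - 1))`;
the F formula reproduces both reported model F values (38.578 and 67.952)
from their printed `(r2, N, c)` to well under 1 percent.

The packaged commercial-software CoMFA statistics (q2 of 0.695/0.671, SEE
of 2.854/2.509) are *not* reproduction targets: the proprietary field
engine and the docking scores behind them are not available, and activities
enter this package as fixture data. What is tested instead is that the PLS
machinery itself is sound: oracle-exact leave-one-out, ordinary
least-squares equivalence at full rank, permutation collapse, and parameter
recovery on synthetic data.

## Synthetic data

`gen_qsar()` emulates what the field matrix looks like statistically:
a few informative latent directions, each spread over a block of
neighboring columns with a smooth Gaussian-bump profile (grid fields vary
smoothly in space), plus small idiosyncratic column noise; the activity is
exactly `y = X beta + eps` with i.i.d. Gaussian noise. Defaults mirror the
phytotoxicity training conditions: 60 molecules, 120 descriptors, 4
informative directions, noise set for a generative R2 of 0.9. Over 50
seeded replicates the fitted leave-one-out q2 lands within 0.1 of the
generative R2 in all replicates (mean about 0.89).

What the generator does *not* emulate: truncation plateaus and buried-point
imputation, the discrete homolog structure of real congener sets, docking
score error. Passing recovery tests therefore demonstrate correctness of
the regression machinery under the model's own assumptions, not field-QSAR
accuracy on new chemistry.

`gen_congeners()` samples congeners uniformly without replacement, seeded;
both generators save and restore the caller's RNG state.

## Risk characterization

Five endpoint scores per molecule: phytotoxicity and estrogen toxicity
(docking total scores against a peroxidase and an estrogen receptor),
bioconcentration (log BCF scale), persistence (log half-life scale, may be
negative), migration (log K~OA~ scale). The external QSAR models behind the
last three are treated as opaque score sources; their values enter via the
fixtures.

`change_rate()` is `100 * (product - parent) / parent`, signed, with no
absolute-value normalization -- a product crossing zero yields changes
beyond -100 percent (the packaged table contains -184.02). Parent zero is
an error, and the arguments are labeled, never swapped. `improvement()`
inverts the orientation for migration only: a higher octanol-air partition
score means *lower* long-range transport risk, the other four endpoints
read the other way, and `risk_direction()` encodes the same convention.

`heat_levels()` bins each pathway-endpoint cell's maximum absolute change
into ten equal-width levels over `[0, global max]` (the binned quantity is
the maximum absolute change; the source specifies only "10 levels", so
equal-width over max-|change| is this package's choice, stated here). An
all-zero matrix maps to level 1.

`recompute_chain_changes()` re-derives every change-rate cell of the
packaged chain table (24 products x 5 endpoints = 120 cells) from the
value columns; all 120 match the printed cells to within 0.01 percentage
points (printed values are rounded to 2 decimals).

## Validation arithmetic

The two printed tables use *opposite* relative-error orientations --
`100*(obs - est)/obs` for the congener estimate table,
`100*(est - ref)/ref` for the metabolite table; both reproduce every
printed cell to 0.01. The convention is therefore a required argument of
`relative_error()`, never inferred.

The linear-fit R values of the observed-vs-estimated plots (0.956
phytotoxicity, 0.949 estrogen toxicity) reproduce only on the *training*
rows (r = 0.9551 over 60 and 0.9487 over 38); across all rows with
observations the estrogen value drops to 0.924 because the 10 test-set
molecules fit worse. The fixtures preserve the test-set markers, and the
package computes these fit statistics on training rows, reporting the
choice here since the source does not state it.

`critical_r()` uses the closed form `r0 = t/sqrt(t^2 + df)` with
`df = n - 2`, two-tailed. The source quotes r0 = 0.339 at alpha 0.05 and
0.539 at alpha 0.001 for n = 33, where this convention gives 0.344 and
0.547; published lookup tables vary in their df convention and neither
quoted value matches `df = n - 2` exactly, so the function returns its
convention alongside the value rather than reverse-engineering a table.

## Worked example

```{r example}
# products of PCB-52 under all four pathways
plant_degrade(52)$name
anaerobic_dechlorinate(52)$name
head(photodechlorinate(52, max_steps = 2)[, c("name", "steps", "site_class")])

# chain risk records and their summary
rec <- chain_evaluate("PCB-52", paste0("52-", 1:4))
summarize_changes(rec)

# validation of the metabolite estimates
t4 <- load_fixture("table4")
validation_report(t4$estro_total, t4$estro_est)
```

## Numerical choices and limitations

* Grid spacing 2.0 Angstrom and +/-30 kcal/mol truncation are standard
  field-QSAR conventions; none are stated in the source.
* Leave-one-out model selection refits the column centering inside each
  fold; the kept-column filter is applied once, outside the loop.
* Problem sizes in the tests: the recovery study runs 50 replicates at
  60 x 120; the geometry tests embed a handful of molecules; the pipeline
  example fits an 8-molecule field model. The full 60-molecule field fit
  runs through `run_pipeline()` with `qsar_molecules = NULL`.
* Stereochemistry/atropisomerism, non-chlorine halogens, kinetics and
  yields, dioxin/furan side chemistry, and docking itself are out of
  scope; docking-derived activities are consumed as data.
* The derivative molecules (P1--P3) enter only as endpoint rows of the
  fixtures; their structures are not modeled.
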