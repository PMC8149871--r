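---
title: "Predicting hemophilia A severity from FVIII structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hemophilia A severity from FVIII structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

severin predicts the clinical severity of single amino-acid
substitutions in coagulation factor VIII (FVIII) from the protein's
3D structure. Hemophilia A severity is defined by residual clotting
activity (FVIII:C): severe below 1% of normal, moderate in [1, 5),
mild in [5, 40]. The package turns a structure plus curated clinical
mutation reports into a classifier ensemble whose output — the
Severity Score — is the estimated probability that a substitution
causes the severe phenotype, and then scores every possible
substitution in the structure.

This vignette explains the model, the parameters that matter, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## The feature model

Each mutation instance is described by fifteen features
(`feature_columns()`), of which fourteen depend only on the wild-type
position:

* **Structural**: solvent-accessible surface area (`areaSAS`),
  solvent-excluded surface area (`areaSES`), Kyte–Doolittle hydropathy
  of the residue type (`kdHydrophobicity`), backbone torsions `PHI`
  and `PSI` (degrees), and the mean heavy-atom B-factor (Å²).
* **Conservation**: a per-residue evolutionary conservation score,
  read from a precomputed alignment-based grade file (lower = more
  conserved; the direction is preserved as given, never
  re-normalized).
* **Network**: seven centralities of the residue interaction network
  (RIN) — degree, betweenness, closeness, Burt's constraint, HITS
  authority, PageRank, and k-core number.
* **Substitution**: the only feature that varies among mutations at
  one position is `aa_distance`, the Euclidean distance between
  wild-type and mutant amino acid in a PCA-reduced physicochemical
  property space.

### Surface areas

`areaSAS` uses the Shrake–Rupley construction: each atom's solvent
sphere (van der Waals radius + probe radius, default 1.4 Å for water)
is sampled with a deterministic golden-spiral point set (default 960
points, about 2% area resolution on an isolated atom) and points
buried inside any neighbour's solvent sphere are discarded. The point
template is anchored to the molecule's principal-axes frame (signs
fixed by projection skewness), so the sampled areas are exactly
equivariant under rigid-body rotation and translation — not merely up
to sampling error — as well as invariant to atom input order, and
they sum exactly over atoms within a residue. (Exactly symmetric
configurations, where the principal axes are degenerate, fall back to
a fixed global frame.)

A true solvent-excluded (molecular) surface requires a surface
triangulation algorithm that this package deliberately does not
contain. `areaSES` therefore defaults to a documented approximation —
the same point construction with probe radius 0, i.e. the exposed van
der Waals contact surface — and `compute_surfaces(ses = )` accepts a
user-supplied backend function for callers who have an external
molecular-surface tool. The approximation tracks buriedness well,
which is what the classifier consumes, but its absolute values are
not molecular-surface areas.

### Torsions

`PHI`/`PSI` are standard IUPAC backbone dihedrals from consecutive
N/CA/C atoms (sign convention cross-checked against an independent
structural-bioinformatics implementation). Torsions are reported
missing — never zero — at chain termini, at chain breaks (peptide C–N
distance above 2.5 Å), and where backbone atoms are absent; missing
backbone atoms warn rather than fail.

### The residue interaction network

Nodes are residues; an undirected, unweighted edge joins two residues
whose heavy atoms approach within `contact_cutoff` (default 5.0 Å, the
conventional heavy-atom contact distance). `min_seq_sep` defaults to 1
so only self-contacts are excluded and backbone neighbours are kept;
the graph is simplified to remove multi-edges and loops. Contact
detection with a probe-based tool would give a slightly different edge
set than a plain distance cutoff, so edge counts are comparable but
not identical across toolchains; node counts are not affected.

Burt's constraint is implemented directly from its definition with
uniform tie weights \(p_{ij} = 1/\deg(i)\):

$$c(i) = \sum_{j \in N(i)} \Big(p_{ij} + \sum_{q} p_{iq}\,p_{qj}\Big)^2$$

Low constraint marks residues that bridge otherwise separate
neighbourhoods (central, typically buried positions); pendant nodes
have constraint 1 and a k-leaf star centre has constraint \(1/k\).
The implementation is validated against brute-force evaluation of the
formula and against an independent graph library. The remaining
centralities go through igraph: PageRank with damping 0.85, authority
scores via HITS, closeness with the within-component convention on
disconnected graphs (recorded in the output's `closeness_mode`
attribute). Isolated nodes get degree 0 and missing closeness and
constraint; downstream, the learning module's missing-value policy
removes such rows.

## The amino-acid distance index

`aa_properties()` supplies 544 numeric amino-acid indices (the AAindex
collection shipped with seqinr); `read_aaindex()` and
`read_property_csv()` ingest external tables. Properties with any
missing amino-acid value are dropped (complete-case; 531 of the 544
survive), matching the pipeline's global removal policy for
incomplete data. Properties are standardized to zero mean and unit
variance before PCA because raw index scales are incommensurate;
`reduce_properties(scale = FALSE)` exposes the alternative. The number
of retained components is the smallest whose cumulative explained
variance reaches `variance_target` (default 0.99). On the bundled
collection the standardized convention retains 18 components at 99%
(19 — the maximum for 20 observations — retain 100%, and the count is
sensitive by ±1 to the scaling convention; the unstandardized
convention gives 10). The 20×20 matrix of Euclidean distances between
amino-acid score rows is the substitution distance index; it is
symmetric, zero-diagonal, satisfies the triangle inequality, and is
invariant to orthogonal rotation of the component space.

## Curation of clinical records

`normalize_activity()` maps verbatim FVIII:C cells to percent values
with fixed, deterministic rules: the sentinel substitutions ">5"→5,
"<10"→10, "<11"→11, "<1"→0; plain numbers pass through; a reported
range ("10–24", "a to b") becomes its midpoint *only when both
endpoints fall in the same severity band* — a range that straddles a
diagnostic boundary ("0 to 2") cannot be labeled and is rejected as
ambiguous, as are inequalities outside the sentinel list ("<2").
This single band-consistency rule reproduces the accepted and rejected
forms of the published cleaning protocol.

`sanitize_mutations()` applies the per-dialect rules in a fixed order
and attributes every dropped row to exactly one named rule, so the
rejection tally plus the kept rows always equals the input (a property
fuzz-tested in the suite). The EAHAD-style order: query-scope filter,
mature-protein range check (FVIII mature chain: 2332 residues),
activity above 100%, unparseable activity, ambiguous activity, rows
with neither activity nor inhibitor information, first- versus
second-assay band discrepancies, stop codons, ambiguous severity
labels ("mild/moderate"). CHAMP-style tables add duplicate removal on
the (position, wild-type, mutant) triple. Severity bands are half-open
([0,1), [1,5), [5,40]) because the clinical definitions overlap at
the boundaries; activities above 40% are labeled non-hemophilic and
excluded from modeling. Clinical tables use mature-protein numbering;
`build_design_matrix(numbering_offset = )` converts to structure
numbering (default 0, matching the legacy FVIII numbering of the
structure the pipeline was designed around).

## Class balancing

ADASYN closes the class imbalance adaptively: with minority size
\(m_s\) and majority size \(m_l\), it generates
\(G = (m_l - m_s)\beta\) synthetic minority rows (default
\(\beta = 1\)), apportioned to minority points in proportion to the
fraction of majority examples among their K nearest neighbours
(default K = 5, Euclidean distance in the normalized feature space,
ties broken by row index). Apportionment uses largest-remainder
rounding so the synthetic total equals G exactly. Each synthetic row
is a convex combination \(x_i + \lambda(x_z - x_i)\),
\(\lambda \sim U(0,1)\), of a minority point and one of its K nearest
minority neighbours; parentage is logged so tests can verify the
construction exactly. When no minority point has majority neighbours
the difficulty weights are undefined by the original formulation;
severin falls back to uniform weights. Original rows are never
modified.

## Training protocol

`severity_train()` runs six algorithms — decision tree, random
forest, radial- and polynomial-kernel SVM, naive Bayes, and
gradient-boosted trees — through a shared, seeded, stratified 10-fold
partition, so every algorithm sees identical folds. Inside each fold,
min–max normalization parameters are fitted on the training part only
and ADASYN augments the training part only; validation rows are never
normalized with their own statistics, never augmented, and remain
byte-identical whether augmentation is on or off (asserted in the
suite). Hyperparameter grids cover the conventional ranges per
algorithm (tree: minsplit 2–50, minbucket 1–20, cp 1e-4–1; forest:
4–100 trees, mtry 2–7, nodesize 1–5; radial SVM: gamma 0.01–1.5;
polynomial SVM: coef 0.1–2, degree 2–5; boosting: depth 1–25, eta and
L2 penalty in [0,1]; naive Bayes has none) with coarse default steps
where only interval endpoints are conventional — the suite is a plain
list of fit/predict closures and fully overridable, and a reduced
`"fast"` preset exists for quick runs.

The best grid point per model maximizes mean fold Cohen's kappa, with
mean AUC as tiebreaker — kappa is preferred as the selection metric
because it discounts chance agreement on imbalanced data. Both
statistics are implemented from their definitions
(\(\kappa = (p_o - p_e)/(1 - p_e)\); rank-based AUC with ties counted
1/2) and cross-checked against an independent ROC implementation in
the tests. The ensemble takes the top two models by the same
criterion and averages their severe-class probabilities into the
Severity Score; averaging two models with decorrelated errors reduces
score variance (a convexity fact asserted in the suite). Selecting
members by held-out kappa is a design choice: an external challenge
set, when available, can override member choice by passing a custom
two-model suite. SVM probabilities come from the usual Platt-style
sigmoid fit; all stochastic learners are seeded from the master seed,
and prediction is RNG-free.

## Gray-zone abstention

A trained scorer can trade coverage for accuracy: scores in a zone
\([lo, hi)\) are called "unknown" rather than forced into a class.
`sweep_thresholds()` evaluates every cutoff pair on a grid (default
step 0.01, matching the two-decimal resolution at which such zones
are conventionally reported) and records per-class accuracy among
classified instances, coverage, and abstention count; a class with no
classified instances reports missing accuracy, never zero.
`select_gray_zone()` maximizes the smaller of the two per-class
accuracies subject to a coverage floor (default 0.5), breaking ties
toward larger coverage and then narrower zones — the published
procedure states only that the zone gave the best classification of
both classes, so the max–min criterion is this package's
formalization, and it is configurable. The landscape is permutation-
invariant and coverage is monotone non-increasing under nested zones.

## Saturation scan

`saturation_scan()` enumerates the 19 substitutions at every position
whose fourteen structure-side features are complete (positions with
any missing feature — chain termini without torsions, residues
without conservation — are skipped and tallied), so the row count is
exactly 19 × the number of complete positions. Within a position only
the mutant identity, its distance, and hence the score vary.
`annotate_structure()` writes per-position aggregated scores (mean
over the 19 substitutions by default; max is available — the choice
of aggregation for display is a convention, not a model claim) into
the PDB B-factor column as score × 100 with two decimals, leaving
every other byte unchanged; unscored residues get the sentinel −1.00.

## The synthetic-data generator

The fixtures module exists so the whole pipeline is testable without
downloads. `make_toy_structure()` builds ideal-geometry backbones
(standard bond lengths/angles, ω = 180°) in helical (φ = −57°,
ψ = −47°), extended (φ = ψ = 180°), or seeded random-coil
conformations, with N/CA/C/O and CB atoms and seeded B-factors.
`make_toy_property_table()` plants a known factor rank when asked.
`make_synthetic_mutations()` labels sampled substitutions with a
logistic model in standardized degree (+), conservation (−) and
substitution distance (+) — deliberately a subset of the features, so
feature-importance checks have a known answer — mirroring the
empirical directionality that severe variants concentrate at buried,
highly connected, conserved positions and chemically dissimilar
replacements. With `severe_fraction` set, labels are the top quantile
of the latent score (exact imbalance control; noise-free labels are
linearly separable); otherwise Bernoulli draws. Activities are then
drawn within the label's clinical band.

What the generator does **not** emulate: real side-chain packing and
real contact topology (toy coils are far less densely connected than
a folded 1336-residue protein), correlated measurement error in
clinical activity assays, database heterogeneity (one record per
mutation, single dialect), and any non-logistic relation between
features and outcome. Passing tests on these fixtures therefore
demonstrates that the machinery is correct — contracts, invariants,
leakage-freedom, recovery of known signal, honesty on pure noise —
not that any particular accuracy will transfer to clinical FVIII
data, where published experience is cross-validated accuracies in the
66–87% band and roughly 60% on fully held-out reports under
abstention.

## Problem sizes and numerical choices

The suite and the acceptance script run on deliberately small
problems chosen to exercise every code path: 40–60-residue toy
structures, 240-point surface sampling (960 for the analytic check),
300–400-row mutation tables, the reduced `"fast"` grid preset with
10-fold cross-validation, and exhaustive graph enumeration up to 6
nodes (all 33 000 labelled graphs) plus 200 random graphs up to 8
nodes for the constraint oracle. Determinism choices: golden-spiral
sphere points (no RNG in surface areas), power-iteration centralities
to 1e-12 via igraph's implementations, one master seed driving folds,
augmentation and stochastic learners, and RNG state always restored
after seeded generators. Degenerate inputs have defined behaviour
throughout: empty structures, single-class labels, minority classes
below two examples, zones that classify nothing, and expected-
agreement-one kappa all produce errors, warnings, or missing values
as documented rather than silent zeros.

## Known limitations

* `areaSES` is an approximation unless an external backend is
  plugged in.
* Contact-edge counts depend on contact semantics; only node-level
  conclusions are toolchain-portable.
* The component count of the property PCA is sensitive (±1) to the
  standardization convention; both are reported.
* Severity bands at the 1% and 5% boundaries are half-open by
  convention here; records exactly at a boundary are assigned to the
  upper band's lower edge deterministically but other conventions
  exist.
* The ensemble's absolute accuracy on real clinical data depends on
  the database snapshot and cannot be certified by synthetic tests.
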