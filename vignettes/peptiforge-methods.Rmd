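---
title: "Methods: in silico discovery and kinetic characterization of DPP-IV inhibitory peptides"
author: "peptiforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico discovery and kinetic characterization of DPP-IV inhibitory peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptiforge)
```

# The problem

Dipeptidyl peptidase-IV (DPP-IV) truncates the incretin hormones GLP-1 and
GIP, and inhibiting it is an established route to glycemic control in type 2
diabetes. Food proteins — here modelled on blood proteins such as hemoglobin
subunits and albumin — are precursors of short peptides that inhibit DPP-IV.
`peptiforge` implements the computational arm of a discovery workflow for
such peptides: theoretical proteolysis of the precursor proteins, a
database-frequency statistic for precursor ranking, a sequence-based
activity classifier, multi-criteria screening of peptidomics tables, and
enzyme-inhibition kinetics for mechanistic characterization of hits.

All stages are driven by synthetic-data generators, so the full pipeline is
testable without database downloads or instrument output.

# Rule-based proteolysis

A protease is modelled as a `cleavage_rule`: the bond after residue $i$ is
cut when residue $i$ belongs to the C-terminal specificity set or residue
$i+1$ to the N-terminal one, unless residue $i+1$ is vetoed (the
`blocked_p1prime` set, used for classic exceptions such as "no cut before
proline", and to encode bromelain's requirement of a basic P1' residue).
Four proteases ship as defaults — pepsin, trypsin, chymotrypsin, bromelain —
and an editable YAML registry (`inst/extdata/enzymes.yaml`,
`read_enzyme_rules()`) accepts any further specificity without code changes.
The trypsin default includes the His site as stated in the source rule
tables for gastrointestinal digestion prediction; the textbook Lys/Arg-only
variant with the proline veto is available via
`default_enzymes(classic_exceptions = TRUE)` and is off by default.

`digest()` at `missed_cleavages = 0` cuts every site, so the fragments
partition the parent (this is the property the tests verify on random
sequences and rules). With `missed_cleavages = k` every run of up to $k+1$
consecutive fully-cleaved fragments is also enumerated — the standard
proteomics convention for partial digestion.

## Sequential gastrointestinal digestion

`sequential_digest()` models the two-phase static digestion protocol:
a gastric phase (pepsin) followed by an intestinal phase (trypsin and
chymotrypsin acting together, so their site sets are pooled). With
`missed_cleavages = 0` digestion is complete and only terminal fragments
are reported. With any missed-cleavage allowance the phases are treated as
*incomplete*: every partial-digestion intermediate — any fragment delimited
by two cleavage boundaries, including the undigested input — may survive a
phase and is included in the reported set, and the stage-2 rules are applied
to each stage-1 product. This is a deliberate design choice: run-based
missed-cleavage counting underestimates which partial products a real,
kinetically heterogeneous digest can leave behind (sites differ greatly in
cleavage probability), whereas the boundary-delimited enumeration contains
exactly the fragments reachable by *some* sequence of cuts. For the
hexapeptide FPHFDL under the default rules this yields the full expected
product set (FPH, FDL, FPHF, FPHFD, DL) at `missed_cleavages = 1`.

The cost is that the output is a superset of what any single partial-digest
realization produces; downstream consumers should treat it as the set of
*candidate* surviving fragments.

# The bioactive-fragment frequency (A value)

For a protein of length $N$ and a database of known bioactive fragments,
$A = a/N$ where $a$ counts database motifs occurring as substrings of the
protein. Occurrences are counted per position (overlapping allowed) and
summed over motifs, the convention of the theoretical-digestion databases;
`a_value(count = "distinct_motifs")` switches to counting each motif once,
since database documentation leaves the convention ambiguous. Published $A$
values depend on the motif-database version, so the package ships only a
small synthetic fixture for tests and validates any user-supplied table
(`load_motif_db()`).

# PseAAC featurization

Each peptide maps to a 27-component pseudo amino acid composition vector:

- components 1–20: amino-acid composition terms, alphabetical by one-letter
  code;
- component 21: the weighted first-order hydrophobicity sequence-correlation
  factor;
- components 22–27: unweighted sequence means of hydrophobicity,
  hydrophilicity, residue mass, pK1, pK2 and pI.

With $f_u$ the relative frequency of residue $u$ and
$\theta_1 = \frac{1}{L-1}\sum_{i=1}^{L-1}\left(H(r_{i+1}) - H(r_i)\right)^2$
over hydrophobicity $H$ normalized to zero mean and unit variance across the
20 residues (population convention), the first 21 components are

$$x_u = \frac{f_u}{1 + w\,\theta_1} \;(u \le 20), \qquad
  x_{21} = \frac{w\,\theta_1}{1 + w\,\theta_1},$$

so components 1–21 sum to one. For a single residue $\theta_1 = 0$ by
definition. The weight $w$ defaults to 0.05, the common convention; it is a
parameter of `featurize()` because the upstream description omits it. The
layout (composition first, then the correlation factor, then the six
property means with mass at component 24 and Pro frequency at component 13)
is fixed so that feature indices are comparable across fitted models.

Components 22–27 use *raw* scale values so that the mass mean stays
interpretable in Daltons; only $\theta_1$ uses the normalized scale. The
default property tables are Kyte–Doolittle hydropathy, Hopp–Woods
hydrophilicity, free amino-acid average masses, and the standard
free-amino-acid pK1/pK2/pI tables; all are replaceable through a CSV
(`read_scales()`), since the choice of table is a modelling degree of
freedom, not a ground truth.

The `standardizer` stores per-feature mean and population standard
deviation from the training matrix and replays them verbatim at prediction
time; constant features are flagged and passed through centred but
unscaled.

# The classifier harness

Training peptides are labelled by the strict IC50 rule: active iff
IC50 $< 2000\,\mu M$. Four tree-ensemble algorithms are exposed through a
thin adapter interface — `gbdt` (exact depth-wise gradient boosting),
`xgboost` (histogram depth-wise), `lightgbm` (histogram leaf-wise /
loss-guided growth) and `rf` (random forest) — plus a deterministic
logistic-regression adapter used in tests. The adapter interface keeps the
harness logic (stratified folds, grid search, metrics, importances)
independent of any one library.

`cross_validate()` runs stratified 5-fold cross-validation of every grid
point, standardizing *inside* each fold (fitted on the training folds
only), and selects the grid point with the best mean out-of-fold ROC-AUC;
ties break by mean accuracy, then grid order. The default 3×3×3 grids over
depth, learning rate and rounds (trees/mtry/nodesize for the forest) are
software defaults — the source workflow does not publish its grids. AUC is
the rank statistic with ties counted one half; it is cross-checked against
an independent implementation in the test suite. The final model is refit
on the full standardized matrix, and `predict_candidates()` flags
candidates whose predicted probability reaches the confidence threshold
(default 0.9, echoing the ≥0.97 predicted values of reported hits;
configurable).

Everything downstream of the seed is deterministic: fold assignment,
boosting (single-threaded), forest fitting and prediction.

# Synthetic data: what it emulates and what it does not

`gen_labeled_peptides()` draws sequences with the two structural signatures
reported for DPP-IV inhibitory peptides — Pro/Ala at position 2 from the
N-terminus and hydrophobic termini — at class-specific probabilities
(defaults 0.7 vs 0.2 for position 2; 0.8 vs 0.4 per terminus), lengths 2–8,
and class-consistent lognormal IC50s (actives strictly below the 2000 µM
threshold). Default class sizes are 588/210, the proportions of the typical
curated training corpus. The hydrophobic set used by the generators is
fixed to A, V, L, I, P, F, M, W, G and documented here because published
"percent hydrophobic" figures imply a set they do not enumerate.

A consequence worth stating plainly: the 27-component representation is
composition-based and cannot directly encode *where* a residue sits, so the
position-2 signal reaches the classifier only diluted through composition
(one residue in $L$) and the correlation factor. Under the default effect
sizes the two classes therefore overlap substantially in feature space, and
cross-validated AUC plateaus well below what a position-aware encoding
could achieve. The harness sanity test accordingly uses the same generative
structure at maximal effect sizes (position-2 probability 1 vs 0,
hydrophobic termini 1 vs 0), where all four algorithms separate the classes
comfortably; the chance-level check uses permuted labels. Passing these
tests shows the harness learns exactly the structure the generator plants —
it does not certify performance on real curated datasets, whose negatives
are reported low-activity inhibitors rather than random sequences.

`gen_kinetics()` produces initial velocities on a substrate × inhibitor
design (defaults: substrate 0.025–0.4 assay units, inhibitor 0/400/800 µM)
under any of the five kinetic models, with mean-one multiplicative
lognormal noise; `cv = 0` is exact. `gen_peptidomics_table()` draws
abundance, score, length and sequence structure independently, so the
expected survivor fraction of the screening filter is the product of the
per-criterion tail probabilities — the property the filter tests exploit.
It does not emulate mass-spectrometry signal (charge states, co-elution,
intensity–sequence correlation).

# Screening

The peptidomics filter keeps a row iff abundance $> 10^7$ (relative
intensity), length $< 10$ residues, external bioactivity score $> 0.9$, and
Pro/Ala at position 2 — all inequalities strict, exactly as the criteria
are stated. Rejections are attributed to the first failed criterion in that
order (the survivor set is order-independent). Dipeptides participate in
the position-2 rule through their C-terminal residue, consistent with the
enzyme's Xaa-Pro/Xaa-Ala dipeptidase definition; single residues always
fail. The external score is an input column produced by a third-party
bioactivity predictor; the package never computes it.

# Inhibition kinetics

The primary estimator is a *global* nonlinear least-squares fit: one
$(K_m, V_{max}, K_i)$ (plus $\alpha$ for the mixed model) shared across all
inhibitor levels, for each candidate mechanism:

- competitive: $v = V_{max} S / (K_m(1 + I/K_i) + S)$
- non-competitive: $v = \frac{V_{max}}{1 + I/K_i}\cdot\frac{S}{K_m + S}$
- uncompetitive: $v = V_{max} S / (K_m + S(1 + I/K_i))$
- mixed: $v = V_{max} S / (K_m(1 + I/K_i) + S(1 + I/(\alpha K_i)))$

The double-reciprocal Lineweaver–Burk regression is used only for starting
values and diagnostics (`lineweaver_burk()`, `plot()`): the reciprocal
transform amplifies noise at low velocities and would be a poor estimator.
Mode discrimination is by small-sample-corrected AIC rather than by
eyeballing line-intersection geometry, which a program cannot do; the
intersection geometry remains visible in the diagnostic plot (competitive
families share the $1/V_{max}$ y-intercept, non-competitive families the
$-1/K_m$ x-intercept).

Two numerical choices matter. First, the AICc error variance is floored at
a $10^{-8}$ relative level so that noiseless data — where nested models all
fit to floating-point dust — resolve by parameter count instead of residual
noise; ties additionally break toward fewer parameters. Second, parameter
lower bounds are set at exactly 0: a tiny positive bound (e.g. $10^{-12}$)
destabilizes the bounded Levenberg–Marquardt scaling and can collapse fits
onto the bound.

Closed forms complement the global fit: `ki_competitive()` implements
$K_i = I/(K_m^{app}/K_m - 1)$ and `ki_noncompetitive()`
$K_i = I/(V_{max}/V_{max}^{app} - 1)$, with guards requiring an actual
inhibition signal ($K_m^{app} > K_m$, $V_{max}^{app} < V_{max}$). On clean
data the closed-form and global estimates agree to numerical precision — a
consistency test in the suite.

Dose-response IC50 (`fit_ic50()`) uses a logistic in $\log_{10}$
concentration with asymptotes fixed at 0 and 100, because the assay
normalizes residual activity to the uninhibited control; the fitted IC50 is
then exactly the 50%-activity concentration. A free-asymptote variant is
available by flag, and the reported IC50 is still the 50% crossing. A
monotonicity check warns when activity rises with concentration beyond
noise. The remaining assay arithmetic (percent inhibition from progress-
curve slopes, OPA degree of hydrolysis, Kjeldahl protein content with
$F = 5.7$, SEC molecular weight from the $\log_{10}MW$–retention-time
line) is implemented exactly as the formulas are printed, with units
carried as labels and never converted.

# Problem sizes and reproducibility

The test suite sizes its simulations to be informative yet quick: digestion
and A-value oracles run on 1,000 and 200 random cases; kinetics recovery on
100 seeded datasets per mechanism at 2% noise (24-point designs); harness
checks on 300–800 peptides; the filter equivalence on $10^5$ synthetic
rows. Every stochastic step takes an explicit seed, and the generators
restore the caller's RNG stream, so results are bitwise reproducible.

`scripts/acceptance.R` recomputes the two headline inhibition constants
from the printed uninhibited/apparent Michaelis–Menten parameters at the
400 µM inhibitor level and writes them as JSON.

# Known limitations

- Cleavage rules are deterministic site sets; per-bond cleavage
  probabilities (which real digestion kinetics exhibit) are out of scope,
  so partial-digest outputs are candidate sets, not abundance predictions.
- The classifier sees composition-level features only; position-specific
  sequence signals reach it indirectly (see above).
- The screening stage consumes external bioactivity scores; it cannot be
  better than the scorer feeding it.
- Kinetic fits assume multiplicative, homoscedastic-in-log noise and
  initial-velocity (not progress-curve) data; tight-binding corrections are
  not implemented.
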