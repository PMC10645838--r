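---
title: "Methods: fructan structure inference and band-table chemometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fructan structure inference and band-table chemometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agavin)
```

This vignette is the package's account of its own methods: the residue-tree
model and its assumptions, the inference procedure and its rounding
conventions, the chemometrics implementation, the synthetic-data model and
its defaults, and the numerical choices made where the design was genuinely
open.

## The residue-tree model

A fructan is represented as a connected acyclic graph of hexose residues
with at most one glucose. Edges are *donations*: each residue attaches
through its anomeric carbon (fructose C2, glucose C1) to a named acceptor
position — fructose C1 or C6, glucose C6. The glucose-donor edge is the
sucrose moiety's anomeric–anomeric bond and lands on a fructose C2, which
is not a substitution of that fructose. A residue's linkage class follows
from its substituted positions alone: fructose with none is `t_fruf`, with
C1 `b21_fruf`, with C6 `b26_fruf`, with both `di_fruf`; glucose with a free
C6 is `t_glcp`, with an occupied C6 `i_glcp` (the *neo* attachment). The
class census of a structure therefore always sums to its DP.

**Ring chemistry is out of scope.** Anomeric configuration beyond the α/β
labels implicit in the class names, ring conformation and 3-D geometry are
not modelled; the object exists to make linkage censuses and topology
predictions explicit and testable.

### Which censuses are tree-realizable

Every edge occupies exactly one acceptor position, and in a
glucose-containing structure exactly one edge (the sucrose bond) occupies
an anomeric position. Counting positions on both sides gives a hard
constraint on any census: the substituted positions
(`b21 + b26 + 2*di + i_glcp`) must equal DP − 2. Rearranged, this is

```
t_fruf = di_fruf + 1            (terminal glucose)
t_fruf = di_fruf + 2            (internal glucose)
```

together with the requirement that levan (`b26`) residues have a branch
residue to hang from. `assemble_core()` enforces these conditions and
raises an infeasibility error naming the violated one. A direct consequence
worth stating plainly: *an internal glucose consumes one extra acceptor
position*, so the "same counts, glucose now internal" reading of an average
agavin is not chemically realizable. `propose_structures()` therefore
builds the agavin counterpart of a graminan core by adding one terminal
fructose on the glucose C6 — the DP-7 graminan core pairs with a DP-8
agavin core. This is a deliberate modelling decision, documented here
because drawn "average" structures in the literature sometimes gloss over
the position accounting.

### Canonical assembly layout

`assemble_core()` is deterministic: glucose at the root, attached to the
head of a single inulin backbone; branch (`di`) residues sit at the
glucose-proximal end (placed evenly when there are several, which does not
occur in the worked example); each branch carries one levan side chain
(`b26` residues split evenly across branches) capped by a terminal
fructose; the backbone is capped by a terminal; an internal glucose takes
one further terminal on its C6. This layout matches the drawn convention
for graminan/agavin cores — inulin chains with short levan branches — and
makes `census(assemble_core(c)) == c` a testable round-trip for every
realizable census.

### Extending a core to the chromatographic maximum DP

The maximum countable DP from anion-exchange chromatography (default 20)
can be reached two ways, and the package deliberately offers both because
the underlying procedure is ambiguous about where the extra residues go:

- **backbone** (default): insert 2→1 fructoses at the glucose-proximal end
  of the inulin backbone until the target DP is reached. This is the
  minimal-assumption reading ("the inulin chain is at least n units
  longer").
- **proportional**: multiply all non-glucose class counts by
  `target_dp / dp(core)`, re-apply the molecule-assignment rounding, and
  reassemble. Scaled counts usually violate the terminal/branch identity
  above (e.g. 20/7 scaling of the DP-7 core rounds to 6 terminals against
  3 branches); the excess terminals are converted to 2→1 backbone units,
  which preserves the scaled DP and keeps the result a valid tree.

Neither mode is asserted as "the" intended structure; the backbone mode is
the default used in reports.

## PMAA classification

The rule cascade mirrors how an analyst reads these electron-impact
spectra: the base peak separates glucitol (m/z 102) from fructose-derived
(m/z 129) backbones; m/z 233 flags the extra C6 acetylation of an internal
glucose and m/z 205 the C2–C3 cleavage of the terminal glucose derivative;
m/z 189 and 190 flag O6 vs O1 acetylation on fructose, their co-occurrence
with the 161/162 epimer pair separating the convolved (2→6/1) peak from the
genuine 1,6-di branch residue. m/z matching is exact integer (the spectra
are unit-mass). When no rule fires, the best cosine match against the
packaged reference library is used, and below cosine 0.5 the result is
`"unclassified"` rather than an error — a batch run should not die on one
noisy spectrum. All eight reference entries classify by rules alone; the
cosine path exists for degraded inputs.

Quantification assumes **equal molar GC response** across PMAA derivatives
(no response factors are available for this derivative set), pools the two
terminal-fructose epimer peaks, and splits the convolved glucitol peak
between the 2→1 and 2→6 classes in proportion to their resolved mannitol
epimer peaks (50/50 when both are absent).

## The inference procedure

Per sample: molar percentages are divided by the summed glucose percentage
(`normalize_to_glucose()`; F-series inputs with no glucose are rejected,
not silently renormalized to another denominator); the ratio sum is the
core DP (`core_dp()`, one decimal); integer molecule counts follow
`assign_molecules()`.

Numerical conventions, fixed once:

- **Rounding is half-up**, not banker's: 2.5 → 3 (`round_half_up()`),
  matching the verbal rule "decimals ≥ 0.5 round to a full number".
  Internal arithmetic is full precision; only reported values are rounded
  (ratios and DPs to one decimal, the scale factor to two).
- **Both standard-deviation conventions** (n−1 and n) are computed and
  reported side by side, because reported spreads for this kind of table
  mix conventions across rows; the sample (n−1) convention is the default
  in print methods. Nothing in the package depends on the choice.
- The **scale factor** uses the one-decimal reported mean DP as its
  denominator (e.g. 20/7.2 = 2.78), because the procedure it implements
  chains reported values, not full-precision intermediates. The scaled
  counts are insensitive to this choice here.
- `branching_frequency()` is the plain ratio of the 2→1 to the 1,6-di
  ratio (its reciprocal-minded reading — "a branch every N backbone
  units" — is left to the user); an unbranched composition returns `Inf`
  rather than an error.

## Chemometrics

`pareto_scale()` centers and divides by the square root of the sample
standard deviation; zero-variance columns are dropped with a warning
(an all-constant matrix is an error). PCA is `stats::prcomp()` on the
already-scaled matrix, with explained-variance shares per component.

`fit_oplsda()` implements single-response O-PLS by NIPALS: each orthogonal
component is the part of the X-loading orthogonal to the predictive weight,
deflated from X; one predictive component is then fitted on the filtered
matrix. Choices that needed fixing:

- **Cross-validation is 7-fold, stratified**, with fold assignment by a
  seeded within-class shuffle dealt round-robin — reproducible bit-exactly
  under a fixed seed. The matrix is scaled once, outside the CV loop, as is
  conventional in the software family this models; with Pareto scaling and
  the small n typical of plate data the difference is negligible.
- **Q²** = 1 − PRESS/SSY over the cross-validated predictions of the
  centered ±1 class code.
- The **S-plot** uses covariance and correlation of each *scaled input*
  variable with the predictive score (not the orthogonality-filtered
  matrix).
- The **permutation test** shuffles labels only and refits the full
  CV pipeline per permutation; p = (1 + #{Q²perm ≥ Q²obs})/(n_perm + 1),
  so 100 permutations bound p below by 1/101.
- **CV-ANOVA** compares (SSY − PRESS) against PRESS with degrees of
  freedom K = 1 + n_orth (model components) and N − K − 1 (residual);
  models with PRESS ≥ SSY get p = 1, a degenerate zero-variance response
  warns and returns p = 1.
- Default validity thresholds Q² ≥ 0.40 and p ≤ 0.05 are recorded on the
  model and used only for pass/fail flags in reports.

`rf_to_dp()` interpolates monotonically through the four anchor bands
(DP-1 at Rf 0.57, DP-2 at 0.51, DP-3 at 0.40, DP-11 at 0.09) and rounds to
the nearest integer DP; anything below Rf 0.09 lies in the application
point zone and is reported as ">11 (application point)" rather than an
extrapolated number.

## The synthetic-data model

`generate_structure()` grows a molecule from sucrose: a geometric number of
2→1 backbone units (mean `mean_backbone_len`), each unit with a chain
continuation branching at C6 with probability `branch_prob` into a levan
chain of geometric extra length (`levan_branch_len_mean`) plus its terminal
cap, and with probability `neo_fraction` a terminal fructose on the glucose
C6. The chain tip never branches: a tip branch would produce censuses with
levan residues but no branch residue, which the canonical assembler
(deliberately) rejects, and it would add nothing to the structural
repertoire the model targets.

The per-molecule expected census is closed-form
(`expected_mixture_census()`): with backbone mean β, branch probability π,
levan mean λ and neo probability ν,

```
E[2-1] = β(1-π)   E[di] = βπ   E[2-6] = βπλ
E[t]   = 1 + βπ + ν   E[tG] = 1-ν   E[iG] = ν
```

Defaults were chosen once by matching these expectations to the worked
example's average composition: β = 2.8 and π = 3/14 give E[2-1] = 2.2 and
E[di] = 0.6; λ = 0.5 gives E[2-6] = 0.3; ν = 0.5 encodes the observed 1:1
terminal/internal glucose split; populations of 2000 molecules; per-sample
noise is multiplicative lognormal with CV 5%, in the range suggested by the
worked example's between-sample spread. Lognormal noise was picked for
positivity and its direct CV parameterization.

What the simulators emulate — and what they do not. They reproduce the
*compositional* structure of linkage tables (single population composition,
multiplicative replicate noise, renormalization to 100%), intensity-jittered
reference spectra with protected diagnostic ions, and two-class band tables
with multiplicative class effects (old samples enriched ≥1.5× in the low-Rf
window, depleted to ≤0.67× in the simple sugars). They do **not** emulate
GC response-factor bias, retention drift, co-elution beyond the one
convolved peak, correlated noise across classes, plate-to-plate HPTLC
variation, or real biological covariance between linkage classes — so
passing recovery tests demonstrates that the *procedures* are correct and
well-conditioned at realistic noise, not that real measurements carry no
systematic error.

## Problem sizes and test design

The test suite exercises the round-trip property on 1000 generator
censuses, DP conservation on the same draws, Monte-Carlo agreement of the
generator with its analytic census at 10⁴ draws (5% relative), parameter
recovery at n = 6 samples and 5% CV, OPLS-DA gates at 6 samples per class
with 100 permutations, and a 20-replicate null study of the permutation p.
These sizes were chosen to make the stochastic assertions comfortably
stable under their fixed seeds while keeping the default suite quick on a
laptop; they are package choices, not statements about any instrument's
throughput.

## Known limitations

- The molecule-assignment rule ("anything in (0,1) is one molecule") makes
  rare classes count fully in every structure; the proposed cores are
  *average* structures of a mixture, not claims that every molecule carries
  each motif.
- The terminal/branch feasibility identity means assigned counts cannot
  always be realized verbatim (see the agavin DP-8 note above); reports
  always state the census of what was actually built.
- Multi-class OPLS-DA, baseline correction of band tables and plate-image
  densitometry are out of scope; band tables are ingested as given.
- The Rf→DP calibration is plate-convention specific; anchor values are
  arguments to change, not constants of nature.
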