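---
title: "Predicting unnatural amino acid substitution sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting unnatural amino acid substitution sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaaScreen)
```

# The model

A site-specific NAA → UAA substitution either yields detectable expression
of the UAA-bearing protein or it does not.  `uaaScreen` treats this binary
outcome as a Bernoulli response and models it with logistic regression on
16 observed variables, expanded into 21 numeric columns:

$$\log\frac{P}{1-P} = b + \sum_i k_i V_i$$

The variables fall into three blocks.

**Evolutional tolerance.** `entropy` is the Shannon entropy
$-\sum_a p_a \ln p_a$ of the amino-acid distribution in the site's
alignment column, collected from a BLAST XML result or an aligned FASTA.
Low entropy marks a conserved — and typically intolerant — site.  The query
residue is always counted; hits are unweighted; gaps and ambiguity codes
are excluded from the frequencies rather than treated as a 21st symbol.
The natural-log base is the default (configurable to log2); the choice only
rescales the fitted coefficient, since the model is linear in the feature.

**Steric environment.** `rasa` is the residue's solvent accessible surface
area (Shrake-Rupley) divided by its residue-type theoretical maximum
(Tien et al. 2013 values, overridable), clamped to [0, 1].  `hsebup` and
`hsebdn` are the half-sphere exposure beta counts: the number of other
residues' Cα atoms within 12 Å of the site's Cα, split by the plane
perpendicular to the Cα→Cβ direction (a virtual Cβ is constructed from
backbone geometry for glycine); a boundary dot product of exactly zero
counts as "down".  The secondary-structure class enters as three dummies
(`isHelix`, `isStrand`, `isTurn`) with coil as the all-zero reference.

**Physiochemical change.** Eight descriptors characterize each amino acid
as a free molecule: AlogP, E-state sum, polar surface area (Å²), molecular
polarizability (Å³), hydrogen-bond acceptor/donor counts, rotatable bonds
and molecular weight (Da).  Seven enter as plain differences UAA − NAA;
molecular weight enters as the relative difference
$(MW_U - MW_N)/MW_N$, making the feature scale-free.  `uaasimi` is the
Tanimoto coefficient of the two binary fingerprints.  Descriptors refer to
the whole amino acid (with backbone), not the side chain alone, which is
what the relative-weight formula presumes.

**Context.** The expanded codon (`isAmber`, `isOchre`, `isOpal`; reference
"other") and the evidential grade of the record (`isDirect`, `isIndirect`;
reference "other", covering auxotrophic and ligated-tRNA routes).

## Fitting and regularization

The fit maximizes the penalized likelihood with a ridge term
$\tfrac{\lambda}{2}\lVert k \rVert^2$ on the coefficients (never the
intercept), by Newton/IRLS with step halving.  The default $\lambda = 1$
on unstandardized features mirrors the default objective of the
machine-learning toolchains this kind of pipeline is usually built with;
both the strength and an optional column standardization are exposed, and
all tests state their configuration explicitly.  Standard errors come from
the inverse of the penalized Fisher information at the optimum.

A deliberate design choice is the **decision rule**: success is called
when $p \ge$ cutoff (inclusive), everywhere in the package.  The cutoff is
chosen by scanning all candidate thresholds — midpoints between adjacent
distinct predicted probabilities, plus 0 and 1, which covers every
achievable confusion matrix — and maximizing sensitivity + specificity,
ties resolved to the smallest threshold.  On success-dominated training
data the cutoff lands far above 0.5 (about 0.84 under the package's
default study conditions); on balanced resamplings it falls near 0.5.
Screening output therefore always carries the training cutoff in its
provenance.

## The efficiency model

Where records carry a measured incorporation efficiency E (expression
relative to wild-type; values > 0.01 count as success), a second model
performs ridge least squares of $\log(E+1)$ on the same 21 columns.
Predictions map back through $\max(0, e^\eta - 1)$.  The transform keeps
the non-negative, right-skewed efficiency scale well behaved near zero;
the clamp handles linear predictors below zero.  Records are selected by
quality tier ("exact" protein-yield values vs "coarse" grayscale
estimates) before fitting.

# Structure features: numerical choices

* **Shrake-Rupley**: each atom's solvated sphere (van der Waals radius +
  1.4 Å probe) is sampled with a deterministic Fibonacci lattice — no RNG,
  so ASA values are exactly reproducible.  960 points is the production
  default; the test suite checks that the total per-structure ASA at 960
  points stays within 2% of a 10,000-point reference on every packaged
  fixture.  Unknown elements are an error unless a fallback radius is
  given.
* **Assembly-wide burial**: ASA and half-sphere exposure use all chains in
  the file, so complex-context burial is obtained simply by supplying the
  complex structure.  Single-chain analysis is available by selecting a
  chain at parse time.
* **Residue addressing** keeps the author numbering of the source file
  (this is the numbering substitution records cite); insertion codes are
  appended to the position key.  Alternate conformers resolve to the
  highest occupancy; the first model of multi-model files is used.
* **Secondary structure** is assigned from backbone hydrogen bonds using
  the classic electrostatic bond energy (bond when E < −0.5 kcal/mol);
  runs of i→i+3/4/5 turns make helices, bridge patterns (parallel and
  antiparallel, including inter-chain) make strands, isolated turns make
  turns, and everything else — including residues with missing backbone
  atoms — is coil.  An external DSSP file can be supplied instead, whose
  8-state letters reduce as H,G,I → helix; E,B → strand; T,S → turn
  (S → turn is a choice, revertable by flag).  The 3-class reduction is
  all the model consumes.

# The synthetic study conditions

The curated experimental databases this kind of model is trained on are
not redistributable, so the package defines its study conditions through
generators whose defaults are fixed once:

* **Structures**: ideal poly-residue helices (φ/ψ = −57°, −47°) and
  antiparallel two-strand sheets (φ/ψ = −139°, 135°) built by natural
  extension (NeRF) with Engh-Huber-style bond geometry; the sheet's second
  strand is placed by a deterministic grid search over the 2-fold rotation
  axis, separation and register that maximizes the package's own
  hydrogen-bond count (with a steric clash guard).  The standard test
  world is a 60-residue helix covering all 20 NAAs plus an 8+8 sheet.
* **Alignments**: at each site the query residue is retained with the
  site's conservation probability, otherwise replaced uniformly by one of
  the other 19 residues.
* **Database**: records are sampled uniformly over sites, the 12
  registered UAAs, codon types (TAG 0.8, TAA 0.1, TGA 0.05, other 0.05)
  and proof levels (direct 0.6, indirect 0.3, other 0.1); publication
  dates are uniform over 2002–2021 and independent of the features, making
  the generative process stationary in time.  Outcomes are Bernoulli draws
  from a fixed ground-truth logistic model; the intercept is calibrated by
  root finding so the mean success probability hits the target prevalence
  of 0.87 (the class ratio of the curated literature corpus this emulates,
  roughly 1064:157) — the coefficients are never altered by calibration.
  Every simulation returns its realized Bayes AUC and emits a JSON sidecar
  of its generative parameters, so tests never hard-code hidden numbers.
* **Chemistry**: descriptors, 2048-bit linear-path (length ≤ 7)
  fingerprints and their Tanimoto matrix for the 20 NAAs and 12
  representative UAAs were computed once from structure line notation and
  frozen into versioned CSVs under `inst/extdata/` (filenames carry the
  `_synthetic` tag).  Imported tables always take precedence over the
  optional Open Babel backend (`computeDescriptorsOB()`), which computes
  only the descriptor subset Open Babel supports and FP2 fingerprints
  (1024-bit linear paths) — useful for registering new UAAs, but never
  asserted to match any external export.

What the generators deliberately do **not** emulate: real evolutionary
covariation (sites are independent), structural flexibility (features come
from one rigid conformation), aaRS/tRNA system compatibility, codon
context, and reporting biases of the literature.  Green tests on synthetic
data therefore certify the *correctness of the machinery* — feature
computation, fitting, cutoff and ROC logic, splitting and screening — not
the real-world predictive performance of any particular trained model.

# Validation battery

* **Repeated holdout** (default seeds 0–99): per round an 80/20 split
  (train size rounded half-up), fit on the training rows, metrics on the
  test rows.  Whether the reported cutoff/accuracy are computed at the
  test-panel optimum (the reporting default, matching how validation
  panels are usually displayed) or frozen from the training cutoff is a
  flag, since both conventions are defensible.
* **Repeated balanced resampling**: all minority-class records plus an
  equal-size uniform sample of the majority class per seed; fit and
  evaluation on the same subset (the in-sample convention such panels
  use), with an out-of-sample variant behind a flag.
* **Timesplit**: train on records published strictly before the split
  date, test on the rest; records without dates are excluded with a
  warning.  On a stationary synthetic database the train/test AUC gap
  stays within 0.05.
* **Reporting statistics**: PCA of the standardized feature matrix
  (constant columns dropped with a warning) with top-2 explained-variance
  ratios; probability quartiles per class; Mann-Whitney U with exact
  two-sided p-values for small tie-free samples (n₁·n₂ ≤ 400) and the
  tie/continuity-corrected normal approximation otherwise.  The tool warns
  when a training set has fewer than 10 rows per feature column.

# Screening

`predictFullMatrix()` scores every registered UAA against every site with
complete features.  Codon type and proof level are properties of the
*planned experiment*, not of the site, so screening assumes a context —
default TAG (by far the most common suppression system) and direct proof —
which is configurable and always recorded in the output provenance.  The
two ranking strategies (`fixed_uaa`, `fixed_site`) sort by probability
with deterministic tie-breaks (site order, then UAA code) and accept a
probability threshold; raising it to 0.90–0.95 trades recall for a
high-confidence candidate list.

# Problem sizes and determinism

The shipped tests and the acceptance script run on fixed problem sizes
chosen to exercise every property at comfortable statistical margins:
5,000-record simulations for coefficient recovery (each fitted coefficient
within 3 standard errors of truth), 1,221-record simulations for the
cutoff-location contrasts, 4,000 records for timesplit stationarity, 100
rounds for the repeated validations, and 100–200 random instances for the
cutoff and AUC oracles.  Every stochastic step takes an explicit seed and
restores the caller's RNG state, so identical inputs and seeds reproduce
identical artifacts byte for byte.

# Known limitations

* The logistic model is linear in the features: no interactions, no
  nonlinear effects, by scope.
* Predictions inherit the rigid-structure assumption; flexible or
  disordered regions will look more buried than they behave.
* Screening a protein whose structure file lacks binding partners
  overstates exposure; supply the complex when burial in context matters.
* The efficiency model is a pilot: on realistic noise levels its
  correlations are modest, and it should be read as a ranking aid rather
  than a quantitative yield predictor.
* Entropy mapping between sequence numbering and author numbering assumes
  the structure's chain is a contiguous window of the query sequence
  (no indels); structures with internal gaps relative to the FASTA need a
  pre-aligned site-feature CSV instead.
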