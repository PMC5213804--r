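---
title: "Partitioning trait variation between phylogeny and ecology with canonical phylogenetic ordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variation between phylogeny and ecology with canonical phylogenetic ordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cpord)
```

## The question and the model

Closely related species resemble each other. When a block of life-history
traits varies across a community, two classes of explanation compete:
present-day ecology (habitat, substrate, climate) and shared ancestry
(phylogenetic inertia). `cpord` quantifies the two contributions — and
their overlap — for a multivariate trait table, using constrained
ordination.

The engine is **redundancy analysis (RDA)**. Let $Y$ be the $n \times p$
species-by-trait matrix, column-centred (and optionally standardised),
and $X$ an $n \times q$ explanatory matrix. RDA regresses every trait
column on $X$ by least squares and performs a PCA of the fitted values
$\hat Y = P_X Y$. The *total inertia* is the sum of trait variances,
$I = \mathrm{tr}(Y^\top Y)/(n-1)$; the *explained fraction* is
$\mathrm{tr}(\hat Y^\top \hat Y)/\mathrm{tr}(Y^\top Y)$, and the
canonical eigenvalues decompose the explained part along orthogonal
axes. Significance uses the pseudo-F statistic

$$F = \frac{\text{explained inertia}/q}{\text{residual inertia}/(n-1-q-p_W)},$$

whose null distribution is obtained by Monte-Carlo row permutations
(add-one convention: $p = (k+1)/(m+1)$ where $k$ of $m$ permutations
reach the observed $F$).

**Canonical phylogenetic ordination (CPO)** is RDA whose explanatory
matrix is built from a rooted phylogeny: one binary column per clade,
marking the species that descend from that node. Because clades are
nested, the columns form a laminar family, and the tree's topology — not
its branch lengths — is what enters the analysis. **Partial CPO** fits
the clade matrix after projecting out ecological covariables (or vice
versa), which yields the classical two-set variance partition: with
$R_{phy}$, $R_{eco}$ and $R_{joint}$ the explained fractions of the
phylogeny-only, ecology-only and combined models,

$$A = R_{joint} - R_{eco}, \quad
  B = R_{joint} - R_{phy}, \quad
  C = R_{eco} + R_{phy} - R_{joint}, \quad
  U = 1 - R_{joint},$$

so $A + B + C + U = 1$ identically. $A$ and $B$ are the unique
(partialled) contributions, $C$ the shared, inseparable part, and the
unique fractions equal the explained fractions of the corresponding
partial RDAs — an identity of the projection algebra that the test suite
asserts to $10^{-10}$. $C$ can be negative in pathological data; it is
reported as computed, never clamped.

## Trait coding

The worked example codes a reproductive trait block as: mean fecundity
(numeric), reproductive mode (oviparous/viviparous dummies),
reproductive frequency (annual/biennial dummies — a species is biennial
when at most half of its mature females are reproductive within the
breeding season) and reproductive potential class (low/medium/high
dummies of the value $\mathrm{MF} \times \mathrm{RF}$, with boundaries
$<5$ / $[5,10]$ / $>10$; the closed middle interval makes the published
open-interval rule total). Categorical variables keep **all** levels
(full redundant dummy coding) so that, e.g., both an "oviparous" and a
"viviparous" arrow appear in triplots; the resulting rank deficiency is
handled by pseudo-inverse projection with a relative singular-value
tolerance of $10^{-8}$, and the constrained dimension $q$ is the
numerical rank, anchored to the pre-conditioning scale of the
explanatory block so that a fully partialled-out matrix has rank zero.

Two codings matter in practice and both are exposed:

* `scaling = "covariance"` (the default of `cpo_analysis()`): columns
  are centred only. This is a variance-covariance RDA, the form under
  which the packaged example's published analysis was run; the numeric
  fecundity column then carries more inertia than any dummy.
* `scaling = "correlation"`: columns are standardised, giving every
  variable equal weight. `response_matrix()` defaults to this scaling
  for general use, since with traits on wildly different scales the
  covariance form lets one column dominate.
* `frequency = "binary"` vs `"numeric"`: the frequency enters either as
  the annual/biennial dummies (default, matching how the categorical
  classification is defined) or as the raw proportion.

## Clade candidates, forward selection, and the resolution floor

`clade_indicators()` emits one column per internal node (the all-species
root column is constant after centring and always dropped). Candidate
sets are configurable: `labelled_only = TRUE` restricts to nodes with
explicit names (tribes and genera in the packaged tree), and
`min_size = 1` admits single-species clades carried as labelled unary
branches — necessary because a single-species tribe can be a legitimate,
even dominant, explanatory variable.

`forward_select()` adds, at each step, the candidate with the largest
additional explained inertia (exact ties broken by label order, making
the procedure invariant to candidate column order), admits it if its
*conditional* permutation p-value — computed under the reduced-model
scheme, permuting residuals of the already-selected model — is at most
`alpha`, and stops otherwise. Each step draws from a fresh seeded
substream (`seed + step - 1`), recorded in the output.

One numerical fact shapes the defaults. A permutation test over $n$ rows
of a **single-species** indicator has only $n$ distinguishable
configurations, so with the add-one convention its p-value concentrates
near $1/n$ — about $0.059$ for $n = 17$ — and can never settle below it.
A strict $\alpha = 0.05$ therefore rejects every single-species clade at
$n = 17$ no matter how much inertia it explains, and on the packaged
dataset returns an empty selection. `forward_select()` keeps the honest
default `alpha = 0.05`; `cpo_analysis()` screens clades at
`clade_alpha = 0.10`, a deliberate, documented choice that admits
candidates sitting at the resolution floor (the subsequent variance
partition, not the screening test, quantifies their contribution), while
the ecology stage keeps `eco_alpha = 0.05`. Users wanting the strict
convention set `clade_alpha = 0.05`.

The selection table reports *sequential* (conditional) contributions —
each step's added fraction of total inertia, which sum exactly to the
selected model's joint fraction. The marginal (each-clade-alone) table
is computed alongside by `clade_tests()`; the two coincide only for the
first selected clade.

## Axis shares

"The first two axes explained x%" is ambiguous between two
denominators: the canonical (fitted) variation and the total inertia.
`axis_fraction()` defaults to the canonical denominator and offers
`denominator = "total"`; on the packaged example the two differ
substantially (the selected-clade model concentrates >99% of its
canonical variation on two axes, which carry ~72% of total inertia).

## The packaged example

`snake_fixture()` loads a 17-species temperate South American
xenodontine snake community (918 mature females; six tribes, nine
genera) and a tribe/genus-level tree. Running

```{r example, eval = FALSE}
fx <- snake_fixture()
res <- cpo_analysis(fx$traits, fx$tree, permutations = 9999, seed = 1)
res
```

selects the single `aquatic` substrate dummy in the ecology stage
(~30.8% of total inertia), then three clades — the single-species tribe
Hydrodynastini (42.3%), the tribe Hydropsini (+20.5%) and the genus
*Xenodon* (+9.4%), jointly 72.2% — and partitions the variance into
roughly 46% unique to phylogeny, 4% unique to ecology, 27% shared and
24% unexplained. The triplot reproduces the expected geometry: the
aquatic arrow points with the viviparous arrow (the aquatic tribes are
the live-bearing ones) and against the *Xenodon* arrow (a
terrestrial/fossorial genus).

Two transcription notes on the fixture. First, one species
(*Erythrolamprus poecilogyrus*) is published with a
reproductive-potential class that contradicts the classification rule
applied to its own published fecundity and frequency; the table keeps
the published letter and flags the row (`rp_printed_mismatch`) instead
of silently correcting it — the analysis is insensitive to the choice
(<0.1 percentage point on every fraction). Second, the published
backbone of the phylogeny is not fully resolved at the inter-tribal
level; the packaged Newick encodes only the certain groupings (tribes,
genera, and Hydrodynastini sister to Pseudoboini) with a root polytomy.
Any alternative hypothesis can be supplied as a Newick file.

## What the simulator emulates

`simulate_dataset()` builds datasets with known ground truth for
recovery testing: a pure-birth (Yule) ultrametric tree; latent traits
$z = a\,\mathrm{std}(\mathrm{BM}) + b\,\mathrm{std}(\text{effect}) +
\varepsilon$ where BM is a Brownian-motion trait evolved branch-wise
along the tree, the effect term gives each ecological category its own
level, and $\varepsilon$ is i.i.d. normal noise — so the latent variance
decomposes as $a^2 : b^2 : \sigma^2$ and the `truth` element is directly
interpretable. Ecological categories are either concentrated on
subtrees (`eco_clustered_on_tree = TRUE`, reproducing the
ecology-confounded-with-phylogeny structure that makes the shared
fraction $C$ large) or assigned i.i.d. Continuous traits are affine
transforms of latents; categorical traits threshold latents at quantiles
(about 30% of species become viviparous, echoing the 5-of-17 split in
the packaged community). Defaults — 17 species, $a = 1$, $b = 0.5$,
$\sigma = 1$, two clustered ecological categories — mirror a community
in which phylogeny dominates but ecology is present and partially
confounded with it.

The simulator deliberately omits several features of real comparative
data: no character-state (Mk-type) evolution for categoricals, no
Ornstein-Uhlenbeck attraction or rate shifts, no extinction, no
measurement error correlated across traits, and no missing data.
Passing recovery tests therefore show that the pipeline attributes
variance correctly when its generative assumptions hold, not that those
assumptions hold for any particular empirical dataset. One recovery
subtlety is worth knowing: with a full clade matrix ($n-2$ columns for
$n$ species) the joint model overfits small communities, so the
"unique phylogeny" fraction is biased upward even at $a = 0$; the
recovery guarantee asserted by the tests is monotonicity of the median
unique-phylogeny fraction in $a$ (30 replicates at $n = 24$ per weight),
not unbiasedness.

## Numerical choices, problem sizes and limitations

* Inertia follows the $1/(n-1)$ convention, matching standard
  constrained-ordination software; explained *fractions* are
  convention-free. Agreement with an independent implementation
  (`vegan::rda`) is asserted to $10^{-10}$ for total, constrained and
  conditioned inertia and eigenvalues.
* Partial fractions are reported against the *original* total inertia,
  so partition components add to one.
* Permutation p-values count ties as extreme (with a
  $\sqrt{\varepsilon}$ guard), use the add-one convention, and are
  reproducible from the recorded seed; null calibration is checked by
  simulation (500 replicates of 199 permutations, Kolmogorov distance
  to uniform < 0.08).
* Degenerate inputs fail loudly: zero total inertia, misaligned row
  labels, fewer than three rows, trees without branch lengths passed to
  the Brownian simulator, unknown category labels.
* Test-suite problem sizes (12-24 species, 199-999 permutations;
  9999 for the packaged example's headline run) keep the default run
  in the tens of seconds while leaving Monte-Carlo noise well inside
  the asserted tolerances.
* The package does not infer trees, estimate branch lengths, or fit
  phylogenetic regression alternatives (independent contrasts,
  phylogenetic eigenvector maps, PGLS); weighted (chi-square) ordination
  such as CCA is out of scope; no multiple-testing correction is applied
  across clade screens.
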