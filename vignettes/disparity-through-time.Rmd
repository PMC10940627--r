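---
title: "Disparity through time from discrete characters: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disparity through time from discrete characters: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodtt)
```

`morphodtt` quantifies how the morphological variety (*disparity*) of a
clade changed through geological time, starting from the two data objects
palaeobiologists typically have: a discrete character matrix scored for
living and fossil taxa, and a time-calibrated phylogeny. It was built with
groups like the cycads in mind — long-lived lineages whose reputation for
morphological stasis invites a formal test — but nothing in it is specific
to any clade.

This vignette explains the statistical machinery, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## From characters to a morphospace

**Distances.** Two taxa are compared character by character over the
characters scored in both. For an unordered character the per-character
distance is 0 (any shared state, polymorphic cells included) or 1; for an
ordered character it is the minimum absolute state difference across the two
cells' state sets. The Gower coefficient (GC) divides the summed distance by
the number of comparable characters; the maximum observable rescaled
distance (MORD) instead divides by the summed *maximum possible* distance
(1 per unordered character, the observed state range per ordered one), which
bounds it in [0, 1] and behaves better when missing data make different
pairs comparable over different characters. The observed state range is a
property of the character across the whole matrix, not of the pair — "the
maximum possible distance" should not shrink because one pair happens to
span fewer states.

A pair sharing no scored character has no defined distance. We treat this as
an error rather than imputing: the appropriate remedy (as in empirical
practice) is to drop the offending taxa, a decision the analyst should make
knowingly.

**Ordination.** Principal coordinates analysis double-centres the squared
distances and eigendecomposes. MORD matrices are generally non-Euclidean, so
by default the Cailliez constant — the smallest addition to all off-diagonal
distances making the centred matrix positive semi-definite — is applied
(`stats::cmdscale(add = TRUE)` is the engine). Axes are retained while their
eigenvalue exceeds `1e-8` times the largest; the constant and the threshold
are stored in the result so they can be audited. All disparity metrics use
*all* retained axes: a leading-axes subset would make "the size of the
morphospace" depend on an arbitrary cut-off. Axis signs are arbitrary and
every downstream metric is sign-invariant.

## Putting ancestors in the same space

The fossil record thins rapidly with age, so old time bins are sampled by
few taxa. Reconstructing a state for every internal node *before*
ordination ("pre-ordination ancestral state reconstruction") lets nodes
occupy the same morphospace as tips and roughly doubles the sample
(`2n - 1` rows for `n` tips).

Each character is reconstructed independently under an equal-rates Mk
model: one transition rate per character, estimated by maximum likelihood
(bounded search on the log rate, with Felsenstein pruning over branch
durations and per-node rescaling against underflow). Missing tips
contribute flat partial likelihoods; polymorphic tips contribute 1 for each
state in their set. Node probabilities are the marginal (rerooting)
probabilities from a second, root-to-tip message pass under a flat root
prior, and the assigned state is the most probable one, ties broken to the
lowest state label for determinism. Characters scored for fewer than two
tips cannot inform ancestors and yield missing node cells.

Two deliberate simplifications: ordering flags affect distances only, not
the Mk transition structure (a single symmetric rate is all 45-character
datasets can realistically support); and the argmax state is always
assigned rather than thresholded on posterior probability — leaving node
cells blank would shrink exactly the sample the method exists to enlarge.
Assigned states are, however, a smoothed version of the truth, which
matters for rate estimation (see *Limitations*).

## Sampling morphospace through time

**Tips only.** With stratigraphic ranges (FAD/LAD, in Ma), a taxon joins
every bin its range overlaps. Bins are half-open — closed at the young
edge, open at the old edge, with the oldest bin closed at both — so a range
touching a shared edge joins only the older bin and nothing is counted
twice. Period-level edges (252, 201.4, 145, 66, 23, 0 Ma) are provided as
`bins_periods()`.

**Tips plus nodes.** The tree is sliced at instants (by default the
midpoints of a 10-Ma grid, `bins_10ma()`). Every branch crossing a slice
contributes exactly one row: under the *gradual-split* model the descendant
is chosen with probability equal to the fraction of the branch already
elapsed (selection probability linear in time); under the *punctuated*
model ancestor and descendant are equally likely (change concentrated at
speciation). A node lying exactly on the slice contributes itself. Point
counts per slice therefore equal the number of lineages crossing it,
whatever the model or seed — a structural invariant the tests rely on.

## Disparity metrics, bootstrap, rarefaction

Two complementary metrics summarise each subset: the **sum of per-axis
sample variances** (denominator `n - 1`) measures the *size* of occupied
morphospace and is translation-invariant; the **mean Euclidean distance
from the origin** measures its *position* (the origin, not the subset
centroid — positional shifts are the signal of interest). Each subset is
bootstrapped (500 replicates by default) and summarised by the
2.5/25/50/75/97.5 percentiles. Rarefaction recomputes the metric on
resamples of fixed size (6 and 3 by default) to ask whether a trend
survives equalised sampling; resampling is with replacement, consistent
with the bootstrap. Empty bins yield gaps, not zeros — absence of data is
not absence of disparity — and single-point bins are flagged degenerate.
Clade-level curves reuse the full-space coordinates (no re-ordination), so
clade and whole-clade curves remain commensurable.

## Rates of character change

Changes are counted between the assigned states at the two ends of every
branch (`|x - y|` ordered, 0/1 unordered), and *exposure* is branch
duration times the number of characters scorable at both ends, so a rate
is in character changes per Ma per character-lineage and comparable across
bins with uneven missing data. A branch crossing several bins has changes
and exposure apportioned proportionally to the duration in each bin
(deterministic and exposure-consistent, unlike midpoint assignment).

Rate models assign contiguous blocks of bins to shared Poisson rates; with
`B` bins there are `2^(B-1)` such models (128 for the 8-bin preset
`bins_rates()`: 330.36, 299, 252, 201, 145, 100, 66, 23, 0 Ma). Each
block's ML rate is total changes over total exposure; the log-likelihood
treats each (branch, bin) cell with positive exposure as an independent
Poisson observation, and AICc uses that cell count as its sample size.
Model selection is by minimal AICc, ties going to fewer parameters. Clade
models compare a single tree-wide rate against clade-vs-background
two-rate models, with exposures summed over all time. Both the AICc
sample-size convention and the apportionment rule are conventions, not
facts; they are stated here because alternative conventions shift AICc by
small amounts.

## Environmental correlation

Disparity medians and environmental drivers (temperature- or CO2-like
series on the same uniform grid) are strongly autocorrelated, so raw
correlations are spurious. Each driver is reduced to ARIMA residuals — the
order selected by AICc over `p <= 3, d <= 2, q <= 3` — and the *same*
order is imposed on the response before residual cross-correlation (up to
±5 grid steps by default; 0.5 is the conventional reporting threshold for
|r|). Differencing is explicit: the series is differenced `d` times and an
ARMA with mean is fitted to the result, so residuals have length `n - d`
and a (0,1,0) fit leaves the first differences minus their mean (i.e. a
drift term is always included).

## The synthetic-data generator

Every stage is validated on data whose truth is known. `simulate_tree()`
grows a birth–death tree over a fixed span; lineages dying before the
present become fossil tips, and the requested numbers of extant and fossil
tips are kept. Fossils are sampled stratified by age (one per age
quantile) so the sample spans the clade's history, as real fossil records
of long-lived clades do; stratigraphic ranges bracket each fossil's age.
`simulate_characters()` evolves each character as an exact jump process —
Poisson change counts per branch segment at block-specific rates, uniform
choice among the other states — so the realised number of changes in any
time interval is recorded exactly, which is precisely the quantity the
rate machinery estimates. Per-branch rate multipliers allow clade-specific
rates with known truth. `mask_missing()` hides tip cells at a chosen
frequency.

What the generator does *not* emulate: correlated characters, ordered
(gradual-series) evolution, heterogeneous per-character rates,
preservation biased by geography or facies, and polymorphism arising from
real infraspecific variation. Passing tests therefore show the estimators
recover what they target under clean Mk-style evolution, not that any
empirical dataset satisfies those assumptions.

Test problem sizes are deliberately modest — trees of 8–170 tips, 10–45
characters, bootstraps of 100–10,000 — chosen so the whole suite exercises
every code path at meaningful statistical power while remaining quick to
run; the 337-row ordination check runs at the full empirical scale (169
tips, 45 characters).

## Numerical choices

* Zero-length branches are floored at 0.001 Ma and ages recomputed
  tip-upward, so every parent is strictly older than its children.
* Ages are Ma before present throughout; larger is older.
* Trees must be bifurcating; polytomies are rejected, not silently
  resolved, because row counts and change tables assume one node per
  split.
* Inapplicable (`-`) cells are recorded distinctly at parse time but
  treated as missing downstream; the distinction is preserved so the
  decision is reversible.
* Ordering flags default to all-unordered when the NEXUS file carries no
  TYPESET block; which characters (if any) to treat as ordered is left to
  the analyst.
* Posterior ties in ancestral states, AICc ties in model selection and
  which.max everywhere break deterministically (lowest state, fewest
  parameters, first listed).
* One master seed per configured run is split deterministically per stage,
  so whole runs are byte-reproducible while stages stay independent.

## Limitations

The important one is quantitative. Counting changes from assigned endpoint
states caps each branch–character pair at one observable change (unordered
case), so the estimated rate is biased low by roughly the factor
`(1 - exp(-lambda * t)) / (lambda * t)` for a branch of duration `t` — a
saturation effect, compounded mildly by the smoothing of argmax ancestral
states and by the apportionment of boundary-crossing branches, which
blurs rate contrasts between adjacent blocks. On trees whose branch
durations approach or exceed `1 / lambda` (tens of Ma at empirical rates
near 0.07 changes per Ma), estimated rates can undershoot generating rates
several-fold, and adjacent rate regimes blur together. The parameter
recovery experiment in the test suite is therefore run on densely sampled
trees (mean branch duration a few Ma, `lambda * t` around 0.2), and even
there the compounded bias approaches the 25% band, so recovery of
generating rates is only partial. The practical reading for empirical
work: rates estimated this way are *apparent* rates of observable change —
informative for relative comparisons between bins or clades, but not
unbiased estimates of underlying transition rates, and increasingly
conservative the sparser the tree. Relatedly, AICc's preference for
merging adjacent blocks means modest rate contrasts (1.4-fold) on
moderate-sized matrices are frequently summarised by fewer blocks than
generated.

Other limitations: reconstructed node states inherit all Mk assumptions
(no character correlation, stationarity, a single symmetric rate);
disparity envelopes reflect bootstrap uncertainty only, not uncertainty in
the tree (use `run_multitree()` across a posterior sample for that); and
the continuous slicing models are two idealised endpoints of how change is
distributed along branches, not an inference about it.

## A worked synthetic run

```{r example, eval = FALSE}
sim <- simulate_tree(n_extant = 20, n_fossil = 10, root_age = 220, seed = 1)
blocks <- data.frame(old = c(220, 100), young = c(100, 0), rate = c(0.005, 0.02))
chars <- simulate_characters(sim$tree, n_char = 30, n_states = 4,
                             rate_blocks = blocks, seed = 2)
m <- mask_missing(chars$matrix, 0.2, seed = 3)

cfg <- analysis_config(m, tree = sim$tree, ranges = sim$ranges,
                       bins = bins_10ma(220, 0, 20),
                       rate_bins = bins_10ma(220, 0, 55),
                       n_boot = 500, seed = 42)
ot <- run_ot(cfg)      # tips-only curves from stratigraphic ranges
po <- run_poasr(cfg)   # node-augmented curves, rate models, and more

po$rates$best          # AICc-selected rate model
head(po$curves$sum_of_variances_gradual)
```
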