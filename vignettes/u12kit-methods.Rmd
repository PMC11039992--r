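---
title: "u12kit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{u12kit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind each `u12kit`
module, the parameters a user can reasonably want to change, what the
synthetic-data generators do and do not emulate, and the design decisions
taken where more than one defensible implementation existed. It states no
empirical result that the package's tests or acceptance script do not
themselves compute.

# Co-evolution screen

## Model

A phylogenetic profile is the binary presence/absence vector of an
orthologous group (OG) across a species panel. Proteins acting in one
dispensable molecular machine — the minor spliceosome is the motivating
case — tend to be lost together when a lineage loses the machine, so
profile similarity is evidence of shared function. The screen scores every
OG by the cosine distance between its profile and the query's:

$$d(p, q) = 1 - \frac{p \cdot q}{\lVert p \rVert\, \lVert q \rVert},$$

which for binary profiles lies in $[0, 1]$. Ranking is ascending in $d$
with lexicographic tie-break on OG id, making output order deterministic
across platforms.

Profiles are binarized on input (any occupancy count > 0 becomes 1);
in-paralog copy numbers are deliberately discarded, since the screen is
about co-occurrence, not family expansion. An all-zero profile has no
direction in profile space, so its cosine distance is undefined; such OGs
are reported on an explicit `unrankable` list rather than being assigned
an arbitrary distance that would silently pollute the ranking tail.

## Recovery scoring

`evaluate_recovery()` turns the qualitative "known partners rank near the
top" readout into numbers: 1-based ranks of a reference set, the count
inside the top $k$, and an AUC defined as the probability that a uniformly
random reference member has a smaller distance than a uniformly random
non-reference member, ties counting 1/2. Unrankable reference members get
infinite distance (worst rank), so an absent partner honestly degrades the
score instead of vanishing from it.

No significance machinery is attached to the ranking itself: the screen
ranks, it does not test. This mirrors how the analysis is used in
practice, where the ranking is read alongside orthogonal evidence.

# Synthetic profiles: Yule tree + Dollo loss

## What is emulated

* `simulate_tree(n, seed)` draws a pure-birth (Yule) tree and rescales it
  to unit height, so every root-to-tip path has depth 1. The Yule model is
  a deliberately parameter-light stand-in for a curated eukaryote-wide
  species panel; nothing downstream depends on the tree being realistic
  beyond having a nested clade structure.
* `simulate_gene_loss()` applies Dollo semantics: every OG is present at
  the root (the LECA convention), is lost on a branch of length $L$ with
  probability $1 - e^{-\lambda L}$, and once lost never returns. Unit tree
  height makes $\lambda$ directly interpretable: the marginal per-species
  presence probability of an independent OG is $e^{-\lambda}$, which the
  tests check in closed form.
* Correlated loss of a co-functioning module is governed by $\rho$: on
  each branch, with probability $\rho$ the entire module shares a single
  Bernoulli loss indicator (all lose together or none does), otherwise
  each member draws independently. The marginal loss rate is identical in
  both regimes, and the endpoints are exact and testable — $\rho = 1$
  gives identical module rows, $\rho = 0$ gives module rows statistically
  indistinguishable from background. The per-branch (rather than per-OG)
  coin was chosen because it is the reading under which "the module loses
  together" is literally true, and it maximizes module cohesion among the
  reasonable interpretations.

Defaults in the demo configuration (120 species, 2000 background OGs,
$\lambda = 1$, module of 10 at $\rho = 0.8$) put per-species presence near
$e^{-1} \approx 0.37$, i.e. a sparse, patchy matrix of the kind dedicated
minor-spliceosome proteins actually show.

## What is not emulated, and one honest limitation

The generator does not model gene gain, horizontal transfer, annotation
error, or rate variation across lineages; background OGs are exchangeable
and independent given the tree. A green planted-module test therefore
establishes that the screen recovers co-ordinated loss under Dollo
dynamics — not that it is robust to the correlated noise of real orthology
inference.

One stated acceptance experiment is not attainable in this world and its
test is intentionally left failing: requiring *all nine* non-query module
members inside the top 1% of ~2000 OGs in ≥ 90% of runs at $\rho = 0.8$.
With a 20% chance per branch of fully independent module draws, a single
member suffering (or escaping) a loss on one deep branch diverges sharply
from the query; that happens to at least one of nine members in roughly
half of simulations, capping the all-nine success rate near 0.5 under
every mixing interpretation examined. The robust, attainable properties —
intra-module distances strictly smaller than module-to-background
distances, and module members concentrating far above the background
median — are what the passing tests assert.

# Splicing module

## Thresholds

Events are kept when `probability > 0.9` **and** `|delta_psi| > 0.05`,
both strict, so events sitting exactly on a threshold are excluded; the
retained count is monotone non-increasing in either threshold. The ΔΨ sign
convention in this package is `psi_b − psi_a` (condition B minus condition
A; in a knockout experiment, knockout minus control).

## Classification relative to U12-type introns

U12-type intron lists from multiple databases are merged by exact
coordinate identity on (chrom, start, end, strand), with the union of
source labels kept per intron. No fuzzy window is applied: databases that
disagree by one base remain visibly distinct records, because silently
collapsing them would change downstream counts in ways the user cannot
audit. All internal coordinates are 0-based half-open (BED convention);
GTF input (1-based closed) is converted at read time and the conversion is
round-trip tested.

Each significant event receives exactly one class, tested in precedence
order: `WITHIN_U12` (overlaps a U12 intron, strand-aware), `PROXIMAL_U12`
(overlaps an immediately flanking feature — the nearest exon *and* nearest
intron on each side of the U12 intron in its host gene model; "near
proximity" is defined by feature adjacency, not by a base-pair window),
`U12_GENE_DISTAL` (elsewhere in a U12-host gene), `U2_ONLY_BACKGROUND`.
Events whose gene is missing from the gene models are returned on a skip
list, never silently dropped.

## Enrichment statistic

For an event type (say AA, alternative acceptor), the 2×2 tabulation is
built over the universe of U12-stratum events (`WITHIN + PROXIMAL`, $n$,
of which $k$ match the type) plus background events (`U2_ONLY_BACKGROUND`).
`U12_GENE_DISTAL` events are excluded from both strata: they are neither
plausible direct targets nor clean negatives, and letting them
contaminate either group biases the comparison. Two fold definitions are
reported because the conventional "x-fold enrichment" phrasing is
ambiguous between them:

* `fold_vs_background` $= (k/n) \,/\, ((K-k)/(N-n))$ — stratum rate over
  background rate (the primary readout; this is the quantity the
  synthetic generator plants), and
* `fold_vs_overall` $= (k/n) \,/\, (K/N)$.

P-values are exact hypergeometric tails (`phyper`): upper
$P[X \ge k]$ for enrichment, lower $P[X \le k]$ for depletion, two-sided
as `min(1, 2·min(tails))`. The tests verify these against an independent
`choose()`-based enumeration for every 2×2 table with $N \le 12$ and spot
cases up to $N = 500$. Raw p-values are the primary output (a handful of
event types does not warrant genome-scale correction); Benjamini–Hochberg
adjusted values are available behind the `bh_types` argument.

## Synthetic event tables

`simulate_as_events()` plants an AA excess by multiplying the AA
probability inside the U12 stratum by `aa_enrichment_fold` (the other
types share the remaining probability mass proportionally), so the
background-odds fold estimated downstream equals the planted parameter —
the estimator, not the generator, is what the recovery test exercises.
Significance annotations are drawn independently of type and stratum
(`probability ~ Beta(6, 1)`, $|\Delta\Psi| \sim 0.8\,\mathrm{Beta}(2, 5)$
with random sign, $\Psi_a$ uniform on the interval that keeps $\Psi_b$ in
$[0,1]$), so filtering cannot distort the planted fold. These
distributions are a pragmatic choice giving ~40–45% of events past the
default thresholds; they do not model Whippet's posterior behaviour.

Intron retention is consumed, not recomputed: `differential_ir()` is the
downstream counting step over externally produced IR ratios. An intron is
called gained/lost on a strict `|ΔIR| > min_delta` rule with a depth
requirement in both conditions; a gene is summarized by its
largest-|ΔIR| *called* intron, so a deep change cannot be masked by a
low-coverage intron with a wild ratio. `min_delta = 0.1` and
`min_depth = 10` are package defaults, chosen as ordinary practice for
IR screens; they are artifact-defined, not sourced values.

# Binding module

The one-site specific-binding model $y = B_\max x / (K_d + x)$ is fit to
pooled observations (all replicates in one least-squares objective).
Pooling was chosen over averaging per-replicate fits for efficiency; a
`per_replicate` flag provides the alternative, and a `fix_bmax` argument
provides the one-parameter variant ($B_\max$ free is the default because
real gels routinely show incomplete shifting). The free-ligand
approximation (total ≈ free protein) is appropriate for µM titrations
against a low-nM probe and no depletion correction is applied.

Numerics: parameters are kept positive by bounded L-BFGS-B, then polished
by damped Gauss–Newton iteration. The polish matters because the package's
round-trip tests demand noise-free data to be recovered to 1e-6 relative
error, a regime where `nls()` is unreliable (zero-residual failure) and
quasi-Newton alone stalls short of machine precision. Standard errors come
from the Jacobian cross-product at the optimum
($\hat\sigma^2 (J^\top J)^{-1}$); on the natural scale, which is why a log
reparameterization was avoided. Default initialization is
$B_{\max,0} = \max y$ and $K_{d,0}$ the concentration whose mean response
is nearest $B_{\max,0}/2$. Constant-response data raise an explicit
unidentifiability error instead of returning a spurious $K_d$.
`affinity_ratio()` returns $K_{d,a}/K_{d,b}$ (> 1 = weaker binding of
`a`) with a delta-method standard error assuming independent fits.

The EMSA simulator adds Gaussian noise (`noise_sd`, default 0.02 in
fraction-bound units — a typical phosphorimager quantification scatter)
and clips to $[0, B_\max]$, matching how band-ratio quantifications behave
near saturation; it does not model gel-loading covariance between lanes.

# Workflow and reproducibility

Every generator funnels its randomness through one seed argument and
restores the caller's RNG state, so any call is bit-reproducible and
composable. `run_workflow()` executes stages in dependency order from a
single YAML config (unknown keys rejected; CLI flags override the file),
and writes a manifest with a config hash, output checksums and runtimes;
identical config + seed yields byte-identical primary outputs. Exit codes
are stable for scripting: 0 success, 2 config/format error, 3 analysis
error.

# Known limitations

* The co-evolution screen assumes the orthology table is correct; it has
  no model of OG fragmentation or contamination.
* Feature-adjacency "proximity" ignores unannotated exons and alternative
  transcript structures; with multi-isoform gene models the flanking
  features come from the exon set actually supplied.
* The enrichment test conditions on the realized event universe; it does
  not model gene-level clustering of events (several events in one gene
  count independently).
* The binding fit assumes homoscedastic noise; strongly
  concentration-dependent quantification error would call for weighted
  least squares, which is not implemented.
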