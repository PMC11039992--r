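# u12kit

Tools for three computational analyses that recur in studies of the minor
(U12-dependent) spliceosome and its candidate protein components:

1. **Phylogenetic-profiling co-evolution screen.** Proteins that work in
   the same molecular machine tend to be lost together across lineages.
   Given a binary presence/absence matrix of orthologous groups (OGs)
   across a species panel, `u12kit` ranks all OGs by the cosine distance
   of their phylogenetic profile to a query gene's profile, and scores how
   well a reference set of known partners concentrates at the top of that
   ranking. The minor spliceosome is the canonical use case: its dedicated
   components (U11/U12 di-snRNP proteins, CENATAC, ...) share a striking
   patchy presence/absence profile across eukaryotes.
2. **Minor-intron-centric alternative-splicing analysis.** Event tables in
   a Whippet-like dialect (event type CE/AA/AD/RI, Ψ per condition, ΔΨ,
   posterior probability) are filtered at the standard significance
   thresholds (Pr > 0.9 and |ΔΨ| > 0.05, both strict), classified relative
   to an annotated set of U12-type introns (within the intron, in an
   immediately flanking exon/intron, elsewhere in a U12-host gene, or in a
   gene with only major introns), and tested for event-type enrichment
   with exact hypergeometric tail probabilities. A companion summary step
   counts genes gaining or losing intron retention from per-intron IR
   tables.
3. **Equilibrium binding (Kd) estimation from EMSA titrations.** Bound
   fractions from a protein titration against a trace-labelled RNA are fit
   with the one-site specific-binding model `y = Bmax·x/(Kd + x)` by
   nonlinear least squares, giving `Kd` and `Bmax` with curvature-based
   standard errors, plus delta-method affinity ratios between datasets.

A synthetic-data module generates every input the pipeline consumes — a
Yule species tree, Dollo (loss-only) presence/absence profiles with a
correlated-loss module, AS event tables with a planted alternative-acceptor
(AA) enrichment at U12 introns, and noisy saturation-binding curves — so
every stage is testable end to end without any external download.

## Worked example

```r
library(u12kit)

## 1) co-evolution screen on synthetic profiles
tree     <- simulate_tree(n_species = 120, seed = 1)
model    <- loss_model(lambda = 1,
                       module_members = sprintf("MINOR%02d", 1:10),
                       rho = 0.8)
profiles <- simulate_gene_loss(tree, n_background = 2000, model, seed = 2)
ranking  <- rank_coevolution("MINOR01", profiles)
print(ranking, n = 5)
#> Co-evolution ranking for query 'MINOR01' (1890 ranked, 119 unrankable)
#>           og_id   distance rank
#> MINOR07 MINOR07 0.01587302    1
#> MINOR09 MINOR09 0.07358889    2
#> MINOR03 MINOR03 0.07480130    3
#> MINOR05 MINOR05 0.11604000    4
#> MINOR08 MINOR08 0.11604000    5
evaluate_recovery(ranking, sprintf("MINOR%02d", 2:10), k = 20)
#> Recovery of 9 reference OGs: 9 in top 20, AUC = 1.000
```

All nine co-lost module members rank in the top 20 of 1890 (AUC 1.0): the
screen recovers the planted co-evolving module, the same qualitative
readout as finding known minor-spliceosome proteins at the top of a real
query's ranking.

```r
## 2) minor-intron splicing enrichment on a planted 3-fold AA excess
cfg <- as_event_config(n_genes = 200, n_events = 2000,
                       aa_enrichment_fold = 3, seed = 4)
gm  <- simulate_gene_models(cfg)
ev  <- simulate_as_events(cfg, gm$u12_introns, gm$exons)
sig <- filter_significant_events(ev, pr_min = 0.9, dpsi_min = 0.05)
cls <- classify_events(sig, gm$u12_introns, gm$exons)
enrichment_test(cls$events, "AA")
#> AA enrichment at U12-type introns: 115/201 vs 115/587 background
#>   fold vs background = 2.92, fold vs overall = 1.96
#>   hypergeometric p: upper = 1.06e-22, lower = 1, two-sided = 2.12e-22
```

The estimated fold versus the U2-only background (2.92) recovers the
planted 3-fold AA excess; the upper-tail hypergeometric p-value is the
enrichment statistic.

```r
## 3) Kd from a simulated EMSA titration (true Kd = 2.14 uM)
emsa <- simulate_emsa(binding_config(kd_true = 2.14, noise_sd = 0.02,
                                     n_replicates = 3, seed = 3))
fit_one_site(emsa)
#> One-site specific binding fit (n = 21)
#>   Kd   = 2.204 +/- 0.0718 uM
#>   Bmax = 1.002 +/- 0.00965
#>   RSS  = 0.004612 (df = 19)
```

## Command line

An executable script is installed at
`system.file("cli", "u12kit", package = "u12kit")`:

```sh
u12kit run --config inst/extdata/demo_config.yaml --out demo_out
u12kit simulate emsa --seed 1 --out sim/
u12kit emsa fit --data sim/emsa.tsv --out fit/
u12kit coevolve rank --query MINOR01 --matrix profiles.tsv \
       --reference partners.txt --k 20 --out rank/
u12kit splice enrich --events events.tsv --u12-bed u12.bed \
       --gene-models genes.bed --out enr/
```

Exit codes: 0 success, 2 config/format error, 3 analysis error. Identical
config + seed reproduces byte-identical outputs; each run writes a
`manifest.json` with checksums and runtimes.

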