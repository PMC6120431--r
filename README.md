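# tidalplast

Transcriptomic plasticity versus evolved divergence in tidal populations.

## The problem

Intertidal and subtidal populations of coastal invertebrates live meters
apart under radically different thermal stress. After a common-garden
generation, baseline (unstressed) expression differences between intertidal
and subtidal progeny reflect heritable, **evolved divergence**; the
expression change of a population under acute heat stress reflects
**plasticity**. The central question is whether the two align: for gene *g*,
with divergence `E_g = mean(I, 0h) − mean(S, 0h)` and plastic change
`Δ_g(t) = mean(S, t) − mean(S, 0h)` on a regularized log scale, same-sign
products `E_g · Δ_g > 0` indicate plasticity pointing in the direction of
adaptation. The package reports the concordant fraction `Np/Nt`, the
Spearman rank correlation `ρ(E, Δ)`, and a permutation p-value from joint
shuffles of the (tide, time) sample labels.

`tidalplast` implements the full pipeline for a two-site × two-tidal-level ×
{0, 6, 24 h} × 3-replicate RNA-seq design:

* counts/metadata I/O (TSV, MatrixMarket, CSV) with strict validation;
* low-expression filtering, median-of-ratios size factors, a shrunken log2
  transform;
* per-gene negative-binomial Wald tests (t-referenced, small-sample
  calibrated) with Benjamini–Hochberg correction, for tide-divergence and
  stress-plasticity contrasts;
* classification into evolutionarily divergent (D), concordantly plastic
  (P) and adaptive plastic (A = D ∩ P) gene sets;
* the concordance table (`Np`, `Nt`, %, ρ, permutation and asymptotic p);
* genome-wide plasticity on a DAPC-style discriminant axis built from
  unstressed samples, with Bayesian linear-mixed-model (Gibbs) inference on
  population shift differences;
* increased-plasticity dynamics (6 h vs 24 h, two-proportion z-tests);
* Livak 2^−ΔΔCt relative expression for candidate-gene qPCR tables;
* a negative-binomial count simulator with planted, correlated divergence
  and plasticity effects and full ground truth — every stage of the
  pipeline is validated against it, including a diagnostic for the
  shared-baseline (regression-to-the-mean) artifact that inflates ρ(E, Δ)
  when both vectors subtract the same noisy 0 h mean.

See the vignette (`vignettes/plasticity-divergence.Rmd`) for the model,
parameter choices, and known caveats.

## Worked example

```r
library(tidalplast)

sim <- simulate_counts(sim_config(n_genes = 2000, seed = 1))
res <- run_plasticity_pipeline(sim$counts, sim$design,
                               B = 1000, n_mcmc = 2800, seed = 2,
                               use_adjusted = FALSE)
res$gene_sets
#> Gene sets:
#>   evolutionarily divergent (D): 94 genes
#>   concordantly plastic (P):     168 genes
#>   adaptive plastic (A = D & P): 16 genes

dplyr::filter(res$concordance, gene_set == "adaptive_plastic")
#>   gene_set         group        np    nt percent   rho p_perm p_spearman
#> 1 adaptive_plastic BYQ-S_6h     15    16    93.8  0.879  0.250    7.19e-6
#> 2 adaptive_plastic BYQ-S_24h    15    16    93.8  0.8    0.369    1.99e-4
#> 3 adaptive_plastic LT-S_6h      15    16    93.8  0.85   0.239    3.05e-5
#> 4 adaptive_plastic LT-S_24h     15    16    93.8  0.838  0.228    5.01e-5

res$shift_inference$BYQ$contrasts
#>   time_h estimate conf.low conf.high   p_mcmc  rhat converged
#> 1      6    6.67     4.43      8.87  0.000357  1.00 TRUE
#> 2     24   -0.622   -2.77      1.62  0.548     1.00 TRUE
```

Reading the output: the simulator planted divergence and plasticity effects
with correlation 0.7, and the recovered adaptive-plastic set shows 15 of 16
genes concordant (93.8%) with ρ ≈ 0.8–0.88 and tiny asymptotic p — the
plasticity-aligned-with-divergence signature. The permutation p is much
larger than the asymptotic p because with genuine stress effects present
the label-shuffling null is conservative (see the vignette). The
mixed-model contrast says the subtidal population shifts further along the
unstressed discriminant axis than the intertidal one at 6 h
(estimate = S − I shift difference, P_MCMC ≈ 3.6e-4), while by 24 h the
difference reverses sign and is no longer credible — the delayed
intertidal response the generator plants by default.

`autoplot()` methods exist for concordance tests, DAPC fits and dynamics
tables; `tidy()`/`glance()` methods give per-gene and one-row summaries.

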