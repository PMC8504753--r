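# lgbn

Linear-Gaussian Bayesian networks for tiered randomised-trial data: learn a
consensus network from change scores under temporal constraints, validate it
by nested cross-validation, and probe it with conditional queries and
arc-zeroing intervention simulations.

## The problem

Randomised trials show *whether* a complex intervention works; they rarely
show *how*. One way to ask the second question is to model the trial's
measured changes — here a binary treatment group plus early (during
treatment) and late (after discharge) change scores of ten pain, disability
and psychological outcomes — as a linear-Gaussian Bayesian network: a DAG in
which each variable is a linear function of its parents plus Gaussian noise,

x_v = α_v + Σ_u β_{uv} x_u + ε_v,  ε_v ~ N(0, σ_v²).

Temporal order supplies hard constraints (late changes cannot cause early
ones; nothing causes the randomised allocation). Structure is learned by
Gaussian-BIC hill climbing; missing values are handled by Structural EM
(iterated conditional-mean imputation and re-learning); spurious arcs are
suppressed by bootstrap model averaging — keep an arc only if it appears in
more than half of the networks learned on resampled data. The fitted network
is validated by nested k-fold cross-validation (per-variable predictive
Pearson r, MAE, MSE, RMSE) and then interrogated: conditional probability
queries by logic sampling, treatment contrasts by regression on sampled
draws, and mediation questions by fixing arc coefficients to zero and
re-reading the total effect, which in a linear system is the sum over
directed paths of coefficient products. Severing arcs one at a time
decomposes a total effect into pathway contributions,
`100·(β_full − β_fixed)/β_full` percent.

Because individual-level trial records of this kind are generally not
public, the package ships a documented synthetic generator
(`lbp_network()`, `simulate_trial()`) that emulates such a trial — treatment
effects entering through early disability change and pain coping, an
anxiety–depression chain, negative early-to-late autocorrelations — with
several coefficients pinned to published estimates so worked examples have
exact answers. Every pipeline stage is tested against exact oracles
(closed-form Gaussian moments, exhaustive DAG enumeration, path tracing).

## Worked example

Pathway decomposition with exact arithmetic on the generator network — how
much of the effect of early disability change on early depression change
flows through fear and through pain persistence:

```r
library(lgbn)
net <- lbp_network()
dec <- decompose_pathways(net, "disability_early", "depress_early", list(
  fear             = c("fear_early", "pain_persist_early"),
  pain_persistence = c("pain_persist_early", "anx_early")))
dec$beta_full
#> [1] 0.045
dec$scenarios
#>           scenario beta_fixed contribution_pct contribution_pct_rounded
#> 1             fear      0.042         6.666667                        7
#> 2 pain_persistence      0.028        37.777778                       38
```

A unit of early disability reduction produces 0.045 units of early
depression reduction; zeroing the fear arc leaves 0.042 (about 7% flowed
via fear), zeroing the pain-persistence-to-anxiety arc leaves 0.028 (about
38% flowed through pain persistence and anxiety).

Learning a consensus network from a synthetic trial (289 participants, 5%
missing cells, 50 bootstrap resamples):

```r
d    <- simulate_trial(n = 289, missing_rate = 0.05, seed = 1)
bl   <- tier_blacklist(attr(d, "tiers"))
dags <- bootstrap_structures(d, bl, B = 50, seed = 2, binary = "group")
s    <- arc_strengths(dags)
cons <- consensus_dag(s, 0.5, nodes = colnames(d))
head(s, 5)
#>               from              to strength
#> 1        anx_early        anx_late        1
#> 2        anx_early    depress_late        1
#> 3    depress_early    depress_late        1
#> 4 disability_early disability_late        1
#> 5       fear_early       fear_late        1
nrow(cons$arcs)
#> [1] 24
```

Probing the network: the sampled treatment contrast on early back-pain
change, before and after severing the treatment-to-disability arc:

```r
e <- group_effect(net, "lbp_early", seed = 3)
sprintf("beta = %.3f, t = %.2f", e$beta, e$t)
#> [1] "beta = -0.490, t = -14.52"
med <- mediation_check(net, c("group", "disability_early"), "lbp_early", seed = 3)
sprintf("beta = %.3f, t = %.2f, p = %.3f", med$beta, med$t, med$p)
#> [1] "beta = -0.070, t = -2.07, p = 0.039"
```

Individualised treatment reduces early back pain by about half a unit more
than the comparator in this draw (the generator plants −0.42); with the
treatment-to-disability arc zeroed, the remaining contrast is within
Monte-Carlo error of zero — the back-pain benefit is mediated by early
disability change. The t statistics scale with the number of draws (default
10⁴) and are Monte-Carlo diagnostics, not trial-level inference.

A command-line shim over the same functions lives in `inst/cli/lgbn.R`
(subcommands `simulate`, `learn`, `validate`, `query`, `intervene`).

## Package layout

- `R/dag.R`, `R/lgn.R`, `R/score.R` — graphs, networks, exact moments,
  sampling, Gaussian BIC
- `R/blacklist.R`, `R/hillclimb.R`, `R/structural_em.R`, `R/averaging.R` —
  constrained search, EM, bootstrap averaging
- `R/validation.R`, `R/queries.R`, `R/interventions.R` — nested CV, sampled
  queries, do-style mutilations
- `R/synthetic.R`, `R/ingest.R`, `R/cli.R` — generator, trial-format
  ingestion, pipeline entry points
- `vignettes/network-pipeline.Rmd` — the methods write-up: model,
  assumptions, defaults, numerical choices, limitations
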