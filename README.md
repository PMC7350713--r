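# carapace

Macroevolution and extinction-risk analysis for dated phylogenies, built
around the biology of turtles and crocodilians: ancient, slowly
diversifying clades in which much of the evolutionary heritage is carried
by threatened species and a quarter of species lack a usable Red List
assessment. `carapace` implements, as one tested pipeline, the four
analyses such a study needs, plus a synthetic-data module that generates
trees, traits, ranges, and ordinal threat statuses with known ground truth
so that every stage can be validated end to end without external data.

Who it is for: comparative biologists and conservation analysts who have a
dated ultrametric tree (Newick/Nexus, branch lengths in Myr), per-species
predictors, and partial IUCN statuses, and want diversification-rate,
trait-evolution, distinctiveness, and status-imputation results from one
coherent, reproducible toolkit.

## The models

**Episodic birth–death with mass extinctions.** Piecewise-constant
speciation λ(t) and extinction μ(t) with sampling fraction ρ and
instantaneous mass-extinction events at which each lineage survives with
probability *s*. The reconstructed-process likelihood propagates the
survival function E(t) and per-lineage flow D(t) in closed form per
segment, conditioned on the crown age and survival of both crown
lineages. A reversible-jump MCMC (up to 2 rate shifts + 2 mass
extinctions; survival prior Beta with mean 0.05, concentration 100;
empirical lognormal hyperpriors from a constant-rate fit) yields
rates-through-time summaries — net diversification r = λ − μ, turnover
μ/λ — and Bayes factors for event presence, reported as 2 ln BF against
the thresholds 6 ("mention") and 10 ("strong").

**Lévy jump-diffusion trait evolution.** Log body size follows Brownian
motion with rate σ² plus compound-Poisson jumps (rate λ_J per Myr per
branch; jump variance α·σ²). Given jump counts the likelihood is Gaussian
pruning over effective branch lengths ℓ + n·α; with counts marginalized it
is a Gaussian-mixture pruning over a capped Poisson. The jump-size ratio
α is profiled on an expanding half-decade log grid, the jump model is
tested against Brownian motion by a likelihood-ratio test (df = 2), and
per-branch jump posteriors are sampled by MCMC, calling branches with
posterior probability > 0.85.

**Fair-proportion ED and EDGE.** Each branch's length is divided equally
among its descendant tips; a tip's ED (Myr) is the sum of its shares, so
ED sums to total tree length. ED is pooled as the per-species median over
a tree posterior and combined with the threat weight GE (LC = 0 … CR = 4)
as EDGE = ln(1 + ED) + GE·ln 2.

**Threat-status imputation ensemble.** Status coded 1–6 (LC…EX) and
treated as continuous; predictors encoded (log/z-scores for the GLS,
min-max for the network, one-hot categories) plus 2 phylogenetic and 2
spatial PCoA axes. Three models — GLS with residual correlation
w·C_phylo + (1 − w)·C_spatial, a 500-tree random forest, a single-hidden-
layer neural network — are cross-validated, pooled by the mean on [1, 6],
and rounded half-up toward the more-threatened class; concordance is
tabulated over the three model pairs per species.

## A worked example

```r
library(carapace)

tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
fair_proportion(tree)
#>   A   B   C
#> 1.5 1.5 2.0
```

A and B share their 1-Myr stem (0.5 each) on top of their own 1-Myr
branches; C keeps its whole 2-Myr branch. The three ED values sum to the
total branch length, 5 Myr. Scoring EDGE with statuses A = LC, B = EN,
C = CR:

```r
et <- edge_table(data.frame(species = names(ed), ed = ed),
                 c(A = "LC", B = "EN", C = "CR"))
rank_edge(et, 3)
#>   species  ed status ge      edge rank
#> C       C 2.0     CR  4 3.8712010    1
#> B       B 1.5     EN  3 2.9957323    2
#> A       A 1.5     LC  0 0.9162907    3
```

C leads: ln(1 + 2) + 4·ln 2 ≈ 3.87 — highest distinctiveness and
highest threat. For diversification, on a 300-tip simulated tree with
true rates λ = 0.07, μ = 0.03:

```r
set.seed(1)
big <- ape::rphylo(300, 0.07, 0.03)
fit_constant_bd(big)
#> lambda_hat = 0.0810, mu_hat = 0.0463
rates_through_time(comet_mcmc(big, n_gen = 5000, thin = 5, seed = 2))
#> posterior median turnover at present: 0.63
```

## The analysis workflow

`analysis/01_simulate.R` … `analysis/07_report.R` run the full study on
synthetic data (400 species, λ = 0.07/μ = 0.03, 100-tree pseudo-posterior,
30% of statuses masked), writing tables under `results/`. Each script
prints what it found; on the default seed the diversification stage
recovers flat rates with no supported mass extinction, the body-size
stage finds the jump model decisively (D ≈ 102) and calls the one large
planted jump, and the imputation stage reaches 38% pooled accuracy
(chance 17%) with mean absolute error 0.77 categories and range area
ranked the top predictor by all three models.

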