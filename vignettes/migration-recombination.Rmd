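---
title: "Solving the migration-recombination equation genealogically"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving the migration-recombination equation genealogically}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrec)
```

## The model

Consider a haploid population subdivided into a finite set of demes $L$,
with each individual carrying a sequence of $n$ sites; site $i$ takes
letters in a finite alphabet $A_i$. The state of deme $\alpha$ at
generation $t$ is a probability measure $\mu_t(\alpha)$ on the type space
$A_1 \times \dots \times A_n$, and one generation acts in two stages:

1. **Migration.** Deme $\alpha$ is refilled by a mixture of the demes
   according to the *backward* migration matrix $M$: the post-migration
   state is $\sum_\beta M(\alpha,\beta)\,\mu_t(\beta)$, where
   $M(\alpha,\beta)$ is the probability that an individual now in
   $\alpha$ came from $\beta$. `backward_from_forward()` derives $M$
   from a forward matrix and deme sizes, warning when the flow does not
   preserve the sizes.
2. **Recombination.** Each offspring chooses a partition $\delta$ of the
   site set with probability $r_\delta$ and inherits the sites of each
   block of $\delta$ from an independent parent. On the level of
   measures this replaces the deme's state $\nu$ by
   $\sum_\delta r_\delta \bigotimes_{d \in \delta} \nu^{(d)}$, the
   mixture of products of its own block marginals ($\nu^{(d)}$ denotes
   the marginal on the sites in $d$).

The composition is the migration-recombination dynamics implemented in
`mre_step()` and iterated by `mre_iterate()`. It is nonlinear (quadratic
and higher in the measure), which makes the following exact solution
methods the heart of the package.

## Exact linearisation

The nonlinearity disappears after a change of variables. For a partition
$\delta$ with blocks labelled by demes — a *labelled partition*
$\bar\delta = \{(d_1,\lambda_1),\dots\}$ — define the labelled
recombinator

$$\mathcal R_{\bar\delta}(\mu) \;=\; \bigotimes_{(d,\lambda)\in\bar\delta} \mu(\lambda)^{(d)},$$

the product measure built from the indicated block marginals of the
indicated demes (`recombinator()`). Collect all values
$\mathcal R_{\bar\delta}(\mu_t)$ into one long vector indexed by the
labelled partitions of the full site set. The dynamics of this vector is
*linear*: it is driven by the transition matrix $T$ of a Markov chain on
labelled partitions, the **labelled partitioning process**, and

$$\mathcal R(\mu_t) = T^t \, \mathcal R(\mu_0),$$

with the physical solution read off at the one-block states. The chain
has a genealogical meaning, obtained by reading the life cycle backward:
each labelled block $(d,\lambda)$ — a set of sites currently carried by
one ancestor in deme $\lambda$ — independently splits according to the
marginal recombination distribution on $d$ and each fragment's ancestor
deme is redrawn from $M(\lambda,\cdot)$. `build_T()` constructs $T$ from
this product form; `build_T_factorised()` constructs it from the
equivalent factorisation into an unlabelled splitting factor times
migration factors, and the tests assert entrywise equality of the two
constructions. `solve_by_matrix_powers()` applies $T^t$ and is checked
against the nonlinear iteration to $10^{-10}$.

Two further exact consequences are implemented:

* **Marginalisation consistency.** The dynamics restricted to any site
  subset $U$ is autonomous, with recombination weights
  $r^U_\delta = \sum_{\delta' : \delta'|_U = \delta} r_{\delta'}$
  (`marginal_mre_step()`, `marginal_recombination()`).
* **Duality.** $\mu_t(\alpha)$ equals the expectation of
  $\mathcal R_{\Sigma_t}(\mu_0)$ over trajectories of the labelled
  partitioning process started from the one-block state labelled
  $\alpha$. `duality_estimate()` turns this into a Monte-Carlo solver
  with cellwise standard errors; `two_site_closed_form()` evaluates the
  resulting explicit formula for $n = 2$ by summing over the single
  splitting generation.

## Asymptotics

When $M$ is primitive (checked via Wielandt's bound in `is_primitive()`)
and the recombination support separates every pair of sites
(`check_separability()`; `collapse_clusters()` reduces the general
case), the dynamics converges geometrically to the same limit in every
deme: the product over sites of the $q$-mixture of initial one-site
marginals, $q$ the stationary distribution of $M$
(`limiting_metapopulation()`).

Conditioned on the base partition not yet having fragmented into
singletons, the partitioning process has a quasi-limiting law. It is
supported on the reachable states of maximal sojourn probability
$\eta$ (`sojourn_eta_F()`), with weights proportional to discounted
hitting-time transforms computed by a triangular linear solve along the
refinement order (`qlim_unlabelled()`); the labelled law factorises into
this base law times independent stationary labels (`qlim_labelled()`).
A noteworthy structural fact, reproduced exactly by the shipped
`fixture_two_pair_example()`, is that sojourn probabilities are *not*
monotone along refinement paths: that model has sojourns
$2/5 \to 1/4 \to 1/2$ along a maximal chain, so the long-time
conditional law concentrates on states strictly finer than the
better-sojourning coarse state.

## Continuous time

The analogous continuous-time model replaces $M$ by a Markov generator
$N$ on the demes and $r$ by partition-indexed splitting rates $\varrho$
(`ct_model()`; the rate of the one-block partition is ignored, as its
recombinator is the identity). The same linearisation gives a generator
$\mathcal Q$ on labelled partitions (`build_generator_Q()`): single
blocks split at marginal rates keeping their label, or change label one
at a time at the rates of $N$. `ct_solve()` integrates the dynamics
either via `Matrix::expm` applied to $\mathcal Q$ or via
`deSolve::ode()` on the nonlinear right-hand side (relative tolerance
$10^{-9}$); the two independent methods agree to $10^{-6}$ and serve as
mutual oracles. For $n = 2$, `ct_two_site()` evaluates the closed-form
solution with an exponentially distributed splitting time by adaptive
quadrature (`stats::integrate`, absolute tolerance $10^{-9}$).

## Numerical design choices

* **Dense arrays, fixed linear order.** Measures are dense R arrays with
  one dimension per site; flat input/output vectors use lexicographic
  order with site 1 most significant (the last site varies fastest).
  The state spaces targeted here ($n \le 6$ or so, small alphabets,
  a handful of demes) make dense linear algebra the simplest correct
  choice; caps guard the combinatorial explosions (Bell numbers times
  $|L|^{\#\text{blocks}}$ for the labelled lattice).
* **Exact rational mode.** Quantities derived from the recombination
  distribution alone — marginal weights, entries of the unlabelled
  transition matrix, sojourn probabilities — are computed in exact
  rational arithmetic whenever the model's weights were given as
  fraction strings. The arithmetic keeps integral numerators and
  denominators in doubles (all values far below $2^{53}$), which is
  exact. Everything involving measures or migration is double
  precision.
* **Renormalisation per generation.** The recombination step
  mathematically preserves total mass, but a mass deviation of size
  $\epsilon$ is amplified by roughly the number of blocks per partition
  each generation (the step is multilinear, not affine). Over tens of
  generations this turns roundoff of order $10^{-16}$ into overflow.
  Each deme's table is therefore divided by its sum once per
  generation — the exact map is unchanged, only the roundoff drift is
  removed — after which trajectories reach the theoretical limit to
  $10^{-16}$ at $t = 60$.
* **Reproducible simulation.** R has no built-in counter-based or
  splittable random number generator, so all Monte-Carlo code derives a
  substream seed per trajectory from the master seed via a fixed
  integer hash below $2^{31}$ (`substream_seed()`) and reseeds the
  Mersenne-Twister; block decisions within a step are made in canonical
  block order. Results are bit-reproducible for the package's serial
  execution model.
* **Conditioned simulation horizon.** Verifying the quasi-limiting law
  by rejection sampling requires surviving trajectories, and survival
  decays like $\eta^t$ ($= 2^{-t}$ for the shipped fixture). The
  stochastic check therefore runs at $t = 10$ with $2 \times 10^5$
  replicates (a few hundred expected survivors) and conditions on the
  base lying in the maximal-sojourn support; for the fixture with
  uniform migration this conditioning is exactly unbiased at any
  horizon, by the site-swap symmetry of the recombination distribution
  and the one-step stationarity of uniform labels. Trajectories are
  abandoned as soon as the base absorbs, which changes no distribution
  and saves most of the work.

## Scope and limitations

The package targets exact structural computation on small systems, not
large-scale simulation: the labelled partition lattice grows like
$B_n |L|^n$, and the dense transition matrices with their tensor-product
entries are the intended regime up to a few thousand labelled states.
Tree-topology path expansions of the continuous-time solution beyond two
sites are not enumerated — the matrix-exponential and ODE solvers cover
$n > 2$. Quasi-stationarity in continuous time and coalescence (joint
genealogies of several individuals) are out of scope.

## A worked session

```{r example}
cfg <- fixture_two_pair_example(demes = c("a", "b"))
Tul <- build_T_unlabelled(cfg$model$r)
sojourn_probabilities(Tul, exact = TRUE)

info <- sojourn_eta_F(cfg$model$r)
info$eta
info$F_keys

qlim_unlabelled(cfg$model$r)

lin <- solve_by_matrix_powers(cfg$initial, cfg$model, 15)
fwd <- trajectory_final(mre_iterate(cfg$initial, cfg$model, 15))
meta_dist(lin, fwd)
```
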