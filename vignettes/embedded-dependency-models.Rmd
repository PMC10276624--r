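---
title: "Embedded-dependency Markov models for inapplicable characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedded-dependency Markov models for inapplicable characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Morphological characters are often anatomically dependent: tail colour can
be red or blue only while a tail exists, and is *inapplicable* (scored "-")
otherwise. Treating such a hierarchy as independent columns misstates the
evolutionary process; treating "-" as just another symbol misstates the
state space. The embedded-dependency (ED) view models the hierarchy
explicitly: a *controlling* character is a birth-death (BD) chain for the
presence of a structure, and each *dependent* character evolves only inside
the controller's "present" state. On every birth of the controller the
dependent restarts from an *embedded initial vector* $\phi$:

* **ED-ql** (qualitative dependent, e.g. colour): $\phi$ is free — a new
  tail appears already red or blue.
* **ED-bd** (BD dependent, e.g. tail armour): $\phi = (1, 0, \ldots)$ — the
  dependent is reborn *absent*, encoding the macroevolutionary lag by which
  nested structures accumulate gradually. The direct jump "no tail" →
  "tail with armour" has rate exactly zero.

## Amalgamation

The duet of interacting chains is equivalent to a single CTMC on a reduced
state space. For a controller with gain $\alpha$ and loss $\beta$ and a
dependent block $Q_d$, the amalgamated generator is

$$
\mathrm{ED}(Q_c, Q_d) \;=\;
\begin{pmatrix} -\alpha & \phi\,\alpha \\ \beta^{T} & Q_d - I\beta \end{pmatrix},
$$

of dimension $\dim(Q_d) + 1$: one "absent" state plus the dependent states.
All states pairing "controller absent" with distinct dependent values are
redundant and removed. The flavour of the dependency is carried entirely by
$\phi$. Independent characters combine by the Kronecker-sum (SMM)
amalgamation instead, which keeps all state combinations. `edmorph`
verifies the chain equivalence by simulation: exact Gillespie trajectories
of the interacting pair reproduce the tip-state distribution
$\exp(Qt)$ of the amalgamated matrix (see `test-simulate.R`).

Arbitrary hierarchies are handled by the dependency-diagram amalgamation
(DDA): the diagram is traversed from the tips toward the root; at each
controlling node the child blocks are SMM-amalgamated pairwise and the
product block is ED-amalgamated into its controller, with the product's
embedded vector formed from the child $\phi$s (BD children contribute the
lag vector). A BD node with children blocks of dimensions $d_1 \ldots d_k$
therefore yields $1 + \prod d_i$ states. The canonical seven-character test
hierarchy (three BD, four qualitative) amalgamates in six steps to a
31-state generator. Each step is recorded in a trace so the bookkeeping is
auditable.

Because the exact drawing of that seven-character hierarchy is available
only as a figure, the package encodes the topology (root BD controlling two
BD characters and one qualitative; the first BD controlling two qualitative
characters, the second one) that reproduces both reference quantities — dimension 31 and six steps,
counting each pairwise SMM and each ED amalgamation as one step. This reconstruction is an assumption of the package.

## Named parametrizations

For tree inference the general matrices (5 free parameters for the
tail-colour ED-ql, 4 for tail-armour ED-bd, 7 for the two-level
tail-colour-armour TCA mixture) are overparameterized. The shipped
factories are:

| name | free Q parameters | idea |
|------|----|-------------------------------------------|
| QTC1 | 0 | symmetric 3-state Mk; the only time-reversible member |
| QTC2 | 2 | gain λ (split ½/½ to the colours), loss β, colour change γ, β+λ+γ=1 |
| QTCA1 | 0 | all non-zero TCA rates equal |
| QTCA2 | 0 | all diagonal elements −1, rows rescaled uniformly |
| QTCA3 | 2 | hierarchy growth q2, loss q1, quality change q3 = 1−q1−q2 |

Two parametrization choices are the package's own: QTC1 is the symmetric
Mk matrix (the unique trivially time-reversible member of the family), and
QTC2 splits the gain equally between the colours ($\phi = (1/2, 1/2)$),
which keeps it at two free parameters. Rate matrices are emitted un-normalised; the clock
rate ψ (below) carries the overall scale.

Root frequencies follow one of three policies: **equal**, **equilibrium**
(the stationary distribution of Q, solved densely), or **inferred** (k−1
free simplex parameters under a flat Dirichlet(1, …, 1) prior; the prior
is this package's choice, as the policy is usually stated without one). The grid
ED1–ED8 crosses QTCA1/2/3 with these policies; parameter counts (Q + root
+ clock) reproduce the published table.

## Likelihood

All models are generally time-irreversible (asymmetric rates, structural
zeros), so likelihoods are computed on rooted trees: Felsenstein pruning
with dense matrix exponentials, branch durations = (parent age − child age)
× a global clock rate ψ. Ambiguity sets and "?" enter as indicator vectors;
"-" cells are illegal at likelihood time — hierarchies must first be
recoded into single amalgamated columns (`recode_characters()`), which is
also the published recommendation. Likelihoods are conditioned on variable
characters (the Mkv correction), subtracting the probability mass of the
constant patterns over the model's own state set; a flagged variant
computes the unconditioned likelihood. Rate heterogeneity across
hierarchies (one recoded column each) is available as an optional
discrete-gamma multiplier in `variable_only_loglik()` — four
equal-probability categories by quantile midpoints, normalised to mean
one, averaging both the column likelihood and the constant-pattern mass —
off by default because the benchmark datasets are single-hierarchy. ED models may equivalently be
written with hidden states (to match the state space of structured Markov
models, SMMs): `expand_with_hidden_states()` produces a strongly lumpable
expansion that returns *identical* likelihoods — congruence that the test
suite checks to 1e-10, and that justifies comparing ED and SMM marginal
likelihoods across state spaces.

Numerical choices: the public `transition_probabilities()` uses
scaling-and-squaring Padé (`Matrix::expm`) — no diagonalisability
assumption. The MCMC hot path uses a spectral cache ($P(t) = \sum_m C_m e^{d_m t}$,
one matrix product for all branches), accepted only if it reproduces the
Padé exponential to 1e-9 at construction; defective generators (QTCA2 has
a triple eigenvalue) fall back to uniformization, $P(t) = \sum_n
\mathrm{Pois}(n; qt)\, M^n$, which needs no diagonalizability and is
truncated at machine precision. Pruning scales per pattern column
in log space. Construction-time tolerances are 1e-12 (row sums, simplex
sums) and 1e-10 after exponentiation, separating modelling errors from
floating-point noise.

## Bayesian engine

`ed_mcmc()` samples rooted ultrametric time trees with the root age fixed
at 1.0, a global clock ψ ~ Exponential(10), and a Yule prior on trees —
uniform over ranked labelled histories with the n−2 free node ages iid
$f(s) = \lambda e^{-\lambda s} / (1 - e^{-\lambda})$, the pure-birth
density conditioned on n tips and the root age. The birth rate λ is given
an Exponential(1) hyperprior and sampled; reference analyses in this
setting typically fix the root age without stating a birth-rate prior, so
marginal likelihoods depend on this choice (flagged prominently — see
Limitations). Moves: node-age slides,
rooted NNI, rooted SPR with uniform reattachment height (exact Hastings
ratios), multipliers for ψ and λ, and Dirichlet proposals for rate
simplices and inferred root frequencies. Monophyly constraints restrict
the topology support by rejection, used to hold a reference backbone
resolved (the tail-colour-problem setup). Correctness is checked the
standard way: with zero data the sampler reproduces the prior (KS tests on
ψ and node ages; topology frequencies against the package's independent
forward Yule simulator).

Marginal likelihoods use stepping-stone sampling along Beta(0.3, 1)-spaced
power posteriors (24 stones × 1500 generations by default, warm-started
from the prior side), averaged over two independent runs. The estimator is
validated against direct numerical integration on a fixed-tree,
one-parameter toy problem to 0.05 log units. Summaries: majority-rule
consensus (default burn-in 30%), maximum-clade-credibility trees,
Robinson–Foulds distances (unrooted bipartitions by default), and a paired
bootstrap for differences in exact-recovery proportions.

## Synthetic benchmarks

The package regenerates all of its benchmark data in code:

* **TCA fixture** — 4 taxa × 50 identical four-state columns (aa1, pa1,
  pp1r, pp1b). The published description does not say how taxa map to
  states; one taxon per state is the minimal informative configuration and
  is our assumption — the marginal-likelihood targets depend on it.
* **TCP fixture** — 14 taxa; tailless backbone with a tailed subclade in
  each half; every resolved clade supported by exactly one binary
  synapomorphy ("at least one" published); the left tailed clade (two red,
  two blue) unresolved and supported by 1 or 11 synapomorphies; the
  three-state colour column replicated 50×. The resolved clades are passed
  to the sampler as monophyly constraints, mirroring the published "assumed
  resolved" phrasing; without constraints the 50 identical colour columns
  overwhelm the ten backbone synapomorphies and the posterior groups taxa
  by colour.
* **Simulated-data series** — Yule trees (birth rate 0.1) rescaled to root
  age 1.0 (the dating framework fixes the root age), with ten variable
  TCA-type characters simulated under ED6 per tree. The number of taxa per
  tree is not published; we use 8, a middle ground between the 4-taxon and
  14-taxon fixtures. The published 54% exact-recovery figure therefore
  carries a wide tolerance here.

What a green test establishes: the estimators behave correctly *under this
stated world* — identical replicated columns, one-column hierarchies,
strict clock, no rate variation across characters. Real matrices have
missing data, heterogeneous hierarchies and clock violations that these
fixtures do not emulate.

## Known limitations

* Marginal-likelihood values depend on the Yule hyperprior and the flat
  Dirichlet on rate simplices; with those choices the QTCA1/QTCA2 model
  families reproduce the published table closely, while the QTCA3 family
  lands a few log units higher — consistent with a different (unstated)
  simplex prior in the original analyses. Rankings are unaffected.
* `ed_mcmc()` samples only models whose free rates form a simplex (the
  named families); the general 4–7-parameter matrices are supported for
  likelihood computation and simulation, not MCMC.
* Amalgamations beyond ~12 states per hierarchy warn: the approach is
  intended for moderate-size morphological hierarchies. The molecular case
  (an N-site gene under birth-death) would need $4^N + 1$ states — the
  dimension law is verified for N ≤ 3, and that is the point: the
  construction does not scale to molecules.
* Fossilised birth-death / serially sampled trees, rate variation across
  sites beyond a simple flag, and the switch-type SMM construction are out
  of scope; `make_model("Mk-SMM-sw")` deliberately errors.

## A worked example

```{r, eval = FALSE}
library(edmorph)
tail  <- char_bd("tail", gain = 1, loss = 1)
armor <- char_bd("armor", gain = 1, loss = 1, labels = c("a1", "p1"))
color <- char_ql("color", rate_matrix(rbind(c(-1, 1), c(1, -1)),
                                      labels = c("r", "b")))
tca <- dependency_diagram(list(tail, armor, color),
                          data.frame(from = c("tail", "armor"),
                                     to   = c("armor", "color")))
res <- dda_traverse(tca)
res$trace          # two steps: ED-ql then ED-bd, dimensions 3 then 4
res$Q              # the four-state amalgamated generator
fit <- ed_mcmc(make_tca_fixture(), make_model("ED3"),
               mcmc_config(generations = 30000, seed = 1))
consensus_tree(fit)
```
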