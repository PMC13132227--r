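---
title: "Models and methods: social transmission of novel-food adoption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social transmission of novel-food adoption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cultdiff` analyses two-option cultural diffusion experiments in wild animal
populations: did knowledge about a novel food spread socially, which social
learning strategies shaped the choices of knowledgeable individuals, and is
fine-scale behavioural variation (how the food is processed) socially
structured? This vignette describes the models, their assumptions, the
tunable parameters, and the design decisions behind the implementation. All
empirical statements about performance refer to quantities that the test
suite or `scripts/acceptance.R` compute.

## Association networks

Group scans of foraging subgroups are pooled across observation periods and
converted to a weighted network under the gambit of the group: all
individuals in the same scan are taken to be associating. The dyadic weight
is the simple ratio index,

$$\mathrm{SRI}_{ij} = \frac{x_{ij}}{x_{ij} + y_i + y_j},$$

with $x_{ij}$ the number of joint scans and $y_i$, $y_j$ the scans with
exactly one of the two present. The denominator counts scans in which either
member was recorded anywhere in the shared observation area; it is not
stratified by site, which matches pooling of a common foraging area covered
by all scan locations. Individuals on the roster that were never scanned are
kept as isolated nodes so that diffusion risk sets can include them.

Between-roost movement is the Jaccard overlap of site attendance sets,
$m_{AB} = n_{ov} / (n_A + n_B - n_{ov})$; an individual attending three
sites contributes to all three pairwise overlaps. Roost membership follows a
two-of-three census rule with the marking site as fallback and `"unknown"`
otherwise. No edge threshold is applied anywhere in the analysis; the full
weighted network is used.

## Order-of-acquisition diffusion analysis (OADA)

The diffusion model asks whether the *order* in which naive individuals
first performed the behaviour follows the network. At each acquisition
event, naive individual $i$ has total learning rate

$$R_i = e^{\Gamma x_i}\, s \sum_j a_{ij} z_j + e^{B x_i},$$

with $a_{ij}$ the SRI connection, $z_j$ the informed indicator, $s \ge 0$
the social transmission rate per unit connection relative to the baseline
asocial rate, and $\Gamma$, $B$ coefficients of individual-level variables
(sex coded $-0.5/0.5/0$ for female/male/unknown, age likewise for
juvenile/adult/unknown) on the social and asocial rates. The baseline rate
cancels from the order likelihood, so the asocial null with no covariates
has zero free parameters. Each event contributes
$-\log(R_{learner}/\sum_{naive} R)$, and probabilities over the naive set
sum to one at every event — a property the test suite verifies by summing
the likelihood over all complete orders on small networks.

Fitting maximises the likelihood with $s$ log-parameterised (the $s \ge 0$
constraint is implicit) from several deterministic starting values spanning
$s$ from 0.01 to 1000, which avoids boundary local optima on flat profiles.
Model comparison uses AICc with $n$ = the number of acquisition events, and
Akaike weights summed per family (social vs. asocial) give the support for
social transmission. The percentage of learning events attributed to social
transmission is the mean over observed events of
$social_e / (social_e + asocial_e)$ for the actual learner, with a
confidence interval obtained by re-evaluating that mean at the bounds of a
profile-likelihood interval for $s$ (other parameters re-optimised at each
fixed $s$).

Conventions: trained demonstrators enter risk sets as seeded informed and
never appear as learners; an individual that learned at one site and then
appears at another site's diffusion is treated as informed on arrival
(transmitting, not learning), with arrival defaulting to the diffusion
start. Each diffusion's risk set is the set of individuals recorded at that
site during the experiment, not the whole population.

## Experience-weighted attraction (EWA) models

Informed individuals keep choosing between the two food colours; the EWA
model decomposes each choice into an individual and a social component:

$$\Pr(k) = (1-\gamma_j)\, I_{kj,t} + \gamma_j\, S_{kj,t}.$$

The individual component is a softmax with sensitivity $\lambda$ over
attraction scores updated by reinforcement,
$A_{k,t+1} = (1-\phi) A_{k,t} + \phi\, \pi_t$, with payoff $\pi = 1$ for a
successful opening and 0 otherwise. $\phi = 0$ freezes the initial state;
$\phi = 1$ erases memory. Tutored demonstrators start at $A = 1$ for the
trained colour, everyone else at zero.

The social component summarises the demonstrations observed in the 60 s
before the choice (half-open window $[t-60, t)$, same site only, focal
excluded, unmarked birds included). Five strategy models are implemented:

* **individual_only** — no social component;
* **frequency** — $S_k = N_k^f / \sum_m N_m^f$; $f>1$ conformist, $f=1$
  unbiased, $f<1$ anti-conformist;
* **male_bias**, **age_bias** — unbiased frequency over demonstrations by
  the category only (males, adults);
* **roost_bias** — every demonstration weighted $e^{\beta}$ if the
  demonstrator shares the focal's roost, 1 otherwise (reference category
  fixed so $\beta$ is identified), summed per option and normalised. The
  composition of cue weights with counts is ambiguous in parts of the
  literature; the per-demonstration exponential weighting used here reduces
  exactly to the unbiased frequency model at $\beta = 0$, which the tests
  assert.

When the window holds no usable demonstrations the social term is undefined
(0/0); the implementation returns a sentinel and the choice falls back to
the individual component, equivalent to $\gamma = 0$ for that event. Whether
dropped almonds count as demonstrations is configurable
(`demos = "all"`, the default, or `"successful-only"`); observers see the
pickup and the colour regardless of outcome, hence the default.

### Hierarchical structure and priors

Each active parameter gets a group-level mean per observed (age × sex) cell
— unknown age and unknown sex are modelled levels, and cells without
choosers are dropped — plus a zero-centred individual offset. Links: log for
$\lambda$ and $f$, logit for $\phi$ and $\gamma$, identity for $\beta$.
Priors are weakly informative: Normal(0, 1) for cell means on the link
scale, offsets Normal(0, $\sigma_p$) with $\sigma_p \sim$ Exponential(1).
A priors-only run (`prior_only = TRUE`) reproduces these distributions, which
the test suite checks.

### Sampling

Because the social-window tallies are functions of the observed data alone,
the likelihood factorises over individuals given their parameters. The
package exploits this with an adaptive Metropolis-within-Gibbs sampler over
a compiled likelihood kernel: per sweep it updates each individual's offset
block jointly, each cell mean as a scalar, and each offset scale twice —
once conditionally on the offsets and once through a non-centred rescaling
move that changes $\sigma_p$ while holding $\mathrm{offset}/\sigma_p$ fixed.
The rescaling move is what keeps the sampler mobile when an offset scale is
small (the usual funnel geometry); with it, the centred parameterisation is
used throughout, which keeps all conditional ratios exact and simple.
Proposal scales adapt during warmup towards fixed acceptance targets
(0.3 for blocks, 0.44 for scalars). The `thin` setting (default 10) runs
several full sweeps per stored draw; since the kernel is compiled this buys
effective sample size at negligible cost. The default configuration for
simulation studies is 2 chains × 500 warmup / 500 stored draws; final
inference on real data should use 4 × 1000/1000. Split-chain R-hat and a
truncated-autocorrelation effective sample size are reported, and R-hat
above 1.05 on any group-level parameter triggers a warning rather than a
silent pass. Frequency weights $N^f$ are evaluated on the log scale so that
extreme $f$ proposals cannot overflow.

Model comparison uses WAIC, $-2(\mathrm{lppd} - p_{WAIC})$, computed from
pointwise posterior log-likelihood draws, with standard errors from the
pointwise variance and paired-difference standard errors against the best
model.

## Opening-technique analysis

Each opening sequence is encoded as unshell (0/1) plus one-hot blocks for
the crack location (tip/seam/hilum/middle) and extraction technique
(nibble/split/other); every column is normalised to zero mean and unit
variance (constant columns become zeros), and pairwise Euclidean distances
form the sequence dissimilarity matrix. Duration is excluded by default — in
typical datasets it is coded for a small subset only — and can be included
via `include_duration`.

Predictor matrices are all expressed as dissimilarities so a positive
Mantel correlation means "similar techniques go with similar pairs": same
individual (0/1), great-circle distance between sites, movement
($1 - m/\max m$ over distinct site pairs, same-site pairs 0), association
($1 - \mathrm{SRI}$, same-individual pairs 0, missing dyads `NA`), and
relatedness ($\max r - r$). The partial Mantel test correlates
lower-triangle vectors with the standard partial-correlation formula and
permutes rows and columns of the response matrix simultaneously,
$p = (\#\{r_{perm} \ge r_{obs}\}+1)/(n_{perm}+1)$, one-tailed "greater" by
default because the hypotheses are directional. Missing dyads are deleted
pairwise from the triangle vectors. For $n \le 7$ an exhaustive mode
enumerates all permutations and returns the exact fraction. Two caveats are
documented rather than resolved: repeated sequences per individual make
exchangeability under the identity-control design imperfect, and the
permutation test is approximate for partial correlations in general.
Group-difference post hocs use chi-square tests without continuity
correction (categories exceed two in general) with Bonferroni correction
over categories.

## The synthetic-data generator

The generator emulates the study structure end to end: five roosting sites
at real coordinates (1.5–10 km apart; three main sites carry social data and
diffusions), a roster with age/sex cells drawn at field-study proportions
(including unknown classes), fluid foraging subgroups scanned 864 times by
default, two trained demonstrators per seeded roost (one roost red, one
blue, the third main roost an unseeded control), an acquisition order drawn
from the diffusion model at $s = 5$, daily two-hour sessions in which
informed birds solve in temporal bouts (several birds at the dispenser
within the same minute, so 60 s windows carry a handful of demonstrations),
colour choices from the frequency-dependent EWA process with $\lambda = 2.5$,
$\phi = 0.22$, $\gamma = 0.15$, juvenile $f = 2.0$, adult and unknown-age
$f = 1.0$, individual offsets of sd 0.3 on the link scale, and 90% opening
success. Openings carry site-level technique profiles that drift along the
main geographic axis with individually consistent propensities (1–17
openings per bird, median about 3). Scan membership mixes a home-roost
preference, a distance-decayed movement propensity damped by a
`scan_mixing` factor, and log-normal individual gregariousness; together
these produce the sparse, strongly modular, heavy-tailed association
networks characteristic of fission–fusion foragers. Ten percent of solve
events come from unmarked birds, exercising the rule that such events feed
social windows but contribute no likelihood terms.

What the generator does *not* emulate: innate colour preferences (the
choice process is symmetric in the options), demographic turnover,
within-day movement between sites during a session, observation error in
scans, and payoff differences between options. Passing recovery tests on
these data therefore shows that the estimators are consistent with their
own generative assumptions at study scale — not that those assumptions hold
for any particular field dataset.

## Problem sizes, information limits, and known limitations

The validation suite runs at deliberately chosen scales: diffusion
discrimination uses 20 replicate diffusions over 60 individuals on sparse
modular networks (about 38 acquisition events each); EWA recovery uses 60
individuals × ~30 choices at reduced sampling; Mantel calibration uses 500
null replicates at $n = 20$ with 199 permutations, plus exact enumeration at
$n = 5$; technique-gradient detection uses about 40 individuals and 120–140
sequences per replicate.

One information limit deserves emphasis. With the social weight at
$\gamma = 0.15$, the conformity exponent moves each choice probability by at
most a few percentage points, so roughly 900 juvenile choices carry only a
fraction of a log-likelihood unit separating $f = 2$ from $f = 1$. At the
60 × 30 scale the posterior for a juvenile cell's $f$ therefore remains wide
(sd of $\log f$ around 0.6–0.8), the posterior mass above 1 fluctuates
between roughly 0.6 and 0.9 across simulation seeds, and WAIC margins
between the frequency model and its competitors are only a few units.
Detecting age-dependent conformity crisply requires event counts several
times larger (the machinery does sharpen correctly as data grow, which the
development checks at 60 × 200 choices confirmed). Consumers of the
frequency-model output at small scales should read `prop_above` values near
0.5 as "uninformative", not as evidence against conformity. A related
geometry effect biases weakly informed individual $f$ draws towards
anti-conformity (at $f \to 0$ the social term hedges to 0.5, which is safer
under a flat likelihood), so group-level $f$ means shrink slightly below
their generative values in small samples.

Other limitations: only two options are supported in the I/O layer
(internals are K-generic); time-of-acquisition diffusion variants, dynamic
networks and Bayesian NBDA are out of scope; the asocial baseline rate is
not estimable from order data by construction; and the Mantel analysis does
not implement MRQAP-style multiple regression.

## Interfaces

All inputs are plain CSV (`individuals.csv`, `scans.csv`, `events.csv`,
`diffusion.csv`, `openings.csv`, `sites.csv`) with readers that validate
schemas and category levels. `validate_inputs()` checks a bundle with
row-level messages; `run_pipeline()` executes the staged analysis and
returns (optionally writes as JSON) a self-describing report with seeds and
convergence diagnostics; `simulate_all()` writes a complete synthetic bundle
plus a `truth.json` sidecar for recovery testing. These functions, together
with the exported building blocks, are the package's interface; there is no
separate shell executable.
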