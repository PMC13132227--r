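# cultdiff

Analysis toolkit for two-option cultural diffusion experiments in wild
animal populations — the kind of field study in which a few trained
demonstrators are seeded into communally roosting groups, a novel food
(offered in two colour variants) is presented daily, and every pickup is
video-coded. The package answers three questions about such data:

1. **Did knowledge spread socially?** Group scans are turned into a weighted
   association network (simple ratio index, gambit of the group), and an
   order-of-acquisition diffusion analysis (OADA) asks whether the order in
   which naive individuals first performed the behaviour follows network
   ties. At each acquisition event the rate for naive individual *i* is

   *R<sub>i</sub>* = e<sup>Γx<sub>i</sub></sup> · *s* · Σ<sub>j</sub> a<sub>ij</sub> z<sub>j</sub> + e<sup>Bx<sub>i</sub></sup>,

   with *s* the social transmission rate per unit connection, a<sub>ij</sub>
   the dyadic association, z<sub>j</sub> the informed indicator, and Γ, B
   age/sex effects on the social and asocial rates. Models in all covariate
   combinations, with and without the network, are compared by AICc, and
   the fitted model yields the percentage of learning events attributable
   to social transmission with a profile-likelihood interval.

2. **Which social learning strategies shape the choices of knowledgeable
   birds?** An experience-weighted attraction (EWA) model mixes a
   reinforcement-learning individual component (softmax with sensitivity λ
   over attractions updated as A ← (1−φ)A + φπ) with a social component
   computed from the demonstrations seen in the previous 60 s, weighted by
   γ. Five strategy models — individual-only, frequency-dependent
   (conformity exponent *f*), male-biased, adult-biased, and same-roost
   biased copying — are fitted hierarchically (age × sex cell means plus
   individual effects) with an adaptive MCMC sampler over a compiled
   likelihood, and compared by WAIC.

3. **Are food-processing techniques socially structured?** Opening
   sequences (unshell / crack location / extraction technique) are encoded,
   pairwise Euclidean dissimilarities computed, and partial Mantel
   permutation tests relate technique dissimilarity to individual identity,
   geographic distance, between-roost movement, association strength and
   relatedness, with chi-square post hocs for group differences.

A synthetic-data generator (`simulate_all()`) produces every input the
pipeline consumes — roster, scans, diffusion records, choice events,
opening sequences, site coordinates — from a known ground truth, and the
test suite validates the estimators against it end to end.

## Worked example

```r
library(cultdiff)

cfg <- synthetic_config(n_per_roost = 15, n_scans = 120, mean_group_size = 8,
                        n_sessions = 4, seed = 42)
bundle <- simulate_all(cfg)
print(bundle$network)
#> Association network: 75 individuals, 120 scans
#>   non-zero dyads: 902 / 2775, mean SRI (non-zero): 0.105

print(bundle$record)
#> site CG: 12 learners / 20 at risk (2 seeded informed)
#> site BA: 9 learners / 24 at risk (10 seeded informed)
#> site NB: 7 learners / 14 at risk (3 seeded informed)
```

Two demonstrators were seeded at CG and BA; the control roost NB has no
trained birds, and the informed individuals it lists were "movers" that
learned elsewhere and arrived knowledgeable (they transmit but are not
counted as learners). Fitting the diffusion models:

```r
ilvs <- ilv_design(bundle$roster)
social  <- fit_oada(bundle$record, bundle$network, ilvs)
asocial <- fit_oada(bundle$record, bundle$network, ilvs, social = FALSE)
tab <- aicc_model_table(list(social, asocial))
print(tab, digits = 3)
#>     model social k logLik AICc dAICc weight
#> 1  social   TRUE 1  -60.7  124  0.00 0.9415
#> 2 asocial  FALSE 0  -64.5  129  5.56 0.0585

ps <- percent_social(social, bundle$record, bundle$network, ilvs)
#> %ST = 74.8% (95% CI 28.3-94.7), generative 77.6%
```

The social model carries 94% of the Akaike weight, and an estimated 74.8%
of acquisition events are attributed to the social term — close to the
generator's realised 77.6%. At this deliberately tiny scale (28 learning
events) the profile interval is wide; full-scale runs tighten it.

The EWA and technique stages follow the same pattern:

```r
fit <- fit_ewa(bundle$events, bundle$roster, strategy = "frequency",
               chains = 2, warmup = 500, samples = 500, seed = 1)
posterior_summary(fit)          # per age x sex cell, incl. Pr(f > 1)
waic_table(list(freq = fit, ind = fit_ewa(bundle$events, bundle$roster,
                                          "individual_only", seed = 1)))

ops <- bundle$openings
D <- sequence_dissimilarity(encode_sequences(ops))
partial_mantel(D,
               build_predictor_matrix(ops, "site_distance", sites = cfg$sites),
               build_predictor_matrix(ops, "same_individual"),
               n_perm = 999, seed = 1)
```

`run_pipeline()` chains all stages and returns a machine-readable report;
`validate_inputs()` checks a CSV bundle before analysis.

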