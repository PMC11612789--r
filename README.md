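# shrewvoc

Vocal-repertoire analysis for the Etruscan shrew (*Suncus etruscus*) and
similar high-frequency callers, for bioacousticians who need to go from raw
192–200 kHz WAV recordings (or a fully synthetic stand-in) to a
classified, context-annotated repertoire with calibrated statistics.

Etruscan shrews vocalize between ~5 and 100 kHz in four call types: long
tonal **screams**, noisy tremolo **screeches**, short modulated **chirps**,
and the graded **screech-scream** that mixes tonal and noisy segments. The
scientific question the pipeline serves is whether such a repertoire is
discrete, graded, or both — and in which social contexts each type is used.

## What the package computes

1. **Call units** from the energy envelope (continuous sound energy;
   sub-50 ms gaps merged for pups).
2. **22 acoustic parameters** per high-quality call — duration, time of
   peak amplitude, voiced percentage, harmonics-to-noise ratio, Wiener
   entropy, spectral moments, F0-contour statistics (tonal calls), and
   LPC formant-like resonances (non-tonal/mixed calls, ceiling from a
   1.2 cm vocal tract).
3. **Soft clustering**: z-scored all-call parameters → 2-D UMAP → fuzzy
   c-means, implemented in-package. With membership values
   *u<sub>ik</sub>* = [Σ<sub>j</sub> (d<sub>ik</sub>/d<sub>jk</sub>)<sup>2/(μ−1)</sup>]<sup>−1</sup>
   (c = 3, μ = 2), each call gets a degree of belonging to every cluster.
4. **Gradation**: typicality coefficient = largest − second-largest
   membership; tercile thresholds split calls into typical / neither /
   atypical.
5. **Call types** from voiced-percentage boundaries: ≥ 95 % tonal in the
   long-tonal cluster → scream; exactly 0 % in the noisy cluster →
   screech; anything in between → screech-scream; short-tonal cluster →
   chirp.
6. **Context statistics**: ethogram alignment (interactions beat position
   events), context and proximity shares, call rates (N/min), ML linear
   mixed models with two crossed per-dyad random intercepts,
   Satterthwaite F-tests, Tukey-adjusted least-squares means, Fisher
   Omnibus combination, Cohen's kappa, and backward stepwise elimination
   of interaction terms.

A seeded synthetic-call generator (`generate_experiment()`) produces
waveforms of all four types with known ground truth, behavior-event
streams and dyad metadata, so the entire chain is testable without any
field data.

## Worked example

```r
library(shrewvoc)

res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
Shrew vocal repertoire pipeline result
  calls measured: 608
  clusters: 3 | roles: long_tonal, short_tonal, noisy
call_type
        scream        screech screech_scream          chirp
           208            200            100            100
  typicality thresholds: atypical < 0.881 , typical > 0.96
  agreement with ground truth: kappa = 1 , ARI = 1
```

Reading this: 608 calls were detected and measured (600 open-door calls
plus 8 closed-door screams); the three soft clusters were identified as
the long-tonal (scream), noisy (screech) and short-tonal (chirp) clusters;
the voiced-percentage boundaries recovered every generated call type
(kappa = 1 against the generator's labels, adjusted Rand index 1 for the
discrete calls' cluster assignment). The typicality thresholds are the
terciles of the coefficient distribution; graded screech-screams
concentrate below the atypicality threshold — the signature of a graded
call type:

```r
tapply(res$typicality$typicality_coefficient,
       res$call_types$call_type, mean)
#>         scream        screech screech_scream          chirp
#>      0.8088119      0.9453248      0.6172457      0.9912091
```

Context tables live in `res$context`: `behavior_shares` (100 % of
caravanning calls are chirps; socio-negative interactions are dominated by
screams/screeches/screech-screams), `proximity_shares`, `call_rates`, and
`rate_models` — the backward-eliminated mixed models per call type, which
recover the generator's built-in effects (higher chirp rates in
male–female dyads, higher socio-negative call rates in pair-housed dyads).

Recordings mode ingests real data instead:

```r
cfg <- pipeline_config(
  mode = "recordings",
  paths = list(recordings = c(exp01 = "exp01.wav"),
               annotations = c(exp01 = "exp01_behavior.TextGrid"),
               dyads = "dyads.csv"))
res <- run_pipeline(cfg)
```

A thin CLI wraps the same functions:
`Rscript inst/cli/shrewvoc.R run-all --seed 1 --out results/`.

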