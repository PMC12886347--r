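# formantcomp

Analysis tools for **compensation-paradigm auditory feedback experiments** on
vowel formants. In these experiments a speaker repeatedly produces a vowel
(here /ɛ/ in hVC words) while their auditory feedback is perturbed in the
F1–F2 plane on randomly interspersed trials. Because perturbations are rare
and flanked by unperturbed trials, the paradigm separates two error-driven
processes of speech motor control:

- the **corrective response** — the within-trial, feedback-driven formant
  change, measured as the mean formant change in the late vowel window
  (300–400 ms) minus the early window (0–100 ms) of a perturbed trial;
- the **adaptive response** — one-shot feedforward learning, measured as the
  early-window (0–100 ms, feedback-free) formant change of the unperturbed
  trial *after* a perturbation relative to the one *before* it.

The package is aimed at speech motor control researchers who design such
experiments and analyse their trajectory exports — and at methodologists who
want a fully simulated test bed with known ground truth.

## What it implements

**Participant-specific geometry.** Vowel centroids are componentwise medians
of repeated pre-test productions of /ɪ/, /ɛ/, /æ/ (`ih`, `eh`, `ae`). With F1
on the abscissa and F2 on the ordinate, the ɛ–æ distance and angle define the
perturbation configurations: the `eps_to_ae` perturbation shifts /ɛ/ along
the ɛ→æ line (F1 up, F2 down), and `eps_to_out` along its perpendicular with
positive F2 component (F1 up, F2 up — out of the vowel space), at 0.5×, 1.0×
or 1.5× the ɛ–æ distance.

**Trial schedules.** Blocks of 120 trials (108 word + 12 sentence trials, two
sentence trials after every 18 word trials) with 18 perturbed word trials
(6 per magnitude) placed uniformly at random subject to ≥ 2 unperturbed word
trials before every perturbed one; sessions of 7 blocks (42 perturbed trials
per magnitude), two counterbalanced sessions per participant.

**Trajectory pipeline.** Word-specific, time-normalised baselines (100-point
linear resampling of eligible unperturbed trials, excluding trials that
immediately follow a perturbation), baseline stretching and subtraction,
exclusion of trials shorter than 400 ms, and half-open window means.

**Response metrics.** Corrective and adaptive responses per trial, in Hz and
as a percentage of the trial's Euclidean perturbation magnitude, plus the
response angle relative to the participant's ɛ–ɪ axis
(vector-average-then-angle for condition summaries).

**Statistics.** Circular mean, mean resultant length, angular deviation
`s = sqrt(2(1 − R̄)) ∈ [0, √2]`, and a 10,000-shuffle label-permutation test
for direction differences in circular mean and angular deviation (two-sided,
add-one convention); a priori one-sample t-tests; random-intercept mixed
models `response ~ direction × magnitude × exposure + (1 | participant)`
with Satterthwaite Type-III tests and Benjamini–Hochberg FDR within each
model; Pearson corrective–adaptive correlations. Exposure halves split the
126 perturbed trials of a session 63/63 ("3.5 blocks" each: block 4 splits
at its 9th perturbed trial).

**Synthetic speaker.** A generative trial model with vowel-onset consonant
transitions, duration variability (450–650 ms), a latency-ramped corrective
response whose direction mixes the anti-perturbation axis with the ɛ–ɪ axis
(bias β), one-shot adaptive updating, exposure decay of the corrective gain,
and trial/sample noise — so every pipeline stage can be verified against
closed-form ground truth.

## Worked example

```r
library(formantcomp)

pretest <- read_pretest(system.file("extdata", "pretest_synthetic.tsv",
                                    package = "formantcomp"))
sp <- vowel_space(pretest)
sp
#> Vowel space (Hz)
#>       f1     f2
#> ih 415.9 2061.6
#> eh 585.8 1810.9
#> ae 740.9 1668.0
#> eh-ae distance: 210.89 Hz
#> eh-ae angle:    -42.66 deg
#> eh-ih angle:    124.13 deg

make_perturbation(sp, "eps_to_ae", 1.0)
#> Perturbation eps_to_ae, scale 1.0: (dF1, dF2) = (155.1, -142.9) Hz, |v| = 210.9 Hz
make_perturbation(sp, "eps_to_out", 0.5)
#> Perturbation eps_to_out, scale 0.5: (dF1, dF2) = (71.5, 77.6) Hz, |v| = 105.4 Hz

sched <- generate_session("eps_to_ae", n_blocks = 7, seed = 42)
sim   <- simulate_session(sched, speaker_params(centroids = sp$centroids),
                          seed = 43)
proc  <- process_session(sim)
proc
#> Processed session: 756 word trials kept, 0 excluded (0.0%)

resp <- compute_responses(proc, sim)
head(as.data.frame(resp), 3)
#>   block index       kind direction magnitude_scale   f1_hz  f2_hz f1_pct
#> 1     1     5 corrective eps_to_ae             1.0 -19.696 33.226 -9.339
#> 2     1     5   adaptive eps_to_ae             1.0  13.039 -1.404  6.183
#> 3     1    24 corrective eps_to_ae             0.5  -7.014 11.778 -6.652
#>    f2_pct rel_angle
#> 1 15.7550    -3.468
#> 2 -0.6657  -130.271
#> 3 11.1698    -3.350

corr <- as.data.frame(resp[resp$kind == "corrective", ])
condition_average_angle(corr$f1_hz, corr$f2_hz, sim$space$eps_ih_angle)
#> [1] -0.63
```

Reading the output: the perturbation raised F1 and lowered F2 (toward /æ/);
the per-trial corrective responses lower F1 and raise F2 — they oppose the
perturbation, here ~9–16 % of its magnitude — and the condition-average
response angle of −0.6° says the mean corrective vector points almost
exactly along this speaker's ɛ–ɪ axis (the simulated speaker's direction
bias is β = 0.8). The adaptive row is a single noisy one-shot trial; only
its average over many triads is interpretable.

The full multi-participant study — simulation, processing, mixed models,
circular statistics and permutation tests in one call — is:

```r
an <- run_pipeline(pipeline_config(n_participants = 30, seed = 1))
summary(an)
```

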