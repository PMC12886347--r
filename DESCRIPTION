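Package: formantcomp
Title: Analysis of Formant-Perturbation Compensation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing auditory-feedback compensation
    experiments in which vowel formants (F1/F2) are perturbed on randomly
    interspersed trials. Computes participant-specific vowel-space geometry and
    perturbation vectors, generates constraint-satisfying trial schedules,
    simulates formant trajectories from a generative speaker model with known
    ground truth, performs time-normalised baseline subtraction of trajectories,
    derives within-trial corrective and between-trial adaptive responses with
    normalised amplitudes and response angles, and provides circular statistics
    (circular mean, angular deviation, label-shuffling permutation tests),
    random-intercept mixed models, FDR adjustment and correlation analyses for
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
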