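Package: tworate
Title: Two-Rate State-Space Modelling of Trial-by-Trial Visuomotor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-by-trial visuomotor adaptation experiments
    with interleaved test trials. Simulates and fits the two-rate (slow/fast) and
    one-rate state-space models of motor adaptation with grid-search multi-start
    least squares, compares candidate models by AIC and relative likelihood, fits
    an exponential-decay-with-asymptote model to estimate per-trial rates of
    change with participant-level bootstrap confidence intervals and saturation
    trials, and fits proportional models of hand-localization shift against the
    visual-proprioceptive discrepancy. Includes a synthetic-cohort generator that
    emulates the interleaved training/test paradigm (aligned, rotated,
    counter-rotated and error-clamp phases) so the full pipeline can be exercised
    and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
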