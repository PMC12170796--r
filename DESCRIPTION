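Package: dyadsync
Title: Dyadic Smiling and Heart-Rate Synchrony with Pseudo-Pair Nulls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating interpersonal synchrony in dyadic
    interaction studies. Implements preprocessing of facial-expression and
    heart-rate time series (integer rounding, short rolling-mean smoothing,
    autoregressive prewhitening), global and windowed cross-lagged
    correlation (WCLC) synchrony estimates, construction of pseudo-pair
    surrogate nulls, and the statistical models linking synchrony and
    experimental condition to relational outcomes (dyad-level change-score
    regressions, dyadic mixed models, Bonferroni-corrected pair versus
    pseudo-pair contrasts). A synthetic-study generator emulates the
    speed-dating-style pairing design, bursty bounded smile signals with
    probabilistic mimicry, heart rate with initial arousal decay and
    optional coupling, and pre/post outcomes with a known dependence on
    latent coupling, so every stage is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    zoo
VignetteBuilder: knitr
Config/testthat/edition: 3
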