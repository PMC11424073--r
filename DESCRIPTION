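Package: trendcircuit
Title: Trend Anticipation by a Two-Timescale Moving-Average Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates stochastic environmental trends (exponentially
    smoothed random walks), integrates a minimal two-state linear circuit
    whose fast-minus-slow exponential moving-average difference (a
    MACD-style momentum signal) predicts the next direction of change,
    scores prediction accuracy against the intrinsic sign-persistence
    ceiling of the input process, and tunes the circuit's production and
    decay rates by Nelder-Mead optimization, including an
    accuracy-versus-robustness objective. All simulators are seeded and
    fully reproducible; results are tidy tibbles with broom-style tidy()
    and glance() methods and ggplot2 autoplot() graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
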