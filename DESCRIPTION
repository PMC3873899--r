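Package: corsens
Title: Correlation-Signature Prediction of Drug Sensitivity from
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains feature-by-drug Pearson correlation signatures of drug
    sensitivity on panels of profiled cell lines, scores test samples
    (cell lines or tumors) by correlating their expression profiles
    against each drug's signature, averages predictions across molecular
    platforms (gene array, RNA-seq, RPPA), and evaluates predicted
    rankings with tie-aware concordance indices against a permutation
    chance baseline.  Includes significance-based feature filters,
    recurrent-correlate selection, cross-dataset signature projection,
    a latent-factor simulator for multi-platform pharmacogenomic data,
    broom-style tidiers, ggplot2 autoplot methods, and a configurable
    pipeline runner with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
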