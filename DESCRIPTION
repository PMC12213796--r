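Package: critowa
Title: CRITIC Criterion Weighting with Induced Probabilistic OWA Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks decision alternatives from a criteria matrix with the
    CRITIC objective-weighting scheme and an induced probabilistic ordered
    weighted averaging (IPOWA) extension. Provides the OWA operator family
    (plain, probabilistic, induced, induced probabilistic), OWA-weighted
    second moments and correlation operators (variance-OWA, covariance-OWA,
    Pearson-OWA/-POWA/-IPOWA), the full IPOWA-CRITIC pipeline with its S, W
    and S-W scoring extensions, baseline multicriteria methods (classic
    CRITIC, SAW, TOPSIS, VIKOR) with Spearman rank agreement, CSV/JSON
    workbench tooling, a command-line interface, and a packaged
    greenhouse-tomato sustainability case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
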