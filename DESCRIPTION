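Package: sqev
Title: Effect Enumeration, Randomization and External Validity via Sample Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric estimation of intervention effects and of their
    generalizability (external validity) from observational samples of binary
    factors. Enumerates Latin-square-like arrangements of sample units around
    reference units, turning across-unit differences into effect observations
    under enumerated backgrounds; computes background-averaged effects, their
    inverse-variance external validity, and cause/confounder/spurious
    classifications; provides ordinal gap statistics with stationarity and
    randomization tests based on permutation inversions, exact combinatorial
    counts (derangements, enumeration ratios, modular sampling sequences,
    golden-ratio sample-size rules), reference estimators (g-formula,
    difference in means, Sobol index, Shapley importance), and synthetic data
    generators with known ground truth for balanced, unbalanced, correlated
    and non-stationary regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
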