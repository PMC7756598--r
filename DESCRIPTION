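Package: predtest
Title: Prediction-Based Global Hypothesis Test for Multiple Correlated Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a global hypothesis test for studies with multiple
    correlated endpoints based on a priori directional predictions. Each
    endpoint's prediction outcome is weighted by the inverse sum of its squared
    pairwise correlations, so that the weighted count of correct predictions
    measures the number of effective (quasi-independent) endpoints correctly
    predicted. Provides the exact enumerated null distribution of the weighted
    statistic, a normal approximation for many endpoints, O'Brien's ordinary
    least squares global test as a comparator, a vine-method generator of
    random correlation matrices uniform over the positive-definite space, and
    a simulation suite for power, type-I error, sample-correlation sensitivity
    and approximation-accuracy studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
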