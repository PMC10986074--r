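Package: allofrac
Title: Allometric-Aggregation Fractal Complexity of Physiological Count Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the fractal dimension of uniformly sampled physiological
    count time series (such as minute-epoch actigraphy activity counts) with
    the allometric aggregation family of methods: the classic static estimator
    (non-overlapping block aggregation with a straight-line log-log
    mean-variance fit), an adapted estimator using a geometric scale schedule,
    overlapping blocks and a cubic log-log fit whose derivative yields a
    scale-local fractal dimension, and a sliding-window temporal extension
    that turns the fractal dimension into a time series. Includes weekly
    summary statistics, complexity-activity correlation, small-sample rank
    correlation against ordinal functioning ratings, seeded synthetic signal
    generators (i.i.d. counts, ramps, AR(1), exact fractional Gaussian noise
    via circulant embedding, diurnal activity-like fixtures), delimited-text
    readers and writers, and diagnostic plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
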