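Package: pcaFE
Title: PCA-Based Unsupervised Feature Extraction for Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("pcaFE", "Maintainers", email = "maintainers@pcafe.invalid", role = c("aut", "cre"))
Description: Selects microarray probes whose expression tracks incubation time
    by decomposing a standardized probes-by-samples expression matrix with the
    singular value decomposition, regressing each sample-loading component on
    time, and scoring probes on the time-associated components with a
    chi-squared statistic under a Gaussian null, with Benjamini-Hochberg
    control of the false discovery rate. Includes a per-probe linear-regression
    baseline, a reader and writer for the GEO series-matrix dialect, a
    synthetic time-course generator with planted linear trends for power and
    calibration studies, and command-line entry points with reproducible run
    manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
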