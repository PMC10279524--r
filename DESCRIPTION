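Package: jumpfdr
Title: Replicability Analysis of Two High-Throughput Studies via the
    Maximum P-Value with Composite-Null FDR Control
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies features (e.g. genes) with replicable signal across
    two independent high-throughput studies from their paired p-value
    sequences. Models the joint hidden states of each feature with a
    four-group mixture, bounds the distribution of the maximum p-value
    under the composite replicability null, and controls the false
    discovery rate with a step-up procedure driven by a conservative
    plug-in FDR estimate. Null-state proportions are estimated by
    Storey-type tail estimators with smoothing-spline selection of the
    tuning parameter. Includes standard comparator procedures
    (Benjamini-Hochberg on max p-values, ad hoc intersection of per-study
    discoveries, Sidak and Lancaster/Fisher p-value combination), a
    Monte-Carlo simulation harness for empirical FDR and power, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
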